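#' Validate a run configuration
#'
#' Reads a YAML key-value configuration file, applies the pipeline defaults
#' (partition thresholds 0.99 / 0.95 / 0.15, clustering cascade 0.90, 0.80,
#' 0.75, 0.70, minimum edge weight 1, seed 42) and validates all settings
#' together, reporting every violation in a single error.
#'
#' Recognised keys: \code{gff_dir}, \code{proteins}, \code{out_dir}
#' (required paths), \code{thresholds} (cascade identity list),
#' \code{retention}, \code{hard}, \code{soft}, \code{shell}, \code{w_min},
#' \code{templates}, \code{circular_contigs}, \code{id_attribute},
#' \code{max_insertion_len}, \code{max_cycle_len}, \code{seed}.
#'
#' @param path path to a YAML configuration file (an empty file is valid and
#'   yields all defaults, given valid paths supplied another way)
#' @param overrides named list merged over the file's settings (e.g. from
#'   command-line flags)
#' @return a validated \code{run_config} list
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_pg("config file not found: %s", path)
    cfg <- yaml::read_yaml(path) %||% list()
  }
  cfg[names(overrides)] <- overrides
  defaults <- list(thresholds = c(0.90, 0.80, 0.75, 0.70),
                   retention = "protein_count",
                   hard = 0.99, soft = 0.95, shell = 0.15,
                   w_min = 1L, id_attribute = "ID",
                   max_insertion_len = 10L, max_cycle_len = 100L,
                   seed = 42L,
                   templates = NULL, circular_contigs = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[k] <- defaults[k]

  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  for (k in c("gff_dir", "proteins")) {
    need(!is.null(cfg[[k]]) && file.exists(cfg[[k]]),
         sprintf("%s: missing or nonexistent path", k))
  }
  need(!is.null(cfg$out_dir), "out_dir: not set")
  th <- as.numeric(cfg$thresholds)
  need(all(th > 0 & th <= 1), "thresholds: must lie in (0, 1]")
  need(length(th) < 2 || all(diff(th) < 0), "thresholds: must be strictly decreasing")
  need(cfg$shell > 0 && cfg$shell < cfg$soft && cfg$soft < cfg$hard &&
         cfg$hard <= 1,
       sprintf("partition thresholds: need 0 < shell < soft < hard <= 1 (got %s/%s/%s)",
               cfg$hard, cfg$soft, cfg$shell))
  need(cfg$w_min >= 1, "w_min: must be >= 1")
  need(cfg$retention %in% c("protein_count", "genome_count"),
       "retention: must be protein_count or genome_count")
  for (k in c("templates", "circular_contigs")) {
    if (!is.null(cfg[[k]])) need(file.exists(cfg[[k]]),
                                 sprintf("%s: file not found", k))
  }
  if (length(problems)) {
    stop_pg("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  cfg$thresholds <- th
  cfg$w_min <- as.integer(cfg$w_min)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Chains the stages: protein clustering (iterative cascade), strain-graph
#' construction, pangenome graph with paralog subcluster splitting and
#' partition assignment, optional chromosomization against template
#' genomes, and pattern detection. Writes to \code{cfg$out_dir}: the cluster
#' file and representative FASTA, one strain GraphML per genome, the
#' pangenome GraphML, the presence/absence TSV, all pattern outputs, and a
#' run log recording parameters and per-stage element counts. The log
#' carries no timestamps, so a rerun with the same inputs and seed
#' reproduces every output byte for byte.
#'
#' @param cfg a \code{run_config} from [validate_config()], or a path to a
#'   YAML config file
#' @return invisibly, a list with the pipeline objects (\code{cluster_set},
#'   \code{strain_graphs}, \code{pangenome}, \code{report},
#'   \code{chromosomes}) and \code{paths}
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- c("pangraphr run log",
           sprintf("package_version\t%s",
                   as.character(utils::packageVersion("pangraphr"))),
           sprintf("seed\t%d", cfg$seed),
           sprintf("thresholds\t%s", paste(cfg$thresholds, collapse = ",")),
           sprintf("partitions\t%s/%s/%s", cfg$hard, cfg$soft, cfg$shell),
           sprintf("w_min\t%d", cfg$w_min),
           sprintf("retention\t%s", cfg$retention))
  stage <- "read_inputs"
  res <- tryCatch({
    records <- read_gff3_dir(cfg$gff_dir, id_attribute = cfg$id_attribute)
    proteins <- read_protein_fasta(cfg$proteins)
    n_genomes <- length(records)
    log <- c(log, sprintf("genomes\t%d", n_genomes),
             sprintf("proteins\t%d", length(proteins)))

    stage <- "cluster"
    cs <- iterative_cluster(
      proteins,
      cascade_config(n_genomes = n_genomes, thresholds = cfg$thresholds,
                     retention = cfg$retention, seed = cfg$seed),
      genome_of = protein_genomes(records))
    log <- c(log, sprintf("clusters\t%d", nrow(cs$clusters)),
             sprintf("clustered_proteins\t%d", length(cs$cluster_of)))
    products <- setNames(
      unlist(lapply(records, `[[`, "product"), use.names = FALSE),
      unlist(lapply(records, `[[`, "locus_id"), use.names = FALSE))
    write_cluster_file(cs, file.path(out, "clusters.tsv"))
    write_representative_fasta(cs, proteins,
                               file.path(out, "representatives.faa"),
                               products = products)

    stage <- "build"
    circ <- character(0)
    if (!is.null(cfg$circular_contigs)) {
      circ <- read.delim(cfg$circular_contigs,
                         stringsAsFactors = FALSE)$contig_id
    }
    sgs <- build_strain_graphs(records, cs$cluster_of, circular = circ)
    bp <- build_pangenome(sgs, w_min = cfg$w_min,
                          thresholds = partition_thresholds(cfg$hard, cfg$soft,
                                                            cfg$shell),
                          cluster_set = cs)
    pg <- bp$pangenome; sgs <- bp$strain_graphs
    log <- c(log, sprintf("pangenome_nodes\t%d", igraph::vcount(pg)),
             sprintf("pangenome_edges\t%d", igraph::ecount(pg)))
    for (p in c("hard_core", "soft_core", "shell", "cloud")) {
      log <- c(log, sprintf("partition_%s\t%d", p,
                            sum(igraph::V(pg)$partition == p)))
    }

    stage <- "chromosomize"
    chromosomes <- NULL
    if (!is.null(cfg$templates)) {
      templates <- read_templates(cfg$templates)
      chromosomes <- assign_chromosomes(templates, sgs, pg)
      ann <- chromosomize_graphs(chromosomes, sgs, pg)
      pg <- ann$pangenome; sgs <- ann$strain_graphs
      log <- c(log, sprintf("chromosome_classes\t%s",
                            paste(sprintf("%s=%d", names(table(chromosomes)),
                                          table(chromosomes)), collapse = ",")))
    }

    stage <- "write_graphs"
    dir.create(file.path(out, "strain_graphs"), showWarnings = FALSE)
    for (sg in sgs) {
      write_graphml(sg, file.path(out, "strain_graphs",
                                  paste0(igraph::graph_attr(sg, "genome_id"),
                                         ".graphml")))
    }
    write_graphml(pg, file.path(out, "pangenome.graphml"))
    write_presence_absence(pg, file.path(out, "presence_absence.tsv"))

    stage <- "patterns"
    report <- detect_patterns(pg, max_insertion_len = cfg$max_insertion_len,
                              max_cycle_len = cfg$max_cycle_len)
    write_pattern_outputs(report, pg, file.path(out, "patterns"))
    log <- c(log,
             sprintf("orphans\t%d", length(report$orphans)),
             sprintf("uniques\t%d", length(report$uniques)),
             sprintf("variant_groups\t%d", length(report$variants)),
             sprintf("insertion_nodes\t%d", nrow(report$insertions)),
             sprintf("indel_cycles\t%d", length(report$indels)))

    list(cluster_set = cs, strain_graphs = sgs, pangenome = pg,
         report = report, chromosomes = chromosomes,
         paths = list(out = out,
                      clusters = file.path(out, "clusters.tsv"),
                      representatives = file.path(out, "representatives.faa"),
                      pangenome = file.path(out, "pangenome.graphml"),
                      presence_absence = file.path(out, "presence_absence.tsv"),
                      patterns = file.path(out, "patterns"),
                      log = file.path(out, "run_log.tsv")))
  }, error = function(e) {
    log <- c(log, sprintf("failed_stage\t%s", stage),
             sprintf("error\t%s", conditionMessage(e)))
    write_lines_det(log, file.path(out, "run_log.tsv"))
    stop_pg("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  write_lines_det(log, file.path(out, "run_log.tsv"))
  invisible(res)
}
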