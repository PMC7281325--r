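#' Pipeline configuration
#'
#' Collects input paths, the column dialect, the comparison design, analysis
#' thresholds and the output directory for a full run. Can be built from a
#' YAML file or from arguments; thresholds are validated up front so an
#' invalid configuration fails before any stage runs.
#'
#' @param phospho_tables named character vector or list: time point ->
#'   phosphosite TSV path. Exactly three time points.
#' @param expression,samples paths to the log2 expression matrix and sample
#'   sheet TSVs.
#' @param edges optional edge-list TSV path.
#' @param gene_sets optional GMT path for enrichment.
#' @param kinases optional path to a one-column text file of kinase symbols.
#' @param out_dir output directory.
#' @param class1_threshold localization threshold in (0, 1), default 0.75.
#' @param cutoff regulation cutoff > 1, default 1.5.
#' @param q_max FDR threshold in (0, 1), default 0.05.
#' @param fc_min expression fold-change threshold > 1, default 2.
#' @param min_overlap 2 or 3 concordant time points, default 2.
#' @param prior_df variance-shrinkage prior degrees of freedom, >= 0.
#' @param design a [comparison_design()].
#' @param dialect a [phospho_dialect()].
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(phospho_tables, expression, samples,
                            edges = NULL, gene_sets = NULL, kinases = NULL,
                            out_dir = "phosmark_out",
                            class1_threshold = 0.75, cutoff = 1.5,
                            q_max = 0.05, fc_min = 2, min_overlap = 2,
                            prior_df = 4,
                            design = comparison_design(),
                            dialect = phospho_dialect()) {
  if (length(phospho_tables) != 3 || is.null(names(phospho_tables)))
    stop("phospho_tables must name exactly three time points")
  if (class1_threshold <= 0 || class1_threshold >= 1)
    stop("class1_threshold must lie in (0, 1)")
  if (cutoff <= 1) stop("cutoff must be greater than 1")
  if (q_max <= 0 || q_max >= 1) stop("q_max must lie in (0, 1)")
  if (fc_min <= 1) stop("fc_min must be greater than 1")
  if (!min_overlap %in% c(2, 3)) stop("min_overlap must be 2 or 3")
  if (prior_df < 0) stop("prior_df must be >= 0")
  structure(list(phospho_tables = as.list(phospho_tables),
                 expression = expression, samples = samples,
                 edges = edges, gene_sets = gene_sets, kinases = kinases,
                 out_dir = out_dir,
                 class1_threshold = class1_threshold, cutoff = cutoff,
                 q_max = q_max, fc_min = fc_min,
                 min_overlap = as.integer(min_overlap),
                 prior_df = prior_df,
                 design = design, dialect = dialect),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments;
#' `phospho_tables` is a map from time-point label to path. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param overrides named list overriding YAML values (e.g. from CLI flags).
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  args <- list(
    phospho_tables = lapply(y$phospho_tables, rel),
    expression = rel(y$expression), samples = rel(y$samples),
    edges = rel(y$edges), gene_sets = rel(y$gene_sets),
    kinases = rel(y$kinases),
    out_dir = if (is.null(y$out_dir)) "phosmark_out" else y$out_dir)
  for (f in c("class1_threshold", "cutoff", "q_max", "fc_min",
              "min_overlap", "prior_df"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

#' Run the full marker-discovery pipeline
#'
#' Executes the stages phospho (read, class-1 filter, orient, signed fold
#' change), markers (set-logic classification and temporal aggregation),
#' differential expression (both contrasts, gene selection), integration
#' (network build and export) and, when a gene-set collection is configured,
#' hypergeometric enrichment of the marker/gene symbols against the measured
#' universe. Writes all result tables plus a run manifest (configuration
#' hash, package version, per-stage counts) into `config$out_dir`. Outputs
#' are a pure function of the configuration and inputs: rerunning the same
#' configuration reproduces them byte for byte.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a result bundle: `markers`, `de_baseline`,
#'   `de_treated`, `genes`, `network`, `enrichment` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, ...)
    if (!quiet) message("[", stage, "] ", ...)
  for (p in c(unlist(config$phospho_tables), config$expression,
              config$samples, config$edges, config$gene_sets,
              config$kinases))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "phospho"
  result <- tryCatch({
    say(stage, "reading ", length(config$phospho_tables), " tables")
    markers <- discover_markers(config$phospho_tables,
                                design = config$design,
                                dialect = config$dialect,
                                class1_threshold = config$class1_threshold,
                                cutoff = config$cutoff,
                                min_overlap = config$min_overlap)
    say("markers", markers$summary$n_markers, " marker site(s): ",
        markers$summary$n_up, " up / ", markers$summary$n_down, " down")
    write_marker_tables(markers, config$out_dir)

    stage <- "de"
    mat <- read_expression_matrix(config$expression)
    ss <- read_sample_sheet(config$samples)
    de_b <- differential_expression(mat, ss, "baseline",
                                    prior_df = config$prior_df)
    de_t <- differential_expression(mat, ss, "treated",
                                    prior_df = config$prior_df)
    genes <- select_resistance_genes(de_b, de_t, q_max = config$q_max,
                                     fc_min = config$fc_min)
    say(stage, genes$summary$n_total, " treatment-independent gene(s)")
    utils::write.table(de_b, file.path(config$out_dir, "de_baseline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de_t, file.path(config$out_dir, "de_treated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(up = genes$up, down = genes$down,
                              summary = genes$summary),
                         file.path(config$out_dir, "gene_sets.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "integrate"
    edges <- if (!is.null(config$edges)) read_edge_list(config$edges)
    kin <- if (!is.null(config$kinases))
      readLines(config$kinases, warn = FALSE) else character()
    network <- build_network(markers, genes, edges, kin)
    export_graph(network, file.path(config$out_dir, "network.graphml"),
                 "graphml")
    export_graph(network, file.path(config$out_dir, "network.cyjs"), "cyjs")
    say(stage, igraph::vcount(network), " node(s), ",
        igraph::ecount(network), " edge(s)")

    stage <- "enrich"
    enrichment <- NULL
    if (!is.null(config$gene_sets)) {
      sets <- read_gmt(config$gene_sets)
      universe <- unique(c(markers$classification$gene_symbol,
                           rownames(mat)))
      selected <- intersect(unique(c(markers$markers$gene_symbol,
                                     genes$up, genes$down)), universe)
      enrichment <- hypergeometric_enrichment(selected, universe, sets)
      utils::write.csv(enrichment,
                       file.path(config$out_dir, "enrichment.csv"),
                       row.names = FALSE)
      say(stage, sum(enrichment$q <= 0.05), " term(s) at q <= 0.05")
    }
    list(markers = markers, de_baseline = de_b, de_treated = de_t,
         genes = genes, network = network, enrichment = enrichment)
  }, error = function(e) {
    writeLines("incomplete", file.path(config$out_dir, "INCOMPLETE"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("phosmark")),
    config_hash = config_hash(config),
    thresholds = config[c("class1_threshold", "cutoff", "q_max", "fc_min",
                          "min_overlap", "prior_df")],
    counts = list(
      phospho = result$markers$summary,
      class1_fraction = result$markers$class1_fraction,
      genes = result$genes$summary,
      network = list(nodes = igraph::vcount(result$network),
                     edges = igraph::ecount(result$network)),
      enrichment_terms = if (is.null(result$enrichment)) 0L
                         else nrow(result$enrichment)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(file.path(config$out_dir, "INCOMPLETE"))
  result$manifest <- manifest
  invisible(result)
}

# deterministic digest of the analysis-relevant configuration (the output
# location does not affect results): canonical YAML -> md5
config_hash <- function(config) {
  plain <- config
  plain$out_dir <- NULL
  plain$design <- as.data.frame(plain$design)
  plain$dialect <- unclass(plain$dialect)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(plain, f)
  unname(tools::md5sum(f))
}
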