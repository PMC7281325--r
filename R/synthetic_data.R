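#' Generate a synthetic SILAC phosphosite time course with ground truth
#'
#' Builds one phosphosite quantification table per time point in the
#' MaxQuant phosphosite-table dialect, with per-experiment normalized H/L
#' ratios for the four contrasts of [comparison_design()]. Measured ratios
#' are `true ratio * 10^N(0, noise_sd)` on the channel orientation of the
#' design: the resistant line is heavy-labeled in the baseline mix and
#' light-labeled in the treated mix. Localization probabilities are drawn so
#' the expected class-1 share equals `class1_fraction`; planted exemplar
#' sites are always class-1. A small number of decoy rows flagged `Reverse`
#' or `Potential contaminant` is appended to each table to exercise the
#' reader's drop rules; decoys carry no truth label.
#'
#' With `swap_channels = TRUE` the heavy/light assignment of every
#' experiment is reversed: raw H/L ratios are inverted and every orientation
#' flag in the returned design is flipped. Under the same seed the oriented
#' (sample/reference) ratios are identical, so downstream results must not
#' change (label-swap invariance).
#'
#' @param config a [simulation_config()].
#' @param swap_channels logical; generate the label-swapped version of the
#'   same dataset.
#' @return list of class `silac_dataset` with elements `tables` (named list
#'   of data frames, one per time point), `truth` (per-site labels:
#'   category, direction, active time points, class-1 status), `design`
#'   (the matching [comparison_design()]) and `config`.
#' @export
generate_silac_dataset <- function(config, swap_channels = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  design <- comparison_design()
  tps <- config$timepoints
  n <- config$n_sites

  with_seed(substream_seed(config$seed, 1L), {
    genes <- gene_universe(config)
    cat_counts <- round(config$fractions * n)
    if (sum(cat_counts) > n)
      stop("category fractions allocate more sites than n_sites")
    category <- rep(c(names(cat_counts), "null"),
                    c(cat_counts, n - sum(cat_counts)))

    residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                      prob = c(0.86, 0.12, 0.02))
    position <- sample.int(2000L, n, replace = TRUE)
    multiplicity <- sample(1:3, n, replace = TRUE, prob = c(0.8, 0.15, 0.05))
    if (config$include_exemplars && cat_counts[["resistance_down"]] >= 1) {
      yap <- match("resistance_down", category)
      residue[yap] <- "S"; position[yap] <- 109L; multiplicity[yap] <- 1L
    }

    # gene assignment (and the key de-duplication it influences) uses its
    # own sub-stream so the site measurements are invariant to n_genes
    ga <- with_seed(substream_seed(config$seed, 3L), {
      gene_idx <- sample.int(length(genes), n, replace = TRUE)
      if (config$include_exemplars &&
          cat_counts[["resistance_down"]] >= 1) {
        # YAP1L Ser-109-like dephosphorylation exemplar on the first
        # resistance_down slot
        yap <- match("resistance_down", category)
        gene_idx[yap] <- match("YAP1L", genes)
      }
      protein_id <- sprintf("P%05d", gene_idx)
      # enforce unique site identity keys (protein, position, residue,
      # multiplicity) by re-drawing colliding positions
      key <- site_key(protein_id, position, residue, multiplicity)
      while (anyDuplicated(key)) {
        dup <- duplicated(key)
        position[dup] <- sample.int(100000L, sum(dup), replace = TRUE)
        key <- site_key(protein_id, position, residue, multiplicity)
      }
      list(gene_symbol = genes[gene_idx], protein_id = protein_id,
           position = position, key = key)
    })
    gene_symbol <- ga$gene_symbol
    protein_id <- ga$protein_id
    position <- ga$position
    key <- ga$key

    direction <- integer(n)
    direction[category == "resistance_up"] <- 1L
    direction[category == "resistance_down"] <- -1L
    other <- category %in% c("treatment_response_only", "de_novo_reversal")
    direction[other] <- sample(c(-1L, 1L), sum(other), replace = TRUE)

    # planted effects are constant across time points unless a share of
    # planted sites is restricted to two of the three
    active <- matrix(TRUE, n, 3, dimnames = list(NULL, tps))
    planted <- category %in% c("resistance_up", "resistance_down",
                               "de_novo_reversal")
    if (config$fraction_two_timepoints > 0) {
      pick <- planted & runif(n) < config$fraction_two_timepoints
      for (i in which(pick)) active[i, sample.int(3L, 1L)] <- FALSE
    }

    class1 <- runif(n) < config$class1_fraction
    if (config$include_exemplars && cat_counts[["resistance_down"]] >= 1)
      class1[match("resistance_down", category)] <- TRUE
    loc_prob <- ifelse(class1,
                       runif(n, 0.7501, 1),
                       runif(n, 0.05, 0.75))

    e <- config$effect_size
    true_ratio <- function(contrast, tp_idx) {
      r <- rep(1, n)
      on_tp <- active[, tp_idx]
      if (contrast %in% c("A", "B")) {
        idx <- planted & on_tp
        r[idx] <- e^direction[idx]
      } else if (contrast == "C") {
        idx <- category == "treatment_response_only" & on_tp
        r[idx] <- e^direction[idx]
      } else {  # D
        idx <- category == "treatment_response_only" & on_tp
        r[idx] <- e^direction[idx]
        idx <- category == "de_novo_reversal" & on_tp
        r[idx] <- e^(-direction[idx])
      }
      r
    }

    tables <- list()
    for (ti in seq_along(tps)) {
      tab <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                        `Protein` = protein_id,
                        `Gene names` = gene_symbol,
                        `Amino acid` = residue,
                        `Position` = position,
                        `Multiplicity` = multiplicity,
                        `Localization prob` = round(loc_prob, 6),
                        `Reverse` = "",
                        `Potential contaminant` = "")
      for (ci in seq_len(nrow(design))) {
        oriented <- true_ratio(design$contrast[ci], ti) *
          10^stats::rnorm(n, 0, config$noise_sd)
        raw <- if (design$heavy_is_sample[ci]) oriented else 1 / oriented
        if (swap_channels) raw <- 1 / raw
        if (config$missing_rate > 0)
          raw[runif(n) < config$missing_rate] <- NA_real_
        tab[[paste0("Ratio H/L normalized ", design$experiment[ci])]] <-
          round(raw, 6)
      }
      tables[[tps[ti]]] <- add_decoy_rows(tab, design)
    }

    truth_sites <- data.frame(site_key = key,
                              protein_id = protein_id,
                              gene_symbol = gene_symbol,
                              residue = residue,
                              position = position,
                              multiplicity = multiplicity,
                              category = category,
                              direction = direction,
                              class1 = class1,
                              active_timepoints =
                                apply(active, 1, function(a)
                                  paste(tps[a], collapse = ",")),
                              stringsAsFactors = FALSE)

    structure(list(tables = tables,
                   truth = truth_sites,
                   design = if (swap_channels) swap_design(design) else design,
                   config = config,
                   swap_channels = swap_channels),
              class = "silac_dataset")
  })
}

gene_universe <- function(config) {
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  if (config$include_exemplars && config$n_genes >= 2)
    genes[1:2] <- c("TEAD2L", "YAP1L")
  genes
}

site_key <- function(protein_id, position, residue, multiplicity) {
  paste(protein_id, position, residue, multiplicity, sep = "_")
}

# decoy rows exercising the reader's Reverse / Potential contaminant drops;
# ~1.5% of n_sites, never labeled in truth
add_decoy_rows <- function(tab, design) {
  n_rev <- max(1L, round(nrow(tab) * 0.005))
  n_con <- max(1L, round(nrow(tab) * 0.010))
  m <- n_rev + n_con
  decoy <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                      `Protein` = c(sprintf("REV__D%04d", seq_len(n_rev)),
                                    sprintf("CON__C%04d", seq_len(n_con))),
                      `Gene names` = "",
                      `Amino acid` = sample(c("S", "T", "Y"), m, TRUE),
                      `Position` = sample.int(2000L, m, TRUE),
                      `Multiplicity` = 1L,
                      `Localization prob` = round(runif(m), 6),
                      `Reverse` = rep(c("+", ""), c(n_rev, n_con)),
                      `Potential contaminant` = rep(c("", "+"),
                                                    c(n_rev, n_con)))
  for (col in paste0("Ratio H/L normalized ", design$experiment))
    decoy[[col]] <- round(10^stats::rnorm(m, 0, 0.3), 6)
  rbind(tab, decoy)
}

#' Generate a synthetic log2 expression matrix with ground truth
#'
#' Two cell lines (parental, resistant) by two treatments (untreated,
#' treated) with `n_replicates_expr` arrays per condition. Genes planted as
#' treatment-independent up/down differ between the cell lines by
#' `log2(effect_size)` in both the untreated and the treated contrast with
#' the same sign; treatment-only genes shift with treatment in both lines;
#' the remainder is null. Gaussian noise is added on the log2 scale. When
#' exemplars are enabled, gene `TEAD2L` is planted as a treatment-independent
#' 2.24-fold increase in the resistant line.
#'
#' @param config a [simulation_config()].
#' @return list of class `expression_dataset` with elements `matrix` (genes
#'   x samples, log2), `samples` (sample sheet: sample, cell_line,
#'   treatment, replicate), `truth` (per-gene category, direction, true
#'   linear fold change) and `config`.
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ng <- config$n_genes
  with_seed(substream_seed(config$seed, 2L), {
    genes <- gene_universe(config)
    counts <- round(config$gene_fractions * ng)
    if (sum(counts) > ng)
      stop("gene category fractions allocate more genes than n_genes")

    category <- rep("null", ng)
    direction <- integer(ng)
    true_fc <- rep(1, ng)
    assignable <- seq_len(ng)
    if (config$include_exemplars) {
      tead <- match("TEAD2L", genes)
      category[tead] <- "trastuzumab_independent_up"
      direction[tead] <- 1L
      true_fc[tead] <- 2.24
      counts["up"] <- max(0L, counts["up"] - 1L)
      assignable <- setdiff(assignable, c(tead, match("YAP1L", genes)))
    }
    pick <- sample(assignable, sum(counts))
    lab <- rep(c("trastuzumab_independent_up", "trastuzumab_independent_down",
                 "treatment_only"), counts[c("up", "down", "treatment_only")])
    category[pick] <- lab
    direction[pick] <- ifelse(lab == "trastuzumab_independent_down", -1L, 1L)
    tro <- category == "treatment_only"
    direction[tro] <- sample(c(-1L, 1L), sum(tro), replace = TRUE)
    true_fc[category != "null" & true_fc == 1] <- config$effect_size

    samples <- expand.grid(replicate = seq_len(config$n_replicates_expr),
                           treatment = c("untreated", "treated"),
                           cell_line = c("parental", "resistant"),
                           stringsAsFactors = FALSE)
    samples <- samples[, c("cell_line", "treatment", "replicate")]
    samples$sample <- with(samples,
                           paste(cell_line, treatment, replicate, sep = "_"))

    base <- runif(ng, 4, 12)
    lfc <- direction * log2(true_fc)
    mat <- matrix(0, ng, nrow(samples),
                  dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- base
      indep <- startsWith(category, "trastuzumab_independent")
      if (samples$cell_line[j] == "resistant")
        mu <- mu + ifelse(indep, lfc, 0)
      if (samples$treatment[j] == "treated")
        mu <- mu + ifelse(tro, direction * log2(config$effect_size), 0)
      mat[, j] <- mu + stats::rnorm(ng, 0, config$expr_noise_sd)
    }

    truth <- data.frame(gene = genes, category = category,
                        direction = direction, true_fc = true_fc,
                        stringsAsFactors = FALSE)
    structure(list(matrix = round(mat, 6),
                   samples = samples[, c("sample", "cell_line",
                                         "treatment", "replicate")],
                   truth = truth, config = config),
              class = "expression_dataset")
  })
}

#' Write a synthetic bundle to disk
#'
#' Serializes one TSV phosphosite table per time point, the log2 expression
#' matrix, the sample sheet, and a single JSON ground-truth file covering
#' sites and genes. Output is byte-deterministic for a given dataset.
#'
#' @param silac a `silac_dataset` from [generate_silac_dataset()].
#' @param expr an `expression_dataset` from [generate_expression_dataset()],
#'   or `NULL` to write the phospho data only.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of written paths.
#' @export
write_synthetic_bundle <- function(silac, expr = NULL, dir) {
  stopifnot(inherits(silac, "silac_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tp in names(silac$tables)) {
    p <- file.path(dir, paste0("phosphosites_", tp, ".tsv"))
    utils::write.table(silac$tables[[tp]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NaN")
    paths[paste0("phospho_", tp)] <- p
  }
  truth <- list(sites = silac$truth)
  if (!is.null(expr)) {
    stopifnot(inherits(expr, "expression_dataset"))
    p <- file.path(dir, "expression_log2.tsv")
    utils::write.table(data.frame(gene = rownames(expr$matrix),
                                  expr$matrix, check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["expression"] <- p
    p <- file.path(dir, "samples.tsv")
    utils::write.table(expr$samples, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["samples"] <- p
    truth$genes <- expr$truth
  }
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, p, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  paths["truth"] <- p
  invisible(paths)
}

#' Score predicted site categories against ground truth
#'
#' Compares per-site predicted categories with the generator's truth labels
#' and reports, for every category, true positives, false positives, false
#' negatives, precision, recall and truth support. Sites predicted `none`
#' count as negative predictions. Precision for a category with no positive
#' predictions is undefined and reported as `NA` with zero predicted
#' support; recall over zero truth support is likewise `NA`.
#'
#' The evaluation universe is the set of sites in `predicted`: sites the
#' pipeline never sees (e.g. non-class-1 sites removed by the localization
#' filter) are not scored, since no downstream method can recover them.
#'
#' @param predicted data frame with columns `site_key`,
#'   `predicted_category`.
#' @param truth the `truth` element of a [generate_silac_dataset()] result
#'   (or any data frame with `site_key`, `category`).
#' @return data frame with one row per category.
#' @export
truth_evaluation <- function(predicted, truth) {
  stopifnot(all(c("site_key", "predicted_category") %in% names(predicted)),
            all(c("site_key", "category") %in% names(truth)))
  if (!all(predicted$site_key %in% truth$site_key))
    stop("identifier mismatch: predicted site keys absent from truth")
  tr <- truth$category[match(predicted$site_key, truth$site_key)]
  pr <- predicted$predicted_category
  cats <- sort(unique(c(tr, setdiff(pr, "none"))))
  out <- lapply(cats, function(ct) {
    tp <- sum(pr == ct & tr == ct)
    fp <- sum(pr == ct & tr != ct)
    fn <- sum(pr != ct & tr == ct)
    data.frame(category = ct, tp = tp, fp = fp, fn = fn,
               n_predicted = tp + fp, n_truth = tp + fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Derive per-site predicted categories from a marker classification
#'
#' Maps the aggregated classification of every analyzed site to the
#' generator's truth vocabulary: a site meeting the overlap requirement is
#' predicted `de_novo_reversal` when its de-novo annotation is itself
#' consistent across at least `min_overlap` contributing time points,
#' otherwise `resistance_up` or `resistance_down` by consensus direction;
#' all other sites are predicted `none`.
#'
#' @param classification result of [aggregate_over_time()] /
#'   [classify_sites()] (site-level table).
#' @param min_overlap minimum number of concordant time points (2 or 3).
#' @return data frame with `site_key`, `predicted_category`.
#' @export
predict_site_categories <- function(classification, min_overlap = 2) {
  stopifnot(min_overlap %in% c(2, 3))
  is_marker <- classification$overlap_level >= min_overlap
  pred <- rep("none", nrow(classification))
  dn <- is_marker & classification$de_novo_level >= min_overlap
  pred[is_marker] <- paste0("resistance_",
                            classification$consensus_direction[is_marker])
  pred[dn] <- "de_novo_reversal"
  data.frame(site_key = classification$site_key,
             predicted_category = pred, stringsAsFactors = FALSE)
}
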