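#' Declare the column dialect of a phosphosite table
#'
#' Default column names follow the MaxQuant phosphosite-table dialect. Ratio
#' columns are discovered by prefix: every column starting with
#' `ratio_prefix` defines one experiment whose key is the remainder of the
#' column name. Flag columns (`reverse`, `contaminant`) are optional; when
#' present, rows marked `"+"` are dropped.
#'
#' @param protein,gene,residue,position,localization_prob column names of
#'   the identifier, residue, position and localization-probability fields.
#' @param multiplicity optional multiplicity column; absent columns default
#'   every record to multiplicity 1.
#' @param ratio_prefix prefix of the normalized H/L ratio columns.
#' @param reverse,contaminant optional decoy/contaminant flag columns.
#' @return list of class `phospho_dialect`.
#' @export
phospho_dialect <- function(protein = "Protein",
                            gene = "Gene names",
                            residue = "Amino acid",
                            position = "Position",
                            localization_prob = "Localization prob",
                            multiplicity = "Multiplicity",
                            ratio_prefix = "Ratio H/L normalized ",
                            reverse = "Reverse",
                            contaminant = "Potential contaminant") {
  structure(list(protein = protein, gene = gene, residue = residue,
                 position = position, localization_prob = localization_prob,
                 multiplicity = multiplicity, ratio_prefix = ratio_prefix,
                 reverse = reverse, contaminant = contaminant),
            class = "phospho_dialect")
}

#' Read a phosphosite quantification table
#'
#' Parses one tab-separated phosphosite table into a validated record table.
#' Rows flagged reverse or contaminant are dropped; rows failing basic
#' validity (localization probability outside \[0, 1\], position < 1,
#' unparseable identifiers) are dropped and counted; non-positive or
#' unparseable ratios become missing values. When several rows share a site
#' identity key (protein, position, residue, multiplicity), the row with the
#' highest localization probability is kept.
#'
#' @param path path to a TSV file, or a data frame already in memory.
#' @param dialect a [phospho_dialect()].
#' @return data frame of class `phosphosite_table` with columns `site_key`,
#'   `protein_id`, `gene_symbol`, `residue`, `position`, `multiplicity`,
#'   `localization_prob` and one `ratio_<experiment>` column per experiment;
#'   attributes `experiments` (keys) and `n_dropped` (malformed-row count).
#' @export
read_phosphosite_table <- function(path, dialect = phospho_dialect()) {
  stopifnot(inherits(dialect, "phospho_dialect"))
  raw <- if (is.data.frame(path)) path
         else utils::read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  mandatory <- c(dialect$protein, dialect$residue, dialect$position,
                 dialect$localization_prob)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0)
    stop("phosphosite table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  ratio_cols <- grep(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                      dialect$ratio_prefix)),
                     names(raw), value = TRUE)
  if (length(ratio_cols) == 0)
    stop("phosphosite table has no ratio columns with prefix '",
         dialect$ratio_prefix, "'")
  experiments <- substring(ratio_cols, nchar(dialect$ratio_prefix) + 1L)

  for (flag in c(dialect$reverse, dialect$contaminant))
    if (!is.null(flag) && flag %in% names(raw))
      raw <- raw[is.na(raw[[flag]]) | raw[[flag]] != "+", , drop = FALSE]

  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(protein_id = as.character(raw[[dialect$protein]]),
                    gene_symbol = if (dialect$gene %in% names(raw))
                      as.character(raw[[dialect$gene]]) else NA_character_,
                    residue = as.character(raw[[dialect$residue]]),
                    position = num(raw[[dialect$position]]),
                    multiplicity = if (dialect$multiplicity %in% names(raw))
                      num(raw[[dialect$multiplicity]]) else 1,
                    localization_prob = num(raw[[dialect$localization_prob]]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ratio_cols)) {
    r <- num(raw[[ratio_cols[i]]])
    r[!is.na(r) & r <= 0] <- NA_real_
    rec[[paste0("ratio_", experiments[i])]] <- r
  }

  valid <- !is.na(rec$position) & rec$position >= 1 &
    !is.na(rec$localization_prob) &
    rec$localization_prob >= 0 & rec$localization_prob <= 1 &
    !is.na(rec$multiplicity) & rec$multiplicity >= 1 &
    nzchar(rec$protein_id) & rec$residue %in% c("S", "T", "Y")
  n_dropped <- sum(!valid)
  if (n_dropped > 0)
    message(n_dropped, " malformed row(s) dropped")
  rec <- rec[valid, , drop = FALSE]
  rec$position <- as.integer(rec$position)
  rec$multiplicity <- as.integer(rec$multiplicity)
  rec$site_key <- site_key(rec$protein_id, rec$position, rec$residue,
                           rec$multiplicity)

  # duplicate identity keys: keep the best-localized row
  if (anyDuplicated(rec$site_key)) {
    ord <- order(rec$site_key, -rec$localization_prob)
    rec <- rec[ord, , drop = FALSE]
    ndup <- sum(duplicated(rec$site_key))
    rec <- rec[!duplicated(rec$site_key), , drop = FALSE]
    message(ndup, " duplicate site key(s) collapsed to the ",
            "highest-localization row")
  }
  rownames(rec) <- NULL
  rec <- rec[, c("site_key", "protein_id", "gene_symbol", "residue",
                 "position", "multiplicity", "localization_prob",
                 paste0("ratio_", experiments))]
  structure(rec, experiments = experiments, n_dropped = n_dropped,
            class = c("phosphosite_table", "data.frame"))
}

#' Keep class-1 phosphosites
#'
#' Retains records whose localization probability strictly exceeds the
#' threshold (class-1 sites at the default 0.75). The retained fraction is
#' attached as attribute `retained_fraction`.
#'
#' @param records a `phosphosite_table`.
#' @param threshold localization-probability threshold in (0, 1).
#' @return the filtered table.
#' @export
filter_class1 <- function(records, threshold = 0.75) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  keep <- records$localization_prob > threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "experiments") <- attr(records, "experiments")
  attr(out, "retained_fraction") <-
    if (nrow(records) > 0) mean(keep) else NA_real_
  class(out) <- class(records)
  out
}

#' Orient a raw H/L ratio to the sample/reference scale
#'
#' The normalized H/L ratio is kept when the heavy channel is the contrast's
#' sample and inverted (L/H) when the light channel is the sample. Missing
#' ratios propagate.
#'
#' @param ratio numeric vector of raw H/L ratios (positive or `NA`).
#' @param heavy_is_sample logical scalar or vector recycled against `ratio`.
#' @return sample/reference ratios.
#' @export
orient_ratio <- function(ratio, heavy_is_sample) {
  if (any(!is.na(ratio) & ratio <= 0))
    stop("ratios must be positive")
  ifelse(rep_len(heavy_is_sample, length(ratio)), ratio, 1 / ratio)
}

#' Signed fold-change transform
#'
#' Maps a sample/reference ratio `r` to `+r` when `r >= 1` and to `-1/r`
#' when `r < 1` (the 10^log10 / -1/10^log10 transform), so +1 denotes no
#' change and magnitudes are symmetric around it. Values never fall in the
#' open interval (-1, 1); missing ratios propagate.
#'
#' @param ratio numeric vector of oriented ratios (positive or `NA`).
#' @return signed fold changes.
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.na(ratio) & ratio <= 0))
    stop("ratios must be positive")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Signed fold changes for every site, contrast and time point
#'
#' Applies channel orientation and the signed transform to every ratio of a
#' set of per-time-point phosphosite tables under a [comparison_design()].
#' Sites absent from a time point's table (or with a missing ratio) yield
#' missing fold changes, which downstream classification treats explicitly.
#'
#' @param tables named list of `phosphosite_table` objects, one per time
#'   point (names are the time-point ids).
#' @param design a [comparison_design()].
#' @return long data frame with columns `site_key`, `time_point`,
#'   `contrast`, `signed_fc`; attribute `sites` holds one metadata row per
#'   site (gene symbol, residue, position, multiplicity).
#' @export
fold_change_table <- function(tables, design) {
  stopifnot(inherits(design, "comparison_design"), length(tables) >= 1,
            !is.null(names(tables)))
  meta_cols <- c("site_key", "protein_id", "gene_symbol", "residue",
                 "position", "multiplicity")
  sites <- unique(do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[, meta_cols])))
  sites <- sites[!duplicated(sites$site_key), , drop = FALSE]
  sites <- sites[order(sites$site_key), , drop = FALSE]
  rownames(sites) <- NULL

  out <- list()
  for (tp in names(tables)) {
    tab <- tables[[tp]]
    idx <- match(sites$site_key, tab$site_key)
    for (ci in seq_len(nrow(design))) {
      col <- paste0("ratio_", design$experiment[ci])
      if (!col %in% names(tab))
        stop("table for time point ", tp, " lacks experiment column ", col)
      raw <- tab[[col]][idx]
      fc <- signed_fold_change(orient_ratio(raw, design$heavy_is_sample[ci]))
      out[[length(out) + 1L]] <-
        data.frame(site_key = sites$site_key, time_point = tp,
                   contrast = design$contrast[ci], signed_fc = fc,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sites") <- sites
  res
}
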