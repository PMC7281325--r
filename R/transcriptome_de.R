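#' Read a log2 expression matrix and its sample sheet
#'
#' @param path TSV with a `gene` identifier column followed by one numeric
#'   column per sample.
#' @return numeric matrix (genes x samples) with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"gene" %in% names(raw)) stop("expression table needs a 'gene' column")
  if (anyDuplicated(raw$gene)) stop("gene identifiers must be unique")
  mat <- as.matrix(raw[, setdiff(names(raw), "gene"), drop = FALSE])
  if (!is.numeric(mat)) stop("expression values must be numeric")
  if (anyNA(mat)) stop("expression matrix must not contain missing values")
  rownames(mat) <- raw$gene
  mat
}

#' @rdname read_expression_matrix
#' @return for `read_sample_sheet`, a data frame with columns `sample`,
#'   `cell_line` (`parental`/`resistant`), `treatment`
#'   (`untreated`/`treated`), `replicate`.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "treatment", "replicate")
  if (!all(need %in% names(ss)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!all(ss$cell_line %in% c("parental", "resistant")) ||
      !all(ss$treatment %in% c("untreated", "treated")))
    stop("sample sheet has unknown cell_line or treatment levels")
  grp <- table(ss$cell_line, ss$treatment)
  if (any(grp < 2))
    stop("every (cell_line, treatment) group needs >= 2 replicates")
  ss
}

#' Collapse probe-level rows to gene-level rows
#'
#' The expression value of a gene with several probes is the arithmetic mean
#' of those probes' log2 values. Probes absent from the mapping are dropped
#' and counted in the `n_unmapped` attribute.
#'
#' @param probe_matrix numeric matrix, probes x samples.
#' @param probe_map data frame with columns `probe`, `gene`; every probe
#'   maps to at most one gene.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  stopifnot(is.matrix(probe_matrix),
            all(c("probe", "gene") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe))
    stop("every probe must map to at most one gene")
  gene <- probe_map$gene[match(rownames(probe_matrix), probe_map$probe)]
  keep <- !is.na(gene) & nzchar(gene)
  n_unmapped <- sum(!keep)
  if (!any(keep)) stop("no probes could be mapped to genes")
  collapsed <- rowsum(probe_matrix[keep, , drop = FALSE], gene[keep]) /
    as.vector(table(gene[keep])[sort(unique(gene[keep]))])
  structure(collapsed, n_unmapped = n_unmapped)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement (delegates to [stats::p.adjust()] with `method = "BH"` after
#' validating the input).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression with pooled variance
#'
#' Per-gene two-sample t statistic comparing resistant against parental
#' samples within one treatment arm, using the pooled within-group variance.
#' Optionally the per-gene variance is shrunk toward the median gene
#' variance with `prior_df` pseudo-observations,
#' `s2* = (prior_df * median(s2) + df * s2) / (prior_df + df)`, and the
#' reference t distribution gains the prior degrees of freedom
#' (`df + prior_df`). With biological duplicates the unshrunk t has only 2
#' degrees of freedom and a heavy-tailed p-value floor, so moderate
#' shrinkage is the practical default for genome-scale FDR control;
#' `prior_df = 0` gives the plain pooled t whose null p-values are exactly
#' uniform.
#'
#' @param mat log2 expression matrix, genes x samples.
#' @param samples sample sheet (see [read_sample_sheet()]).
#' @param contrast `"baseline"` (untreated arm) or `"treated"` (treated
#'   arm); both compare resistant minus parental.
#' @param prior_df prior degrees of freedom for variance shrinkage toward
#'   the median gene variance; 0 disables shrinkage.
#' @return data frame of class `de_result`: `gene`, `log2fc`, `fc` (signed
#'   linear fold change, `sign(log2fc) * 2^|log2fc|`), `t`, `df`, `p`, `q`,
#'   plus attribute `contrast`.
#' @export
differential_expression <- function(mat, samples,
                                    contrast = c("baseline", "treated"),
                                    prior_df = 4) {
  contrast <- match.arg(contrast)
  stopifnot(is.matrix(mat), prior_df >= 0)
  if (!all(samples$sample %in% colnames(mat)))
    stop("sample sheet refers to samples absent from the matrix")
  arm <- if (contrast == "baseline") "untreated" else "treated"
  ss <- samples[samples$treatment == arm, , drop = FALSE]
  g1 <- ss$sample[ss$cell_line == "resistant"]
  g2 <- ss$sample[ss$cell_line == "parental"]
  if (length(g1) < 2 || length(g2) < 2)
    stop("both groups need >= 2 replicates in the ", arm, " arm")

  x1 <- mat[, g1, drop = FALSE]
  x2 <- mat[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  if (all(s2 == 0))
    stop("zero within-group variance for every gene; the input is ",
         "degenerate - inject noise when simulating")
  if (prior_df > 0) {
    s2 <- (prior_df * stats::median(s2) + df * s2) / (prior_df + df)
    df_t <- df + prior_df
  } else {
    df_t <- df
  }
  lfc <- m1 - m2
  tstat <- lfc / sqrt(s2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df_t)
  out <- data.frame(gene = rownames(mat),
                    log2fc = lfc,
                    fc = ifelse(lfc >= 0, 2^lfc, -(2^(-lfc))),
                    t = tstat, df = df_t, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select treatment-independent resistance genes
#'
#' A gene shows treatment-independent differential regulation when it is
#' significant (`q < q_max` and linear fold change magnitude `> fc_min`,
#' both strict) in both the baseline and the treated contrast with the same
#' sign. The result is split into up- and down-regulated sets (sign of the
#' resistant-minus-parental change).
#'
#' @param de_baseline,de_treated `de_result` objects on the same gene
#'   universe.
#' @param q_max FDR threshold (default 0.05).
#' @param fc_min linear fold-change threshold (default 2).
#' @return list with `up`, `down` (gene vectors), `table` (per selected
#'   gene: both contrasts' fold changes and q-values) and `summary` counts.
#' @export
select_resistance_genes <- function(de_baseline, de_treated,
                                    q_max = 0.05, fc_min = 2) {
  if (!identical(de_baseline$gene, de_treated$gene))
    stop("the two contrasts must be computed on the same gene universe")
  sig <- function(de) !is.na(de$q) & de$q < q_max & abs(de$fc) > fc_min
  s1 <- sig(de_baseline); s2 <- sig(de_treated)
  same_sign <- sign(de_baseline$log2fc) == sign(de_treated$log2fc)
  hit <- s1 & s2 & same_sign
  dirn <- ifelse(de_baseline$log2fc > 0, "up", "down")
  tab <- data.frame(gene = de_baseline$gene[hit],
                    direction = dirn[hit],
                    fc_baseline = de_baseline$fc[hit],
                    q_baseline = de_baseline$q[hit],
                    fc_treated = de_treated$fc[hit],
                    q_treated = de_treated$q[hit],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-pmin(abs(tab$fc_baseline), abs(tab$fc_treated)),
                   tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(up = tab$gene[tab$direction == "up"],
       down = tab$gene[tab$direction == "down"],
       table = tab,
       summary = list(n_total = nrow(tab),
                      n_up = sum(tab$direction == "up"),
                      n_down = sum(tab$direction == "down")))
}
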