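#' SILAC comparison design: contrasts, experiments, channel orientation
#'
#' Maps the four biological contrasts evaluated at every time point to the
#' experiment (ratio column) that supplies each one, together with the
#' channel-orientation flag stating whether the heavy channel carries the
#' contrast's sample (numerator) or its reference (denominator):
#'
#' \describe{
#'   \item{A}{resistant vs parental, untreated (baseline mix: resistant line
#'     heavy-labeled, so the heavy channel is the sample).}
#'   \item{B}{resistant + treatment vs parental + treatment (treated mix:
#'     resistant line light-labeled, so the light channel is the sample and
#'     the raw H/L ratio must be inverted).}
#'   \item{C}{resistant + treatment vs resistant untreated (sample is the
#'     light-labeled treated resistant population).}
#'   \item{D}{parental + treatment vs parental untreated (sample is the
#'     heavy-labeled treated parental population).}
#' }
#'
#' @param experiments named character vector mapping contrast id (A-D) to
#'   the experiment key that appears in the ratio column names.
#' @param heavy_is_sample named logical vector per contrast; `TRUE` when the
#'   heavy channel is the contrast's sample.
#' @return data frame of class `comparison_design` with columns `contrast`,
#'   `experiment`, `heavy_is_sample`.
#' @export
comparison_design <- function(experiments = c(A = "A", B = "B",
                                              C = "C", D = "D"),
                              heavy_is_sample = c(A = TRUE, B = FALSE,
                                                  C = FALSE, D = TRUE)) {
  contrasts <- c("A", "B", "C", "D")
  if (!setequal(names(experiments), contrasts))
    stop("experiments must be named with contrasts A, B, C, D")
  if (!setequal(names(heavy_is_sample), contrasts))
    stop("heavy_is_sample must be named with contrasts A, B, C, D")
  if (anyNA(heavy_is_sample))
    stop("orientation flag must be defined for every contrast")
  if (anyDuplicated(experiments))
    stop("every contrast must map to exactly one experiment key")
  out <- data.frame(contrast = contrasts,
                    experiment = unname(experiments[contrasts]),
                    heavy_is_sample = unname(heavy_is_sample[contrasts]),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_design", "data.frame")
  out
}

#' Swap every channel assignment of a design
#'
#' Returns the label-swapped design: the same contrasts and experiment keys
#' with every orientation flag flipped. Applied together with inverted raw
#' H/L ratios it must leave all oriented fold changes unchanged.
#'
#' @param design a [comparison_design()].
#' @return the flipped design.
#' @export
swap_design <- function(design) {
  design$heavy_is_sample <- !design$heavy_is_sample
  design
}
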