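#' Configuration for the synthetic multi-omic generator
#'
#' Defines the conditions a generated dataset emulates: a SILAC
#' phosphoproteomics time course of a drug-resistant cell line and its
#' parental line, each untreated or treated, measured at three time points
#' with swapped heavy/light channel assignment between the baseline and
#' treated mixes, plus a log2 expression matrix with replicated arrays per
#' condition. Planted effects carry ground-truth labels so recovery by the
#' downstream pipeline can be scored.
#'
#' Site truth categories:
#' \describe{
#'   \item{resistance_up / resistance_down}{phosphorylation shifted in the
#'     resistant line relative to parental, regardless of treatment (the
#'     acquired-resistance marker pattern).}
#'   \item{treatment_response_only}{phosphorylation shifted by treatment in
#'     both lines equally; must never be reported as a resistance marker.}
#'   \item{de_novo_reversal}{a resistance shift accompanied by a
#'     treatment-induced shift in the parental line in the opposite
#'     direction (loss of a sensitivity-relevant response).}
#'   \item{null}{no effect anywhere.}
#' }
#'
#' @param n_sites number of phosphosites per time-point table.
#' @param n_genes number of genes in the expression matrix.
#' @param fractions named numeric vector of site category proportions for
#'   `resistance_up`, `resistance_down`, `treatment_response_only` and
#'   `de_novo_reversal`; each in \[0, 1\] and summing to at most 1. The
#'   remainder of sites is null.
#' @param gene_fractions named numeric vector of gene category proportions
#'   for `up`, `down` (treatment-independent differential expression) and
#'   `treatment_only`; remainder is null.
#' @param effect_size true absolute fold change of planted effects on the
#'   linear ratio scale; must exceed the downstream regulation cutoff for
#'   planted effects to be detectable at zero noise.
#' @param noise_sd standard deviation of the multiplicative log-normal ratio
#'   noise, on the log10 scale (measured ratio = true ratio * 10^N(0, sd)).
#' @param class1_fraction target share of sites with localization
#'   probability above 0.75 (class-1 sites).
#' @param missing_rate probability that any one site x experiment ratio is
#'   missing, independently (missing completely at random).
#' @param fraction_two_timepoints share of planted resistance and de-novo
#'   sites whose effect is present at only two of the three time points
#'   (exercises the 2-of-3 vs 3-of-3 overlap tiers). Default 0: planted
#'   effects are constant across time points.
#' @param n_replicates_expr arrays per (cell line, treatment) condition;
#'   at least 2 so the differential-expression stage has within-group
#'   variance.
#' @param expr_noise_sd gaussian noise standard deviation on the log2
#'   expression scale.
#' @param timepoints character vector of three time-point labels.
#' @param include_exemplars plant two named exemplars: a "YAP1L" Ser-109
#'   dephosphorylation marker (resistance_down) and a "TEAD2L" gene with a
#'   2.24-fold treatment-independent increase. Both symbols are synthetic.
#' @param seed integer master seed; sub-streams for the phosphosite tables
#'   and the expression matrix are derived from it independently, so
#'   changing `n_genes` does not perturb site generation.
#'
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 2000,
                              n_genes = 2000,
                              fractions = c(resistance_up = 0.02,
                                            resistance_down = 0.02,
                                            treatment_response_only = 0.05,
                                            de_novo_reversal = 0.01),
                              gene_fractions = c(up = 0.008,
                                                 down = 0.010,
                                                 treatment_only = 0.02),
                              effect_size = 3.0,
                              noise_sd = 0.05,
                              class1_fraction = 0.74,
                              missing_rate = 0.10,
                              fraction_two_timepoints = 0,
                              n_replicates_expr = 2,
                              expr_noise_sd = 0.2,
                              timepoints = c("T1", "T2", "T3"),
                              include_exemplars = TRUE,
                              seed = 1L) {
  site_cats <- c("resistance_up", "resistance_down",
                 "treatment_response_only", "de_novo_reversal")
  gene_cats <- c("up", "down", "treatment_only")
  fr <- rep(0, length(site_cats)); names(fr) <- site_cats
  fr[names(fractions)] <- fractions
  gfr <- rep(0, length(gene_cats)); names(gfr) <- gene_cats
  gfr[names(gene_fractions)] <- gene_fractions

  stopifnot(n_sites >= 1, n_genes >= 1, length(timepoints) == 3)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("site category fractions must lie in [0, 1] and sum to at most 1")
  if (any(gfr < 0 | gfr > 1) || sum(gfr) > 1)
    stop("gene category fractions must lie in [0, 1] and sum to at most 1")
  if (!is.numeric(effect_size) || effect_size <= 0)
    stop("effect_size must be positive")
  if (effect_size <= 1)
    stop("effect_size must exceed 1 so planted effects have a direction")
  if (noise_sd < 0 || expr_noise_sd < 0) stop("noise sd must be >= 0")
  if (class1_fraction < 0 || class1_fraction > 1)
    stop("class1_fraction must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (fraction_two_timepoints < 0 || fraction_two_timepoints > 1)
    stop("fraction_two_timepoints must lie in [0, 1]")
  if (n_replicates_expr < 2)
    stop("n_replicates_expr must be >= 2: the differential-expression ",
         "stage needs within-group variance")

  structure(list(n_sites = as.integer(n_sites),
                 n_genes = as.integer(n_genes),
                 fractions = fr,
                 gene_fractions = gfr,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 class1_fraction = class1_fraction,
                 missing_rate = missing_rate,
                 fraction_two_timepoints = fraction_two_timepoints,
                 n_replicates_expr = as.integer(n_replicates_expr),
                 expr_noise_sd = expr_noise_sd,
                 timepoints = as.character(timepoints),
                 include_exemplars = isTRUE(include_exemplars),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards, so generator sub-streams stay independent.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Derived sub-stream seeds, kept inside 32-bit integer range.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
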