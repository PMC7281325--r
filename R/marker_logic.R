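#' Threshold a signed fold change into a regulation call
#'
#' A site-contrast measurement is called `up` when its signed fold change is
#' at least `+cutoff`, `down` when at most `-cutoff`, `unchanged` otherwise,
#' and `missing` when unquantified. The boundary is inclusive: a fold change
#' of exactly the cutoff magnitude counts as regulated.
#'
#' @param signed_fc numeric vector of signed fold changes (`NA` = missing).
#' @param cutoff regulation cutoff on the linear ratio scale, > 1
#'   (default 1.5).
#' @return character vector in `up`, `down`, `unchanged`, `missing`.
#' @export
call_regulation <- function(signed_fc, cutoff = 1.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 1)
    stop("cutoff must be a single value greater than 1")
  out <- rep("unchanged", length(signed_fc))
  out[is.na(signed_fc)] <- "missing"
  out[!is.na(signed_fc) & signed_fc >= cutoff] <- "up"
  out[!is.na(signed_fc) & signed_fc <= -cutoff] <- "down"
  out
}

#' Classify one site at one time point from its four contrast calls
#'
#' Implements the set-algebra selection of resistance-associated regulation.
#' Writing A = resistant vs parental (untreated), B = treated resistant vs
#' treated parental, C = treated vs untreated resistant, D = treated vs
#' untreated parental, a site is a resistance candidate in direction `d` at
#' a time point when:
#'
#' * A or B is regulated in direction `d`, and neither is regulated in the
#'   opposite direction (the union term; direction conflicts between A and B
#'   never classify);
#' * C is unchanged, missing, or regulated in the same direction `d` (the
#'   intersection term: the resistance change must not be a response the
#'   resistant line still mounts in the opposite direction);
#' * D is not regulated in direction `d` (the set-difference term: the
#'   change must not be a shared treatment response).
#'
#' D regulated opposite to `d` marks de-novo loss of a sensitivity-relevant
#' response; it is recorded as the `de_novo` annotation, not an exclusion.
#' Missing C or D calls never veto classification. When both A and B are
#' missing the time point is `insufficient_data`.
#'
#' @param calls named character vector (or data frame with columns)
#'   `A`, `B`, `C`, `D`, each in `up`, `down`, `unchanged`, `missing`.
#' @return for a vector input, a list with `status` (one of
#'   `resistance_up`, `resistance_down`, `none`, `insufficient_data`) and
#'   `de_novo` (logical); for a data frame input, a data frame with those
#'   two columns, row per input row.
#' @export
classify_site_at_timepoint <- function(calls) {
  if (!is.data.frame(calls)) {
    stopifnot(all(c("A", "B", "C", "D") %in% names(calls)))
    res <- classify_calls(calls[["A"]], calls[["B"]],
                          calls[["C"]], calls[["D"]])
    return(list(status = res$status, de_novo = res$de_novo))
  }
  stopifnot(all(c("A", "B", "C", "D") %in% names(calls)))
  classify_calls(calls$A, calls$B, calls$C, calls$D)
}

classify_calls <- function(A, B, C, D) {
  valid <- c("up", "down", "unchanged", "missing")
  if (!all(c(A, B, C, D) %in% valid))
    stop("calls must be one of: ", paste(valid, collapse = ", "))
  flip <- function(d) ifelse(d == "up", "down", "up")
  d <- ifelse(A %in% c("up", "down"), A,
              ifelse(B %in% c("up", "down"), B, NA_character_))
  insufficient <- A == "missing" & B == "missing"
  opp <- flip(d)
  ok_ab <- !is.na(d) & A != opp & B != opp
  ok_c <- C %in% c("unchanged", "missing") | C == d
  ok_d <- D != d
  is_marker <- !insufficient & ok_ab & ok_c & ok_d
  status <- ifelse(insufficient, "insufficient_data",
                   ifelse(is_marker, paste0("resistance_", d), "none"))
  data.frame(status = status,
             de_novo = is_marker & D == opp,
             stringsAsFactors = FALSE)
}

#' Aggregate per-time-point statuses into a marker classification
#'
#' Counts, per direction, the time points at which a site carries the
#' corresponding resistance status. `overlap_level` is the larger of the two
#' direction counts; time points discordant with the consensus direction
#' never contribute to it. The stringency tier is `three_of_three` at
#' overlap 3, `two_of_three` at overlap 2, `none` below. The consensus
#' direction is defined only at overlap >= 2.
#'
#' @param statuses character vector of per-time-point statuses (from
#'   [classify_site_at_timepoint()]), one per configured time point.
#' @param de_novo logical vector of per-time-point de-novo annotations.
#' @param min_overlap minimum concordant time points for marker selection;
#'   must be 2 or 3.
#' @return list with `overlap_level`, `consensus_direction` (`up`, `down` or
#'   `NA`), `tier`, `is_marker` (overlap_level >= min_overlap), and
#'   `de_novo_level` (contributing time points also carrying the de-novo
#'   annotation).
#' @export
aggregate_over_time <- function(statuses, de_novo = NULL, min_overlap = 2) {
  if (!min_overlap %in% c(2, 3))
    stop("min_overlap must be 2 or 3")
  if (is.null(de_novo)) de_novo <- rep(FALSE, length(statuses))
  stopifnot(length(de_novo) == length(statuses))
  n_up <- sum(statuses == "resistance_up")
  n_down <- sum(statuses == "resistance_down")
  overlap <- max(n_up, n_down)
  dir <- if (overlap >= 2) c("up", "down")[which.max(c(n_up, n_down))]
         else NA_character_
  tier <- if (overlap >= 3) "three_of_three"
          else if (overlap >= 2) "two_of_three" else "none"
  dn <- if (is.na(dir)) 0L
        else sum(de_novo & statuses == paste0("resistance_", dir))
  list(overlap_level = overlap,
       consensus_direction = dir,
       tier = tier,
       is_marker = overlap >= min_overlap,
       de_novo_level = dn)
}

#' Classify every site across all time points
#'
#' Runs [call_regulation()], [classify_site_at_timepoint()] and
#' [aggregate_over_time()] over a long fold-change table.
#'
#' @param fc_long result of [fold_change_table()].
#' @param cutoff regulation cutoff (> 1), default 1.5.
#' @param min_overlap minimum concordant time points (2 or 3).
#' @return data frame with one row per site: site metadata, per-time-point
#'   signed fold changes for contrasts A-D (`fc_<contrast>_<tp>`),
#'   per-time-point status (`status_<tp>`), `overlap_level`,
#'   `consensus_direction`, `tier`, `de_novo_level`, `de_novo`,
#'   `consensus_fc` (mean signed A/B fold change over contributing time
#'   points) and `is_marker`.
#' @export
classify_sites <- function(fc_long, cutoff = 1.5, min_overlap = 2) {
  if (!min_overlap %in% c(2, 3)) stop("min_overlap must be 2 or 3")
  sites <- attr(fc_long, "sites")
  if (is.null(sites))
    sites <- data.frame(site_key = sort(unique(fc_long$site_key)),
                        stringsAsFactors = FALSE)
  tps <- unique(fc_long$time_point)

  fc_long$call <- call_regulation(fc_long$signed_fc, cutoff)
  wide_fc <- list(); wide_call <- list()
  for (ct in c("A", "B", "C", "D")) {
    for (tp in tps) {
      sel <- fc_long$contrast == ct & fc_long$time_point == tp
      idx <- match(sites$site_key, fc_long$site_key[sel])
      wide_fc[[paste0("fc_", ct, "_", tp)]] <- fc_long$signed_fc[sel][idx]
      wide_call[[paste(ct, tp, sep = "_")]] <- {
        v <- fc_long$call[sel][idx]
        v[is.na(v)] <- "missing"
        v
      }
    }
  }

  status <- matrix(NA_character_, nrow(sites), length(tps),
                   dimnames = list(NULL, tps))
  de_novo <- matrix(FALSE, nrow(sites), length(tps),
                    dimnames = list(NULL, tps))
  for (tp in tps) {
    res <- classify_calls(wide_call[[paste0("A_", tp)]],
                          wide_call[[paste0("B_", tp)]],
                          wide_call[[paste0("C_", tp)]],
                          wide_call[[paste0("D_", tp)]])
    status[, tp] <- res$status
    de_novo[, tp] <- res$de_novo
  }

  agg <- lapply(seq_len(nrow(sites)), function(i)
    aggregate_over_time(status[i, ], de_novo[i, ], min_overlap))
  out <- cbind(sites, as.data.frame(wide_fc, optional = TRUE))
  for (tp in tps) out[[paste0("status_", tp)]] <- status[, tp]
  out$overlap_level <- vapply(agg, `[[`, integer(1), "overlap_level")
  out$consensus_direction <- vapply(agg, `[[`, character(1),
                                    "consensus_direction")
  out$tier <- vapply(agg, `[[`, character(1), "tier")
  out$de_novo_level <- vapply(agg, `[[`, integer(1), "de_novo_level")
  out$de_novo <- out$de_novo_level >= min_overlap
  out$is_marker <- vapply(agg, `[[`, logical(1), "is_marker")

  # consensus FC: mean signed A/B fold change over the time points whose
  # status matches the consensus direction
  cons <- rep(NA_real_, nrow(out))
  for (i in which(out$is_marker)) {
    want <- paste0("resistance_", out$consensus_direction[i])
    use <- tps[status[i, ] == want]
    vals <- unlist(lapply(use, function(tp)
      c(out[[paste0("fc_A_", tp)]][i], out[[paste0("fc_B_", tp)]][i])))
    cons[i] <- mean(vals, na.rm = TRUE)
  }
  out$consensus_fc <- cons
  attr(out, "cutoff") <- cutoff
  attr(out, "min_overlap") <- min_overlap
  attr(out, "timepoints") <- tps
  out
}

#' Select marker tables and summary counts
#'
#' Splits classified sites into per-tier, per-direction marker lists. The
#' `markers` table contains every site meeting the `min_overlap` requirement
#' used in [classify_sites()], ordered by decreasing |consensus fold change|
#' with site key as the tie-break, so reports are reproducible.
#'
#' @param classification result of [classify_sites()].
#' @return list with `markers` (ordered data frame), `up` and `down`
#'   (site-key vectors at the >= min_overlap tier), `up_strict` and
#'   `down_strict` (3-of-3 tier), and `summary` (named counts).
#' @export
select_markers <- function(classification) {
  m <- classification[classification$is_marker, , drop = FALSE]
  if (nrow(m) > 0) {
    m <- m[order(-abs(m$consensus_fc), m$site_key), , drop = FALSE]
    rownames(m) <- NULL
  }
  strict <- m[m$tier == "three_of_three", , drop = FALSE]
  up <- m$site_key[m$consensus_direction == "up"]
  down <- m$site_key[m$consensus_direction == "down"]
  up3 <- strict$site_key[strict$consensus_direction == "up"]
  down3 <- strict$site_key[strict$consensus_direction == "down"]
  list(markers = m,
       up = up, down = down,
       up_strict = up3, down_strict = down3,
       summary = list(n_sites = nrow(classification),
                      n_markers = nrow(m),
                      n_up = length(up), n_down = length(down),
                      n_up_strict = length(up3),
                      n_down_strict = length(down3),
                      n_de_novo = sum(m$de_novo)))
}

#' Discover resistance markers from phosphosite tables
#'
#' End-to-end convenience wrapper: read each per-time-point table, apply the
#' class-1 localization filter, orient ratios and compute signed fold
#' changes under the comparison design, classify each site at each time
#' point, aggregate across time points and select markers.
#'
#' @param tables named list (by time point) of file paths, data frames, or
#'   `phosphosite_table` objects.
#' @param design a [comparison_design()].
#' @param dialect a [phospho_dialect()] used when reading paths/raw frames.
#' @param class1_threshold localization-probability threshold (default
#'   0.75).
#' @param cutoff regulation cutoff (default 1.5).
#' @param min_overlap minimum concordant time points, 2 or 3.
#' @return list as [select_markers()], plus `classification` (the full
#'   per-site table) and `class1_fraction` (mean retained fraction across
#'   time points).
#' @export
discover_markers <- function(tables, design = comparison_design(),
                             dialect = phospho_dialect(),
                             class1_threshold = 0.75, cutoff = 1.5,
                             min_overlap = 2) {
  recs <- lapply(tables, function(t) {
    if (!inherits(t, "phosphosite_table"))
      t <- read_phosphosite_table(t, dialect)
    filter_class1(t, class1_threshold)
  })
  retained <- vapply(recs, function(r) attr(r, "retained_fraction"),
                     numeric(1))
  fc <- fold_change_table(recs, design)
  cls <- classify_sites(fc, cutoff = cutoff, min_overlap = min_overlap)
  out <- select_markers(cls)
  out$classification <- cls
  out$class1_fraction <- mean(retained, na.rm = TRUE)
  out
}

#' Write marker tables to disk
#'
#' Writes the ordered marker table as TSV and the summary counts as JSON.
#'
#' @param markers result of [select_markers()] or [discover_markers()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_marker_tables <- function(markers, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "markers.tsv")
  utils::write.table(markers$markers, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  js <- file.path(dir, "marker_summary.json")
  jsonlite::write_json(markers$summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(markers = tsv, summary = js))
}
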