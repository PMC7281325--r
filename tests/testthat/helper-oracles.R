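# Independent oracles used by unit and acceptance tests. These are written
# from the definitions (step-up formula, set algebra, combinatorics), not
# from the package implementation.

# Brute-force Benjamini-Hochberg step-up: q_i = min_{j: p_(j) >= p_i}
# of m * p_(j) / j, computed literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Set-algebra classification oracle: builds the explicit sets of the
# formula [(A) union (B)] intersect (C-compatible) setminus (D) per
# direction, over a table of call combinations.
oracle_set_formula <- function(calls) {
  n <- nrow(calls)
  idx <- seq_len(n)
  status <- rep("none", n)
  de_novo <- rep(FALSE, n)
  insufficient <- calls$A == "missing" & calls$B == "missing"
  status[insufficient] <- "insufficient_data"
  for (d in c("up", "down")) {
    opp <- setdiff(c("up", "down"), d)
    in_A <- idx[calls$A == d]
    in_B <- idx[calls$B == d]
    conflicted <- idx[calls$A == opp | calls$B == opp]
    s_union <- setdiff(union(in_A, in_B), conflicted)
    c_ok <- idx[calls$C %in% c("unchanged", "missing", d)]
    in_D <- idx[calls$D == d]
    members <- setdiff(setdiff(intersect(s_union, c_ok), in_D),
                       idx[insufficient])
    status[members] <- paste0("resistance_", d)
    de_novo[members] <- calls$D[members] == opp
  }
  data.frame(status = status, de_novo = de_novo, stringsAsFactors = FALSE)
}

# Exact upper-tail hypergeometric probability by direct enumeration.
oracle_hypergeom <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- seq(from = k, to = hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small well-formed phosphosite table in the default dialect.
make_toy_table <- function(n = 5, experiments = c("A", "B", "C", "D")) {
  tab <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    `Protein` = sprintf("P%05d", seq_len(n)),
                    `Gene names` = sprintf("GENE%04d", seq_len(n)),
                    `Amino acid` = rep(c("S", "T", "Y"), length.out = n),
                    `Position` = seq(10, by = 10, length.out = n),
                    `Multiplicity` = 1L,
                    `Localization prob` = seq(0.80, 0.99,
                                              length.out = n),
                    `Reverse` = "",
                    `Potential contaminant` = "")
  for (e in experiments)
    tab[[paste0("Ratio H/L normalized ", e)]] <- seq(0.5, 2, length.out = n)
  tab
}

# Site identity key of a raw MaxQuant-dialect table.
site_key_of <- function(tab) {
  paste(tab$Protein, tab$Position, tab$`Amino acid`, tab$Multiplicity,
        sep = "_")
}

# All 256 combinations of the four contrast calls.
all_call_combos <- function() {
  lv <- c("up", "down", "unchanged", "missing")
  expand.grid(A = lv, B = lv, C = lv, D = lv,
              stringsAsFactors = FALSE)
}
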