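make_sheet <- function(n_rep = 2) {
  ss <- expand.grid(replicate = seq_len(n_rep),
                    treatment = c("untreated", "treated"),
                    cell_line = c("parental", "resistant"),
                    stringsAsFactors = FALSE)
  ss$sample <- with(ss, paste(cell_line, treatment, replicate, sep = "_"))
  ss[, c("sample", "cell_line", "treatment", "replicate")]
}

make_null_matrix <- function(n_genes, ss, sd = 0.2) {
  mat <- matrix(rnorm(n_genes * nrow(ss), 8, sd), n_genes, nrow(ss),
                dimnames = list(sprintf("G%05d", seq_len(n_genes)),
                                ss$sample))
  mat
}

test_that("probe collapsing averages log2 values per gene", {
  mat <- matrix(c(4, 6, 10, 3), 4, 2,
                dimnames = list(paste0("pr", 1:4), c("s1", "s2")))
  mat[, 2] <- c(5, 7, 11, 2)
  map <- data.frame(probe = c("pr1", "pr2", "pr3"),
                    gene = c("GA", "GA", "GB"))
  out <- collapse_probes(mat, map)
  expect_equal(out["GA", ], c(s1 = 5, s2 = 6))
  expect_equal(out["GB", ], c(s1 = 10, s2 = 11))
  expect_equal(attr(out, "n_unmapped"), 1)
  expect_error(collapse_probes(mat, data.frame(probe = "px", gene = "GX")),
               "no probes")
  expect_error(collapse_probes(mat, rbind(map, map[1, ])), "at most one")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.5, 5)), rep(0.5, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- runif(sample(1:60, 1))
      expect_equal(bh_adjust(p), oracle_bh(p))
    }
  })
})

test_that("planted effects are estimated and detected across replicates", {
  ss <- make_sheet()
  reps <- 200
  fc <- numeric(reps)
  qsig <- logical(reps)
  withr::with_seed(2024, {
    for (r in seq_len(reps)) {
      mat <- make_null_matrix(10, ss, sd = 0.1)
      res_unt <- ss$sample[ss$cell_line == "resistant" &
                           ss$treatment == "untreated"]
      mat[1, res_unt] <- mat[1, res_unt] + 2
      de <- differential_expression(mat, ss, "baseline")
      fc[r] <- de$fc[1]
      qsig[r] <- de$q[1] < 0.05
    }
  })
  expect_gt(median(fc), 3.5)
  expect_lt(median(fc), 4.6)
  expect_gte(mean(qsig), 0.95)
})

test_that("swapping group labels negates the fold change, p unchanged", {
  ss <- make_sheet()
  withr::with_seed(7, mat <- make_null_matrix(50, ss))
  de1 <- differential_expression(mat, ss, "baseline")
  ss2 <- ss
  ss2$cell_line <- ifelse(ss$cell_line == "parental", "resistant",
                          "parental")
  de2 <- differential_expression(mat, ss2, "baseline")
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p, de2$p)
})

test_that("pooled t matches stats::t.test gene by gene without shrinkage", {
  ss <- make_sheet(3)
  withr::with_seed(5, mat <- make_null_matrix(20, ss))
  de <- differential_expression(mat, ss, "treated", prior_df = 0)
  g1 <- ss$sample[ss$cell_line == "resistant" & ss$treatment == "treated"]
  g2 <- ss$sample[ss$cell_line == "parental" & ss$treatment == "treated"]
  for (i in c(1, 7, 20)) {
    tt <- t.test(mat[i, g1], mat[i, g2], var.equal = TRUE)
    expect_equal(de$p[i], tt$p.value)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))))
  }
})

test_that("estimated fold changes agree with limma's linear-model fit", {
  ss <- make_sheet()
  withr::with_seed(6, mat <- make_null_matrix(30, ss))
  de <- differential_expression(mat, ss, "baseline")
  unt <- ss[ss$treatment == "untreated", ]
  design <- cbind(1, unt$cell_line == "resistant")
  fit <- limma::lmFit(mat[, unt$sample], design)
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]))
})

test_that("null p-values are uniform and q-values dominate p-values", {
  ss <- make_sheet(3)
  withr::with_seed(99, mat <- make_null_matrix(5000, ss))
  de <- differential_expression(mat, ss, "baseline", prior_df = 0)
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.01)
  expect_true(all(de$q >= de$p))
  expect_true(all(de$q <= 1))
  # q is monotone non-decreasing along the p ranking
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= 0))
})

test_that("degenerate zero-variance input raises an instructive error", {
  ss <- make_sheet()
  mat <- matrix(8, 10, nrow(ss),
                dimnames = list(paste0("g", 1:10), ss$sample))
  expect_error(differential_expression(mat, ss, "baseline"),
               "inject noise")
})

test_that("treatment-independent selection needs both contrasts, same
           sign, strict thresholds", {
  de_frame <- function(q, fc) {
    data.frame(gene = paste0("g", seq_along(q)),
               log2fc = sign(fc) * log2(abs(fc)),
               fc = fc, q = q, stringsAsFactors = FALSE)
  }
  base <- de_frame(q = c(0.01, 0.01, 0.01, 0.2, 0.049, 0.01),
                   fc = c(3, 3, 3, 3, 2.5, 2))
  trt <- de_frame(q = c(0.01, 0.2, 0.01, 0.01, 0.049, 0.01),
                  fc = c(3, 3, -3, 3, 2.5, 2))
  sel <- select_resistance_genes(base, trt)
  # g1: significant up in both -> selected; g2 fails treated significance;
  # g3 conflicts in direction; g4 fails baseline; g5 passes both (strict
  # q < 0.05 at 0.049); g6 fails strict FC > 2
  expect_setequal(sel$up, c("g1", "g5"))
  expect_length(sel$down, 0)

  sel2 <- select_resistance_genes(trt, base)
  expect_setequal(sel2$up, sel$up)
  expect_setequal(sel2$down, sel$down)

  down <- de_frame(q = c(0.01), fc = c(-4))
  expect_error(select_resistance_genes(base, down), "same gene universe")
  sel3 <- select_resistance_genes(de_frame(0.01, -4), de_frame(0.01, -3))
  expect_equal(sel3$down, "g1")
})
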