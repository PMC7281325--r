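test_that("configuration validation rejects impossible conditions", {
  expect_error(simulation_config(fractions = c(resistance_up = 0.8,
                                               resistance_down = 0.5)),
               "sum to at most 1")
  expect_error(simulation_config(effect_size = -2), "positive")
  expect_error(simulation_config(effect_size = 1), "exceed 1")
  expect_error(simulation_config(n_replicates_expr = 1), "variance")
  expect_error(simulation_config(missing_rate = 1.2), "missing_rate")
})

test_that("same seed and config reproduce the dataset exactly", {
  cfg <- simulation_config(n_sites = 150, n_genes = 200, seed = 5)
  d1 <- generate_silac_dataset(cfg)
  d2 <- generate_silac_dataset(cfg)
  expect_identical(d1$tables, d2$tables)
  expect_identical(d1$truth, d2$truth)
  e1 <- generate_expression_dataset(cfg)
  e2 <- generate_expression_dataset(cfg)
  expect_identical(e1$matrix, e2$matrix)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_synthetic_bundle(d1, e1, dir1)
  p2 <- write_synthetic_bundle(d2, e2, dir2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("site generation is independent of the expression sub-stream", {
  cfg1 <- simulation_config(n_sites = 100, n_genes = 150, seed = 9)
  cfg2 <- simulation_config(n_sites = 100, n_genes = 400, seed = 9)
  d1 <- generate_silac_dataset(cfg1)
  d2 <- generate_silac_dataset(cfg2)
  # ratios and probabilities coincide; only sampled gene symbols may differ
  expect_identical(d1$tables$T1$`Ratio H/L normalized A`,
                   d2$tables$T1$`Ratio H/L normalized A`)
  expect_identical(d1$tables$T2$`Localization prob`,
                   d2$tables$T2$`Localization prob`)
})

test_that("noise-free ratios follow the channel-orientation algebra", {
  cfg <- simulation_config(n_sites = 200, noise_sd = 0, missing_rate = 0,
                           seed = 3, include_exemplars = FALSE)
  d <- generate_silac_dataset(cfg)
  tab <- d$tables$T1
  tab <- tab[!startsWith(tab$Protein, "REV__") &
             !startsWith(tab$Protein, "CON__"), ]
  key <- site_key_of(tab)
  truth <- d$truth
  down <- truth$site_key[truth$category == "resistance_down"]
  up <- truth$site_key[truth$category == "resistance_up"]
  null <- truth$site_key[truth$category == "null"]
  # baseline pair: resistant is heavy, so a down site has raw H/L = 1/3
  expect_equal(tab$`Ratio H/L normalized A`[key %in% down],
               rep(1 / 3, length(down)), tolerance = 1e-5)
  # treated pair: resistant is light, so the same true change appears
  # inverted in the raw H/L ratio
  expect_equal(tab$`Ratio H/L normalized B`[key %in% down],
               rep(3, length(down)), tolerance = 1e-5)
  expect_equal(tab$`Ratio H/L normalized A`[key %in% up],
               rep(3, length(up)), tolerance = 1e-5)
  for (e in c("A", "B", "C", "D"))
    expect_equal(tab[[paste0("Ratio H/L normalized ", e)]][key %in% null],
                 rep(1, length(null)), tolerance = 1e-5)
})

test_that("class-1 share matches the configured fraction", {
  cfg <- simulation_config(n_sites = 10000, seed = 21)
  d <- generate_silac_dataset(cfg)
  share <- mean(d$truth$class1)
  expect_lt(abs(share - 0.74), 0.02)
  # and the observed share after reading + filtering agrees
  rec <- read_phosphosite_table(d$tables$T1)
  f <- filter_class1(rec)
  expect_lt(abs(attr(f, "retained_fraction") - 0.74), 0.02)
})

test_that("noise-free expression matrix carries the planted fold changes", {
  cfg <- simulation_config(n_genes = 300, effect_size = 4,
                           expr_noise_sd = 0, seed = 13)
  e <- generate_expression_dataset(cfg)
  ss <- e$samples
  grp <- function(line, trt)
    rowMeans(e$matrix[, ss$sample[ss$cell_line == line &
                                  ss$treatment == trt], drop = FALSE])
  lfc_base <- grp("resistant", "untreated") - grp("parental", "untreated")
  lfc_trt <- grp("resistant", "treated") - grp("parental", "treated")
  up <- e$truth$category == "trastuzumab_independent_up" &
    e$truth$gene != "TEAD2L"
  expect_equal(unname(2^lfc_base[up]), rep(4, sum(up)), tolerance = 1e-4)
  expect_equal(unname(2^lfc_trt[up]), rep(4, sum(up)), tolerance = 1e-4)
  expect_equal(unname(2^lfc_base[e$truth$gene == "TEAD2L"]), 2.24,
               tolerance = 1e-4)
  null <- e$truth$category == "null"
  expect_equal(unname(2^lfc_base[null]), rep(1, sum(null)),
               tolerance = 1e-4)
  expect_equal(unname(2^lfc_trt[null]), rep(1, sum(null)),
               tolerance = 1e-4)
})

test_that("truth labels are complete and unique per site and gene", {
  cfg <- simulation_config(n_sites = 500, n_genes = 400, seed = 17)
  d <- generate_silac_dataset(cfg)
  e <- generate_expression_dataset(cfg)
  expect_equal(nrow(d$truth), cfg$n_sites)
  expect_false(anyDuplicated(d$truth$site_key) > 0)
  expect_true(all(d$truth$category %in%
                    c("resistance_up", "resistance_down",
                      "treatment_response_only", "de_novo_reversal",
                      "null")))
  expect_equal(nrow(e$truth), cfg$n_genes)
  expect_false(anyDuplicated(e$truth$gene) > 0)
})

test_that("truth evaluation counts confusions as defined", {
  truth <- data.frame(site_key = paste0("s", 1:6),
                      category = c(rep("resistance_down", 3),
                                   rep("null", 3)))
  perfect <- data.frame(site_key = truth$site_key,
                        predicted_category = c(rep("resistance_down", 3),
                                               rep("none", 3)))
  ev <- truth_evaluation(perfect, truth)
  row <- ev[ev$category == "resistance_down", ]
  expect_equal(row$precision, 1)
  expect_equal(row$recall, 1)

  # 2 of 3 planted markers found plus 1 false positive
  partial <- perfect
  partial$predicted_category <- c("resistance_down", "resistance_down",
                                  "none", "resistance_down", "none", "none")
  row <- truth_evaluation(partial, truth)
  row <- row[row$category == "resistance_down", ]
  expect_equal(row$precision, 2 / 3)
  expect_equal(row$recall, 2 / 3)

  # empty prediction set: zero support, undefined precision, zero recall
  none <- perfect
  none$predicted_category <- "none"
  row <- truth_evaluation(none, truth)
  row <- row[row$category == "resistance_down", ]
  expect_true(is.na(row$precision))
  expect_equal(row$n_predicted, 0)
  expect_equal(row$recall, 0)

  bad <- data.frame(site_key = "unknown", predicted_category = "none")
  expect_error(truth_evaluation(bad, truth), "identifier mismatch")
})

test_that("two-time-point planted effects land in the 2-of-3 tier only", {
  cfg <- simulation_config(n_sites = 300, noise_sd = 0, missing_rate = 0,
                           fraction_two_timepoints = 1, seed = 31,
                           include_exemplars = FALSE)
  d <- generate_silac_dataset(cfg)
  res <- discover_markers(d$tables, d$design)
  planted <- d$truth[d$truth$category %in%
                       c("resistance_up", "resistance_down",
                         "de_novo_reversal") &
                     d$truth$class1, ]
  expect_setequal(c(res$up, res$down), planted$site_key)
  expect_length(res$up_strict, 0)
  expect_length(res$down_strict, 0)
  expect_true(all(res$markers$tier == "two_of_three"))
})
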