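test_that("BH adjustment matches its step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(123)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("group fold change follows direct arithmetic and flags degeneracy", {
  om <- cohort_from_fcs(rep(1, 4),
                        extra = rbind(
                          protB = c(8, 8, 8, 8, 4, 4, 4, 4) / 2,
                          protC = c(20, 20, 20, 20, 30, 30, 30, 30),
                          protD = c(0, 0, 0, 0, 5, 5, 5, 5)))
  fc <- group_fold_change(om)
  expect_equal(fc$fc[fc$feature == "protA"], 1)
  expect_equal(fc$fc[fc$feature == "protB"], 0.5)
  expect_equal(fc$fc[fc$feature == "protC"], 1.5)
  expect_true(fc$flagged[fc$feature == "protD"])  # zero control mean
  expect_true(is.na(fc$fc[fc$feature == "protD"]))
})

test_that("Welch test equals the closed-form statistic", {
  x <- rbind(same = c(1, 2, 3, 1, 2, 3),
             shift = c(10, 11, 12, 20, 21, 22))
  colnames(x) <- paste0("s", 1:6)
  grp <- rep(c("control", "primed"), each = 3)
  tt <- welch_t_per_feature(x, grp)
  expect_equal(tt$p[tt$feature == "same"], 1)

  a <- c(10, 11, 12, 13); b <- c(20, 21, 22, 23)
  x2 <- rbind(f = c(a, b))
  colnames(x2) <- paste0("s", 1:8)
  tt2 <- welch_t_per_feature(x2, rep(c("control", "primed"), each = 4))
  o <- welch_oracle(a, b)
  expect_equal(tt2$t, o$t, tolerance = 1e-12)
  expect_equal(tt2$df, o$df, tolerance = 1e-12)
  expect_equal(tt2$p, o$p, tolerance = 1e-12)
  expect_lt(tt2$p, 0.001)

  # fewer than 2 per group after NA removal -> NA
  x3 <- rbind(g = c(1, NA, NA, 4, 5, 6))
  colnames(x3) <- paste0("s", 1:6)
  tt3 <- welch_t_per_feature(x3, rep(c("control", "primed"), each = 3))
  expect_true(is.na(tt3$p))
})

test_that("presence rule counts per-donor modulated fold changes", {
  cfg <- univariate_config()
  om1 <- cohort_from_fcs(c(2, 2, 2, 2, 1, 1, 1))
  expect_equal(presence_modulation_filter(om1, cfg)$n_modulated, 4L)

  om2 <- cohort_from_fcs(rep(1, 7))
  expect_equal(presence_modulation_filter(om2, cfg)$n_modulated, 0L)

  om3 <- cohort_from_fcs(c(0.5, 0.6, 2, 1, 1, 1, 1))
  expect_equal(presence_modulation_filter(om3, cfg)$n_modulated, 3L)

  # boundary: FC exactly at fc_high is not modulated
  om4 <- cohort_from_fcs(rep(1.5, 7))
  expect_equal(presence_modulation_filter(om4, cfg)$n_modulated, 0L)
})

test_that("selection is the conjunction of all three criteria", {
  # strong p-value but fold change inside the window -> not selected
  set.seed(10)
  ni <- 7; r <- 3
  meta <- data.frame(
    observation = sprintf("o%02d", 1:(2 * ni * r)),
    individual = rep(sprintf("i%02d", 1:ni), each = 2 * r),
    condition = rep(rep(c("control", "primed"), each = r), ni),
    compartment = "EV", replicate = rep(1:r, 2 * ni),
    stringsAsFactors = FALSE)
  prim <- meta$condition == "primed"
  vals <- rbind(narrow = 2^(10 + 0.2 * prim + rnorm(2 * ni * r, 0, 0.01)),
                wide = 2^(10 + 2.0 * prim + rnorm(2 * ni * r, 0, 0.01)))
  colnames(vals) <- meta$observation
  om <- omics_matrix(vals, meta)
  res <- select_univariate(om)
  expect_lt(res$padj[res$feature == "narrow"], 0.05)  # significant...
  expect_false(res$selected[res$feature == "narrow"]) # ...but FC ~ 1.15
  expect_true(res$selected[res$feature == "wide"])
  expect_equal(res$direction[res$feature == "wide"], "up")
})

test_that("null cohorts stay near the nominal false-selection rate", {
  sim <- simulate_proteomics(sim_design(n_features = 400, n_de = 0,
                                        individual_sd = 0, seed = 31))
  res <- select_univariate(sim$matrix)
  # selection conjuncts three filters, so false selection is far below alpha
  expect_lte(mean(res$selected), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("extreme planted effects are always selected", {
  sim <- simulate_proteomics(sim_design(n_features = 200, n_de = 20,
                                        log2_effect = 2, noise_sd = 0.2,
                                        missing_rate = 0, seed = 17))
  res <- select_univariate(sim$matrix)
  expect_true(all(sim$truth$feature %in% res$feature[res$selected]))
})

test_that("condition swap inverts fold changes and preserves the selection", {
  sim <- simulate_proteomics(sim_design(n_features = 120, n_de = 12,
                                        seed = 23))
  om <- sim$matrix
  res <- select_univariate(om)

  sw <- om
  cc <- as.character(sw$metadata$condition)
  sw$metadata$condition <- factor(ifelse(cc == "control", "primed", "control"),
                                  levels = c("control", "primed"))
  res_sw <- select_univariate(sw)
  ok <- !res$flagged & !res_sw$flagged
  expect_equal(res_sw$fc[ok], 1 / res$fc[ok], tolerance = 1e-12)
  # thresholds are reciprocal (1.5 and 1/1.5), so the selected set is stable
  expect_setequal(res$feature[res$selected], res_sw$feature[res_sw$selected])
})

test_that("selection is invariant to feature order", {
  sim <- simulate_proteomics(sim_design(n_features = 50, n_de = 5, seed = 3))
  om <- sim$matrix
  perm <- sample(nrow(om$values))
  om2 <- omics_matrix(om$values[perm, ], om$metadata)
  r1 <- select_univariate(om)
  r2 <- select_univariate(om2)
  expect_setequal(r1$feature[r1$selected], r2$feature[r2$selected])
})

test_that("delta-delta-Ct relative quantities follow the definition", {
  expect_equal(ddct_relative_expression(20, 20, 20, 20), 1)
  expect_equal(ddct_relative_expression(24, 20, 26, 20), 4)
  # ddCt of +1 halves the relative quantity
  expect_equal(ddct_relative_expression(21, 20, 20, 20), 0.5)
  expect_error(ddct_relative_expression(NA, 20, 20, 20), "finite")
})
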