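rand_instance <- function(n = 10, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("o", 1:n), sprintf("f%02d", 1:p)))
  cls <- rep(c("control", "primed"), length.out = n)
  list(x = x, cls = cls)
}

test_that("preprocessing stores and reapplies the training transform", {
  x <- matrix(c(2, 4, 10, 30), 2, 2, dimnames = list(NULL, c("a", "b")))
  pp <- preprocess(x, "autoscale")
  expect_equal(unname(colMeans(pp$z)), c(0, 0))
  expect_equal(unname(apply(pp$z, 2, sd)), c(1, 1))
  expect_equal(pp$z[, "a"], c(-1, 1) / sqrt(2), ignore_attr = TRUE)

  # centered input is unchanged under centering
  xc <- scale(rand_instance(8, 3)$x, scale = FALSE)
  attr(xc, "scaled:center") <- NULL
  ppc <- preprocess(unclass(xc), "center")
  expect_equal(ppc$z, unclass(xc), ignore_attr = TRUE)

  # out-of-fold data uses training parameters, not its own
  inst <- rand_instance(10, 4, seed = 2)
  pp2 <- preprocess(inst$x[1:6, ], "autoscale")
  znew <- apply_preprocess(pp2, inst$x[7:10, ])
  manual <- sweep(sweep(inst$x[7:10, ], 2, pp2$center, "-"), 2, pp2$scale, "/")
  expect_equal(znew, manual)

  # zero-variance feature dropped with warning under autoscale
  x3 <- cbind(inst$x[, 1:2], const = 5)
  expect_warning(pp3 <- preprocess(x3, "autoscale"), "zero-variance")
  expect_false("const" %in% colnames(pp3$z))
})

test_that("PCA has SVD structure: orthonormal loadings, full reconstruction", {
  inst <- rand_instance(6, 10, seed = 4)
  pc <- pca_fit(inst$x, mode = "center")
  # reconstruction from all components
  rec <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(rec - pc$preprocess$z)), 1e-10)
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  ev <- pc$explained_variance
  expect_true(all(diff(ev) <= 1e-12) && all(ev >= 0) && sum(ev) <= 1 + 1e-12)
  # score columns mutually orthogonal
  g <- crossprod(pc$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)

  # single varying feature carries 100% of the variance
  x1 <- cbind(v = rnorm(8), w = rep(1, 8), u = rep(2, 8))
  pc1 <- pca_fit(x1, n_components = 1, mode = "center")
  expect_equal(pc1$explained_variance[1], 1)

  # duplicating every observation leaves loadings unchanged
  pc2 <- pca_fit(rbind(inst$x, inst$x), mode = "center")
  aligned <- sweep(pc2$loadings[, 1:5], 2,
                   sign(colSums(pc2$loadings[, 1:5] * pc$loadings[, 1:5])),
                   "*")
  expect_equal(aligned, pc$loadings[, 1:5], tolerance = 1e-8)

  expect_error(pca_fit(inst$x[1, , drop = FALSE]), ">= 2")
  expect_error(pca_fit(inst$x, n_components = 50), "exceeds")
})

test_that("ranking's first pick equals the exhaustive single-feature argmax", {
  for (s in 1:20) {
    set.seed(s)
    p <- sample(5:50, 1)
    inst <- rand_instance(n = 12, p = p, seed = s + 100)
    # plant a moderately informative feature so argmax is non-trivial
    j <- sample(p, 1)
    inst$x[, j] <- inst$x[, j] + 2 * (inst$cls == "primed")
    cls_f <- factor(inst$cls, c("control", "primed"))

    # each criterion against its own exhaustive single-feature oracle;
    # argmax with first-in-ascending-identifier tie-break
    Dsep <- single_feature_sep(inst$x, cls_f)
    rk <- ranking_pca(inst$x, inst$cls, budget = 1)
    expect_equal(rk$feature[1], names(which.max(Dsep[sort(names(Dsep))])))
    expect_equal(unname(rk$score[1]), unname(max(Dsep)), tolerance = 1e-8)

    Dstd <- single_feature_D(inst$x, cls_f)
    rk2 <- ranking_pca(inst$x, inst$cls, budget = 1,
                       criterion = "standardized")
    expect_equal(rk2$feature[1], names(which.max(Dstd[sort(names(Dstd))])))
    expect_equal(unname(rk2$score[1]), unname(max(Dstd)), tolerance = 1e-8)
  }
})

test_that("ranking ties break by ascending identifier; constants score zero", {
  x <- matrix(5, 6, 4, dimnames = list(NULL, c("b2", "a1", "d4", "c3")))
  cls <- rep(c("control", "primed"), 3)
  rk <- ranking_pca(x, cls, budget = 4)
  expect_equal(rk$feature, c("a1", "b2", "c3", "d4"))
  expect_equal(rk$score, rep(0, 4))

  # a perfectly separating feature outranks noise; under the
  # standardized criterion it carries the infinite sentinel
  set.seed(1)
  xs <- matrix(rnorm(60), 10, 6,
               dimnames = list(NULL, sprintf("f%d", 1:6)))
  cls2 <- rep(c("control", "primed"), each = 5)
  xs[, "f4"] <- ifelse(cls2 == "primed", 1, 0)   # zero within-class sd
  rk2 <- ranking_pca(xs, cls2, budget = 3)
  expect_equal(rk2$feature[1], "f4")
  expect_true(is.finite(rk2$score[1]))
  rk2s <- ranking_pca(xs, cls2, budget = 3, criterion = "standardized")
  expect_equal(rk2s$feature[1], "f4")
  expect_true(is.infinite(rk2s$score[1]))

  expect_error(ranking_pca(xs, cls2, budget = 10), "budget")
  expect_error(ranking_pca(xs, rep("control", 10)), "two classes")
})

test_that("1-LV PLS-DA weights equal the normalized X'y closed form", {
  for (s in 1:25) {
    inst <- rand_instance(n = 8 + (s %% 5), p = 3 + (s %% 7), seed = s)
    m <- plsda_fit(inst$x, inst$cls, n_lv = 1)
    z <- m$preprocess$z
    y <- ifelse(inst$cls == "primed", 1, -1)
    w_ref <- drop(crossprod(z, y - mean(y)))
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    expect_lt(max(abs(m$W[, 1] - w_ref)), 1e-10)
    expect_lt(max(abs(m$b / sqrt(sum(m$b^2)) - w_ref * sign(sum(m$b * w_ref)) /
                        1)), 1e-10)  # b proportional to w at 1 LV
  }
})

test_that("PLS-DA separates a signed single-feature problem", {
  y_cls <- rep(c("control", "primed"), each = 4)
  x <- cbind(sig = ifelse(y_cls == "primed", 1, -1) + rnorm(8, 0, 1e-6))
  m <- plsda_fit(x, y_cls)
  expect_gt(m$b["sig"], 0)
  pr <- plsda_predict(m, x)
  expect_equal(pr$class, y_cls)

  # flipping a feature's sign flips its coefficient, not the predictions
  inst <- rand_instance(10, 5, seed = 9)
  inst$x[, 2] <- inst$x[, 2] + (inst$cls == "primed")
  m1 <- plsda_fit(inst$x, inst$cls)
  x2 <- inst$x; x2[, 3] <- -x2[, 3]
  m2 <- plsda_fit(x2, inst$cls)
  expect_equal(unname(m2$b[3]), -unname(m1$b[3]), tolerance = 1e-10)
  expect_equal(plsda_predict(m2, x2)$yhat, plsda_predict(m1, inst$x)$yhat,
               tolerance = 1e-10)

  expect_error(plsda_fit(inst$x, rep("primed", 10)), "two classes")
  expect_error(plsda_fit(inst$x, inst$cls, n_lv = 9), "rank|exceeds")
})

test_that("predictions equal the linear rule recomputed independently", {
  inst <- rand_instance(12, 6, seed = 5)
  inst$x[, 1] <- inst$x[, 1] + 2 * (inst$cls == "primed")
  m <- plsda_fit(inst$x, inst$cls, n_lv = 2)
  pr <- plsda_predict(m, inst$x)
  z <- sweep(sweep(inst$x[, names(m$b)], 2, m$preprocess$center, "-"),
             2, m$preprocess$scale, "/")
  yhat_ref <- unname(drop(z %*% m$b) + m$y_mean)
  expect_equal(pr$yhat, yhat_ref, tolerance = 1e-12)
  expect_equal(pr$class, ifelse(yhat_ref > 0, "primed", "control"))

  # exact zero prediction ties to the control class with a warning
  m0 <- m
  m0$b[] <- 0; m0$y_mean <- 0
  expect_warning(pr0 <- plsda_predict(m0, inst$x), "tie")
  expect_true(all(pr0$class == "control"))
})

test_that("accuracy and NER follow their definitions", {
  perfect <- matrix(c(5, 0, 0, 7), 2, 2)
  expect_equal(unname(classification_metrics(perfect)),
               c(100, 100))

  cm <- matrix(c(1, 0, 1, 4), 2, 2,
               dimnames = list(c("control", "primed"),
                               c("control", "primed")))
  # control: 1 of 2 correct; primed: 4 of 4
  m <- classification_metrics(cm)
  expect_equal(unname(m["accuracy"]), 100 * 5 / 6, tolerance = 1e-10)
  expect_equal(round(unname(m["accuracy"]), 2), 83.33)
  expect_equal(unname(m["ner"]), 75)

  # balanced classes with equal recall: NER equals accuracy
  bal <- matrix(c(3, 1, 1, 3), 2, 2)
  mb <- classification_metrics(bal)
  expect_equal(unname(mb["ner"]), unname(mb["accuracy"]))

  expect_warning(classification_metrics(matrix(c(2, 1, 0, 0), 2, 2,
                                               byrow = TRUE)),
                 "zero support")
  expect_error(classification_metrics(matrix(0, 2, 2)), "positive total")
})

test_that("LOO folds partition the observations by individual", {
  sim <- simulate_proteomics(sim_design(n_individuals = 5, n_features = 60,
                                        n_de = 10, seed = 12))
  cv <- loo_cv_by_individual(sim$matrix, budget = 10)
  expect_equal(length(cv$fold_features), 5)
  expect_setequal(cv$predictions$observation,
                  sim$matrix$metadata$observation)
  expect_equal(nrow(cv$predictions), ncol(sim$matrix$values))
  # each fold holds out exactly one individual's observations
  for (k in unique(cv$predictions$fold)) {
    held <- cv$predictions[cv$predictions$fold == k, ]
    expect_equal(length(unique(held$individual)), 1)
  }
  expect_equal(sum(cv$confusion_cv), ncol(sim$matrix$values))
})

test_that("a strongly separated cohort classifies perfectly in CV", {
  sim <- simulate_proteomics(sim_design(n_individuals = 5, n_features = 80,
                                        n_de = 20, log2_effect = 3,
                                        seed = 21))
  cv <- loo_cv_by_individual(sim$matrix, budget = 10)
  expect_equal(unname(cv$metrics_cv), c(100, 100))
  expect_equal(unname(cv$metrics_fit), c(100, 100))
})

test_that("coefficient directions recover planted regulation and symmetry", {
  sim <- simulate_proteomics(sim_design(n_features = 60, n_de = 10,
                                        log2_effect = 3, seed = 14))
  x <- t(log2(sim$matrix$values))
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  cls <- as.character(sim$matrix$metadata$condition)
  m <- plsda_fit(x[, sim$truth$feature], cls)
  dirs <- coefficient_directions(m)
  got <- dirs$direction[match(sim$truth$feature, dirs$feature)]
  expect_equal(got, sim$truth$direction)
  # ordered by decreasing |coefficient|
  expect_true(all(diff(abs(dirs$coefficient)) <= 1e-12))

  swapped <- ifelse(cls == "control", "primed", "control")
  m2 <- plsda_fit(x[, sim$truth$feature], swapped)
  d2 <- coefficient_directions(m2)
  expect_true(all(d2$direction[match(dirs$feature, d2$feature)] !=
                    dirs$direction | dirs$direction == "none"))
})

test_that("selection intersection is plain set algebra", {
  sim <- simulate_proteomics(sim_design(n_features = 80, n_de = 10,
                                        seed = 19))
  uni <- select_univariate(sim$matrix)
  rk <- ranking_pca(t(log2(sim$matrix$values)),
                    sim$matrix$metadata$condition, budget = 20)
  inter <- intersect_selections(uni, rk)
  expect_true(all(inter$features$feature %in% uni$feature[uni$selected]))
  expect_true(all(inter$features$feature %in% rk$feature))

  # univariate subset of multivariate -> intersection is the univariate set
  inter2 <- intersect_selections(uni, uni$feature[uni$selected])
  expect_setequal(inter2$features$feature, uni$feature[uni$selected])

  # disjoint inputs -> empty with warning
  expect_warning(inter3 <- intersect_selections(uni, "not_a_feature"),
                 "empty")
  expect_equal(nrow(inter3$features), 0)
})
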