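#' Center / autoscale a data matrix, keeping the transform
#'
#' Column-wise preprocessing as used throughout the multivariate stage:
#' `"center"` subtracts feature means; `"autoscale"` additionally divides
#' by feature standard deviations (the chemometrics convention before PCA
#' and PLS). Missing values are imputed at the feature mean (i.e. 0 after
#' centering). Zero-variance features are dropped with a warning under
#' autoscaling. The returned transform can be applied to new
#' (out-of-fold) observations with [apply_preprocess()].
#'
#' @param x numeric matrix, observations x features, with column names.
#' @param mode `"autoscale"` (default) or `"center"`.
#' @return list of class `preprocess`: `z` (transformed matrix), `center`,
#'   `scale`, `mode`, `dropped` (names of removed zero-sd features).
#' @export
preprocess <- function(x, mode = c("autoscale", "center")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (nrow(x) < 2L) stop("need >= 2 observations", call. = FALSE)
  ctr <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  dropped <- character(0)
  if (mode == "autoscale") {
    zero <- !is.finite(sdv) | sdv == 0
    if (all(zero)) stop("all features have zero variance", call. = FALSE)
    if (any(zero)) {
      dropped <- colnames(x)[zero]
      warning(length(dropped), " zero-variance feature(s) dropped",
              call. = FALSE)
      x <- x[, !zero, drop = FALSE]
      ctr <- ctr[!zero]; sdv <- sdv[!zero]
    }
  } else {
    sdv <- rep(1, length(ctr))
    names(sdv) <- names(ctr)
  }
  z <- sweep(sweep(x, 2, ctr, "-"), 2, sdv, "/")
  z[is.na(z)] <- 0
  structure(list(z = z, center = ctr, scale = sdv, mode = mode,
                 dropped = dropped), class = "preprocess")
}

#' Apply a stored preprocessing transform to new observations
#'
#' Uses the training means/scales, never the new data's own; missing
#' values map to the training feature mean.
#'
#' @param pp a `preprocess` object.
#' @param x_new matrix with (at least) the transform's features as columns.
#' @return transformed matrix restricted to the transform's features.
#' @export
apply_preprocess <- function(pp, x_new) {
  stopifnot(inherits(pp, "preprocess"))
  feats <- names(pp$center)
  missing <- setdiff(feats, colnames(x_new))
  if (length(missing))
    stop("new data lacks feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x_new[, feats, drop = FALSE], 2, pp$center, "-"),
             2, pp$scale, "/")
  z[is.na(z)] <- 0
  z
}

# internal: autoscale retaining zero-sd features as all-zero columns
# (needed by the ranking kernel where every feature keeps its slot)
autoscale_keep <- function(x) {
  ctr <- colMeans(x, na.rm = TRUE)
  ctr[is.nan(ctr)] <- 0
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf   # maps column to exact zeros
  z <- sweep(sweep(x, 2, ctr, "-"), 2, sdv, "/")
  z[is.na(z)] <- 0
  z
}

#' Principal component analysis via singular value decomposition
#'
#' @param x numeric matrix, observations x features.
#' @param n_components number of components to keep; defaults to the
#'   maximum `min(nrow - 1, ncol)`.
#' @param mode preprocessing mode, see [preprocess()].
#' @return list of class `pca_result`: `scores` (obs x comp), `loadings`
#'   (features x comp, orthonormal columns), `explained_variance`
#'   (fractions), `preprocess`.
#' @export
pca_fit <- function(x, n_components = NULL, mode = c("autoscale", "center")) {
  mode <- match.arg(mode)
  if (nrow(x) < 2L) stop("PCA needs >= 2 observations", call. = FALSE)
  pp <- preprocess(x, mode)
  z <- pp$z
  k_max <- min(nrow(z) - 1L, ncol(z))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max)
    stop("n_components exceeds min(observations - 1, features)",
         call. = FALSE)
  sv <- svd(z)
  ev <- sv$d^2 / sum(sv$d^2)
  k <- n_components
  scores <- z %*% sv$v[, seq_len(k), drop = FALSE]
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(z), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(z), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)], preprocess = pp),
            class = "pca_result")
}

# internal: map class labels to the -1/+1 coding (control -> -1,
# primed -> +1; otherwise first factor level -> -1)
class_coding <- function(classes) {
  f <- droplevels(as.factor(classes))
  if (nlevels(f) != 2L)
    stop("exactly two classes required", call. = FALSE)
  lv <- levels(f)
  if (all(c("control", "primed") %in% lv)) lv <- c("control", "primed")
  y <- ifelse(as.character(f) == lv[2], 1, -1)
  list(y = y, negative = lv[1], positive = lv[2], f = factor(f, levels = lv))
}

#' Rank features by the class discrimination they add in PCA score space
#'
#' Greedy forward selection: starting from the empty set, each unranked
#' feature is tentatively added, PCA (autoscaled) is run on the candidate
#' set, and the discrimination score
#' D = |mean(t | class+) - mean(t | class-)| / pooled within-class sd(t),
#' summed over the first `n_pc` score vectors, is computed; the feature
#' maximizing D is permanently added. Perfect separation (pooled sd 0,
#' unequal means) scores +Inf and ranks ahead of all finite scores; ties
#' are broken by ascending feature identifier.
#'
#' Two discrimination criteria are available. `"separation"` (the
#' default) scores a candidate set by the absolute between-class
#' difference of the PC score means; because autoscaling bounds every
#' feature's contribution, this variant keeps accumulating genuinely
#' class-separated variables and is the criterion used for biomarker
#' recovery. `"standardized"` additionally divides by the pooled
#' within-class sd of the scores; it sharpens the very first picks but,
#' once the classes are fully separated, rewards variance-cancelling
#' "suppressor" variables, so deep ranks mix in features without a class
#' effect — use it when the goal is a minimal classification panel
#' rather than an exhaustive biomarker list.
#'
#' @param x numeric matrix, observations x features (column names are the
#'   feature identifiers). Missing values are mean-imputed.
#' @param classes two-level class labels per observation.
#' @param n_pc number of leading PCs scored, default 1.
#' @param budget number of features to rank; default all.
#' @param criterion `"separation"` or `"standardized"` (see above).
#' @return data.frame of class `ranking_result`: `rank`, `feature`,
#'   `score`; attributes `n_pc`, `budget`, `criterion`.
#' @export
ranking_pca <- function(x, classes, n_pc = 1L, budget = ncol(x),
                        criterion = c("separation", "standardized")) {
  criterion <- match.arg(criterion)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  cc <- class_coding(classes)
  if (min(table(cc$f)) < 2L)
    stop("each class needs >= 2 observations", call. = FALSE)
  if (budget > ncol(x))
    stop("budget cannot exceed the number of features", call. = FALSE)
  ord <- order(colnames(x))            # ascending-identifier tie-break
  xo <- x[, ord, drop = FALSE]
  z <- autoscale_keep(xo)
  C <- crossprod(z)
  cls <- as.integer(cc$y == 1)
  res <- rank_pca_greedy_cpp(z, C, cls, as.integer(n_pc), as.integer(budget),
                             criterion == "standardized")
  feats <- colnames(xo)[res$order]
  out <- data.frame(rank = seq_along(feats), feature = feats,
                    score = res$score, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranking_result", "data.frame")
  attr(out, "n_pc") <- as.integer(n_pc)
  attr(out, "budget") <- as.integer(budget)
  attr(out, "criterion") <- criterion
  out
}

#' Fit a PLS-DA model (NIPALS PLS1 against a -1/+1 class coding)
#'
#' The class response is coded -1 for control and +1 for primed samples
#' and regressed on the preprocessed feature block by NIPALS partial
#' least squares. With one latent variable the weight vector is
#' proportional to X'y. The regression coefficients map preprocessed
#' features to the continuous prediction; the decision threshold sits at
#' predicted y = 0.
#'
#' @param x numeric matrix, observations x features.
#' @param classes two-level labels (control/primed or any two levels, the
#'   second being the positive class).
#' @param n_lv number of latent variables, default 1.
#' @param mode preprocessing, see [preprocess()].
#' @return object of class `plsda_model`: weights `W`, X-loadings `P`,
#'   Y-loadings `q`, `scores`, coefficients `b` (preprocessed scale),
#'   `y_mean`, the preprocessing transform and the class coding.
#' @export
plsda_fit <- function(x, classes, n_lv = 1L, mode = c("autoscale", "center")) {
  mode <- match.arg(mode)
  cc <- class_coding(classes)
  if (length(unique(cc$y)) < 2L) stop("constant class vector", call. = FALSE)
  pp <- preprocess(x, mode)
  z <- pp$z
  rk <- qr(z)$rank
  if (n_lv > rk)
    stop("n_lv (", n_lv, ") exceeds the rank of the preprocessed matrix (",
         rk, ")", call. = FALSE)
  y <- cc$y
  y_mean <- mean(y)
  e <- z; f <- y - y_mean
  p_dim <- ncol(z)
  W <- matrix(0, p_dim, n_lv); P <- matrix(0, p_dim, n_lv)
  Tm <- matrix(0, nrow(z), n_lv); q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(e, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("residual X'y vanished at component ", a,
           "; reduce n_lv", call. = FALSE)
    w <- w / nw
    t_a <- drop(e %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(e, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    e <- e - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  names(b) <- colnames(z)
  dimnames(W) <- dimnames(P) <- list(colnames(z), paste0("LV", seq_len(n_lv)))
  dimnames(Tm) <- list(rownames(z), paste0("LV", seq_len(n_lv)))
  structure(list(W = W, P = P, q = q, scores = Tm, b = b, y_mean = y_mean,
                 n_lv = as.integer(n_lv), preprocess = pp,
                 coding = c(stats::setNames(-1, cc$negative),
                            stats::setNames(+1, cc$positive)),
                 negative = cc$negative, positive = cc$positive),
            class = "plsda_model")
}

#' Predict classes from a PLS-DA model
#'
#' Continuous predictions are thresholded at 0: positive values map to
#' the positive (primed) class, zero maps to the negative (control) class
#' with a warning.
#'
#' @param model a [plsda_fit()] model.
#' @param x_new matrix of new observations with the model's features.
#' @return data.frame with `observation`, `yhat`, `class`.
#' @export
plsda_predict <- function(model, x_new) {
  stopifnot(inherits(model, "plsda_model"))
  z <- apply_preprocess(model$preprocess, x_new)
  yhat <- drop(z %*% model$b) + model$y_mean
  if (any(yhat == 0))
    warning("tie (predicted y exactly 0) assigned to the negative class",
            call. = FALSE)
  cls <- ifelse(yhat > 0, model$positive, model$negative)
  data.frame(observation = if (!is.null(rownames(x_new))) rownames(x_new)
             else seq_along(yhat),
             yhat = yhat, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Accuracy and non-error rate from a confusion matrix
#'
#' Accuracy is the percentage of correctly assigned observations
#' (100 * trace / total); NER% is the unweighted mean of the per-class
#' accuracies (recalls), robust to class imbalance. Classes with zero
#' support are excluded from the NER average with a warning.
#'
#' @param confusion square contingency table/matrix, true classes in
#'   rows, predicted in columns (same ordering).
#' @return named numeric vector `c(accuracy, ner)`, both in percent.
#' @export
classification_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || sum(cm) == 0)
    stop("confusion matrix must be square with positive total",
         call. = FALSE)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  support <- rowSums(cm)
  if (any(support == 0))
    warning("class(es) with zero support excluded from NER%", call. = FALSE)
  recalls <- diag(cm)[support > 0] / support[support > 0]
  c(accuracy = acc, ner = 100 * mean(recalls))
}

#' Leave-one-individual-out cross-validation of Ranking-PCA + PLS-DA
#'
#' One fold per donor: all of that donor's observations (both conditions,
#' every replicate) are held out together. Inside each fold, feature
#' ranking (when `features` is `NULL`), preprocessing and the PLS-DA fit
#' are recomputed on training data only, so no selection information
#' leaks into the held-out predictions. Held-out predictions are pooled
#' into a single confusion matrix; fitting metrics come from the
#' full-data model.
#'
#' @param om an [omics_matrix()]; the multivariate stage works on
#'   log2-transformed intensities when `log2 = TRUE` (default).
#' @param budget number of features Ranking-PCA keeps per fold.
#' @param n_pc PCs scored inside Ranking-PCA, default 1.
#' @param n_lv PLS-DA latent variables, default 1.
#' @param features optional fixed feature set; when given, no per-fold
#'   selection is performed (used e.g. for univariate-selected panels).
#' @param mode preprocessing mode for PLS-DA.
#' @param log2 transform intensities to log2 before modelling.
#' @return list of class `cv_report`: per-observation `predictions`
#'   (fold, individual, truth, predicted, yhat), `confusion_cv`,
#'   `confusion_fit`, `metrics_cv`, `metrics_fit`, `selected_full`
#'   (full-data ranking or the fixed panel), `fold_features`.
#' @export
loo_cv_by_individual <- function(om, budget = 50L, n_pc = 1L, n_lv = 1L,
                                 features = NULL,
                                 mode = c("autoscale", "center"),
                                 log2 = TRUE,
                                 criterion = c("separation",
                                               "standardized")) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  stopifnot(inherits(om, "omics_matrix"))
  x <- obs_matrix(om)
  if (log2) x <- base::log2(x)
  cls <- as.character(obs_conditions(om))
  ind <- om$metadata$individual
  inds <- unique(ind)
  if (length(inds) < 3L) stop("need >= 3 individuals for LOO", call. = FALSE)

  one_sided <- vapply(inds, function(i)
    length(unique(cls[ind == i])) < 2L, logical(1))
  if (any(one_sided))
    warning("individual(s) present in only one condition: ",
            paste(inds[one_sided], collapse = ", "), call. = FALSE)

  fit_features <- function(xtr, ctr) {
    if (!is.null(features)) return(intersect(features, colnames(xtr)))
    rk <- ranking_pca(xtr, ctr, n_pc = n_pc,
                      budget = min(budget, ncol(xtr)),
                      criterion = criterion)
    rk$feature
  }

  preds <- vector("list", length(inds))
  fold_feats <- vector("list", length(inds))
  names(fold_feats) <- inds
  for (k in seq_along(inds)) {
    i <- inds[k]
    tr <- ind != i; te <- ind == i
    feats <- fit_features(x[tr, , drop = FALSE], cls[tr])
    fold_feats[[k]] <- feats
    m <- plsda_fit(x[tr, feats, drop = FALSE], cls[tr], n_lv = n_lv,
                   mode = mode)
    pr <- plsda_predict(m, x[te, , drop = FALSE])
    preds[[k]] <- data.frame(fold = k, individual = i,
                             observation = pr$observation,
                             truth = cls[te], predicted = pr$class,
                             yhat = pr$yhat, stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)

  lev <- c("control", "primed")
  confusion_cv <- table(factor(preds$truth, lev),
                        factor(preds$predicted, lev))

  feats_full <- fit_features(x, cls)
  m_full <- plsda_fit(x[, feats_full, drop = FALSE], cls, n_lv = n_lv,
                      mode = mode)
  pr_full <- plsda_predict(m_full, x)
  confusion_fit <- table(factor(cls, lev), factor(pr_full$class, lev))

  structure(list(predictions = preds,
                 confusion_cv = confusion_cv,
                 confusion_fit = confusion_fit,
                 metrics_cv = classification_metrics(confusion_cv),
                 metrics_fit = classification_metrics(confusion_fit),
                 selected_full = feats_full,
                 fold_features = fold_feats,
                 model_full = m_full),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", length(x$fold_features), " folds (one per individual)\n",
      sep = "")
  cat(sprintf("  fitting: accuracy %.1f%%, NER %.1f%%\n",
              x$metrics_fit["accuracy"], x$metrics_fit["ner"]))
  cat(sprintf("  cross-validation: accuracy %.1f%%, NER %.1f%%\n",
              x$metrics_cv["accuracy"], x$metrics_cv["ner"]))
  invisible(x)
}

#' Feature directions and importance from PLS-DA coefficients
#'
#' Positive regression coefficients correspond to features up-regulated
#' in the positive (primed) class, negative coefficients to
#' down-regulated ones; features are ordered by decreasing absolute
#' coefficient (decreasing discrimination ability).
#'
#' @param model a [plsda_fit()] model.
#' @return data.frame with `feature`, `coefficient`, `direction`
#'   (up/down/none), ordered by decreasing |coefficient|.
#' @export
coefficient_directions <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  b <- model$b
  out <- data.frame(feature = names(b), coefficient = unname(b),
                    direction = ifelse(b == 0, "none",
                                       ifelse(b > 0, "up", "down")),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient), out$feature), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Intersect univariate and multivariate selections
#'
#' The final modulated panel is the set intersection of the features
#' passing the univariate rule and the top-ranked multivariate features;
#' directions are taken from the univariate fold changes.
#'
#' @param univariate a `univariate_result` from [select_univariate()].
#' @param multivariate a `ranking_result` from [ranking_pca()], or a
#'   character vector of features.
#' @param budget optional cap on how many top-ranked multivariate
#'   features enter the intersection (default: all provided).
#' @return list of class `selection_intersection`: `features` (data.frame
#'   `feature`, `direction`), `dropped_univariate`,
#'   `dropped_multivariate`.
#' @export
intersect_selections <- function(univariate, multivariate, budget = NULL) {
  stopifnot(inherits(univariate, "univariate_result"))
  uni <- univariate$feature[univariate$selected]
  multi <- if (is.character(multivariate)) multivariate else {
    stopifnot(inherits(multivariate, "ranking_result"))
    multivariate$feature
  }
  if (!is.null(budget)) multi <- utils::head(multi, budget)
  common <- intersect(uni, multi)
  if (length(common) == 0L)
    warning("empty univariate/multivariate intersection", call. = FALSE)
  dirs <- univariate$direction[match(common, univariate$feature)]
  structure(list(features = data.frame(feature = common, direction = dirs,
                                       stringsAsFactors = FALSE),
                 dropped_univariate = setdiff(uni, common),
                 dropped_multivariate = setdiff(multi, common)),
            class = "selection_intersection")
}
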