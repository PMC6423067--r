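#' Configuration of the univariate protein-selection rule
#'
#' A protein is called modulated when all three criteria hold: BH-adjusted
#' Welch p below `alpha`, group fold change outside the
#' (`fc_low`, `fc_high`) window, and a per-donor fold change crossing the
#' same window in at least `k_min` of `n_total` donors.
#'
#' @param fc_high upper fold-change threshold (selection requires
#'   FC > fc_high or FC < fc_low). Default 1.5.
#' @param fc_low lower fold-change threshold. Default 1/1.5, symmetric
#'   with `fc_high`; 0.5 is another conventional choice.
#' @param alpha adjusted-p cut-off, default 0.05.
#' @param k_min minimum number of donors with a modulated per-donor fold
#'   change, default 4.
#' @param n_total total donors the `k_min` rule is counted over; `NULL`
#'   (default) uses the number of donors present in the data.
#' @param adjust_method multiple-testing method passed to
#'   [stats::p.adjust()], default `"BH"`.
#' @return object of class `univariate_config`.
#' @export
univariate_config <- function(fc_high = 1.5, fc_low = 1 / 1.5, alpha = 0.05,
                              k_min = 4L, n_total = NULL,
                              adjust_method = "BH") {
  if (!(0 < fc_low && fc_low < 1 && 1 < fc_high))
    stop("need 0 < fc_low < 1 < fc_high", call. = FALSE)
  if (!(0 < alpha && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  if (k_min < 1L) stop("k_min must be >= 1", call. = FALSE)
  if (!is.null(n_total) && k_min > n_total)
    stop("k_min cannot exceed n_total", call. = FALSE)
  structure(list(fc_high = fc_high, fc_low = fc_low, alpha = alpha,
                 k_min = as.integer(k_min),
                 n_total = if (is.null(n_total)) NULL else as.integer(n_total),
                 adjust_method = adjust_method),
            class = "univariate_config")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around [stats::p.adjust()]: adjusted values are
#' order-preserving with the input, monotone after sorting, and clipped
#' at 1.
#'
#' @param p numeric vector of raw p-values in \[0,1\].
#' @param method adjustment method, default `"BH"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = "BH") {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Per-feature group fold change on the linear intensity scale
#'
#' FC = mean(primed) / mean(control), computed after pairwise removal of
#' missing values. Features with an all-missing group or a zero control
#' mean get `NA` and are flagged; they can never be selected.
#'
#' @param om an [omics_matrix()] (linear-scale intensities).
#' @return data.frame with `feature`, `fc`, `log2fc`, `flagged`.
#' @export
group_fold_change <- function(om) {
  stopifnot(inherits(om, "omics_matrix"))
  v <- om$values
  grp <- obs_conditions(om)
  m_ctrl <- rowMeans(v[, grp == "control", drop = FALSE], na.rm = TRUE)
  m_prim <- rowMeans(v[, grp == "primed", drop = FALSE], na.rm = TRUE)
  fc <- m_prim / m_ctrl
  flagged <- !is.finite(fc) | m_ctrl == 0 | is.nan(m_prim)
  fc[flagged] <- NA_real_
  data.frame(feature = rownames(v), fc = fc, log2fc = log2(fc),
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Welch t-test per feature
#'
#' Applies [stats::t.test()] with `var.equal = FALSE` row-wise. Features
#' with fewer than two non-missing observations in either group get
#' `NA`. Identical groups (zero variance in both, equal means) get p = 1
#' by convention.
#'
#' @param x numeric matrix, features x observations (any scale; the
#'   selection pipeline passes log2 intensities).
#' @param condition factor/character per observation with two levels.
#' @return data.frame with `feature`, `t`, `df`, `p`.
#' @export
welch_t_per_feature <- function(x, condition) {
  stopifnot(is.matrix(x))
  condition <- as.factor(condition)
  if (nlevels(droplevels(condition)) != 2L)
    stop("exactly two condition levels required", call. = FALSE)
  lv <- levels(droplevels(condition))
  a_idx <- condition == lv[1]; b_idx <- condition == lv[2]
  res <- t(apply(x, 1, function(row) {
    a <- row[a_idx]; b <- row[b_idx]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(c(NA_real_, NA_real_, NA_real_))
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) return(c(0, length(a) + length(b) - 2, 1))
      return(c(Inf, length(a) + length(b) - 2, 0))
    }
    tt <- stats::t.test(b, a, var.equal = FALSE)
    c(unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }))
  data.frame(feature = rownames(x), t = res[, 1], df = res[, 2], p = res[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-donor modulation counts (presence-of-modulation rule)
#'
#' For each donor i the paired fold change FC_i = mean over
#' replicates(primed) / mean over replicates(control); the feature is
#' modulated in that donor when FC_i > fc_high or FC_i < fc_low. Donors
#' with an entirely missing side contribute 0 while the denominator stays
#' at `n_total`.
#'
#' @param om an [omics_matrix()] (linear-scale intensities).
#' @param config a [univariate_config()].
#' @return data.frame with `feature`, `n_modulated`, `n_total`.
#' @export
presence_modulation_filter <- function(om, config = univariate_config()) {
  stopifnot(inherits(om, "omics_matrix"), inherits(config, "univariate_config"))
  v <- om$values
  meta <- om$metadata
  inds <- unique(meta$individual)
  keep <- vapply(inds, function(i) {
    has_c <- any(meta$individual == i & meta$condition == "control")
    has_p <- any(meta$individual == i & meta$condition == "primed")
    if (!has_c && !has_p)
      warning("individual ", i, " has no observations; excluded",
              call. = FALSE)
    has_c || has_p
  }, logical(1))
  inds <- inds[keep]
  n_total <- if (is.null(config$n_total)) length(inds) else config$n_total

  counts <- integer(nrow(v))
  for (i in inds) {
    ci <- meta$individual == i & meta$condition == "control"
    pi <- meta$individual == i & meta$condition == "primed"
    if (!any(ci) || !any(pi)) next  # missing side contributes 0
    mc <- rowMeans(v[, ci, drop = FALSE], na.rm = TRUE)
    mp <- rowMeans(v[, pi, drop = FALSE], na.rm = TRUE)
    fci <- mp / mc
    hit <- is.finite(fci) & (fci > config$fc_high | fci < config$fc_low)
    counts <- counts + as.integer(hit)
  }
  data.frame(feature = rownames(v), n_modulated = counts, n_total = n_total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate protein selection
#'
#' Combines the Welch test on log2 intensities (BH-adjusted), the group
#' fold-change window and the per-donor presence rule. A feature is
#' selected iff adjusted p < alpha AND (FC > fc_high OR FC < fc_low) AND
#' modulation count >= k_min.
#'
#' @param om an [omics_matrix()] of linear-scale intensities.
#' @param config a [univariate_config()].
#' @return data.frame of class `univariate_result` with per-feature `fc`,
#'   `log2fc`, `p`, `padj`, `n_modulated`, `direction` (up/down/none) and
#'   `selected`.
#' @export
select_univariate <- function(om, config = univariate_config()) {
  stopifnot(inherits(om, "omics_matrix"))
  fc <- group_fold_change(om)
  tt <- welch_t_per_feature(log2(om$values), obs_conditions(om))
  mod <- presence_modulation_filter(om, config)

  padj <- rep(NA_real_, nrow(tt))
  ok <- !is.na(tt$p)
  padj[ok] <- bh_adjust(tt$p[ok], method = config$adjust_method)

  fc_hit <- !fc$flagged & (fc$fc > config$fc_high | fc$fc < config$fc_low)
  selected <- !is.na(padj) & padj < config$alpha & fc_hit &
    mod$n_modulated >= config$k_min
  direction <- ifelse(is.na(fc$fc) | fc$fc == 1, "none",
                      ifelse(fc$fc > 1, "up", "down"))

  out <- data.frame(feature = fc$feature, fc = fc$fc, log2fc = fc$log2fc,
                    p = tt$p, padj = padj, n_modulated = mod$n_modulated,
                    n_total = mod$n_total, direction = direction,
                    flagged = fc$flagged, selected = selected,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("univariate_result", "data.frame")
  attr(out, "config") <- config
  out
}

#' Relative quantity by the delta-delta-Ct method
#'
#' RQ = 2^-((Ct_target,case - Ct_ref,case) - (Ct_target,cal - Ct_ref,cal)),
#' the standard relative qPCR quantification against a reference RNA
#' (e.g. U6) and a calibrator sample. Vectorized over its arguments.
#'
#' @param ct_target_case,ct_reference_case Ct values in the sample of
#'   interest for the target and the reference assay.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator sample.
#' @return relative quantity (1 = no change; 2 = twofold up).
#' @export
ddct_relative_expression <- function(ct_target_case, ct_reference_case,
                                     ct_target_calibrator,
                                     ct_reference_calibrator) {
  args <- list(ct_target_case, ct_reference_case, ct_target_calibrator,
               ct_reference_calibrator)
  if (any(!vapply(args, function(a) all(is.finite(a)), logical(1))))
    stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_reference_case) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
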