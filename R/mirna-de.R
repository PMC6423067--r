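#' Median-of-ratios size factors
#'
#' Per-sample normalization constants for count data: each sample's factor
#' is the median, over features with nonzero counts in every sample, of
#' the ratio of its count to the feature's geometric mean across samples.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param pseudo_reference if `TRUE`, build the geometric-mean reference
#'   over positive counts only, so matrices without an all-nonzero
#'   feature can still be normalized.
#' @return numeric vector of size factors, one per sample.
#' @export
median_of_ratios_size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!pseudo_reference) {
    all_pos <- rowSums(counts == 0) == 0
    if (!any(all_pos))
      stop("no feature has nonzero counts in all samples; ",
           "set pseudo_reference = TRUE to use a positive-count reference",
           call. = FALSE)
    loggeo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    # median taken on the log-ratio scale (geometric interpolation at even
    # feature counts), the convention of the reference implementations
    apply(log(counts[all_pos, , drop = FALSE]) - loggeo, 2,
          function(r) exp(stats::median(r)))
  } else {
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    ref <- exp(rowMeans(logc, na.rm = TRUE))
    keep <- is.finite(ref) & ref > 0
    if (!any(keep)) stop("all features are zero in all samples", call. = FALSE)
    ratios <- counts[keep, , drop = FALSE] / ref[keep]
    apply(ratios, 2, function(r) exp(stats::median(log(r[r > 0]))))
  }
}

#' Two-group negative binomial Wald test for miRNA counts
#'
#' A deliberately simple differential-expression stage for small miRNA
#' panels: counts are normalized by median-of-ratios size factors, a
#' method-of-moments dispersion is pooled within groups
#' (alpha = max(0, (s^2 - m) / m^2)), and the difference of log2 group
#' means is tested with a Wald-type statistic whose standard error comes
#' from the NB variance model, referenced to a t distribution with
#' n1 + n2 - 2 degrees of freedom to absorb dispersion-estimation noise
#' at small sample sizes. P-values are BH-adjusted; features are flagged
#' significant at adjusted p < `fdr`.
#'
#' This is not a reimplementation of shrinkage-based DE packages: no
#' dispersion shrinkage, outlier filtering, or independent filtering is
#' performed.
#'
#' @param counts non-negative integer matrix, miRNAs x samples.
#' @param condition factor/character per sample, levels control/primed
#'   (or any two levels; the second level is the "up" direction).
#' @param size_factors optional precomputed size factors; computed by
#'   [median_of_ratios_size_factors()] when `NULL`.
#' @param fdr adjusted-p cut-off for the `significant` flag, default 0.05.
#' @return data.frame of class `de_result`: per miRNA `base_mean`,
#'   `log2fc`, `dispersion`, `stat`, `p`, `padj`, `significant`,
#'   `direction`. All-zero features carry `NA` statistics and are never
#'   significant.
#' @export
nb_two_group_test <- function(counts, condition, size_factors = NULL,
                              fdr = 0.05) {
  stopifnot(is.matrix(counts))
  condition <- as.factor(condition)
  lv <- levels(droplevels(condition))
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  n1 <- sum(condition == lv[1]); n2 <- sum(condition == lv[2])
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group", call. = FALSE)
  if (is.null(size_factors))
    size_factors <- median_of_ratios_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")

  a <- norm[, condition == lv[1], drop = FALSE]   # reference (control)
  b <- norm[, condition == lv[2], drop = FALSE]   # "up" direction (primed)
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- apply(a, 1, stats::var); v_b <- apply(b, 1, stats::var)
  base_mean <- rowMeans(norm)
  all_zero <- rowSums(counts) == 0

  # pooled method-of-moments dispersion, floored at the Poisson limit
  alpha_a <- (v_a - m_a) / m_a^2
  alpha_b <- (v_b - m_b) / m_b^2
  alpha_a[!is.finite(alpha_a)] <- 0
  alpha_b[!is.finite(alpha_b)] <- 0
  disp <- pmax(0, ((n1 - 1) * alpha_a + (n2 - 1) * alpha_b) / (n1 + n2 - 2))

  # log2 fold change of group means; pseudo-count 0.5 only when a group
  # mean is zero, so noise-free inputs recover planted effects exactly
  need_pseudo <- m_a == 0 | m_b == 0
  lfc <- ifelse(need_pseudo,
                log2((m_b + 0.5) / (m_a + 0.5)),
                log2(m_b / m_a))

  # Wald statistic: delta-method SE of the log-mean difference under
  # var(count) = mu + alpha mu^2  =>  var(log mean) ~ (1/mu + alpha)/n
  mm_a <- ifelse(m_a == 0, 0.5, m_a)
  mm_b <- ifelse(m_b == 0, 0.5, m_b)
  se_ln <- sqrt((1 / mm_a + disp) / n1 + (1 / mm_b + disp) / n2)
  stat <- (log(mm_b) - log(mm_a)) / se_ln
  p <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  p[m_a == m_b] <- 1

  stat[all_zero] <- NA_real_
  p[all_zero] <- NA_real_
  lfc[all_zero] <- NA_real_
  disp[all_zero] <- NA_real_

  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  significant <- !is.na(padj) & padj < fdr
  direction <- ifelse(is.na(lfc) | lfc == 0, "none",
                      ifelse(lfc > 0, "up", "down"))

  out <- data.frame(feature = rownames(counts), base_mean = base_mean,
                    log2fc = lfc, dispersion = disp, stat = stat, p = p,
                    padj = padj, significant = significant,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "size_factors") <- size_factors
  attr(out, "groups") <- lv
  out
}
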