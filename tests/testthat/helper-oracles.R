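# Shared fixtures and independent oracles, all built in code.

# Hand-built paired cohort: per-individual primed/control fold changes are
# set explicitly so the presence rule can be checked by direct arithmetic.
# fcs: one fold change per individual; control intensity fixed at `base`.
cohort_from_fcs <- function(fcs, base = 8, feature = "protA",
                            extra = NULL) {
  ni <- length(fcs)
  inds <- sprintf("ind%02d", seq_len(ni))
  meta <- data.frame(
    observation = c(paste0(inds, "_c"), paste0(inds, "_p")),
    individual = rep(inds, 2),
    condition = rep(c("control", "primed"), each = ni),
    compartment = "EV", replicate = 1L,
    stringsAsFactors = FALSE)
  vals <- rbind(c(rep(base, ni), base * fcs))
  rownames(vals) <- feature
  colnames(vals) <- meta$observation
  if (!is.null(extra)) {
    vals <- rbind(vals, extra)
  }
  omics_matrix(vals, meta)
}

# Brute-force Benjamini-Hochberg step-up: sort, scale by m/i, enforce
# monotonicity from the largest down, clip at 1, restore input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Single-feature separation score: |class-mean difference| of the
# autoscaled column (the PC1 of a one-feature PCA is the feature itself
# up to sign).
single_feature_sep <- function(x, cls) {
  apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(0)
    z <- (col - mean(col)) / s
    a <- z[cls == levels(factor(cls))[1]]
    b <- z[cls != levels(factor(cls))[1]]
    abs(mean(a) - mean(b))
  })
}

# Single-feature standardized score: the separation divided by the pooled
# within-class sd of the autoscaled column.
single_feature_D <- function(x, cls) {
  apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(0)
    z <- (col - mean(col)) / s
    a <- z[cls == levels(factor(cls))[1]]
    b <- z[cls != levels(factor(cls))[1]]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    d <- abs(mean(a) - mean(b))
    if (sp < 1e-12) return(if (d > 1e-9) Inf else 0)
    d / sp
  })
}

# Welch t and Satterthwaite df from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# universe and count those overlapping the set in >= k elements.
hyper_enumerate <- function(N, K, n, k) {
  universe <- seq_len(N)
  set <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% set) >= k))
}

# Brute-force coverage: double loop over (pathway gene, miRNA).
coverage_bruteforce <- function(de, target_map, sets) {
  sapply(names(sets), function(pw) {
    genes <- sets[[pw]]
    hit <- 0
    for (g in genes) {
      targeted <- FALSE
      for (m in de) {
        if (any(target_map$mirna == m & target_map$gene == g))
          targeted <- TRUE
      }
      if (targeted) hit <- hit + 1
    }
    100 * hit / length(genes)
  })
}
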