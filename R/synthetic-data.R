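#' Simulation design for a paired proteomics cohort
#'
#' Describes a donor-paired label-free proteomics experiment: each of
#' `n_individuals` donors contributes replicated acquisitions under both
#' the control and the primed condition. Log2 intensities decompose as
#' feature baseline + shared donor effect + condition effect (planted
#' features only) + replicate noise; measurements go missing either
#' completely at random or preferentially at low abundance.
#'
#' Defaults describe the cohort the validation suite runs on: 7 donors,
#' 3 technical replicates per condition, 500 proteins of which 50 carry a
#' planted |log2 fold change| of 3 (half up-, half down-regulated in
#' primed), donor standard deviation 0.5, replicate noise 0.3, and 5%
#' missing values.
#'
#' @param n_individuals donors per cohort (paired across conditions).
#' @param replicates_per_condition technical replicates per donor and
#'   condition.
#' @param n_features number of proteins simulated.
#' @param n_de number of features with a planted condition effect.
#' @param log2_effect planted |log2 fold change| (primed vs control).
#' @param individual_sd between-donor standard deviation, log2 scale.
#' @param noise_sd replicate noise standard deviation, log2 scale.
#' @param missing_rate probability in \[0,1\] that a measurement is missing.
#' @param missing_mode `"mcar"` (uniform) or `"censored"` (probability
#'   concentrated on low-intensity measurements, emulating abundance-biased
#'   label-free MS missingness).
#' @param compartment label recorded in the metadata (`"EV"` or `"cell"`).
#' @param seed integer random seed; identical seeds give identical output.
#' @return object of class `sim_design` (a validated list).
#' @export
sim_design <- function(n_individuals = 7L, replicates_per_condition = 3L,
                       n_features = 500L, n_de = 50L, log2_effect = 3,
                       individual_sd = 0.5, noise_sd = 0.3,
                       missing_rate = 0.05, missing_mode = c("mcar", "censored"),
                       compartment = "EV", seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  d <- list(n_individuals = as.integer(n_individuals),
            replicates_per_condition = as.integer(replicates_per_condition),
            n_features = as.integer(n_features), n_de = as.integer(n_de),
            log2_effect = log2_effect, individual_sd = individual_sd,
            noise_sd = noise_sd, missing_rate = missing_rate,
            missing_mode = missing_mode, compartment = compartment,
            seed = as.integer(seed))
  if (d$n_individuals < 1L || d$replicates_per_condition < 1L ||
      d$n_features < 1L)
    stop("simulation dimensions must be positive", call. = FALSE)
  if (d$n_de < 0L || d$n_de > d$n_features)
    stop("n_de must lie in [0, n_features]", call. = FALSE)
  if (d$individual_sd < 0 || d$noise_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (d$missing_rate < 0 || d$missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  structure(d, class = "sim_design")
}

#' Simulate a paired label-free proteomics cohort
#'
#' @param design a [sim_design()].
#' @return list with `matrix` (an [omics_matrix()] of linear-scale
#'   intensities, i.e. 2^log2) and `truth` (data.frame of planted features:
#'   `feature`, `direction` in up/down, `log2_effect` signed).
#' @export
simulate_proteomics <- function(design = sim_design()) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  ni <- design$n_individuals; r <- design$replicates_per_condition
  p <- design$n_features
  feat <- sprintf("prot%04d", seq_len(p))
  inds <- sprintf("ind%02d", seq_len(ni))

  # planted effects: first n_de features, half up / half down
  eff <- numeric(p)
  if (design$n_de > 0L) {
    n_up <- ceiling(design$n_de / 2)
    eff[seq_len(design$n_de)] <-
      rep(c(1, -1), c(n_up, design$n_de - n_up)) * design$log2_effect
  }

  baseline <- stats::rnorm(p, mean = 22, sd = 2)
  ind_eff <- matrix(stats::rnorm(p * ni, 0, design$individual_sd), p, ni)

  meta <- expand.grid(replicate = seq_len(r),
                      condition = c("control", "primed"),
                      individual = inds, stringsAsFactors = FALSE)
  meta <- meta[, c("individual", "condition", "replicate")]
  meta$compartment <- design$compartment
  meta$observation <- sprintf("%s_%s_r%d", meta$individual,
                              substr(meta$condition, 1, 1), meta$replicate)

  n_obs <- nrow(meta)
  log2x <- matrix(0, p, n_obs, dimnames = list(feat, meta$observation))
  ind_idx <- match(meta$individual, inds)
  cond_up <- as.numeric(meta$condition == "primed")
  for (j in seq_len(n_obs)) {
    log2x[, j] <- baseline + ind_eff[, ind_idx[j]] + eff * cond_up[j] +
      stats::rnorm(p, 0, design$noise_sd)
  }

  if (design$missing_rate > 0) {
    if (design$missing_mode == "mcar") {
      miss <- matrix(stats::runif(p * n_obs) < design$missing_rate, p, n_obs)
    } else {
      # left-censored: logistic probability decreasing in intensity, scaled
      # so the marginal missing rate matches missing_rate
      z <- (log2x - mean(log2x)) / stats::sd(log2x)
      w <- stats::plogis(-2 * z)
      w <- w * (design$missing_rate / mean(w))
      miss <- matrix(stats::runif(p * n_obs) < pmin(w, 1), p, n_obs)
    }
    log2x[miss] <- NA_real_
  }

  truth <- data.frame(feature = feat[seq_len(design$n_de)],
                      direction = ifelse(eff[seq_len(design$n_de)] > 0,
                                         "up", "down"),
                      log2_effect = eff[seq_len(design$n_de)],
                      stringsAsFactors = FALSE)
  if (design$n_de == 0L)
    truth <- data.frame(feature = character(), direction = character(),
                        log2_effect = numeric(), stringsAsFactors = FALSE)

  list(matrix = omics_matrix(2^log2x, meta), truth = truth)
}

#' Simulation design for miRNA count data
#'
#' Negative binomial counts with multiplicative library-size factors:
#' count ~ NB(mu = sf_j * base_mean * 2^(+-log2_effect for planted
#' features in primed), variance = mu + dispersion * mu^2). Dispersion 0
#' is the Poisson limit.
#'
#' @param n_samples samples per group (control and primed).
#' @param n_mirnas number of miRNA features.
#' @param n_de planted differentially expressed miRNAs (half up, half down).
#' @param log2_effect planted |log2 fold change|.
#' @param base_mean expected count of an unperturbed feature at size
#'   factor 1.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param size_factor_range length-2 range library-size factors are drawn
#'   from (log-uniform); use `c(1, 1)` for equal depths.
#' @param seed integer random seed.
#' @return object of class `count_sim_design`.
#' @export
count_sim_design <- function(n_samples = 5L, n_mirnas = 300L, n_de = 15L,
                             log2_effect = 2, base_mean = 500,
                             dispersion = 0.05,
                             size_factor_range = c(0.7, 1.4), seed = 1L) {
  d <- list(n_samples = as.integer(n_samples), n_mirnas = as.integer(n_mirnas),
            n_de = as.integer(n_de), log2_effect = log2_effect,
            base_mean = base_mean, dispersion = dispersion,
            size_factor_range = range(size_factor_range),
            seed = as.integer(seed))
  if (d$base_mean <= 0) stop("base_mean must be > 0", call. = FALSE)
  if (d$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (d$n_de < 0L || d$n_de > d$n_mirnas)
    stop("n_de must lie in [0, n_mirnas]", call. = FALSE)
  if (d$n_samples < 1L || d$n_mirnas < 1L)
    stop("simulation dimensions must be positive", call. = FALSE)
  if (any(d$size_factor_range <= 0))
    stop("size factors must be positive", call. = FALSE)
  structure(d, class = "count_sim_design")
}

#' Simulate miRNA sequencing counts
#'
#' @param design a [count_sim_design()].
#' @return list with `counts` (integer matrix, miRNAs x samples),
#'   `condition` (factor per sample), `size_factors` (true multiplicative
#'   depths) and `truth` (planted DE table as in [simulate_proteomics()]).
#' @export
simulate_mirna_counts <- function(design = count_sim_design()) {
  stopifnot(inherits(design, "count_sim_design"))
  set.seed(design$seed)
  n <- design$n_samples; p <- design$n_mirnas
  feat <- sprintf("mir%04d", seq_len(p))
  cond <- factor(rep(c("control", "primed"), each = n),
                 levels = c("control", "primed"))
  samp <- sprintf("%s_s%d", substr(as.character(cond), 1, 1),
                  rep(seq_len(n), 2))

  eff <- numeric(p)
  if (design$n_de > 0L) {
    n_up <- ceiling(design$n_de / 2)
    eff[seq_len(design$n_de)] <-
      rep(c(1, -1), c(n_up, design$n_de - n_up)) * design$log2_effect
  }

  # per-feature baseline spread around base_mean (log-normal, mild),
  # rescaled so the realized average baseline is exactly base_mean
  base <- design$base_mean * 2^stats::rnorm(p, 0, 0.5)
  base <- base * (design$base_mean / mean(base))
  sfr <- design$size_factor_range
  sf <- if (diff(sfr) == 0) rep(sfr[1], 2 * n) else
    exp(stats::runif(2 * n, log(sfr[1]), log(sfr[2])))

  counts <- matrix(0L, p, 2 * n, dimnames = list(feat, samp))
  up <- as.numeric(cond == "primed")
  for (j in seq_len(2 * n)) {
    mu <- sf[j] * base * 2^(eff * up[j])
    counts[, j] <- if (design$dispersion == 0)
      stats::rpois(p, mu)
    else
      stats::rnbinom(p, size = 1 / design$dispersion, mu = mu)
  }

  truth <- data.frame(feature = feat[seq_len(design$n_de)],
                      direction = ifelse(eff[seq_len(design$n_de)] > 0,
                                         "up", "down"),
                      log2_effect = eff[seq_len(design$n_de)],
                      stringsAsFactors = FALSE)
  if (design$n_de == 0L)
    truth <- data.frame(feature = character(), direction = character(),
                        log2_effect = numeric(), stringsAsFactors = FALSE)

  list(counts = counts, condition = cond, size_factors = sf, truth = truth)
}

#' Specification of synthetic pathway / miRNA-target resources
#'
#' @param n_pathways number of pathways.
#' @param genes_per_pathway genes per pathway (scalar or per-pathway
#'   vector).
#' @param n_mirnas number of miRNAs available as regulators.
#' @param planted_coverage per-pathway fraction of genes that receive at
#'   least one targeting miRNA (scalar recycled, each in \[0,1\]).
#' @param seed integer random seed.
#' @return object of class `pathway_resource_spec`.
#' @export
pathway_resource_spec <- function(n_pathways = 4L, genes_per_pathway = 500L,
                                  n_mirnas = 15L, planted_coverage = 0.618,
                                  seed = 1L) {
  d <- list(n_pathways = as.integer(n_pathways),
            genes_per_pathway = rep_len(as.integer(genes_per_pathway),
                                        n_pathways),
            n_mirnas = as.integer(n_mirnas),
            planted_coverage = rep_len(planted_coverage, n_pathways),
            seed = as.integer(seed))
  if (any(d$planted_coverage < 0) || any(d$planted_coverage > 1))
    stop("planted_coverage must lie in [0, 1]", call. = FALSE)
  if (d$n_pathways < 1L || d$n_mirnas < 1L || any(d$genes_per_pathway < 1L))
    stop("resource dimensions must be positive", call. = FALSE)
  structure(d, class = "pathway_resource_spec")
}

#' Simulate pathway gene sets and a miRNA-target map with planted coverage
#'
#' Builds, for each pathway, a gene set in which exactly
#' `round(planted_coverage * genes_per_pathway)` genes are assigned at
#' least one targeting miRNA, so the downstream coverage statistic
#' recovers the planted fraction exactly.
#'
#' @param spec a [pathway_resource_spec()].
#' @return list with `target_map` (data.frame `mirna`, `gene`),
#'   `pathways` (a [pathway_db()]), `mirnas` (character vector) and
#'   `planted` (data.frame `pathway`, `coverage` in percent).
#' @export
simulate_pathway_resources <- function(spec = pathway_resource_spec()) {
  stopifnot(inherits(spec, "pathway_resource_spec"))
  set.seed(spec$seed)
  mirnas <- sprintf("mir%04d", seq_len(spec$n_mirnas))
  sets <- vector("list", spec$n_pathways)
  names(sets) <- sprintf("PW%02d", seq_len(spec$n_pathways))
  edges <- list()
  planted_pct <- numeric(spec$n_pathways)
  for (k in seq_len(spec$n_pathways)) {
    g <- spec$genes_per_pathway[k]
    genes <- sprintf("%s_g%04d", names(sets)[k], seq_len(g))
    sets[[k]] <- genes
    n_t <- round(spec$planted_coverage[k] * g)
    planted_pct[k] <- 100 * n_t / g
    if (n_t > 0) {
      targeted <- sample(genes, n_t)
      edges[[k]] <- data.frame(mirna = sample(mirnas, n_t, replace = TRUE),
                               gene = targeted, stringsAsFactors = FALSE)
    }
  }
  tm <- if (length(edges)) do.call(rbind, edges) else
    data.frame(mirna = character(), gene = character(),
               stringsAsFactors = FALSE)
  rownames(tm) <- NULL
  list(target_map = tm,
       pathways = pathway_db(sets,
                             description = paste("synthetic pathway",
                                                 seq_len(spec$n_pathways))),
       mirnas = mirnas,
       planted = data.frame(pathway = names(sets), coverage = planted_pct,
                            stringsAsFactors = FALSE))
}
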