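#' Merge protein and miRNA profiles into one block-labelled matrix
#'
#' Follows the retention rules of a donor-matched cross-omics merge:
#' observations are collapsed to one profile per (individual, condition)
#' by averaging replicates, only individuals present in both
#' characterizations are retained, and protein features quantified in
#' fewer than `min_presence` retained individuals are dropped. miRNA
#' counts are transformed to log2(normalized count + 1); the two blocks
#' are autoscaled independently before stacking so neither block's
#' variance scale dominates downstream ranking.
#'
#' @param protein an [omics_matrix()] of linear-scale protein intensities.
#' @param mirna_counts integer matrix, miRNAs x samples.
#' @param mirna_meta data.frame with `observation`, `individual`,
#'   `condition` for the count columns.
#' @param min_presence minimum number of retained individuals a protein
#'   must be quantified in (non-missing in at least one observation of
#'   that individual), default 2. Applies to proteins only; miRNAs are
#'   kept when nonzero in at least one retained sample.
#' @param size_factors optional size factors for the count block;
#'   computed by [median_of_ratios_size_factors()] when `NULL`.
#' @return list of class `merged_matrix`: `values` (features x
#'   individual-condition observations, per-block autoscaled), `block`
#'   (factor protein/mirna per feature), `metadata` (individual,
#'   condition per column), `dropped` (list with `proteins`, `mirnas`,
#'   `individuals_protein_only`, `individuals_mirna_only`).
#' @export
merge_blocks <- function(protein, mirna_counts, mirna_meta,
                         min_presence = 2L, size_factors = NULL) {
  stopifnot(inherits(protein, "omics_matrix"), is.matrix(mirna_counts))
  pm <- protein$metadata
  mm <- mirna_meta
  mm$individual <- as.character(mm$individual)
  if (!all(colnames(mirna_counts) %in% mm$observation))
    stop("mirna metadata must cover every count column", call. = FALSE)
  mm <- mm[match(colnames(mirna_counts), mm$observation), , drop = FALSE]

  ind_p <- unique(pm$individual)
  ind_m <- unique(mm$individual)
  common <- intersect(ind_p, ind_m)
  if (length(common) == 0L)
    stop("no individuals shared between the protein and miRNA data",
         call. = FALSE)

  # collapse each block to (individual, condition) means
  collapse <- function(values, individual, condition, transform = identity) {
    key <- paste(individual, condition, sep = ".")
    keep <- individual %in% common
    values <- values[, keep, drop = FALSE]
    key <- key[keep]
    groups <- unique(key)
    out <- vapply(groups, function(g)
      rowMeans(transform(values[, key == g, drop = FALSE]), na.rm = TRUE),
      numeric(nrow(values)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(values),
                                         dimnames = list(rownames(values),
                                                         groups))
    out
  }

  prot_c <- collapse(protein$values, pm$individual,
                     as.character(pm$condition), base::log2)
  prot_c[is.nan(prot_c)] <- NA_real_

  if (is.null(size_factors))
    size_factors <- median_of_ratios_size_factors(mirna_counts,
                                                  pseudo_reference = TRUE)
  norm_counts <- sweep(mirna_counts, 2, size_factors, "/")
  mir_c <- collapse(log2(norm_counts + 1), mm$individual,
                    as.character(mm$condition))

  cols <- intersect(colnames(prot_c), colnames(mir_c))
  if (length(cols) == 0L)
    stop("no shared (individual, condition) observations", call. = FALSE)
  prot_c <- prot_c[, cols, drop = FALSE]
  mir_c <- mir_c[, cols, drop = FALSE]

  meta <- data.frame(observation = cols,
                     individual = sub("\\.[^.]+$", "", cols),
                     condition = sub("^.*\\.", "", cols),
                     stringsAsFactors = FALSE)

  # protein presence rule: quantified in >= min_presence individuals
  pres <- vapply(unique(meta$individual), function(i)
    rowSums(!is.na(prot_c[, meta$individual == i, drop = FALSE])) > 0,
    logical(nrow(prot_c)))
  n_pres <- rowSums(pres)
  keep_p <- n_pres >= min_presence
  dropped_proteins <- rownames(prot_c)[!keep_p]
  prot_c <- prot_c[keep_p, , drop = FALSE]

  keep_m <- rowSums(mir_c > 0, na.rm = TRUE) > 0
  dropped_mirnas <- rownames(mir_c)[!keep_m]
  mir_c <- mir_c[keep_m, , drop = FALSE]

  # per-block autoscale across observations (feature-wise)
  scale_rows <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- apply(m, 1, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- Inf
    z <- (m - mu) / sd
    z[is.na(z)] <- 0
    z
  }
  values <- rbind(scale_rows(prot_c), scale_rows(mir_c))
  block <- factor(rep(c("protein", "mirna"),
                      c(nrow(prot_c), nrow(mir_c))),
                  levels = c("protein", "mirna"))

  structure(list(values = values, block = block, metadata = meta,
                 dropped = list(proteins = dropped_proteins,
                                mirnas = dropped_mirnas,
                                individuals_protein_only = setdiff(ind_p,
                                                                   common),
                                individuals_mirna_only = setdiff(ind_m,
                                                                 common))),
            class = "merged_matrix")
}

#' @export
print.merged_matrix <- function(x, ...) {
  cat("<merged_matrix> ", sum(x$block == "protein"), " proteins + ",
      sum(x$block == "mirna"), " miRNAs x ", ncol(x$values),
      " observations (", length(unique(x$metadata$individual)),
      " individuals)\n", sep = "")
  invisible(x)
}

#' Rank the merged miRNA/protein block and summarize its composition
#'
#' Runs Ranking-PCA (1 PC by default) on the merged matrix to `budget`
#' features, then PCA on the selected subset, and reports how many of the
#' top-ranked variables come from each block together with their PC1
#' loading signs (positive loadings correspond to variables
#' over-expressed in primed samples when PC1 is oriented toward the
#' primed class mean).
#'
#' @param merged a [merge_blocks()] result.
#' @param budget number of variables to rank, default 200; clamped to the
#'   total feature count with a warning.
#' @param n_pc PCs scored inside Ranking-PCA, default 1.
#' @param criterion discrimination criterion, see [ranking_pca()].
#' @return list of class `integrated_ranking`: `ranking`
#'   (a `ranking_result` with a `block` column), `pca` (on the ranked
#'   subset), `block_composition` (counts per block) and `loadings`
#'   (feature, block, PC1 loading, sign).
#' @export
integrated_ranking <- function(merged, budget = 200L, n_pc = 1L,
                               criterion = c("separation",
                                             "standardized")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(merged, "merged_matrix"))
  x <- t(merged$values)
  cls <- merged$metadata$condition
  if (min(table(cls)) < 2L)
    stop("need >= 2 observations per class", call. = FALSE)
  if (budget > ncol(x)) {
    warning("budget clamped to the ", ncol(x), " available features",
            call. = FALSE)
    budget <- ncol(x)
  }
  rk <- ranking_pca(x, cls, n_pc = n_pc, budget = budget,
                    criterion = criterion)
  rk$block <- as.character(merged$block[match(rk$feature,
                                              rownames(merged$values))])
  pca <- pca_fit(x[, rk$feature, drop = FALSE],
                 n_components = min(nrow(x) - 1L, length(rk$feature)),
                 mode = "center")  # block already autoscaled in the merge

  # orient PC1 so positive loadings align with the primed class
  s1 <- pca$scores[, 1]
  flip <- mean(s1[cls == "primed"]) < mean(s1[cls == "control"])
  if (flip) {
    pca$scores <- -pca$scores
    pca$loadings <- -pca$loadings
  }
  l1 <- pca$loadings[, 1]
  loadings <- data.frame(feature = rk$feature, block = rk$block,
                         loading_pc1 = unname(l1[rk$feature]),
                         direction = ifelse(l1[rk$feature] > 0, "up",
                                            ifelse(l1[rk$feature] < 0,
                                                   "down", "none")),
                         stringsAsFactors = FALSE)
  comp <- table(factor(rk$block, levels = c("protein", "mirna")))
  structure(list(ranking = rk, pca = pca,
                 block_composition = comp, loadings = loadings),
            class = "integrated_ranking")
}
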