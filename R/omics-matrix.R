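#' Quantitative omics matrix with sample metadata
#'
#' Container pairing a features-by-observations numeric matrix with the
#' sample metadata the downstream statistics need: which donor (individual)
#' an observation comes from, its condition (`control` or `primed`), the
#' compartment (`cell` or `EV`) and a technical replicate index. Missing
#' measurements are stored as `NA`.
#'
#' @param values numeric matrix, features in rows (rownames = feature IDs),
#'   observations in columns (colnames = observation IDs).
#' @param metadata data.frame with columns `observation`, `individual`,
#'   `condition`, `compartment`, `replicate`; one row per matrix column.
#' @return an object of class `omics_matrix`: a list with elements
#'   `values` and `metadata` (rows ordered to match the matrix columns).
#' @export
omics_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature rownames and observation colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs in `values`: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  needed <- c("observation", "individual", "condition", "compartment",
              "replicate")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  metadata$observation <- as.character(metadata$observation)
  absent <- setdiff(colnames(values), metadata$observation)
  if (length(absent))
    stop("no metadata row for observation(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  metadata <- metadata[match(colnames(values), metadata$observation), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  bad <- setdiff(unique(as.character(metadata$condition)),
                 c("control", "primed"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; expected 'control' or 'primed'", call. = FALSE)
  metadata$condition <- factor(as.character(metadata$condition),
                               levels = c("control", "primed"))
  metadata$individual <- as.character(metadata$individual)
  structure(list(values = values, metadata = metadata),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  v <- x$values
  cat("<omics_matrix> ", nrow(v), " features x ", ncol(v), " observations\n",
      sep = "")
  cat("  individuals: ", length(unique(x$metadata$individual)),
      " | conditions: ",
      paste(levels(droplevels(x$metadata$condition)), collapse = "/"),
      " | missing: ", sprintf("%.1f%%", 100 * mean(is.na(v))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# internal: observations x features numeric matrix for multivariate code
obs_matrix <- function(om) t(om$values)

# internal: condition factor aligned with observations
obs_conditions <- function(om) om$metadata$condition
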