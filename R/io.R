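# File readers/writers for the small set of plain-text formats the
# pipeline exchanges: feature-by-observation TSV/CSV matrices with a
# sample-metadata table, GMT gene sets, and two-column miRNA-target maps.

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature-by-observation matrix with its sample metadata
#'
#' The matrix file carries feature IDs in the first column and
#' observation IDs in the header; empty cells become missing values. The
#' metadata file needs columns `observation`, `individual`, `condition`,
#' `compartment`, `replicate` and must cover every matrix column. The
#' delimiter is chosen by extension (`.csv` = comma, otherwise tab) and
#' can be overridden.
#'
#' @param path matrix file.
#' @param metadata_path metadata file.
#' @param sep optional delimiter override applied to both files.
#' @return an [omics_matrix()].
#' @export
read_feature_matrix <- function(path, metadata_path, sep = NULL) {
  tab <- utils::read.table(path, sep = detect_sep(path, sep), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (anyDuplicated(tab[[1]]))
    stop("duplicate feature IDs in ", path, ": ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "),
         call. = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  storage.mode(values) <- "double"
  meta <- utils::read.table(metadata_path, sep = detect_sep(metadata_path, sep),
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  omics_matrix(values, meta)
}

#' Write a feature matrix and its metadata as TSV
#'
#' Inverse of [read_feature_matrix()]; round-trips losslessly.
#'
#' @param om an [omics_matrix()].
#' @param path matrix file to write.
#' @param metadata_path metadata file to write.
#' @export
write_feature_matrix <- function(om, path, metadata_path) {
  stopifnot(inherits(om, "omics_matrix"))
  df <- data.frame(feature = rownames(om$values), om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- om$metadata
  meta$condition <- as.character(meta$condition)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' CRLF line endings are accepted; empty sets and malformed lines raise
#' errors naming the offending line.
#'
#' @param path GMT file.
#' @return a [pathway_db()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           " (need name, description and >= 1 gene)", call. = FALSE)
    name <- parts[1]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("empty gene set at GMT line ", i, " in ", path, call. = FALSE)
    sets[[name]] <- genes
    desc[name] <- parts[2]
  }
  pathway_db(sets, description = desc)
}

#' Write gene sets in GMT format
#'
#' @param db a [pathway_db()].
#' @param path file to write.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$sets), function(nm)
    paste(c(nm, db$description[[nm]], db$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column miRNA-to-gene target map
#'
#' Tab-separated with header `mirna<TAB>gene`; duplicated pairs are
#' de-duplicated with a warning reporting the count.
#'
#' @param path target-map file.
#' @return data.frame with `mirna`, `gene`.
#' @export
read_target_map <- function(path) {
  tm <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tm)))
    stop("target map needs header columns 'mirna' and 'gene'",
         call. = FALSE)
  if (any(!nzchar(tm$mirna)) || any(!nzchar(tm$gene)))
    stop("empty identifiers in target map", call. = FALSE)
  dup <- duplicated(tm[, c("mirna", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (miRNA, gene) pair(s) de-duplicated",
            call. = FALSE)
    tm <- tm[!dup, , drop = FALSE]
    rownames(tm) <- NULL
  }
  tm
}

#' Write a miRNA-to-gene target map
#'
#' @param target_map data.frame with `mirna`, `gene`.
#' @param path file to write.
#' @export
write_target_map <- function(target_map, path) {
  utils::write.table(target_map[, c("mirna", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
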