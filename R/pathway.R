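#' Pathway database (named gene sets)
#'
#' @param sets named list of character vectors (gene identifiers, unique
#'   within a set).
#' @param description optional character vector of pathway descriptions.
#' @return object of class `pathway_db`.
#' @export
pathway_db <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("pathway sets need unique names", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("empty pathway gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description)) description <- rep("", length(sets))
  structure(list(sets = sets,
                 description = stats::setNames(as.character(description),
                                               names(sets))),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", length(x$sets), " pathways, ",
      length(unique(unlist(x$sets))), " distinct genes\n", sep = "")
  invisible(x)
}

#' Fraction of pathway genes targeted by differentially expressed miRNAs
#'
#' A pathway gene counts as targeted when at least one miRNA from
#' `de_mirnas` targets it (multiply-targeted genes count once); coverage
#' is 100 * n_targeted / n_genes. Per-(miRNA, pathway) targeted-gene
#' counts are kept as chord-diagram edges: there a gene contributes to
#' every miRNA that targets it.
#'
#' @param de_mirnas character vector of differentially expressed miRNAs.
#' @param target_map data.frame with columns `mirna`, `gene` (the
#'   miRNA-target relation, e.g. from [read_target_map()]).
#' @param pathways a [pathway_db()].
#' @return list of class `coverage_result`: `table` (pathway, n_genes,
#'   n_targeted, coverage, n_mirnas_contributing), `edges` (mirna,
#'   pathway, n_genes_targeted; positive counts only), `unmapped`
#'   (DE miRNAs absent from the target map).
#' @export
pathway_target_coverage <- function(de_mirnas, target_map, pathways) {
  stopifnot(inherits(pathways, "pathway_db"))
  if (!all(c("mirna", "gene") %in% names(target_map)))
    stop("target_map needs columns 'mirna' and 'gene'", call. = FALSE)
  de_mirnas <- unique(as.character(de_mirnas))
  unmapped <- setdiff(de_mirnas, unique(target_map$mirna))
  tm <- target_map[target_map$mirna %in% de_mirnas, , drop = FALSE]
  targets_by_mirna <- split(tm$gene, tm$mirna)
  all_targets <- unique(tm$gene)

  rows <- lapply(names(pathways$sets), function(pw) {
    genes <- pathways$sets[[pw]]
    hit <- genes[genes %in% all_targets]
    per_mirna <- vapply(targets_by_mirna,
                        function(g) length(intersect(g, genes)), integer(1))
    per_mirna <- per_mirna[per_mirna > 0]
    list(table = data.frame(pathway = pw, n_genes = length(genes),
                            n_targeted = length(hit),
                            coverage = 100 * length(hit) / length(genes),
                            n_mirnas_contributing = length(per_mirna),
                            stringsAsFactors = FALSE),
         edges = if (length(per_mirna))
           data.frame(mirna = names(per_mirna), pathway = pw,
                      n_genes_targeted = unname(per_mirna),
                      stringsAsFactors = FALSE)
         else NULL)
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "table"))
  edges <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(rows, `[[`, "edges")))
  if (is.null(edges))
    edges <- data.frame(mirna = character(), pathway = character(),
                        n_genes_targeted = integer(),
                        stringsAsFactors = FALSE)
  rownames(tab) <- rownames(edges) <- NULL
  structure(list(table = tab, edges = edges, unmapped = unmapped,
                 de_mirnas = de_mirnas),
            class = "coverage_result")
}

#' Chord-diagram edge table from a coverage result
#'
#' One row per (miRNA, pathway) pair with a positive targeted-gene count,
#' ready for chord-diagram rendering downstream.
#'
#' @param coverage a [pathway_target_coverage()] result.
#' @return data.frame with `mirna`, `pathway`, `n_genes_targeted`.
#' @export
chord_edges <- function(coverage) {
  stopifnot(inherits(coverage, "coverage_result"))
  coverage$edges
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap: p = P(X >= k) with X ~
#' Hypergeometric(N = |universe|, K = |set ∩ universe|, n = |query|).
#' P-values are BH-adjusted across pathways; pathways are flagged
#' enriched at adjusted p < `alpha`.
#'
#' @param query_genes character vector of genes of interest; genes
#'   outside the universe are dropped with a warning.
#' @param pathways a [pathway_db()]; sets are intersected with the
#'   universe.
#' @param universe gene universe; default the union of all pathway genes.
#' @param alpha adjusted-p threshold for the `enriched` flag,
#'   default 0.05.
#' @return data.frame with `pathway`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `padj`, `enriched`.
#' @export
hypergeometric_ora <- function(query_genes, pathways, universe = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(pathways, "pathway_db"))
  if (is.null(universe)) universe <- unique(unlist(pathways$sets))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  res <- lapply(names(pathways$sets), function(pw) {
    set <- intersect(pathways$sets[[pw]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out$enriched <- out$padj < alpha
  rownames(out) <- NULL
  out
}
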