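# Hypergeometric over-representation analysis and weight-based re-ranking.

#' Construct a gene-set collection
#'
#' @param sets named list; each element a list with `description` (string)
#'   and `genes` (character vector), or simply a character vector of genes.
#' @param universe optional background gene universe. Defaults to the union
#'   of all pathway genes (the annotation universe). Pathway gene sets are
#'   restricted to the universe; sets left empty by the restriction are
#'   dropped.
#' @return object of class `gene_set_collection`: list with `sets` (each
#'   `description` + normalized `genes`) and sorted `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    validation_error("every pathway gene set needs a non-empty id")
  if (anyDuplicated(names(sets)))
    validation_error("duplicate pathway ids: ",
                     paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  norm <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", genes = s)
    list(description = as.character(s$description %||% ""),
         genes = sort(unique(normalize_genes(s$genes))))
  })
  all_genes <- sort(unique(unlist(lapply(norm, `[[`, "genes"), use.names = FALSE)))
  universe <- if (is.null(universe)) all_genes
              else sort(unique(normalize_genes(as_gene_set(universe, "universe")$genes)))
  norm <- lapply(norm, function(s) {
    s$genes <- intersect(s$genes, universe)
    s
  })
  keep <- vapply(norm, function(s) length(s$genes) > 0, logical(1))
  structure(list(sets = norm[keep], universe = universe),
            class = "gene_set_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d sets, universe %d genes>\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line, fields `id`, `description`,
#' then member genes.
#'
#' @param path file path.
#' @param universe optional background universe passed to
#'   [gene_set_collection()].
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short))
    stop_wcnp("GMT line(s) with fewer than 3 fields: ",
              paste(which(short), collapse = ", "), class = "wcnp_parse_error")
  ids <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p)
    list(description = p[[2L]], genes = p[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the query gene set overlaps it more than
#' expected by chance within the background universe, using the upper-tail
#' hypergeometric probability `P(X >= k)` with
#' `X ~ Hypergeom(N, K, n)` -- the one-sided Fisher exact test of
#' over-representation. P-values are corrected across the tested pathways by
#' Benjamini-Hochberg. Pathways are ranked by ascending p-value, ties broken
#' by descending overlap `k`, then pathway id, so output order is
#' deterministic.
#'
#' @param query a [gene_set()] (or character vector) of query genes; genes
#'   outside the universe are ignored.
#' @param collection a [gene_set_collection()].
#' @param k_min minimum overlap required for a pathway to be tested
#'   (default 0: every pathway with at least one universe gene is tested and
#'   enters the BH family).
#' @return data.frame of class `enrichment_result`, one row per tested
#'   pathway, with columns `pathway_id`, `description`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr_bh`, `unweighted_rank`, `weight_c`, `weighted_rank`,
#'   `rank_delta` (the last three `NA` until [rerank_by_weight()]).
#' @export
hypergeom_enrich <- function(query, collection, k_min = 0) {
  if (!inherits(collection, "gene_set_collection"))
    validation_error("collection must be a gene_set_collection")
  universe <- collection$universe
  if (length(universe) == 0) stop_wcnp("empty universe")
  q <- intersect(as_gene_set(query, "query")$genes, universe)
  if (length(q) == 0)
    stop_wcnp("query shares no genes with the universe")
  n <- length(q)
  N <- length(universe)
  ids <- names(collection$sets)
  K <- vapply(collection$sets, function(s) length(s$genes), integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(s$genes, q)),
              integer(1))
  keep <- k >= k_min
  ids <- ids[keep]; K <- K[keep]; k <- k[keep]
  # upper tail P(X >= k); phyper's lower.tail=FALSE gives P(X > k-1)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    pathway_id = ids,
    description = vapply(collection$sets[keep], `[[`, "", "description"),
    k = as.integer(k), K = as.integer(K), n = n, N = N,
    p_value = p, fdr_bh = fdr,
    stringsAsFactors = FALSE
  )
  ord <- order(res$p_value, -res$k, res$pathway_id)
  res <- res[ord, , drop = FALSE]
  res$unweighted_rank <- seq_len(nrow(res))
  res$weight_c <- NA_real_
  res$weighted_rank <- NA_integer_
  res$rank_delta <- NA_integer_
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Re-rank enrichment results by weight coefficient
#'
#' Orders pathways by descending weight coefficient C; ties are broken by
#' ascending p-value then pathway id, so an all-equal weight vector leaves
#' the unweighted order untouched. Re-ranking is a pure permutation: it never
#' alters p-values, overlap counts or the set of pathways.
#' `rank_delta = unweighted_rank - weighted_rank`, positive when the weights
#' promote a pathway (e.g. a pathway moving from 12th to 2nd has
#' `rank_delta = +10`).
#'
#' @param result an [hypergeom_enrich()] result.
#' @param c_scores named numeric vector of pathway C scores; pathways absent
#'   from it are scored 0 with a warning.
#' @return the result with `weight_c`, `weighted_rank`, `rank_delta` filled
#'   and rows ordered by weighted rank.
#' @export
rerank_by_weight <- function(result, c_scores) {
  if (!inherits(result, "enrichment_result"))
    validation_error("result must come from hypergeom_enrich()")
  res <- result
  cvec <- c_scores[res$pathway_id]
  miss <- is.na(cvec) | !(res$pathway_id %in% names(c_scores))
  if (any(miss)) {
    warning("no weight coefficient for pathway(s): ",
            paste(res$pathway_id[miss], collapse = ", "), "; using C = 0")
    cvec[miss] <- 0
  }
  res$weight_c <- as.numeric(cvec)
  ord <- order(-res$weight_c, res$p_value, res$pathway_id)
  res <- res[ord, , drop = FALSE]
  res$weighted_rank <- seq_len(nrow(res))
  res$rank_delta <- res$unweighted_rank - res$weighted_rank
  rownames(res) <- NULL
  res
}

#' Enrich and re-rank in one call
#'
#' Composes the pipeline tail: per-target weights B from the component table
#' and edge map, per-pathway weights C, hypergeometric enrichment of the
#' query, and weight-based re-ranking.
#'
#' @inheritParams hypergeom_enrich
#' @param component_table a [component_table()].
#' @param edges a [target_map()].
#' @return an [hypergeom_enrich()] result with weighted ranks filled.
#' @export
enrich_and_rerank <- function(query, collection, component_table, edges,
                              k_min = 0) {
  b <- target_scores(component_table, edges)
  cs <- pathway_scores(b, collection)
  res <- hypergeom_enrich(query, collection, k_min = k_min)
  rerank_by_weight(res, cs)
}

#' Write an enrichment result table
#'
#' @param result an [hypergeom_enrich()]/[rerank_by_weight()] result.
#' @param path output TSV path.
#' @export
write_enrichment <- function(result, path) {
  cols <- c("pathway_id", "description", "k", "K", "n", "N", "p_value",
            "fdr_bh", "unweighted_rank", "weight_c", "weighted_rank",
            "rank_delta")
  write_flat(as.data.frame(result)[, cols], path)
}
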