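# The weighting cascade: A per component, B per target, C per pathway.
#
# A = OB * I          (oral bioavailability x relative content)
# B(t) = sum of A over components with an edge to target t
# C(p) = sum of B over scored targets contained in pathway p
#
# All three are raw sums: no normalization by pathway size is applied, so C
# favours large pathways with many weighted targets; downstream use is
# rank-only. Content I enters on the percent scale as printed in GC-MS area
# reports; since the cascade is linear, the scale choice rescales every
# A/B/C by the same factor and leaves all rankings unchanged.

#' Per-component weight A = OB * I
#'
#' @param ob oral bioavailability, fraction in \[0, 1\] (vectorized).
#' @param content_i relative content, typically area percent, >= 0.
#' @return numeric vector of A scores.
#' @export
component_score <- function(ob, content_i) {
  ob <- as.numeric(ob); content_i <- as.numeric(content_i)
  if (anyNA(ob) || any(ob < 0 | ob > 1))
    validation_error("ob must be within [0, 1]")
  if (anyNA(content_i) || any(content_i < 0))
    validation_error("content must be >= 0")
  ob * content_i
}

#' Read a component-target edge map
#'
#' TSV with header `component`, `target`. Duplicate (component, target)
#' pairs -- e.g. the same interaction reported by several prediction
#' databases -- are collapsed to a single edge: repeated database hits are
#' evidence redundancy, not dosage.
#'
#' @param path file path.
#' @return data.frame of class `target_map` with columns `component`,
#'   `target` (targets normalized as gene symbols).
#' @export
read_target_map <- function(path) {
  df <- read_flat(path, sep = sep_for(path))
  target_map(df)
}

#' Validate a component-target edge map
#'
#' @param df data.frame with columns `component` and `target`.
#' @return deduplicated data.frame of class `target_map`.
#' @export
target_map <- function(df) {
  need <- c("component", "target")
  if (!all(need %in% names(df)))
    stop_wcnp("target map must have columns: ", paste(need, collapse = ", "),
              class = "wcnp_parse_error")
  out <- data.frame(component = squish(df$component),
                    target = normalize_genes(df$target),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$component, out$target), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("target_map", "data.frame"))
}

#' Write a component-target edge map
#'
#' @param edges a [target_map()].
#' @param path output path.
#' @export
write_target_map <- function(edges, path) {
  write_flat(as.data.frame(edges)[, c("component", "target")], path)
}

# A per table row; duplicate compound names each keep their own row score.
component_a_scores <- function(table) {
  component_score(table$ob, table$area_pct)
}

#' Per-target weights B
#'
#' `B(t)` sums the A scores of every component linked to target `t`. A
#' component name listed in the table under several CAS numbers contributes
#' each of its row scores (they are distinct constituents with distinct
#' contents sharing a display name). A component appearing in several targets
#' contributes its full A to each; nothing is split. Targets with no edges
#' are absent from the result, not zero-filled.
#'
#' @param table a [component_table()].
#' @param edges a [target_map()] (or data.frame with `component`, `target`).
#' @return named numeric vector of B scores, one per target with >= 1 edge,
#'   sorted by target symbol.
#' @export
target_scores <- function(table, edges) {
  if (!inherits(edges, "target_map")) edges <- target_map(edges)
  if (nrow(edges) == 0) return(stats::setNames(numeric(0), character(0)))
  a <- component_a_scores(table)
  # total A per component name (summing duplicate-name rows)
  a_by_name <- tapply(a, norm_key(table$name), sum)
  key <- norm_key(edges$component)
  missing <- !(key %in% names(a_by_name))
  if (any(missing))
    validation_error("target map references unknown component(s): ",
                     paste(unique(edges$component[missing]), collapse = ", "))
  contrib <- as.numeric(a_by_name[key])
  b <- tapply(contrib, edges$target, sum)
  b <- stats::setNames(as.numeric(b), names(b))
  b[order(names(b))]
}

#' Per-pathway weights C
#'
#' `C(p)` sums the B scores of the scored targets contained in pathway `p`.
#' Pathway members without a B score contribute zero.
#'
#' @param b named numeric vector of target B scores (from [target_scores()]).
#' @param pathways a [gene_set_collection()] or a named list of gene-symbol
#'   vectors.
#' @return named numeric vector of C scores, one per pathway.
#' @export
pathway_scores <- function(b, pathways) {
  sets <- pathway_gene_list(pathways)
  vapply(sets, function(g) sum(b[intersect(normalize_genes(g), names(b))]),
         numeric(1))
}

# Accept either a gene_set_collection or a bare named list of vectors.
pathway_gene_list <- function(pathways) {
  if (inherits(pathways, "gene_set_collection"))
    lapply(pathways$sets, `[[`, "genes")
  else if (is.list(pathways)) pathways
  else validation_error("pathways must be a gene_set_collection or named list")
}

#' Full weight cascade for a component table
#'
#' Convenience wrapper computing the per-component A, per-target B and
#' per-pathway C scores in one pass.
#'
#' @inheritParams target_scores
#' @param pathways optional pathway collection; if omitted, `c_scores` is
#'   empty.
#' @return object of class `weight_table`: list with data.frame `a_scores`
#'   (`name`, `cas`, `a`), named vectors `b_scores` and `c_scores`.
#' @export
weight_table <- function(table, edges, pathways = NULL) {
  a <- data.frame(name = table$name, cas = table$cas,
                  a = component_a_scores(table), stringsAsFactors = FALSE)
  b <- target_scores(table, edges)
  cs <- if (is.null(pathways)) stats::setNames(numeric(0), character(0))
        else pathway_scores(b, pathways)
  structure(list(a_scores = a, b_scores = b, c_scores = cs),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table: %d components, %d targets, %d pathways>\n",
              nrow(x$a_scores), length(x$b_scores), length(x$c_scores)))
  invisible(x)
}

#' Write weight reports
#'
#' Emits `component_weights.tsv` (name, cas, A), `target_weights.tsv`
#' (target, B) and `pathway_weights.tsv` (pathway, C), each sorted by
#' descending weight.
#'
#' @param weights a [weight_table()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_weight_reports <- function(weights, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- weights$a_scores[order(-weights$a_scores$a, weights$a_scores$name), ]
  p1 <- write_flat(a, file.path(dir, "component_weights.tsv"))
  b <- weights$b_scores
  bd <- data.frame(target = names(b), b = as.numeric(b))
  bd <- bd[order(-bd$b, bd$target), , drop = FALSE]
  p2 <- write_flat(bd, file.path(dir, "target_weights.tsv"))
  cs <- weights$c_scores
  cd <- data.frame(pathway = names(cs), c = as.numeric(cs))
  cd <- cd[order(-cd$c, cd$pathway), , drop = FALSE]
  p3 <- write_flat(cd, file.path(dir, "pathway_weights.tsv"))
  invisible(c(p1, p2, p3))
}
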