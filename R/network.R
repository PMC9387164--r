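# Component-target-pathway network construction and PPI edge filtering.

#' Read a STRING-style PPI edge list
#'
#' TSV with header `protein_a`, `protein_b`, `combined_score`. Edges are
#' undirected: endpoint pairs are canonicalized to lexicographic order and
#' duplicates collapsed (keeping the maximum score when A-B and B-A rows
#' disagree). Self-loops are dropped.
#'
#' @param path file path.
#' @return data.frame of class `ppi_edge_list`.
#' @export
read_ppi_edges <- function(path) {
  df <- read_flat(path, sep = sep_for(path))
  ppi_edge_list(df)
}

#' Validate and canonicalize a PPI edge list
#'
#' @param df data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score`. Scores may be on the STRING 0-1000 scale or already
#'   normalized to 0-1.
#' @return canonicalized data.frame of class `ppi_edge_list`.
#' @export
ppi_edge_list <- function(df) {
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(df)))
    stop_wcnp("PPI table must have columns: ", paste(need, collapse = ", "),
              class = "wcnp_parse_error")
  a <- normalize_genes(df$protein_a)
  b <- normalize_genes(df$protein_b)
  s <- as.numeric(df$combined_score)
  if (anyNA(s) || any(s < 0 | s > 1000))
    validation_error("combined_score must lie in [0, 1] or [0, 1000]")
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep]); s <- s[keep]
  out <- data.frame(protein_a = a2, protein_b = b2, combined_score = s,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0) {
    key <- paste(out$protein_a, out$protein_b, sep = "\r")
    agg <- tapply(out$combined_score, key, max)
    split_key <- strsplit(names(agg), "\r", fixed = TRUE)
    out <- data.frame(protein_a = vapply(split_key, `[[`, "", 1L),
                      protein_b = vapply(split_key, `[[`, "", 2L),
                      combined_score = as.numeric(agg),
                      stringsAsFactors = FALSE)
    out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("ppi_edge_list", "data.frame"))
}

#' Filter PPI edges by confidence
#'
#' Retains edges whose confidence is strictly greater than `min_confidence`
#' on the normalized 0-1 scale -- the STRING "highest confidence" preset is
#' `min_confidence = 0.9`, and an edge at exactly 0.900 is removed. Scores on
#' the STRING 0-1000 integer scale are divided by 1000 before comparison.
#'
#' @param edges a [ppi_edge_list()] (or coercible data.frame).
#' @param min_confidence threshold in \[0, 1\]; default 0.9.
#' @param scale `"auto"` (default: any score > 1 implies the 0-1000
#'   dialect), `"s1000"`, or `"unit"`.
#' @return filtered [ppi_edge_list()] with scores on the input scale.
#' @export
filter_ppi_edges <- function(edges, min_confidence = 0.9,
                             scale = c("auto", "s1000", "unit")) {
  scale <- match.arg(scale)
  if (!inherits(edges, "ppi_edge_list")) edges <- ppi_edge_list(edges)
  if (!is.numeric(min_confidence) || min_confidence < 0 || min_confidence > 1)
    validation_error("min_confidence must be in [0, 1]")
  s <- edges$combined_score
  is1000 <- switch(scale,
                   auto = length(s) > 0 && any(s > 1),
                   s1000 = TRUE,
                   unit = FALSE)
  if (is1000 && any(s > 1000)) validation_error("scores exceed the 0-1000 scale")
  if (!is1000 && any(s > 1))
    validation_error("scores exceed 1 but unit scale was requested")
  norm <- if (is1000) s / 1000 else s
  out <- edges[norm > min_confidence, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ppi_edge_list", "data.frame"))
}

#' Write a PPI edge list
#'
#' @param edges a [ppi_edge_list()].
#' @param path output TSV path.
#' @export
write_ppi_edges <- function(edges, path) {
  write_flat(as.data.frame(edges)[, c("protein_a", "protein_b",
                                      "combined_score")], path)
}

node_kinds <- c("component", "target", "pathway")
edge_kinds <- c("component-target", "target-pathway", "ppi")

#' Construct a typed tripartite network
#'
#' @param nodes data.frame with columns `id`, `kind` (one of `component`,
#'   `target`, `pathway`).
#' @param edges data.frame with columns `source`, `target`, `kind` (one of
#'   `component-target`, `target-pathway`, `ppi`), `weight` (>= 0).
#' @return object of class `tripartite_network`.
#' @export
tripartite_network <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      kind = as.character(edges$kind),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    validation_error("duplicate node ids")
  if (!all(nodes$kind %in% node_kinds))
    validation_error("node kind must be one of: ", paste(node_kinds, collapse = ", "))
  if (!all(edges$kind %in% edge_kinds))
    validation_error("edge kind must be one of: ", paste(edge_kinds, collapse = ", "))
  if (!all(c(edges$source, edges$target) %in% nodes$id))
    validation_error("edge endpoint(s) missing from node table")
  if (any(edges$source == edges$target))
    validation_error("self-loops are not allowed")
  if (any(edges$weight < 0)) validation_error("edge weights must be >= 0")
  kind_of <- stats::setNames(nodes$kind, nodes$id)
  expected <- list("component-target" = c("component", "target"),
                   "target-pathway" = c("target", "pathway"),
                   "ppi" = c("target", "target"))
  ok <- mapply(function(s, t, k) {
    e <- expected[[k]]
    identical(c(kind_of[[s]], kind_of[[t]]), e)
  }, edges$source, edges$target, edges$kind)
  if (!all(ok))
    validation_error("edge kind inconsistent with endpoint kinds for edge(s): ",
                     paste(which(!ok), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  tab <- table(factor(x$nodes$kind, levels = node_kinds))
  cat(sprintf("<tripartite_network: %d nodes (%s), %d edges>\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Drop isolated nodes from a network
#'
#' Removes every node of degree zero ("hiding the free proteins"); edges are
#' untouched.
#'
#' @param net a [tripartite_network()].
#' @return the network with only degree >= 1 nodes.
#' @export
drop_isolated_nodes <- function(net) {
  used <- unique(c(net$edges$source, net$edges$target))
  nodes <- net$nodes[net$nodes$id %in% used, , drop = FALSE]
  rownames(nodes) <- NULL
  tripartite_network(nodes, net$edges)
}

#' Build the component-target-pathway network
#'
#' Component-target edges are created only for targets in `key_targets`,
#' weighted by the component's A score (total over duplicate-name rows);
#' target-pathway edges connect key targets to the pathways containing them,
#' weighted by the target's B score. Components and pathways that end up with
#' no edges are not added as nodes.
#'
#' @param table a [component_table()].
#' @param edges a [target_map()].
#' @param pathways a [gene_set_collection()] (or named list of gene vectors).
#' @param key_targets a [gene_set()] (or character vector) restricting which
#'   targets become nodes.
#' @return a [tripartite_network()].
#' @export
build_tripartite <- function(table, edges, pathways, key_targets) {
  if (!inherits(edges, "target_map")) edges <- target_map(edges)
  keys <- as_gene_set(key_targets, "key_targets")$genes
  a_by_name <- tapply(component_a_scores(table), norm_key(table$name), sum)
  display <- stats::setNames(squish(table$name), norm_key(table$name))
  b <- target_scores(table, edges)

  ct <- edges[edges$target %in% keys, , drop = FALSE]
  ct_edges <- data.frame(source = as.character(display[norm_key(ct$component)]),
                         target = ct$target,
                         kind = rep("component-target", nrow(ct)),
                         weight = as.numeric(a_by_name[norm_key(ct$component)]),
                         stringsAsFactors = FALSE)

  sets <- pathway_gene_list(pathways)
  tp <- do.call(rbind, c(list(
    data.frame(source = character(0), target = character(0),
               stringsAsFactors = FALSE)),
    lapply(names(sets), function(pid) {
      hit <- intersect(normalize_genes(sets[[pid]]), intersect(keys, ct$target))
      if (length(hit) == 0) return(NULL)
      data.frame(source = hit, target = pid, stringsAsFactors = FALSE)
    })))
  tp_edges <- data.frame(source = tp$source, target = tp$target,
                         kind = rep("target-pathway", nrow(tp)),
                         weight = if (nrow(tp)) as.numeric(b[tp$source]) else numeric(0),
                         stringsAsFactors = FALSE)

  all_edges <- rbind(ct_edges, tp_edges)
  ids <- list(component = unique(ct_edges$source),
              target = unique(ct$target),
              pathway = unique(tp_edges$target))
  nodes <- data.frame(id = unlist(ids, use.names = FALSE),
                      kind = rep(names(ids), lengths(ids)),
                      stringsAsFactors = FALSE)
  tripartite_network(nodes, all_edges)
}

#' Export a network as SIF
#'
#' Simple interaction format: `source<TAB>interaction-kind<TAB>target`, one
#' edge per line; isolated nodes are appended as single-field lines so the
#' round trip preserves them.
#'
#' @param net a [tripartite_network()].
#' @param path output path.
#' @export
export_sif <- function(net, path) {
  lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$kind,
                   net$edges$target)
  used <- unique(c(net$edges$source, net$edges$target))
  iso <- setdiff(net$nodes$id, used)
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a SIF file back into an edge table
#'
#' Node kinds and weights are not part of SIF; the result is a plain
#' data.frame of edges plus any isolated node ids.
#'
#' @param path SIF path.
#' @return list with `edges` (source, kind, target) and `isolated` ids.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, integer(1))
  ed <- parts[n >= 3]
  list(
    edges = data.frame(
      source = vapply(ed, `[[`, "", 1L),
      kind = vapply(ed, `[[`, "", 2L),
      target = vapply(ed, `[[`, "", 3L),
      stringsAsFactors = FALSE),
    isolated = vapply(parts[n == 1], `[[`, "", 1L)
  )
}

#' Export a network as GraphML
#'
#' Writes node `kind` and edge `kind`/`weight` attributes via igraph.
#'
#' @param net a [tripartite_network()].
#' @param path output path.
#' @export
export_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$source, to = net$edges$target,
                   kind = net$edges$kind, weight = net$edges$weight,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, kind = net$nodes$kind,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file back into a tripartite network
#'
#' @param path GraphML path.
#' @return a [tripartite_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  tripartite_network(
    nodes = data.frame(id = nd$name, kind = nd$kind, stringsAsFactors = FALSE),
    edges = data.frame(source = ed$from, target = ed$to, kind = ed$kind,
                       weight = as.numeric(ed$weight), stringsAsFactors = FALSE))
}
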