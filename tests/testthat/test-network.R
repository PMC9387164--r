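test_that("PPI filtering is strictly greater-than on the normalized scale", {
  edges <- ppi_edge_list(data.frame(
    protein_a = c("a", "b", "c", "d"),
    protein_b = c("x", "y", "z", "w"),
    combined_score = c(0.95, 0.91, 0.89, 0.40)))
  kept <- filter_ppi_edges(edges, 0.9)
  expect_identical(nrow(kept), 2L)
  expect_setequal(kept$combined_score, c(0.95, 0.91))
  # the exact 0.900 boundary is excluded, in both dialects
  b1 <- ppi_edge_list(data.frame(protein_a = "a", protein_b = "b",
                                 combined_score = 0.9))
  expect_identical(nrow(filter_ppi_edges(b1, 0.9)), 0L)
  b2 <- ppi_edge_list(data.frame(protein_a = "a", protein_b = "b",
                                 combined_score = 900))
  expect_identical(nrow(filter_ppi_edges(b2, 0.9)), 0L)
  expect_identical(nrow(filter_ppi_edges(b2, 0.9, scale = "s1000")), 0L)
  # empty in, empty out
  empty <- ppi_edge_list(data.frame(protein_a = character(0),
                                    protein_b = character(0),
                                    combined_score = numeric(0)))
  expect_identical(nrow(filter_ppi_edges(empty, 0.9)), 0L)
})

test_that("PPI filter equals brute-force comprehension in both dialects", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    unit <- rep %% 2 == 0
    prot <- sprintf("P%02d", 1:15)
    df <- data.frame(protein_a = sample(prot, n, replace = TRUE),
                     protein_b = sample(prot, n, replace = TRUE),
                     combined_score = if (unit) round(runif(n), 3)
                                      else sample(0:1000, n, replace = TRUE))
    edges <- ppi_edge_list(df)
    thr <- runif(1)
    kept <- filter_ppi_edges(edges, thr,
                             scale = if (unit) "unit" else "s1000")
    norm <- if (unit) edges$combined_score else edges$combined_score / 1000
    expect_equal(as.data.frame(kept),
                 as.data.frame(edges)[norm > thr, , drop = FALSE],
                 ignore_attr = TRUE)
    # subset of input and idempotent
    expect_true(nrow(kept) <= nrow(edges))
    expect_equal(as.data.frame(filter_ppi_edges(kept, thr,
                                                scale = if (unit) "unit" else "auto")),
                 as.data.frame(kept), ignore_attr = TRUE)
  }
})

test_that("PPI lists canonicalize undirected duplicates and reject bad scores", {
  df <- data.frame(protein_a = c("B", "A", "A"), protein_b = c("A", "B", "A"),
                   combined_score = c(700, 800, 999))
  edges <- ppi_edge_list(df)
  # A-B and B-A collapse (max score kept); the self-loop is dropped
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$protein_a, "A")
  expect_equal(edges$combined_score, 800)
  expect_error(ppi_edge_list(data.frame(protein_a = "a", protein_b = "b",
                                        combined_score = 1001)),
               class = "wcnp_validation_error")
  expect_error(filter_ppi_edges(ppi_edge_list(df), 1.5),
               class = "wcnp_validation_error")
})

toy_net <- function() {
  tripartite_network(
    nodes = data.frame(
      id = c("cmp1", "T1", "T2", "T3", "PW1"),
      kind = c("component", "target", "target", "target", "pathway")),
    edges = data.frame(
      source = c("cmp1", "T1"), target = c("T1", "PW1"),
      kind = c("component-target", "target-pathway"), weight = c(2, 5)))
}

test_that("tripartite networks validate node and edge typing", {
  net <- toy_net()
  expect_identical(nrow(net$nodes), 5L)
  # wrong endpoint kinds for the declared edge kind
  expect_error(tripartite_network(
    nodes = data.frame(id = c("a", "b"), kind = c("component", "pathway")),
    edges = data.frame(source = "a", target = "b", kind = "component-target",
                       weight = 1)), class = "wcnp_validation_error")
  expect_error(tripartite_network(
    nodes = data.frame(id = "a", kind = "target"),
    edges = data.frame(source = "a", target = "a", kind = "ppi", weight = 1)),
    class = "wcnp_validation_error")
  expect_error(tripartite_network(
    nodes = data.frame(id = "a", kind = "target"),
    edges = data.frame(source = "a", target = "ghost", kind = "ppi",
                       weight = 1)), class = "wcnp_validation_error")
})

test_that("drop_isolated_nodes removes exactly the degree-zero nodes", {
  net <- toy_net()  # T2, T3 isolated
  pruned <- drop_isolated_nodes(net)
  expect_identical(nrow(pruned$nodes), nrow(net$nodes) - 2L)
  expect_false(any(c("T2", "T3") %in% pruned$nodes$id))
  expect_equal(pruned$edges, net$edges)
  # degree census: every survivor has degree >= 1
  deg <- table(c(pruned$edges$source, pruned$edges$target))
  expect_true(all(pruned$nodes$id %in% names(deg)))
  # no edges -> empty network; fully connected -> unchanged
  empty <- tripartite_network(
    nodes = data.frame(id = c("x", "y"), kind = c("target", "target")),
    edges = data.frame(source = character(0), target = character(0),
                       kind = character(0), weight = numeric(0)))
  expect_identical(nrow(drop_isolated_nodes(empty)$nodes), 0L)
  expect_identical(nrow(drop_isolated_nodes(pruned)$nodes),
                   nrow(pruned$nodes))
})

test_that("build_tripartite wires components, key targets and pathways", {
  tab <- toy_components()
  edges <- target_map(data.frame(
    component = c("alpha-pinene", "camphene", "bornyl acetate", "camphene"),
    target = c("t1", "t1", "t2", "t3")))
  pathways <- list(PW1 = c("T1", "T2"), PW2 = c("T3"))
  keys <- gene_set("k", c("t1", "t2"))
  net <- build_tripartite(tab, edges, pathways, keys)
  # t3 is not a key target: no node, no edges, PW2 never appears
  expect_false(any(c("T3", "PW2") %in% net$nodes$id))
  # brute-force census: 3 components + 2 targets + 1 pathway
  expect_identical(nrow(net$nodes), 6L)
  ct <- net$edges[net$edges$kind == "component-target", ]
  expect_identical(nrow(ct), 3L)
  tp <- net$edges[net$edges$kind == "target-pathway", ]
  expect_identical(nrow(tp), 2L)
  # weights carry A on component-target and B on target-pathway edges
  a <- setNames(component_score(tab$ob, tab$area_pct), tab$name)
  expect_equal(ct$weight[ct$source == "camphene"],
               rep(unname(a["camphene"]), 1))
  b <- target_scores(tab, edges)
  expect_equal(setNames(tp$weight, tp$source), b[tp$source])
  # degree of a component node = number of its key targets
  for (cn in unique(ct$source))
    expect_identical(sum(net$edges$source == cn),
                     length(unique(edges$target[
                       edges$component == cn & edges$target %in% keys$genes])))
  # empty key set -> no target nodes
  net0 <- build_tripartite(tab, edges, pathways, character(0))
  expect_false(any(net0$nodes$kind == "target"))
  # minimal chain: 3 nodes, 2 edges
  net1 <- build_tripartite(tab,
                           target_map(data.frame(component = "camphene",
                                                 target = "t9")),
                           list(PW = "T9"), gene_set("k", "t9"))
  expect_identical(nrow(net1$nodes), 3L)
  expect_identical(nrow(net1$edges), 2L)
})

test_that("SIF and GraphML exports round-trip node and edge multisets", {
  net <- toy_net()
  sif <- withr::local_tempfile(fileext = ".sif")
  export_sif(net, sif)
  back <- read_sif(sif)
  expect_setequal(paste(back$edges$source, back$edges$kind, back$edges$target),
                  paste(net$edges$source, net$edges$kind, net$edges$target))
  expect_setequal(c(back$isolated, unique(c(back$edges$source, back$edges$target))),
                  net$nodes$id)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  g <- read_graphml(gml)
  expect_setequal(paste(g$nodes$id, g$nodes$kind),
                  paste(net$nodes$id, net$nodes$kind))
  canon <- function(e) sort(paste(pmin(e$source, e$target), e$kind,
                                  pmax(e$source, e$target), e$weight))
  expect_identical(canon(g$edges), canon(net$edges))
})
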