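toy_collection <- function() {
  gene_set_collection(list(
    P1 = list(description = "one", genes = c("a", "b", "c")),
    P2 = list(description = "two", genes = c("c", "d")),
    P3 = list(description = "three", genes = c("e", "f", "g"))))
}

test_that("hypergeometric p matches exhaustive enumeration for all N <= 12", {
  for (N in 2:12) {
    for (n in 1:N) {
      for (K in 1:N) {
        universe <- sprintf("G%02d", 1:N)
        coll <- gene_set_collection(
          list(P = list(description = "", genes = universe[seq_len(K)])),
          universe = universe)
        res <- hypergeom_enrich(gene_set("q", universe[seq_len(n)]), coll)
        expect_equal(res$p_value, enum_hyper_p(N, K, n, res$k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the 2-of-2 overlap in a 5-gene universe has p exactly 1/10", {
  universe <- c("g1", "g2", "g3", "g4", "g5")
  coll <- gene_set_collection(
    list(P = list(description = "", genes = c("g1", "g2"))),
    universe = universe)
  res <- hypergeom_enrich(gene_set("q", c("g1", "g2")), coll)
  expect_identical(res$k, 2L)
  expect_equal(res$p_value, 0.1, tolerance = 1e-15)
  expect_equal(res$p_value, enum_hyper_p(5, 2, 2, 2))
})

test_that("zero overlap gives p = 1 and BH matches the step-up definition", {
  universe <- sprintf("G%02d", 1:20)
  coll <- gene_set_collection(
    list(P0 = list(description = "", genes = universe[11:15]),
         P1 = list(description = "", genes = universe[1:5])),
    universe = universe)
  res <- hypergeom_enrich(gene_set("q", universe[1:5]), coll)
  expect_equal(res$p_value[res$pathway_id == "P0"], 1)

  # hand-checked BH step-up on (0.01, 0.02, 0.03)
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))

  set.seed(5)
  for (rep in 1:50) {
    p <- runif(sample(1:30, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_stepup(p))
  }
  # BH values within a result are the step-up of its p-values
  expect_equal(res$fdr_bh, bh_stepup(res$p_value))
  # step-up values are monotone in p-rank
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr_bh[o]) >= 0))
})

test_that("enrichment validates universe and query overlap", {
  coll <- toy_collection()
  expect_error(hypergeom_enrich(gene_set("q", c("zz")), coll),
               "no genes", class = "wcnp_error")
  # query genes outside the universe are ignored, not counted in n
  res <- hypergeom_enrich(gene_set("q", c("a", "zz")), coll)
  expect_identical(unique(res$n), 1L)
  expect_identical(unique(res$N), length(coll$universe))
})

test_that("rerank_by_weight is a pure permutation with documented tie-breaks", {
  universe <- sprintf("G%02d", 1:30)
  set.seed(8)
  sets <- setNames(lapply(1:6, function(i)
    list(description = "", genes = sample(universe, 8))),
    paste0("P", 1:6))
  coll <- gene_set_collection(sets, universe = universe)
  res <- hypergeom_enrich(gene_set("q", sample(universe, 10)), coll)

  cs <- setNames(runif(6), paste0("P", 1:6))
  rr <- rerank_by_weight(res, cs)
  # permutation of 1..m in both rank columns
  m <- nrow(rr)
  expect_setequal(rr$unweighted_rank, seq_len(m))
  expect_setequal(rr$weighted_rank, seq_len(m))
  # p, k, K, n, N untouched
  key <- rr[order(rr$pathway_id), c("pathway_id", "k", "K", "n", "N", "p_value", "fdr_bh")]
  key0 <- res[order(res$pathway_id), c("pathway_id", "k", "K", "n", "N", "p_value", "fdr_bh")]
  expect_equal(key, key0, ignore_attr = TRUE)
  # ordered by descending C
  expect_true(all(diff(rr$weight_c) <= 0))
  expect_identical(rr$rank_delta, rr$unweighted_rank - rr$weighted_rank)
  # idempotent
  rr2 <- rerank_by_weight(rr, cs)
  expect_equal(rr2, rr)
  # all-equal weights preserve the unweighted order exactly
  eq <- rerank_by_weight(res, setNames(rep(1, 6), paste0("P", 1:6)))
  expect_identical(eq$pathway_id,
                   res$pathway_id[order(res$unweighted_rank)])
  expect_identical(eq$weighted_rank, eq$unweighted_rank)
  expect_true(all(eq$rank_delta == 0))
})

test_that("a pathway promoted from 12th to 2nd has rank_delta +10", {
  universe <- sprintf("G%03d", 1:200)
  m <- 15
  # pathway sizes chosen so p-values are strictly increasing with index
  sets <- setNames(lapply(1:m, function(i)
    list(description = "", genes = universe[1:(i + 3)])), sprintf("S%02d", 1:m))
  coll <- gene_set_collection(sets, universe = universe)
  res <- hypergeom_enrich(gene_set("q", universe[1:4]), coll)
  target <- res$pathway_id[res$unweighted_rank == 12]
  cs <- setNames(rep(0, m), res$pathway_id)
  cs[res$pathway_id[res$unweighted_rank == 1]] <- 100  # stays first
  cs[target] <- 50                                     # promoted to second
  rr <- rerank_by_weight(res, cs)
  expect_identical(rr$weighted_rank[rr$pathway_id == target], 2L)
  expect_identical(rr$rank_delta[rr$pathway_id == target], 10L)
})

test_that("missing weight coefficients warn and count as zero", {
  coll <- toy_collection()
  res <- hypergeom_enrich(gene_set("q", c("a", "c")), coll)
  expect_warning(rr <- rerank_by_weight(res, c(P1 = 5)), "P2")
  expect_equal(rr$weight_c[rr$pathway_id == "P2"], 0)
  expect_identical(rr$weighted_rank[rr$pathway_id == "P1"], 1L)
})

test_that("enrich_and_rerank equals the staged composition", {
  tab <- toy_components()
  edges <- target_map(data.frame(
    component = c("alpha-pinene", "camphene", "bornyl acetate"),
    target = c("a", "a", "c")))
  coll <- toy_collection()
  res <- enrich_and_rerank(gene_set("q", c("a", "c", "e")), coll, tab, edges)
  b <- target_scores(tab, edges)
  cs <- pathway_scores(b, coll)
  staged <- rerank_by_weight(
    hypergeom_enrich(gene_set("q", c("a", "c", "e")), coll), cs)
  expect_equal(res, staged)
  # single-pathway collection: both ranks 1, delta 0
  single <- gene_set_collection(list(P = c("a", "b")), universe = c("a", "b", "c"))
  r1 <- enrich_and_rerank(gene_set("q", "a"), single, tab, edges)
  expect_identical(r1$unweighted_rank, 1L)
  expect_identical(r1$weighted_rank, 1L)
  expect_identical(r1$rank_delta, 0L)
  # empty edge map: all C = 0, weighted order equals unweighted order
  none <- target_map(data.frame(component = character(0), target = character(0)))
  r0 <- enrich_and_rerank(gene_set("q", c("a", "c", "e")), coll, tab, none)
  expect_true(all(r0$weight_c == 0))
  expect_identical(r0$weighted_rank, r0$unweighted_rank)
})

test_that("GMT files round-trip through read and write", {
  coll <- toy_collection()
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, p)
  back <- read_gmt(p)
  expect_equal(back$sets, coll$sets)
  expect_equal(back$universe, coll$universe)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("id_only\tdesc", bad)
  expect_error(read_gmt(bad), class = "wcnp_parse_error")
})
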