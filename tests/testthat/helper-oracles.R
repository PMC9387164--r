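# Independent oracles and small random-instance builders used across the
# suite. Everything here is deliberately naive -- enumeration, double/triple
# loops, the textbook step-up formula -- and never calls into the package
# code paths it checks.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws: universe 1..N, successes 1..K, P(overlap >= k).
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min over j >= i of m * p_(j) / j, capped at 1, mapped back to the
# original order.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force weighting cascade: triple loop over (component row, edge,
# pathway member) incidences. components: data.frame(name, area_pct, ob);
# edges: data.frame(component, target); pathways: named list of gene vectors.
brute_force_weights <- function(components, edges, pathways) {
  a <- components$ob * components$area_pct
  edges <- unique(edges[, c("component", "target")])
  targets <- unique(edges$target)
  b <- setNames(numeric(length(targets)), targets)
  for (t in targets) {
    for (j in seq_len(nrow(edges))) {
      if (edges$target[j] != t) next
      for (i in seq_len(nrow(components))) {
        if (toupper(trimws(components$name[i])) ==
            toupper(trimws(edges$component[j])))
          b[[t]] <- b[[t]] + a[i]
      }
    }
  }
  cs <- setNames(numeric(length(pathways)), names(pathways))
  for (p in names(pathways)) {
    for (t in names(b)) {
      if (t %in% toupper(pathways[[p]])) cs[[p]] <- cs[[p]] + b[[t]]
    }
  }
  list(a = setNames(a, components$name), b = b, c = cs)
}

# Random weighting instance within the stated size bounds.
random_weight_instance <- function(n_comp = sample(1:20, 1),
                                   n_targ = sample(1:60, 1),
                                   n_path = sample(1:25, 1)) {
  comps <- data.frame(
    name = sprintf("c%02d", seq_len(n_comp)),
    cas = sprintf("%06d-00-0", seq_len(n_comp)),
    area_pct = round(runif(n_comp, 0, 40), 4),
    ob = round(runif(n_comp), 4),
    stringsAsFactors = FALSE)
  targets <- sprintf("T%03d", seq_len(n_targ))
  n_edge <- sample(0:(3 * n_targ), 1)
  edges <- data.frame(
    component = sample(comps$name, n_edge, replace = TRUE),
    target = sample(targets, n_edge, replace = TRUE),
    stringsAsFactors = FALSE)
  pathways <- setNames(lapply(seq_len(n_path), function(i)
    sample(c(targets, sprintf("G%03d", 1:30)), sample(2:15, 1))),
    sprintf("P%02d", seq_len(n_path)))
  list(components = comps, edges = edges, pathways = pathways)
}

# Small component table used by several files.
toy_components <- function() {
  component_table(data.frame(
    name = c("alpha-pinene", "camphene", "bornyl acetate"),
    cas = c("0001", "0002", "0003"),
    retention_time = c(5.0, 6.0, 7.0),
    retention_index = NA_real_,
    area_pct = c(7.6523, 22.1145, 30.0004),
    ob = c(0.5, 0.4, 0.8),
    stringsAsFactors = FALSE))
}
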