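# Independent oracles and small fixture builders used across the suite.

# Brute-force Benjamini-Hochberg step-up: for each p(i) (sorted ascending),
# padj(i) = min_{j >= i} min(1, m * p(j) / j), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m / (i:m)) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact hypergeometric upper tail P(X >= k) by enumeration with choose().
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Minimal DEG-set constructor for set-logic tests.
make_deg <- function(ids, dirs = rep("up", length(ids))) {
  ids <- as.character(ids)
  dirs <- as.character(dirs)
  structure(
    data.frame(gene_id = ids, direction = dirs,
               log2FC = ifelse(dirs == "up", 2, -2),
               stringsAsFactors = FALSE),
    class = c("deg_set", "data.frame")
  )
}

# Per-gene set-membership oracle: loops genes and checks each set with %in%.
oracle_partition <- function(sets) {
  universe <- sort(unique(unlist(lapply(sets, function(s) s$gene_id))))
  res <- lapply(universe, function(g) {
    memb <- vapply(sets, function(s) g %in% s$gene_id, TRUE)
    dirs <- vapply(sets, function(s) {
      i <- match(g, s$gene_id)
      if (is.na(i)) NA_integer_ else if (s$direction[i] == "up") 1L else -1L
    }, 1L)
    list(segment = paste(names(sets)[memb], collapse = "+"), dirs = dirs)
  })
  names(res) <- universe
  res
}

# Random DEG sets over a pool of gene ids.
random_deg_sets <- function(set_names, pool, p_member = 0.4) {
  sets <- lapply(set_names, function(nm) {
    ids <- pool[stats::runif(length(pool)) < p_member]
    make_deg(ids, sample(c("up", "down"), length(ids), replace = TRUE))
  })
  names(sets) <- set_names
  sets
}

# Small simulation used by several engine tests.
quick_sim <- function(seed = 101, ...) {
  simulate_counts(simulation_config(seed = seed, ...))
}
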