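# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (loops, direct formula evaluation) and never call the
# package code paths they check.

# Step-up Benjamini-Hochberg, computed directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (k in n:1) {
    i <- ord[k]
    running_min <- min(running_min, p[i] * n / k)
    adj[i] <- min(running_min, 1)
  }
  adj
}

# Median-of-ratios size factors by direct re-implementation.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1L, function(r) all(r > 0))
  geo <- apply(counts[keep, , drop = FALSE], 1L, function(r) exp(mean(log(r))))
  sapply(seq_len(ncol(counts)), function(s) {
    median(counts[keep, s] / geo)
  })
}

# One-sided KS set statistics a, b by explicit enumeration over j.
oracle_ks_ab <- function(set_ranks, n) {
  v <- sort(set_ranks)
  t <- length(v)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  c(a = a, b = b)
}

oracle_cmap1 <- function(up_ranks, down_ranks, n) {
  ks <- function(r) {
    ab <- oracle_ks_ab(r, n)
    if (ab["a"] > ab["b"]) ab[["a"]] else -ab[["b"]]
  }
  ku <- ks(up_ranks); kd <- ks(down_ranks)
  if (sign(ku) == sign(kd)) 0 else (ku - kd) / 2
}

# Weighted enrichment score by an explicit position-by-position running sum.
oracle_weighted_es <- function(set, gene_ids, lfc) {
  ord <- order(-lfc, gene_ids)
  ids <- gene_ids[ord]; w <- abs(lfc[ord])
  t <- sum(ids %in% set); n <- length(ids)
  wsum <- sum(w[ids %in% set])
  rs <- 0; best <- 0
  for (k in seq_len(n)) {
    rs <- rs + if (ids[k] %in% set) w[k] / wsum else -1 / (n - t)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Average precision as the mean of precision at each positive's position.
oracle_average_precision <- function(labels) {
  hits <- 0; total <- 0
  for (k in seq_along(labels)) {
    if (labels[k]) {
      hits <- hits + 1
      total <- total + hits / k
    }
  }
  total / sum(labels)
}

# Interpolation-free area under the precision-recall steps (equivalent sum,
# written as an explicit finite integral over recall increments).
oracle_pr_area <- function(labels) {
  npos <- sum(labels)
  r_prev <- 0; area <- 0
  for (k in seq_along(labels)) {
    r_k <- sum(labels[1:k]) / npos
    p_k <- sum(labels[1:k]) / k
    area <- area + p_k * (r_k - r_prev)
    r_prev <- r_k
  }
  area
}

# Random signature over a fixed universe.
random_signature <- function(G, seed, sd = 1.5) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%05d", seq_len(G)),
             lfc = rnorm(G, 0, sd), stringsAsFactors = FALSE)
}

default_omega <- c(0.07, 0.80, 0.13)
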