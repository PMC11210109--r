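# Seven connectivity scores relating a query signature to a reference
# profile: the CMAP KS score (cmap1), the weighted two-sided connectivity
# score (cmap2), the connectivity strength score (css) and four extreme
# similarity metrics (xsum, xcos, xpearson, xspearman).

score_methods <- c("cmap1", "cmap2", "css", "xsum", "xcos", "xpearson",
                   "xspearman")

# Dense 1..G ranking of a reference by decreasing lfc, ties broken by gene id.
reference_ranks <- function(gene_ids, lfc) {
  ord <- order(-lfc, gene_ids)
  rk <- integer(length(lfc))
  rk[ord] <- seq_along(lfc)
  names(rk) <- gene_ids
  rk
}

#' Derive query gene sets from a signature
#'
#' The up set is the `top_k` genes with highest lfc and the down set the
#' `top_k` with lowest, ties broken lexicographically by gene id so the
#' result is deterministic. Errors if the two sets would overlap.
#'
#' @param signature data.frame with columns `gene_id` and `lfc`.
#' @param top_k set size (2 * top_k must not exceed the number of genes).
#' @return list of class `query_gene_sets` with character vectors `up` and
#'   `down`.
#' @export
derive_gene_sets <- function(signature, top_k = 100L) {
  G <- nrow(signature)
  if (top_k < 1L || 2L * top_k > G) {
    stopf("top_k must satisfy 1 <= top_k and 2 * top_k <= G")
  }
  ord_up <- order(-signature$lfc, signature$gene_id)
  ord_dn <- order(signature$lfc, signature$gene_id)
  up <- signature$gene_id[ord_up[seq_len(top_k)]]
  down_pool <- setdiff(signature$gene_id[ord_dn], up) # tie rule keeps sets disjoint
  down <- down_pool[seq_len(top_k)]
  structure(list(up = up, down = down), class = "query_gene_sets")
}

# One-sided KS-style statistic of a gene set inside a ranked reference.
ks_set_statistic <- function(set_ranks, n) {
  v <- sort(set_ranks)
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' CMAP KS connectivity score
#'
#' The Kolmogorov-Smirnov-based score of the original connectivity map: a
#' one-sided KS statistic is computed for the up and the down query sets
#' against the reference ranking (1 = most up-regulated); if the two
#' statistics have the same sign the score is 0, otherwise their difference
#' divided by 2, giving a pairwise score in [-1, 1]. Collection-wide batch
#' normalization is applied separately by the benchmark harness.
#'
#' @param query a [derive_gene_sets()] object.
#' @param ref reference signature: data.frame with `gene_id` and `lfc`.
#' @return numeric score in [-1, 1].
#' @export
cmap1_score <- function(query, ref) {
  rk <- reference_ranks(ref$gene_id, ref$lfc)
  if (!all(query$up %in% names(rk)) || !all(query$down %in% names(rk))) {
    stopf("query gene absent from the reference profile")
  }
  n <- length(rk)
  ks_up <- ks_set_statistic(rk[query$up], n)
  ks_down <- ks_set_statistic(rk[query$down], n)
  if (sign(ks_up) == sign(ks_down)) return(0)
  (ks_up - ks_down) / 2
}

# Weighted enrichment score of one set (GSEA running sum, weight |lfc|).
weighted_es <- function(set, gene_ids, lfc) {
  ord <- order(-lfc, gene_ids)
  ids <- gene_ids[ord]; w <- abs(lfc[ord])
  hit <- ids %in% set
  t <- sum(hit); n <- length(ids)
  if (t == 0L) stopf("empty or absent gene set")
  wsum <- sum(w[hit])
  inc <- ifelse(hit, if (wsum > 0) w / wsum else 1 / t, -1 / (n - t))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Weighted two-sided connectivity score (WTCS)
#'
#' The weighted KS enrichment score of the up and down query sets along the
#' lfc-sorted reference, with hit increments proportional to |lfc| and a
#' constant miss decrement. WTCS = (ES_up - ES_down) / 2 when the two
#' enrichment scores have opposite signs, else 0.
#'
#' @inheritParams cmap1_score
#' @return numeric score in [-1, 1].
#' @export
cmap2_wtcs <- function(query, ref) {
  if (!all(c(query$up, query$down) %in% ref$gene_id)) {
    stopf("query gene absent from the reference profile")
  }
  es_up <- weighted_es(query$up, ref$gene_id, ref$lfc)
  es_down <- weighted_es(query$down, ref$gene_id, ref$lfc)
  if (sign(es_up) == sign(es_down)) return(0)
  (es_up - es_down) / 2
}

# Signed ranks by |lfc|: the gene with the largest |lfc| gets +-G.
signed_ranks <- function(gene_ids, lfc) {
  ord <- order(abs(lfc), gene_ids)
  rk <- integer(length(lfc))
  rk[ord] <- seq_along(lfc)
  out <- sign(lfc) * rk
  out[lfc == 0] <- rk[lfc == 0] # sign 0 would erase the rank; treat as positive
  names(out) <- gene_ids
  out
}

#' Connectivity strength score (CSS)
#'
#' Sum over the query's deregulated gene set of the products of signed
#' |lfc|-ranks in the query and the reference, normalized by the maximum
#' attainable value for a set of that size (perfectly matched extreme
#' ranks), giving a score in [-1, 1]. With `set = NULL` the set defaults to
#' the query's `2 * top_k` genes with largest |lfc|, for which the
#' self-connectivity css(query, query) is exactly 1.
#'
#' @param query query signature: data.frame with `gene_id` and `lfc`.
#' @param ref reference signature: data.frame with `gene_id` and `lfc`.
#' @param set character vector of deregulated query genes, or `NULL`.
#' @param top_k used when `set` is `NULL` (default 100).
#' @return numeric score in [-1, 1].
#' @export
css_score <- function(query, ref, set = NULL, top_k = 100L) {
  if (is.null(set)) {
    t <- min(2L * top_k, nrow(query))
    ord <- order(-abs(query$lfc), query$gene_id)
    set <- query$gene_id[ord[seq_len(t)]]
  }
  if (!length(set)) stopf("deregulated gene set is empty")
  if (!all(set %in% query$gene_id) || !all(set %in% ref$gene_id)) {
    stopf("set gene absent from query or reference")
  }
  qr <- signed_ranks(query$gene_id, query$lfc)
  rr <- signed_ranks(ref$gene_id, ref$lfc)
  G <- nrow(ref)
  t <- length(set)
  max_sum <- sum((G - seq_len(t) + 1)^2)
  sum(qr[set] * rr[set]) / max_sum
}

#' Extreme similarity between two signatures
#'
#' The reference is masked to its `n_extreme` most up- and `n_extreme` most
#' down-regulated genes (all other reference values set to 0). `sum` adds
#' the masked reference values over the query's up set minus its down set;
#' `cos`, `pearson` and `spearman` compute the respective similarity between
#' the query lfc vector and the masked reference over the full gene
#' universe.
#'
#' @param query query signature: data.frame with `gene_id` and `lfc`.
#' @param ref reference signature over the same gene universe.
#' @param n_extreme number of genes kept at each extreme (default 500).
#' @param method one of `"sum"`, `"cos"`, `"pearson"`, `"spearman"`.
#' @param top_k query set size for `method = "sum"`.
#' @return numeric similarity; `sum` is unbounded, the others lie in [-1, 1].
#' @export
extreme_similarity <- function(query, ref, n_extreme = 500L,
                               method = c("sum", "cos", "pearson", "spearman"),
                               top_k = 100L) {
  method <- match.arg(method)
  G <- nrow(ref)
  if (n_extreme < 1L || 2L * n_extreme > G) {
    stopf("n_extreme must satisfy 2 * n_extreme <= G")
  }
  ord_up <- order(-ref$lfc, ref$gene_id)
  keep <- c(ord_up[seq_len(n_extreme)], rev(ord_up)[seq_len(n_extreme)])
  masked <- numeric(G)
  masked[keep] <- ref$lfc[keep]
  names(masked) <- ref$gene_id
  if (method == "sum") {
    gs <- derive_gene_sets(query, top_k)
    return(sum(masked[gs$up]) - sum(masked[gs$down]))
  }
  q <- query$lfc[match(ref$gene_id, query$gene_id)]
  if (any(is.na(q))) stopf("query and reference gene universes differ")
  switch(method,
    cos = {
      den <- sqrt(sum(q^2)) * sqrt(sum(masked^2))
      if (den == 0) 0 else sum(q * masked) / den
    },
    pearson = stats::cor(q, masked),
    spearman = stats::cor(q, masked, method = "spearman"))
}

#' Score one (query, reference) pair with several methods
#'
#' @param query query signature (data.frame `gene_id`, `lfc`).
#' @param ref reference signature over the same universe.
#' @param methods subset of `c("cmap1", "cmap2", "css", "xsum", "xcos",
#'   "xpearson", "xspearman")`.
#' @param top_k query set size for the set-based scores.
#' @param n_extreme extreme mask size for the x-scores.
#' @return named numeric vector of scores.
#' @export
score_pair <- function(query, ref, methods = score_methods, top_k = 100L,
                       n_extreme = 500L) {
  methods <- match.arg(methods, score_methods, several.ok = TRUE)
  gs <- if (any(methods %in% c("cmap1", "cmap2"))) derive_gene_sets(query, top_k)
  vapply(methods, function(m) switch(m,
    cmap1 = cmap1_score(gs, ref),
    cmap2 = cmap2_wtcs(gs, ref),
    css = css_score(query, ref, top_k = top_k),
    xsum = extreme_similarity(query, ref, n_extreme, "sum", top_k),
    xcos = extreme_similarity(query, ref, n_extreme, "cos"),
    xpearson = extreme_similarity(query, ref, n_extreme, "pearson"),
    xspearman = extreme_similarity(query, ref, n_extreme, "spearman")),
    numeric(1))
}

# Collection-wide normalization of cmap1 scores: positive scores divided by
# the maximum positive, negative by the absolute minimum.
normalize_cmap1_batch <- function(scores) {
  out <- scores
  pos <- scores > 0; neg <- scores < 0
  if (any(pos)) out[pos] <- scores[pos] / max(scores[pos])
  if (any(neg)) out[neg] <- scores[neg] / abs(min(scores[neg]))
  out
}
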