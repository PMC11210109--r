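#' Generate a benchmark dataset of interconnected signature pairs
#'
#' True connectivities are evenly spaced on [0, 1] (`n_pairs` values; a
#' single pair sits at c = 1). For each value an independent primary
#' signature is simulated and a secondary signature is generated from it
#' under the symmetric transition model. Optionally each signature of the
#' pair is passed through the replicate/count/DE pipeline so the pair
#' carries re-inferred signatures ("simulated triplicates").
#'
#' @param n_pairs number of pairs.
#' @param G genes per signature.
#' @param omega modality proportions of the primary signatures.
#' @param bank a [build_submodality_bank()] bank.
#' @param gamma noise factor of the modality transition.
#' @param sub_config,prob_config transition configurations (default
#'   deterministic).
#' @param use_count_pipeline logical; if `TRUE`, replace both signatures by
#'   their NB-Wald re-inferred estimates from simulated 3v3 counts.
#' @param n_replicates replicates per condition for the count pipeline.
#' @param count_model_ a [count_model()] for the pipeline.
#' @param seed optional integer seed.
#' @return list of class `benchmark_dataset`; each element is a
#'   `benchmark_pair`: list with `pair_id`, `true_connectivity`, `primary`,
#'   `secondary` (data.frames `gene_id`, `lfc`) and `dereg_proportion`.
#' @export
generate_benchmark <- function(n_pairs, G = 2000, omega = c(0.07, 0.80, 0.13),
                               bank = default_realistic_bank(), gamma = 0.02,
                               sub_config = submod_transition_config("deterministic"),
                               prob_config = prob_transition_config("deterministic"),
                               use_count_pipeline = FALSE, n_replicates = 3,
                               count_model_ = count_model(), seed = NULL) {
  if (n_pairs < 1L) stopf("n_pairs must be >= 1")
  cs <- if (n_pairs == 1L) 1 else seq(0, 1, length.out = n_pairs)
  pairs <- lapply(seq_len(n_pairs), function(k) {
    sk <- if (is.null(seed)) NULL else stage_seed(seed, paste0("pair", k))
    pri <- sample_primary_layers(omega, bank, G,
                                 seed = if (is.null(sk)) NULL else sk)
    sec <- simulate_secondary(pri, connectivity_model(cs[k], gamma), bank,
                              sub_config, prob_config,
                              seed = if (is.null(sk)) NULL else sk + 1L)
    psig <- compose_lfc(pri, bank, 1L)
    ssig <- sec$signature
    if (use_count_pipeline) {
      base <- simulate_base_expression(G, seed = if (is.null(sk)) NULL else sk + 2L)
      psig <- de_signature(pri, bank, base, n_replicates, count_model_,
                           seed = if (is.null(sk)) NULL else sk + 3L)
      ssig <- de_signature(sec$layers, bank, base, n_replicates, count_model_,
                           seed = if (is.null(sk)) NULL else sk + 4L)
    }
    structure(list(pair_id = k, true_connectivity = cs[k],
                   primary = psig, secondary = ssig,
                   dereg_proportion = mean(pri$modality != 2L)),
              class = "benchmark_pair")
  })
  structure(pairs, class = "benchmark_dataset")
}

# Run one layer set through the count pipeline and return the re-inferred
# signature as a gene_id/lfc/pvalue/padj data.frame.
de_signature <- function(layers, bank, base, n_replicates, model, seed = NULL) {
  cm <- simulate_count_experiment(layers, bank, base, n_replicates, model,
                                  seed = seed)
  de <- nb_wald_de(cm)
  data.frame(gene_id = de$gene_id, lfc = de$lfc_hat, pvalue = de$pvalue,
             padj = de$padj, stringsAsFactors = FALSE)
}

#' Label the top-N pairs of a benchmark as positive
#'
#' The `top_n` pairs with highest true connectivity are labeled positive,
#' the rest negative; ties are broken by pair id.
#'
#' @param pairs a `benchmark_dataset`.
#' @param top_n number of positive labels (1 <= top_n <= number of pairs).
#' @return the dataset with a logical `label` added to each pair.
#' @export
label_top_n <- function(pairs, top_n) {
  n <- length(pairs)
  if (top_n < 1L || top_n > n) stopf("top_n must lie in [1, n_pairs]")
  tc <- vapply(pairs, function(p) p$true_connectivity, numeric(1))
  id <- vapply(pairs, function(p) p$pair_id, numeric(1))
  pos <- order(-tc, id)[seq_len(top_n)]
  for (k in seq_len(n)) pairs[[k]]$label <- k %in% pos
  pairs
}

#' Average precision of a ranked label sequence
#'
#' The finite-sum average precision over the ranked retrieval list:
#' `AP = sum_k P_k * (r_k - r_{k-1})` with `P_k` the precision at cut-off k
#' and `r_k` the recall after k items.
#'
#' @param ranked_labels logical (or 0/1) vector in retrieval order, best
#'   first.
#' @return numeric AP in [0, 1].
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE)) # 5/6
#' @export
average_precision <- function(ranked_labels) {
  lab <- as.logical(ranked_labels)
  npos <- sum(lab)
  if (npos == 0L) stopf("average precision undefined without positive labels")
  k <- seq_along(lab)
  prec <- cumsum(lab) / k
  sum(prec[lab]) / npos
}

#' Evaluate scoring methods on replicated benchmark datasets
#'
#' For each dataset replicate: simulate a fresh benchmark, score every pair
#' (query = primary, reference = secondary) with each method, rank the pairs
#' by decreasing score (cmap1 is batch-normalized within the replicate,
#' ranking ties broken by pair id), and compute the average precision for
#' each top-N labeling. Means and t-interval 95% confidence bounds are
#' reported across replicates.
#'
#' @param config list of arguments for [generate_benchmark()] (`n_pairs`,
#'   `G`, `omega`, `bank`, `gamma`, ...).
#' @param methods character vector of score method names.
#' @param top_n_grid integer vector of top-N values.
#' @param n_dataset_replicates number of dataset replicates (default 20).
#' @param top_k,n_extreme scoring parameters.
#' @param seed optional integer seed.
#' @return list of class `benchmark_evaluation` with `results` (data.frame
#'   method, top_n, replicate, ap) and `summary` (data.frame method, top_n,
#'   mean_ap, ci_lower, ci_upper).
#' @export
evaluate_methods <- function(config, methods = score_methods,
                             top_n_grid = c(1, 5, 10, 50),
                             n_dataset_replicates = 20, top_k = 100L,
                             n_extreme = 500L, seed = NULL) {
  if (!length(methods)) stopf("methods must be nonempty")
  methods <- match.arg(methods, score_methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(n_dataset_replicates)) {
    args <- config
    args$seed <- if (is.null(seed)) NULL else stage_seed(seed, paste0("dataset", r))
    ds <- do.call(generate_benchmark, args)
    id <- vapply(ds, function(p) p$pair_id, numeric(1))
    smat <- vapply(ds, function(p)
      score_pair(p$primary, p$secondary, methods, top_k, n_extreme),
      numeric(length(methods)))
    smat <- matrix(smat, nrow = length(methods),
                   dimnames = list(methods, NULL))
    for (m in methods) {
      sc <- smat[m, ]
      if (m == "cmap1") sc <- normalize_cmap1_batch(sc)
      ord <- order(-sc, id)
      for (tn in top_n_grid) {
        labeled <- label_top_n(ds, tn)
        lab <- vapply(labeled, function(p) p$label, logical(1))
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, top_n = tn, replicate = r,
          ap = average_precision(lab[ord]), stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results[c("method", "top_n")],
                                      drop = TRUE), function(d) {
    m <- mean(d$ap)
    half <- if (nrow(d) > 1L) {
      stats::qt(0.975, nrow(d) - 1L) * stats::sd(d$ap) / sqrt(nrow(d))
    } else 0
    data.frame(method = d$method[1], top_n = d$top_n[1], mean_ap = m,
               ci_lower = max(m - half, 0), ci_upper = min(m + half, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ),
            class = "benchmark_evaluation")
}

#' @export
print.benchmark_evaluation <- function(x, ...) {
  cat("Benchmark evaluation (mean average precision):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-pair correlation summary of a benchmark dataset
#'
#' Correlation between the primary and secondary lfc vectors of every pair,
#' optionally grouped into tertiles of the deregulated-gene proportion with
#' a Kruskal-Wallis test across groups.
#'
#' @param pairs a `benchmark_dataset`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `per_pair` (data.frame pair_id, true_connectivity,
#'   correlation, dereg_proportion), and, when proportions vary,
#'   `group_medians` and `kruskal` (htest).
#' @export
pair_correlation_summary <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!length(pairs)) stopf("need at least one pair")
  per <- do.call(rbind, lapply(pairs, function(p) data.frame(
    pair_id = p$pair_id, true_connectivity = p$true_connectivity,
    correlation = stats::cor(p$primary$lfc, p$secondary$lfc, method = method),
    dereg_proportion = p$dereg_proportion %||% NA_real_)))
  out <- list(per_pair = per)
  dp <- per$dereg_proportion
  if (length(unique(dp)) >= 3L && !anyNA(dp)) {
    grp <- cut(dp, stats::quantile(dp, c(0, 1 / 3, 2 / 3, 1)),
               include.lowest = TRUE, labels = c("low", "medium", "high"))
    out$group_medians <- tapply(per$correlation, grp, stats::median)
    out$kruskal <- stats::kruskal.test(per$correlation, grp)
  }
  out
}

#' Kullback-Leibler divergence between two lfc distributions
#'
#' Discrete KL divergence between histogram densities of two samples on a
#' shared equal-width binning spanning both, with additive smoothing.
#'
#' @param lfc_a,lfc_b numeric vectors.
#' @param n_bins number of bins (default 100).
#' @param smoothing additive mass per bin before renormalization.
#' @return nonnegative KL(a || b).
#' @export
lfc_kl_divergence <- function(lfc_a, lfc_b, n_bins = 100L, smoothing = 1e-9) {
  if (!length(lfc_a) || !length(lfc_b)) stopf("inputs must be nonempty")
  rng <- range(c(lfc_a, lfc_b))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  p <- tabulate(findInterval(lfc_a, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) + smoothing
  q <- tabulate(findInterval(lfc_b, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins) + smoothing
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}
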