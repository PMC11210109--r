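#' Base expression levels
#'
#' Per-gene mean expression across the two conditions (TPM-like units) and
#' gene lengths (1 for 3'RNA-Seq protocols, where counts are
#' length-independent).
#'
#' @param mu_tilde nonnegative numeric vector of mean expression levels.
#' @param lengths strictly positive gene lengths (default 1).
#' @return list of class `base_expression`.
#' @export
base_expression <- function(mu_tilde, lengths = rep(1, length(mu_tilde))) {
  if (any(!is.finite(mu_tilde)) || any(mu_tilde < 0)) {
    stopf("mu_tilde must be finite and nonnegative")
  }
  if (length(lengths) != length(mu_tilde) || any(lengths <= 0)) {
    stopf("lengths must be strictly positive and match mu_tilde")
  }
  structure(list(mu_tilde = as.numeric(mu_tilde),
                 lengths = as.numeric(lengths)),
            class = "base_expression")
}

#' Simulate base expression levels
#'
#' Draws log2-normal mean expression values emulating the skewed TPM
#' distribution of a bulk RNA-seq experiment: most genes low-expressed, a
#' long right tail of highly expressed ones.
#'
#' @param G number of genes.
#' @param log2_mean,log2_sd location and spread of log2 expression
#'   (defaults 5 and 2, i.e. a median near 32 with a realistic dynamic range).
#' @param seed optional integer seed.
#' @return a [base_expression()].
#' @export
simulate_base_expression <- function(G, log2_mean = 5, log2_sd = 2, seed = NULL) {
  mu <- with_seed(seed, 2^stats::rnorm(G, log2_mean, log2_sd))
  base_expression(mu)
}

#' Control expression from base expression and sub-modality means
#'
#' Derives the control-condition expression level from the cross-condition
#' mean and each gene's expected log2 fold-change:
#' `mu_C = 2 * mu_tilde / (1 + 2^xi)`, so that the mean of the control and
#' the expected treated level `mu_C * 2^xi` equals `mu_tilde` exactly.
#'
#' @param base a [base_expression()].
#' @param xi_per_gene per-gene mean LFC of the selected sub-modality
#'   (see [bank_xi_per_gene()]).
#' @return numeric vector of control expression levels.
#' @examples
#' control_expression(base_expression(c(100, 100)), c(0, 1))
#' @export
control_expression <- function(base, xi_per_gene) {
  if (length(xi_per_gene) != length(base$mu_tilde)) {
    stopf("xi_per_gene must match the number of genes")
  }
  2 * base$mu_tilde / (1 + 2^xi_per_gene)
}

#' Perturb control expression with multiplicative log2-scale noise
#'
#' Models biological replicate variability of the control condition by
#' multiplying each expression level by 2^eps with eps ~ Normal(0, sd).
#'
#' @param mu_control numeric vector of control expression levels.
#' @param sd standard deviation of the log2-scale noise (default 0.5).
#' @param seed optional integer seed.
#' @return perturbed nonnegative expression vector.
#' @export
perturb_control <- function(mu_control, sd = 0.5, seed = NULL) {
  if (sd < 0) stopf("sd must be nonnegative")
  if (sd == 0) return(mu_control)
  mu_control * 2^with_seed(seed, stats::rnorm(length(mu_control), 0, sd))
}

#' Read-count model parameters
#'
#' @param total_reads expected total reads per sample (library size N).
#' @param size_factor multiplier f defining the negative-binomial size
#'   r = f * Delta; the default 1/3 corresponds to a dispersion factor of
#'   Delta/3, and larger values (e.g. 0.7) push the model toward Poisson.
#' @param control_noise_sd log2-scale noise for control replicates.
#' @return list of class `count_model`.
#' @export
count_model <- function(total_reads = 1e7, size_factor = 1 / 3,
                        control_noise_sd = 0.5) {
  if (total_reads <= 0) stopf("total_reads must be positive")
  if (size_factor <= 0) stopf("size_factor must be positive")
  if (control_noise_sd < 0) stopf("control_noise_sd must be nonnegative")
  structure(list(total_reads = total_reads, size_factor = size_factor,
                 control_noise_sd = control_noise_sd), class = "count_model")
}

#' Simulate one sample's read counts
#'
#' Computes per-gene negative-binomial means
#' `Delta_i = mu_C_i * X_i * L_i / S * N` with
#' `S = sum(mu_C * X * L)`, so the expected library size is exactly N, and
#' draws counts with size `r = f * Delta` (variance `Delta + Delta / f`).
#'
#' @param mu_control control expression levels.
#' @param fold_change linear-scale fold changes (2^lfc); all ones for a
#'   control sample.
#' @param base a [base_expression()] (supplies gene lengths).
#' @param model a [count_model()].
#' @param seed optional integer seed.
#' @return list with `counts` (integer vector) and `delta` (the NB means).
#' @export
simulate_counts <- function(mu_control, fold_change, base, model = count_model(),
                            seed = NULL) {
  if (any(fold_change <= 0)) stopf("fold changes must be positive (linear scale)")
  w <- mu_control * fold_change * base$lengths
  S <- sum(w)
  if (S <= 0) stopf("all-zero expression: cannot normalize library")
  delta <- w / S * model$total_reads
  counts <- with_seed(seed, {
    k <- integer(length(delta))
    pos <- delta > 0
    k[pos] <- stats::rnbinom(sum(pos), size = model$size_factor * delta[pos],
                             mu = delta[pos])
    k
  })
  list(counts = counts, delta = delta)
}

#' Simulate replicate signatures of a parent layer set
#'
#' Experimental replicates are generated as secondary signatures of the same
#' parent with high connectivity and low noise (defaults c = 0.9,
#' gamma = 0.02) and deterministic sub-modality and probability transitions,
#' introducing mild replicate-to-replicate variability.
#'
#' @param layers parent [layer_set()].
#' @param n_replicates number of replicates (>= 1).
#' @param rep_connectivity,rep_noise connectivity and noise of the replicate
#'   transition.
#' @param bank a [build_submodality_bank()] bank.
#' @param seed optional integer seed.
#' @return list of `n_replicates` lists, each with `layers` and `signature`.
#' @export
simulate_replicate_layers <- function(layers, n_replicates, rep_connectivity = 0.9,
                                      rep_noise = 0.02, bank, seed = NULL) {
  if (n_replicates < 1L) stopf("n_replicates must be >= 1")
  lapply(seq_len(n_replicates), function(r) {
    simulate_secondary(layers, connectivity_model(rep_connectivity, rep_noise),
                       bank,
                       submod_transition_config("deterministic"),
                       prob_transition_config("deterministic"),
                       seed = if (is.null(seed)) NULL else
                         stage_seed(seed, paste0("replicate", r)))
  })
}

#' Simulate a treated-vs-control count experiment from a signature
#'
#' Full pipeline for one signature: replicate signatures of the parent
#' layers, control expression from the base expression and the per-gene
#' sub-modality means, perturbed control replicates, and negative-binomial
#' counts for every sample.
#'
#' @param layers parent [layer_set()] of the treatment signature.
#' @param bank a [build_submodality_bank()] bank.
#' @param base a [base_expression()].
#' @param n_replicates replicates per condition (default 3).
#' @param model a [count_model()].
#' @param rep_connectivity,rep_noise replicate-transition parameters.
#' @param seed optional integer seed.
#' @return list of class `count_matrix`: `counts` (G x 2n integer matrix),
#'   `condition` (factor treated/control), `replicate` (integer),
#'   `gene_ids`, and `replicate_lfc` (G x n matrix of the replicate
#'   signatures actually used for the treated samples).
#' @export
simulate_count_experiment <- function(layers, bank, base, n_replicates = 3,
                                      model = count_model(),
                                      rep_connectivity = 0.9, rep_noise = 0.02,
                                      seed = NULL) {
  G <- length(layers$modality)
  if (length(base$mu_tilde) != G) stopf("base expression must match gene count")
  xi <- bank_xi_per_gene(layers, bank, 1L)
  mu_c <- control_expression(base, xi)
  reps <- simulate_replicate_layers(layers, n_replicates, rep_connectivity,
                                    rep_noise, bank,
                                    seed = if (is.null(seed)) NULL else
                                      stage_seed(seed, "replicates"))
  rep_lfc <- vapply(reps, function(r) r$signature$lfc, numeric(G))
  counts <- matrix(0L, nrow = G, ncol = 2L * n_replicates)
  for (r in seq_len(n_replicates)) {
    counts[, r] <- simulate_counts(
      mu_c, 2^rep_lfc[, r], base, model,
      seed = if (is.null(seed)) NULL else stage_seed(seed, paste0("trt", r)))$counts
    mu_ctrl_r <- perturb_control(mu_c, model$control_noise_sd,
                                 seed = if (is.null(seed)) NULL else
                                   stage_seed(seed, paste0("ctlnoise", r)))
    counts[, n_replicates + r] <- simulate_counts(
      mu_ctrl_r, rep(1, G), base, model,
      seed = if (is.null(seed)) NULL else stage_seed(seed, paste0("ctl", r)))$counts
  }
  colnames(counts) <- c(sprintf("treated_%d", seq_len(n_replicates)),
                        sprintf("control_%d", seq_len(n_replicates)))
  structure(list(counts = counts,
                 condition = factor(rep(c("treated", "control"),
                                        each = n_replicates),
                                    levels = c("control", "treated")),
                 replicate = rep(seq_len(n_replicates), 2L),
                 gene_ids = layers$gene_ids,
                 replicate_lfc = rep_lfc),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over genes with nonzero
#' counts in every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts integer matrix (genes x samples) or a `count_matrix`.
#' @return numeric vector of size factors, one per sample.
#' @export
median_of_ratios_size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) stopf("no gene has nonzero counts in all samples")
  sub <- counts[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(col) stats::median(col / geo))
}

#' Negative-binomial Wald differential expression test
#'
#' A simplified two-group NB Wald analysis on a simulated count matrix:
#' median-of-ratios normalization, log2 ratio of normalized condition means
#' (zero means replaced by a 0.5 pseudocount), per-gene NB dispersion by
#' method of moments on the pooled within-group variance (floored at 1e-8),
#' a delta-method standard error, two-sided normal p-values and
#' Benjamini-Hochberg adjustment.
#'
#' @param cm a `count_matrix` (see [simulate_count_experiment()]) or a list
#'   with `counts`, `condition` and `gene_ids`.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `lfc_hat`, `se`, `wald_stat`, `pvalue`, `padj`.
#' @export
nb_wald_de <- function(cm) {
  counts <- cm$counts
  cond <- cm$condition
  trt <- which(cond == "treated"); ctl <- which(cond == "control")
  if (length(trt) < 2L || length(ctl) < 2L) {
    stopf("need at least 2 replicates per condition")
  }
  sf <- median_of_ratios_size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  mT <- rowMeans(norm[, trt, drop = FALSE])
  mC <- rowMeans(norm[, ctl, drop = FALSE])
  vT <- apply(norm[, trt, drop = FALSE], 1L, stats::var)
  vC <- apply(norm[, ctl, drop = FALSE], 1L, stats::var)
  # method-of-moments NB dispersion with a mean-proportional trend: per-gene
  # moment estimates are far too noisy at 2-3 replicates, so the excess
  # variance ratio (var - mu)/mu is pooled across genes (median) and mapped
  # back to alpha = phi / mu, matching a size r = f * Delta count model
  nT <- length(trt); nC <- length(ctl)
  pooled_var <- ((nT - 1) * vT + (nC - 1) * vC) / (nT + nC - 2)
  pooled_mean <- (mT + mC) / 2
  phi <- (pooled_var - pooled_mean) / pmax(pooled_mean, 1e-8)
  phi_pos <- phi[phi > 0 & pooled_mean > 0]
  alpha <- if (length(phi_pos) >= 10L) {
    pmax(mean(phi_pos) / pmax(pooled_mean, 1e-8), 1e-8)
  } else {
    pmax((pooled_var - pooled_mean) / pmax(pooled_mean^2, 1e-8), 1e-8)
  }
  mT_ <- ifelse(mT > 0, mT, 0.5)
  mC_ <- ifelse(mC > 0, mC, 0.5)
  lfc_hat <- log2(mT_ / mC_)
  var_mT <- (mT_ + alpha * mT_^2) / nT
  var_mC <- (mC_ + alpha * mC_^2) / nC
  se <- sqrt(var_mT / mT_^2 + var_mC / mC_^2) / log(2)
  wald <- lfc_hat / se
  p <- 2 * stats::pnorm(-abs(wald))
  structure(data.frame(gene_id = cm$gene_ids, lfc_hat = lfc_hat, se = se,
                       wald_stat = wald, pvalue = p,
                       padj = stats::p.adjust(p, method = "BH"),
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}
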