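#' Detect modes of a log2 fold-change distribution
#'
#' Gaussian-kernel density estimate on a fixed grid; modes are strict local
#' maxima whose height exceeds a relative floor. Diagnostic companion to
#' [fit_bank_from_lfc()].
#'
#' @param lfc numeric vector (length >= 100).
#' @param bandwidth kernel bandwidth, or `"nrd0"` for the usual automatic
#'   rule.
#' @param rel_floor minimum mode height relative to the global maximum.
#' @return list of class `mode_estimate` with `locations` (ascending) and
#'   `densities`.
#' @export
detect_lfc_modes <- function(lfc, bandwidth = "nrd0", rel_floor = 0.05) {
  lfc <- lfc[is.finite(lfc)]
  if (length(lfc) < 100L) stopf("need at least 100 finite values")
  d <- stats::density(lfc, bw = bandwidth, n = 512L)
  y <- d$y
  is_max <- c(FALSE, y[2:511] > y[1:510] & y[2:511] > y[3:512], FALSE)
  is_max <- is_max & y > rel_floor * max(y)
  structure(list(locations = d$x[is_max], densities = y[is_max]),
            class = "mode_estimate")
}

#' @export
print.mode_estimate <- function(x, ...) {
  cat(sprintf("%d mode(s) at: %s\n", length(x$locations),
              paste(signif(x$locations, 3), collapse = ", ")))
  invisible(x)
}

# Weighted method-of-moments gamma parameters from a sample.
gamma_mom <- function(x, w = rep(1, length(x))) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  v <- max(v, 1e-12)
  list(shape = m^2 / v, scale = v / m)
}

# EM fit of a K-component gamma mixture on positive data, initialized from
# equal-occupancy quantile bands; M-step by weighted method of moments.
gamma_mixture_em <- function(x, K, max_iter = 200L, tol = 1e-8) {
  qs <- stats::quantile(x, seq(0, 1, length.out = K + 1L))
  band <- cut(x, unique(qs), include.lowest = TRUE)
  comp <- lapply(split(x, band), gamma_mom)
  if (length(comp) < K) comp <- rep(comp, length.out = K)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      pi_k[k] * stats::dgamma(x, shape = comp[[k]]$shape,
                              scale = comp[[k]]$scale), numeric(length(x)))
    tot <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(tot))
    resp <- dens / tot
    pi_k <- colMeans(resp)
    comp <- lapply(seq_len(K), function(k) gamma_mom(x, resp[, k]))
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(vapply(comp, function(cp) cp$shape * cp$scale, numeric(1)))
  list(proportions = pi_k[ord], components = comp[ord])
}

#' Fit modality proportions and a sub-modality bank from an lfc vector
#'
#' Decomposes an observed log2 fold-change distribution into simulation
#' parameters: modality proportions from the deregulation threshold, a
#' Gaussian fitted to the central (non-deregulated) mass, and per tail a
#' gamma mixture with `n_sub` components fitted by EM on |lfc| (weighted
#' method-of-moments M-step, quantile-band initialization); component
#' weights give the sub-modality proportions and the down-regulated
#' components carry negative sign.
#'
#' @param lfc numeric vector of log2 fold-changes.
#' @param n_sub_up,n_sub_down number of sub-modalities per tail.
#' @param dereg_threshold |lfc| cut separating deregulated tails
#'   (default 0.5).
#' @return list with `omega` (a [modality_distribution()]) and `bank` (a
#'   `submodality_bank`).
#' @export
fit_bank_from_lfc <- function(lfc, n_sub_up = 3L, n_sub_down = 3L,
                              dereg_threshold = 0.5) {
  lfc <- lfc[is.finite(lfc)]
  up <- lfc[lfc > dereg_threshold]
  down <- -lfc[lfc < -dereg_threshold]
  mid <- lfc[abs(lfc) <= dereg_threshold]
  if (length(up) < 20L * n_sub_up || length(down) < 20L * n_sub_down) {
    stopf("insufficient deregulated mass beyond |lfc| > %.3g", dereg_threshold)
  }
  G <- length(lfc)
  omega <- modality_distribution(c(length(up), length(mid), length(down)) / G)
  gauss <- list(list(family = "gaussian",
                     params = list(mean = mean(mid), sd = stats::sd(mid)),
                     proportion = 1))
  tail_cfg <- function(x, K) {
    fit <- gamma_mixture_em(x, K)
    lapply(seq_len(K), function(k) list(
      family = "gamma",
      params = list(shape = fit$components[[k]]$shape,
                    scale = fit$components[[k]]$scale),
      proportion = fit$proportions[k]))
  }
  bank <- build_submodality_bank(list(up = tail_cfg(up, n_sub_up),
                                      null = gauss,
                                      down = tail_cfg(down, n_sub_down)))
  list(omega = omega, bank = bank)
}
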