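#' Modality proportions of a signature
#'
#' The first layer of the signature model assigns every gene one of three
#' modalities: up-regulated (1), non-deregulated (2) or down-regulated (3).
#' `modality_distribution()` validates the three proportions
#' (omega_up, omega_null, omega_down).
#'
#' @param omega numeric vector of length 3 summing to 1: probabilities of the
#'   up, non-deregulated and down modalities.
#' @return a numeric vector of class `modality_distribution`.
#' @examples
#' modality_distribution(c(0.07, 0.80, 0.13))
#' @export
modality_distribution <- function(omega) {
  if (length(omega) != 3L) stopf("omega must have length 3")
  if (any(!is.finite(omega)) || any(omega < 0) || any(omega > 1)) {
    stopf("omega entries must lie in [0, 1]")
  }
  if (abs(sum(omega) - 1) > 1e-12) {
    stopf("omega must sum to 1 (got %.15g)", sum(omega))
  }
  structure(as.numeric(omega), names = c("up", "null", "down"),
            class = "modality_distribution")
}

# -- sub-modality distribution descriptors ------------------------------------

# A descriptor is list(family = "gamma"|"gaussian", params, sign). The base
# quantile function is nondecreasing; `sign` is applied afterwards, so that
# down-regulated amplitudes are negated gamma quantiles (mirror image of the
# up-regulated ones).
submodality_dist <- function(family, params, sign = 1) {
  family <- match.arg(family, c("gamma", "gaussian"))
  if (!sign %in% c(-1, 1)) stopf("sign must be -1 or +1")
  if (family == "gamma") {
    if (is.null(params$shape) || is.null(params$scale)) {
      stopf("gamma descriptor needs shape and scale")
    }
    if (params$shape <= 0 || params$scale <= 0) {
      stopf("gamma shape and scale must be positive")
    }
    xi <- sign * params$shape * params$scale
  } else {
    if (is.null(params$mean) || is.null(params$sd)) {
      stopf("gaussian descriptor needs mean and sd")
    }
    if (params$sd < 0) stopf("gaussian sd must be nonnegative")
    xi <- params$mean
    sign <- 1
  }
  list(family = family, params = params, sign = sign, xi = xi)
}

dist_quantile <- function(dist, p) {
  if (dist$family == "gamma") {
    dist$sign * stats::qgamma(p, shape = dist$params$shape,
                              scale = dist$params$scale)
  } else {
    stats::qnorm(p, mean = dist$params$mean, sd = dist$params$sd)
  }
}

# -- bank construction --------------------------------------------------------

validate_bank_side <- function(side, m) {
  n <- length(side$dists)
  if (n < 1L) stopf("modality %d needs at least one sub-modality", m)
  if (length(side$proportions) != n) {
    stopf("modality %d: proportions and distributions disagree in length", m)
  }
  check_prob_vector(side$proportions, sprintf("modality %d proportions", m))
  xi <- vapply(side$dists, function(d) d$xi, numeric(1))
  if (m == 1L && any(xi < 0)) stopf("up-regulated sub-modalities must have xi >= 0")
  if (m == 3L && any(xi > 0)) stopf("down-regulated sub-modalities must have xi <= 0")
  if (n > 1L && any(diff(abs(xi)) <= 0)) {
    stopf("modality %d sub-modalities must be ordered by strictly increasing |xi|", m)
  }
  side$xi <- xi
  side
}

build_bank_config_side <- function(cfg, m) {
  sgn <- if (m == 3L) -1 else 1
  dists <- lapply(cfg, function(entry) {
    fam <- entry$family
    if (fam %in% c("gaussian", "normal")) {
      submodality_dist("gaussian", list(mean = entry$params$mean %||% 0,
                                        sd = entry$params$sd))
    } else if (fam == "gamma") {
      submodality_dist("gamma", list(shape = entry$params$shape,
                                     scale = entry$params$scale), sign = sgn)
    } else stopf("unknown distribution family '%s'", fam)
  })
  props <- vapply(cfg, function(entry) entry$proportion, numeric(1))
  validate_bank_side(list(proportions = props, dists = dists), m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a sub-modality bank from a configuration
#'
#' The bank stores, per signature index (primary = 1, secondary = 2) and per
#' modality, the sub-modality proportions, their amplitude distributions
#' (quantile functions) and the mean log2 fold-change `xi` of each
#' sub-modality. `xi` is computed analytically from the distribution
#' (gamma: sign * shape * scale; gaussian: mean). Within a modality the
#' sub-modality ranks are ordered by strictly increasing |xi|.
#'
#' @param config a list with entries `up`, `null` and `down`, each a list of
#'   sub-modality descriptors `list(family, params, proportion)` where
#'   `family` is `"gamma"` (deregulated amplitudes; `params$shape`,
#'   `params$scale`) or `"gaussian"` (`params$mean`, `params$sd`).
#'   Alternatively a list with entries `primary` and `secondary`, each of the
#'   above form, when the two signatures use different banks.
#' @return an object of class `submodality_bank`.
#' @examples
#' cfg <- list(
#'   up   = list(list(family = "gamma", params = list(shape = 4, scale = 0.5),
#'               proportion = 1)),
#'   null = list(list(family = "gaussian", params = list(mean = 0, sd = 0.1),
#'               proportion = 1)),
#'   down = list(list(family = "gamma", params = list(shape = 4, scale = 0.5),
#'               proportion = 1)))
#' build_submodality_bank(cfg)
#' @export
build_submodality_bank <- function(config) {
  if (!is.null(config$primary)) {
    sides <- list(config$primary, config$secondary %||% config$primary)
  } else {
    sides <- list(config, config)
  }
  sig <- lapply(sides, function(cf) {
    if (is.null(cf$up) || is.null(cf$null) || is.null(cf$down)) {
      stopf("bank configuration needs 'up', 'null' and 'down' entries")
    }
    list(build_bank_config_side(cf$up, 1L),
         build_bank_config_side(cf$null, 2L),
         build_bank_config_side(cf$down, 3L))
  })
  structure(list(sig = sig), class = "submodality_bank")
}

#' @export
print.submodality_bank <- function(x, ...) {
  cat("Sub-modality bank\n")
  lab <- c("up", "null", "down")
  for (j in 1:2) {
    cat(sprintf("  signature %d:\n", j))
    for (m in 1:3) {
      side <- x$sig[[j]][[m]]
      cat(sprintf("    %-4s N=%d  xi = %s  phi = %s\n", lab[m],
                  length(side$dists),
                  paste(signif(side$xi, 3), collapse = ", "),
                  paste(signif(side$proportions, 3), collapse = ", ")))
    }
    if (identical(x$sig[[1]], x$sig[[2]])) { cat("  (secondary identical)\n"); break }
  }
  invisible(x)
}

bank_side <- function(bank, j, m) bank$sig[[j]][[m]]

bank_counts <- function(bank, j) {
  vapply(bank$sig[[j]], function(s) length(s$dists), integer(1))
}

#' Mean log2 fold-change of each gene's sub-modality
#'
#' Looks up, for every gene, the analytic mean `xi` of the amplitude
#' distribution selected by its (modality, sub-modality) pair. Used by the
#' read-count pipeline to derive control expression levels.
#'
#' @param layers a [layer_set()].
#' @param bank a [build_submodality_bank()] bank.
#' @param j signature index (1 primary, 2 secondary).
#' @return numeric vector of per-gene mean LFCs (log2 units).
#' @export
bank_xi_per_gene <- function(layers, bank, j = 1L) {
  xi <- numeric(length(layers$modality))
  for (m in 1:3) {
    sel <- layers$modality == m
    if (any(sel)) xi[sel] <- bank_side(bank, j, m)$xi[layers$submodality[sel]]
  }
  xi
}

#' Default realistic sub-modality bank
#'
#' A documented default standing in for a bank fitted from real data: a
#' centred Gaussian (sd 0.1) non-deregulated mode and three gamma
#' sub-modalities per deregulated tail with mean |LFC| amplitudes 0.8, 1.6
#' and 3.0 and geometrically decaying proportions (4:2:1), identical for the
#' primary and secondary signatures. Shapes are chosen so that deregulated
#' |LFC| values fall mostly in [0.5, 5].
#'
#' @return a `submodality_bank`.
#' @examples
#' default_realistic_bank()
#' @export
default_realistic_bank <- function() {
  tail_cfg <- list(
    list(family = "gamma", params = list(shape = 16, scale = 0.05), proportion = 4 / 7),
    list(family = "gamma", params = list(shape = 16, scale = 0.10), proportion = 2 / 7),
    list(family = "gamma", params = list(shape = 9,  scale = 1 / 3), proportion = 1 / 7))
  build_submodality_bank(list(
    up   = tail_cfg,
    null = list(list(family = "gaussian", params = list(mean = 0, sd = 0.1),
                     proportion = 1)),
    down = tail_cfg))
}
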