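#' Connectivity model parameters
#'
#' Validates the two parameters of the symmetric modality-transition model:
#' the connectivity score `c` in [-1, 1] and the non-deregulated noise
#' factor `gamma` in [0, 0.5].
#'
#' @param c connectivity score.
#' @param gamma noise factor: probability mass routed through the
#'   non-deregulated state during the modality transition.
#' @return a list of class `connectivity_model`.
#' @export
connectivity_model <- function(c, gamma = 0.02) {
  if (!is.finite(c) || c < -1 || c > 1) stopf("c must lie in [-1, 1]")
  if (!is.finite(gamma) || gamma < 0 || gamma > 0.5) {
    stopf("gamma must lie in [0, 0.5]")
  }
  structure(list(c = c, gamma = gamma), class = "connectivity_model")
}

#' Symmetric modality transition matrix
#'
#' Builds the 3x3 row-stochastic matrix Lambda of conditional probabilities
#' P(secondary modality = beta | primary modality = alpha) under the
#' symmetric connectivity model:
#' lambda_11 = lambda_33 = (1 + c)(1 - gamma/2)/2,
#' lambda_13 = lambda_31 = (1 - c)(1 - gamma/2)/2,
#' lambda_12 = lambda_21 = lambda_32 = lambda_23 = gamma/2,
#' lambda_22 = 1 - gamma. Rows sum to 1 by algebraic identity.
#'
#' @param model a [connectivity_model()] (or a list with `c` and `gamma`).
#' @return a 3x3 matrix of class `transition_matrix` (rows: primary modality;
#'   columns: secondary modality).
#' @examples
#' symmetric_transition_matrix(connectivity_model(0.5, 0.02))
#' @export
symmetric_transition_matrix <- function(model) {
  model <- connectivity_model(model$c, model$gamma)
  c <- model$c; g <- model$gamma
  keep <- 0.5 * (1 + c) * (1 - g / 2)
  flip <- 0.5 * (1 - c) * (1 - g / 2)
  L <- matrix(c(keep, g / 2, flip,
                g / 2, 1 - g, g / 2,
                flip, g / 2, keep),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("from", 1:3), paste0("to", 1:3)))
  structure(L, class = c("transition_matrix", "matrix"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  print(matrix(x, 3, 3, dimnames = dimnames(x)), ...)
  invisible(x)
}

#' Validate a modality transition matrix
#'
#' Accepts a user-supplied 3x3 matrix in place of the parametric model.
#'
#' @param lambda 3x3 numeric matrix with entries in [0, 1], rows summing to 1.
#' @return the matrix with class `transition_matrix`.
#' @export
transition_matrix <- function(lambda) {
  lambda <- as.matrix(unclass(lambda))
  if (!all(dim(lambda) == c(3L, 3L))) stopf("transition matrix must be 3x3")
  if (any(!is.finite(lambda)) || any(lambda < 0) || any(lambda > 1)) {
    stopf("transition matrix entries must lie in [0, 1]")
  }
  if (any(abs(rowSums(lambda) - 1) > 1e-12)) {
    stopf("transition matrix rows must sum to 1")
  }
  structure(lambda, class = c("transition_matrix", "matrix"))
}

#' Sample secondary modalities from a transition matrix
#'
#' Each gene's secondary modality is drawn independently from the row of the
#' transition matrix indexed by its primary modality.
#'
#' @param primary_modality integer vector in {1, 2, 3}.
#' @param matrix a [transition_matrix()] (validated on entry).
#' @param seed optional integer seed.
#' @return integer vector of secondary modalities.
#' @export
transition_modalities <- function(primary_modality, matrix, seed = NULL) {
  L <- transition_matrix(matrix)
  if (any(!primary_modality %in% 1:3)) stopf("primary modalities must be in {1, 2, 3}")
  cum <- t(apply(L, 1L, cumsum))
  with_seed(seed, {
    u <- stats::runif(length(primary_modality))
    c1 <- cum[primary_modality, 1L]
    c2 <- cum[primary_modality, 2L]
    as.integer(1L + (u > c1) + (u > c2))
  })
}

#' Sub-modality transition configuration
#'
#' @param strategy one of `"independent"`, `"deterministic"`, `"stochastic"`,
#'   `"copula"`.
#' @param copula_family for the copula strategy: `"frank"`, `"plackett"` or
#'   `"gauss"`.
#' @param target_correlation for the copula strategy: desired Pearson
#'   correlation between the primary and secondary sub-modality ranks.
#' @return a list of class `submod_transition_config`.
#' @export
submod_transition_config <- function(strategy = c("deterministic", "independent",
                                                  "stochastic", "copula"),
                                     copula_family = NULL,
                                     target_correlation = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "copula") {
    if (is.null(copula_family) || is.null(target_correlation)) {
      stopf("copula strategy requires copula_family and target_correlation")
    }
    copula_family <- match.arg(copula_family, copula_families)
  }
  structure(list(strategy = strategy, copula_family = copula_family,
                 target_correlation = target_correlation),
            class = "submod_transition_config")
}

#' Probability transition configuration
#'
#' @param strategy one of `"independent"`, `"deterministic"`, `"copula"`.
#' @inheritParams submod_transition_config
#' @return a list of class `prob_transition_config`.
#' @export
prob_transition_config <- function(strategy = c("deterministic", "independent",
                                                "copula"),
                                   copula_family = NULL,
                                   target_correlation = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "copula") {
    if (is.null(copula_family) || is.null(target_correlation)) {
      stopf("copula strategy requires copula_family and target_correlation")
    }
    copula_family <- match.arg(copula_family, copula_families)
  }
  structure(list(strategy = strategy, copula_family = copula_family,
                 target_correlation = target_correlation),
            class = "prob_transition_config")
}

#' Transition the sub-modality layer
#'
#' Genes that are non-deregulated in either signature (primary modality 2 or
#' secondary modality 2) always draw the secondary sub-modality
#' independently from the secondary bank's proportions. For genes
#' deregulated in both signatures the configured strategy applies:
#' independent draw, deterministic copy (requires equal sub-modality counts),
#' a Binomial(N, tau/N) draw clamped into [1, N], or a draw from the
#' conditional row of a fitted discrete copula joint.
#'
#' @param primary a [layer_set()] (primary signature).
#' @param secondary_modality integer vector of secondary modalities.
#' @param bank a [build_submodality_bank()] bank.
#' @param config a [submod_transition_config()].
#' @param seed optional integer seed.
#' @return integer vector of secondary sub-modality ranks.
#' @export
transition_submodalities <- function(primary, secondary_modality, bank,
                                     config = submod_transition_config(),
                                     seed = NULL) {
  G <- length(primary$modality)
  alpha <- primary$modality; beta <- as.integer(secondary_modality)
  if (length(beta) != G) stopf("secondary modality length mismatch")
  out <- integer(G)
  with_seed(seed, {
    indep <- alpha == 2L | beta == 2L
    if (config$strategy == "independent") indep <- rep(TRUE, G)
    if (any(indep)) {
      out[indep] <- draw_submodalities(beta[indep], bank, 2L)
    }
    both <- which(!indep)
    if (length(both)) {
      n1 <- bank_counts(bank, 1L); n2 <- bank_counts(bank, 2L)
      if (config$strategy %in% c("deterministic", "stochastic")) {
        pairs <- unique(cbind(alpha[both], beta[both]))
        if (any(n1[pairs[, 1]] != n2[pairs[, 2]])) {
          stopf("%s transition requires equal sub-modality counts", config$strategy)
        }
      }
      tau <- primary$submodality[both]
      if (config$strategy == "deterministic") {
        out[both] <- tau
      } else if (config$strategy == "stochastic") {
        n <- n1[alpha[both]]
        out[both] <- pmin(pmax(stats::rbinom(length(both), n, tau / n), 1L), n)
      } else { # copula
        for (a in c(1L, 3L)) for (b in c(1L, 3L)) {
          sel <- both[alpha[both] == a & beta[both] == b]
          if (!length(sel)) next
          fit <- fit_discrete_copula(bank_side(bank, 1L, a)$proportions,
                                     bank_side(bank, 2L, b)$proportions,
                                     config$copula_family,
                                     config$target_correlation)
          cond <- fit$conditional
          tt <- primary$submodality[sel]
          for (s in unique(tt)) {
            idx <- sel[tt == s]
            out[idx] <- sample.int(ncol(cond), length(idx), replace = TRUE,
                                   prob = cond[s, ])
          }
        }
      }
    }
  })
  out
}

#' Transition the probability layer
#'
#' Independent: fresh uniforms. Deterministic: identical copy. Copula:
#' element-wise conditional sampling under a copula whose parameter is
#' calibrated so the Pearson correlation of the two uniform layers equals
#' the configured target.
#'
#' @param primary_probability numeric vector in [0, 1].
#' @param config a [prob_transition_config()].
#' @param seed optional integer seed.
#' @return numeric vector in [0, 1].
#' @export
transition_probabilities <- function(primary_probability,
                                     config = prob_transition_config(),
                                     seed = NULL) {
  if (any(primary_probability < 0 | primary_probability > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  switch(config$strategy,
    deterministic = primary_probability,
    independent = with_seed(seed, stats::runif(length(primary_probability))),
    copula = {
      theta <- copula_theta_for_uniform_corr(config$copula_family,
                                             config$target_correlation)
      copula_conditional_sample(primary_probability, config$copula_family,
                                theta, seed = seed)
    })
}

#' Simulate a secondary signature connected to a primary one
#'
#' Applies the modality, sub-modality and probability transitions in order
#' and composes the secondary log2 fold-change vector with the secondary
#' bank.
#'
#' @param primary a [layer_set()].
#' @param model a [connectivity_model()] (c, gamma) or a full 3x3
#'   [transition_matrix()].
#' @param bank a [build_submodality_bank()] bank.
#' @param sub_config a [submod_transition_config()].
#' @param prob_config a [prob_transition_config()].
#' @param seed optional integer seed.
#' @return list with `layers` (secondary `layer_set`) and `signature`
#'   (data.frame `gene_id`, `lfc`).
#' @examples
#' bank <- default_realistic_bank()
#' pri <- sample_primary_layers(c(0.07, 0.8, 0.13), bank, 1000, seed = 1)
#' sec <- simulate_secondary(pri, connectivity_model(0.8, 0.02), bank, seed = 2)
#' cor(compose_lfc(pri, bank)$lfc, sec$signature$lfc)
#' @export
simulate_secondary <- function(primary, model, bank,
                               sub_config = submod_transition_config(),
                               prob_config = prob_transition_config(),
                               seed = NULL) {
  L <- if (inherits(model, "connectivity_model") ||
           (is.list(model) && !is.matrix(model))) {
    symmetric_transition_matrix(model)
  } else {
    transition_matrix(model)
  }
  sd1 <- if (is.null(seed)) NULL else stage_seed(seed, "modality2")
  sd2 <- if (is.null(seed)) NULL else stage_seed(seed, "submodality2")
  sd3 <- if (is.null(seed)) NULL else stage_seed(seed, "probability2")
  beta <- transition_modalities(primary$modality, L, seed = sd1)
  upsilon <- transition_submodalities(primary, beta, bank, sub_config, seed = sd2)
  rho <- transition_probabilities(primary$probability, prob_config, seed = sd3)
  layers <- layer_set(beta, upsilon, rho, gene_ids = primary$gene_ids)
  list(layers = layers, signature = compose_lfc(layers, bank, 2L))
}
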