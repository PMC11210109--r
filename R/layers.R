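#' Three-layer representation of one signature
#'
#' Bundles the per-gene modality (1 up, 2 non-deregulated, 3 down),
#' sub-modality rank and probability value that jointly encode a
#' differential expression signature.
#'
#' @param modality integer vector with values in {1, 2, 3}.
#' @param submodality integer vector of sub-modality ranks.
#' @param probability numeric vector in [0, 1].
#' @param gene_ids optional character vector of gene identifiers.
#' @return an object of class `layer_set`.
#' @export
layer_set <- function(modality, submodality, probability, gene_ids = NULL) {
  G <- length(modality)
  if (G < 1L) stopf("layer set needs at least one gene")
  if (length(submodality) != G || length(probability) != G) {
    stopf("modality, submodality and probability must share length")
  }
  if (any(!modality %in% 1:3)) stopf("modality values must be in {1, 2, 3}")
  if (any(submodality < 1L)) stopf("submodality ranks must be >= 1")
  if (any(probability < 0 | probability > 1)) {
    stopf("probability values must lie in [0, 1]")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(G))
  structure(list(modality = as.integer(modality),
                 submodality = as.integer(submodality),
                 probability = as.numeric(probability),
                 gene_ids = as.character(gene_ids)),
            class = "layer_set")
}

#' @export
print.layer_set <- function(x, ...) {
  tab <- tabulate(x$modality, 3L)
  cat(sprintf("Layer set: %d genes (up %d / null %d / down %d)\n",
              length(x$modality), tab[1], tab[2], tab[3]))
  invisible(x)
}

check_layers_vs_bank <- function(layers, bank, j) {
  counts <- bank_counts(bank, j)
  if (any(layers$submodality > counts[layers$modality])) {
    stopf("sub-modality rank exceeds the bank's count for its modality")
  }
  invisible(TRUE)
}

# Vectorized draw of sub-modality ranks given each gene's modality.
draw_submodalities <- function(modality, bank, j) {
  out <- integer(length(modality))
  for (m in 1:3) {
    sel <- which(modality == m)
    if (length(sel)) {
      phi <- bank_side(bank, j, m)$proportions
      out[sel] <- sample.int(length(phi), length(sel), replace = TRUE, prob = phi)
    }
  }
  out
}

#' Sample the three layers of a primary signature
#'
#' Modalities are sampled i.i.d. from the omega proportions, sub-modalities
#' from the bank's per-modality proportions conditional on each gene's
#' modality, and probabilities i.i.d. uniform on [0, 1]. Each stage consumes
#' an independent child stream derived from `seed`, so the same seed always
#' reproduces the same layers.
#'
#' @param omega a [modality_distribution()] (or a valid length-3 vector).
#' @param bank a [build_submodality_bank()] bank.
#' @param G number of genes.
#' @param seed integer seed (optional).
#' @return a [layer_set()].
#' @examples
#' lay <- sample_primary_layers(modality_distribution(c(0.07, 0.8, 0.13)),
#'                              default_realistic_bank(), 1000, seed = 1)
#' table(lay$modality)
#' @export
sample_primary_layers <- function(omega, bank, G, seed = NULL) {
  omega <- modality_distribution(unclass(omega))
  if (G < 1L) stopf("G must be >= 1")
  modality <- with_seed(if (is.null(seed)) NULL else stage_seed(seed, "modality"),
                        sample.int(3L, G, replace = TRUE, prob = omega))
  submod <- with_seed(if (is.null(seed)) NULL else stage_seed(seed, "submodality"),
                      draw_submodalities(modality, bank, 1L))
  prob <- with_seed(if (is.null(seed)) NULL else stage_seed(seed, "probability"),
                    stats::runif(G))
  layer_set(modality, submod, prob)
}

#' Compose log2 fold-changes from a layer set
#'
#' Maps each gene's probability through the quantile function selected by its
#' (modality, sub-modality) pair: `lfc[i] = Q_{s|m}(p[i])`. Deterministic
#' given the layers and the bank. Up-regulated genes yield lfc >= 0 and
#' down-regulated genes lfc <= 0 (negated gamma quantiles).
#'
#' @param layers a [layer_set()].
#' @param bank a [build_submodality_bank()] bank.
#' @param j signature index of the bank to use (1 primary, 2 secondary).
#' @return a data.frame with columns `gene_id` and `lfc` (log2 units).
#' @examples
#' lay <- sample_primary_layers(c(0.1, 0.8, 0.1), default_realistic_bank(),
#'                              100, seed = 1)
#' head(compose_lfc(lay, default_realistic_bank()))
#' @export
compose_lfc <- function(layers, bank, j = 1L) {
  check_layers_vs_bank(layers, bank, j)
  lfc <- numeric(length(layers$modality))
  for (m in 1:3) {
    side <- bank_side(bank, j, m)
    for (s in seq_along(side$dists)) {
      sel <- layers$modality == m & layers$submodality == s
      if (any(sel)) lfc[sel] <- dist_quantile(side$dists[[s]], layers$probability[sel])
    }
  }
  data.frame(gene_id = layers$gene_ids, lfc = lfc, stringsAsFactors = FALSE)
}

#' Simulate an independent primary signature
#'
#' Convenience wrapper: samples primary layers and composes the LFC vector.
#'
#' @inheritParams sample_primary_layers
#' @return a list with elements `layers` (a `layer_set`) and `signature`
#'   (data.frame `gene_id`, `lfc`).
#' @export
simulate_primary <- function(omega, bank, G, seed = NULL) {
  layers <- sample_primary_layers(omega, bank, G, seed)
  list(layers = layers, signature = compose_lfc(layers, bank, 1L))
}
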