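#' Read a signature table
#'
#' Reads a tab-separated signature file with a header; columns `gene_id` and
#' `lfc` are required, `pvalue` and `padj` optional. Malformed rows are
#' reported with their line numbers.
#'
#' @param path file path.
#' @return data.frame with the validated columns.
#' @export
read_signature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "lfc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$lfc))))
  if (length(bad)) {
    stopf("non-numeric or missing lfc at line(s): %s",
          paste(bad + 1L, collapse = ", ")) # +1 for the header line
  }
  df$lfc <- as.numeric(df$lfc)
  for (col in c("pvalue", "padj")) {
    if (col %in% names(df)) {
      v <- as.numeric(df[[col]])
      if (any(!is.finite(v) | v < 0 | v > 1)) {
        stopf("%s values must lie in [0, 1]", col)
      }
      df[[col]] <- v
    }
  }
  df
}

#' Write a signature table
#'
#' @param signature data.frame with `gene_id`, `lfc` and optional
#'   `pvalue`/`padj` columns.
#' @param path output path (TSV with header).
#' @export
write_signature_table <- function(signature, path) {
  utils::write.table(signature, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a count matrix with its sample sheet
#'
#' @param cm a `count_matrix` (see [simulate_count_experiment()]).
#' @param counts_path TSV output: first column `gene_id`, then one column
#'   per sample.
#' @param samples_path companion sample sheet TSV (`sample_id`, `condition`,
#'   `replicate`).
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss <- data.frame(sample_id = colnames(cm$counts),
                   condition = as.character(cm$condition),
                   replicate = cm$replicate)
  utils::write.table(ss, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read a count matrix and its sample sheet
#'
#' @param counts_path,samples_path files written by [write_count_matrix()].
#' @return a list of class `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  ss <- utils::read.delim(samples_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 condition = factor(ss$condition,
                                    levels = c("control", "treated")),
                 replicate = ss$replicate,
                 gene_ids = df$gene_id),
            class = "count_matrix")
}

# -- bank YAML ---------------------------------------------------------------

bank_side_to_config <- function(side) {
  lapply(seq_along(side$dists), function(s) {
    d <- side$dists[[s]]
    list(family = d$family,
         params = if (d$family == "gamma") {
           list(shape = d$params$shape, scale = d$params$scale)
         } else {
           list(mean = d$params$mean, sd = d$params$sd)
         },
         proportion = side$proportions[s])
  })
}

#' Write a bank (and optional modality proportions) to YAML
#'
#' @param bank a `submodality_bank`.
#' @param path output YAML path.
#' @param omega optional [modality_distribution()] stored alongside.
#' @export
write_bank_yaml <- function(bank, path, omega = NULL) {
  cfg <- list(modalities = list(up = bank_side_to_config(bank$sig[[1]][[1]]),
                                null = bank_side_to_config(bank$sig[[1]][[2]]),
                                down = bank_side_to_config(bank$sig[[1]][[3]])))
  if (!is.null(omega)) cfg$omega <- as.numeric(omega)
  writeLines(yaml::as.yaml(cfg, precision = 12L), path)
  invisible(path)
}

#' Read a bank YAML written by [write_bank_yaml()]
#'
#' @param path YAML path.
#' @return list with `bank` and (if stored) `omega`.
#' @export
read_bank_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(bank = build_submodality_bank(cfg$modalities))
  if (!is.null(cfg$omega)) out$omega <- modality_distribution(cfg$omega)
  out
}

#' Generate small seeded fixture datasets
#'
#' Writes deterministic, documented fixtures for examples and tests so no
#' external download is needed: a trimodal lfc vector (synthetic stand-in
#' for a real DE signature), a 200-gene 3v3 count matrix, or a 20-pair
#' benchmark written as per-pair signature TSVs.
#'
#' @param kind one of `"lfc_vector"`, `"count_matrix"`, `"benchmark_small"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return character vector of the files written.
#' @export
make_fixture_dataset <- function(kind = c("lfc_vector", "count_matrix",
                                          "benchmark_small"),
                                 dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bank <- default_realistic_bank()
  if (kind == "lfc_vector") {
    sim <- simulate_primary(c(0.12, 0.70, 0.18), bank, 5000L, seed = seed)
    sig <- sim$signature
    path <- file.path(dir, "fixture_lfc_vector.tsv")
    write_signature_table(sig, path)
    return(path)
  }
  if (kind == "count_matrix") {
    lay <- sample_primary_layers(c(0.1, 0.8, 0.1), bank, 200L, seed = seed)
    base <- simulate_base_expression(200L, seed = seed + 1L)
    cm <- simulate_count_experiment(lay, bank, base, 3L,
                                    count_model(total_reads = 1e6),
                                    seed = seed + 2L)
    paths <- file.path(dir, c("fixture_counts.tsv", "fixture_samples.tsv"))
    write_count_matrix(cm, paths[1], paths[2])
    return(paths)
  }
  ds <- generate_benchmark(20L, G = 500L, seed = seed)
  paths <- character(0)
  for (p in ds) {
    f1 <- file.path(dir, sprintf("fixture_pair%02d_primary.tsv", p$pair_id))
    f2 <- file.path(dir, sprintf("fixture_pair%02d_secondary.tsv", p$pair_id))
    write_signature_table(p$primary, f1)
    write_signature_table(p$secondary, f2)
    paths <- c(paths, f1, f2)
  }
  paths
}
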