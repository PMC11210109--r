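bank <- default_realistic_bank()

test_that("control expression inverts the mean-preservation identity", {
  expect_equal(control_expression(base_expression(100), 0), 100)
  expect_equal(control_expression(base_expression(100), 1), 200 / 3)
  expect_equal(control_expression(base_expression(100), -1), 400 / 3)
  expect_error(base_expression(-5), "nonnegative")

  # identity (mu_C + mu_C * 2^xi) / 2 = mu_tilde to machine precision
  set.seed(1)
  mu <- runif(5000, 0, 1000)
  xi <- rnorm(5000, 0, 2)
  mc <- control_expression(base_expression(mu), xi)
  expect_lt(max(abs((mc + mc * 2^xi) / 2 - mu)), 1e-9)
})

test_that("control perturbation applies multiplicative log2 noise", {
  mu <- rep(100, 50000)
  expect_identical(perturb_control(mu, 0), mu)
  out <- perturb_control(mu, 0.5, seed = 2)
  s <- sd(log2(out / mu))
  expect_gt(s, 0.49); expect_lt(s, 0.51)
  expect_identical(perturb_control(mu, 0.5, seed = 2), out)
  expect_true(all(out >= 0))
})

test_that("count simulation conserves the expected library size", {
  base <- simulate_base_expression(2000, seed = 3)
  mc <- control_expression(base, rep(0, 2000))
  sim <- simulate_counts(mc, rep(1, 2000), base, count_model(total_reads = 1e7),
                         seed = 4)
  expect_equal(sum(sim$delta), 1e7, tolerance = 1e-9)
  expect_lt(abs(sum(sim$counts) - 1e7) / 1e7, 0.01)

  # single gene receives the whole library
  b1 <- base_expression(42)
  s1 <- simulate_counts(7, 3, b1, count_model(total_reads = 1e5), seed = 5)
  expect_equal(s1$delta, 1e5)

  expect_error(simulate_counts(rep(0, 3), rep(1, 3), base_expression(rep(0, 3)),
                               count_model()), "all-zero")
})

test_that("large size factors reach the Poisson limit", {
  base <- simulate_base_expression(200, seed = 6)
  mc <- control_expression(base, rep(0, 200))
  draws <- sapply(1:400, function(k)
    simulate_counts(mc, rep(1, 200), base,
                    count_model(total_reads = 1e6, size_factor = 1e6),
                    seed = 600 + k)$counts)
  m <- rowMeans(draws); v <- apply(draws, 1, var)
  hi <- m > 500
  ratio <- v[hi] / m[hi]
  expect_lt(abs(median(ratio) - 1), 0.15)
})

test_that("replicate simulation reproduces the parent at c=1, noise=0", {
  lay <- sample_primary_layers(default_omega, bank, 3000, seed = 7)
  reps <- simulate_replicate_layers(lay, 2, rep_connectivity = 1, rep_noise = 0,
                                    bank = bank, seed = 8)
  parent <- compose_lfc(lay, bank)
  for (r in reps) expect_equal(r$signature$lfc, parent$lfc, tolerance = 1e-12)

  # defaults (c = 0.9, gamma = 0.02) keep replicates strongly correlated:
  # each replicate tracks the parent at roughly the replicate connectivity,
  # so parent-replicate correlation sits near 0.9 and replicate-replicate
  # correlation near its square
  reps2 <- simulate_replicate_layers(lay, 3, bank = bank, seed = 9)
  for (r in reps2) expect_gt(cor(parent$lfc, r$signature$lfc), 0.8)
  cors <- combn(3, 2, function(ix)
    cor(reps2[[ix[1]]]$signature$lfc, reps2[[ix[2]]]$signature$lfc))
  expect_true(all(cors > 0.65))

  expect_identical(simulate_replicate_layers(lay, 2, bank = bank, seed = 10),
                   simulate_replicate_layers(lay, 2, bank = bank, seed = 10))
})

test_that("median-of-ratios size factors match the brute-force oracle", {
  eq <- matrix(c(5L, 9L, 14L, 5L, 9L, 14L, 5L, 9L, 14L), nrow = 3)
  expect_equal(unname(median_of_ratios_size_factors(eq)), rep(1, 3))

  dbl <- cbind(eq, eq[, 1] * 2L)
  sf <- median_of_ratios_size_factors(dbl)
  expect_equal(sf[4] / sf[1], 2)

  set.seed(11)
  rnd <- matrix(rnbinom(600, mu = 50, size = 5) + 1L, nrow = 100)
  expect_equal(unname(median_of_ratios_size_factors(rnd)),
               oracle_size_factors(rnd), tolerance = 1e-12)

  expect_error(median_of_ratios_size_factors(matrix(0L, 2, 2)), "nonzero")
})

test_that("NB Wald test behaves on null genes and matches BH", {
  counts <- matrix(rep(c(100L, 200L, 400L), 6), nrow = 3)
  cm <- list(counts = counts,
             condition = factor(rep(c("treated", "control"), each = 3),
                                levels = c("control", "treated")),
             gene_ids = c("a", "b", "c"))
  de <- nb_wald_de(cm)
  expect_equal(de$lfc_hat, rep(0, 3))
  expect_equal(de$pvalue, rep(1, 3))

  set.seed(12)
  lay <- sample_primary_layers(c(0.15, 0.7, 0.15), bank, 400, seed = 13)
  base <- simulate_base_expression(400, seed = 14)
  cm2 <- simulate_count_experiment(lay, bank, base, 3,
                                   count_model(total_reads = 1e6), seed = 15)
  de2 <- nb_wald_de(cm2)
  expect_equal(de2$padj, oracle_bh(de2$pvalue), tolerance = 1e-12)
  expect_true(all(de2$pvalue >= 0 & de2$pvalue <= 1))
  expect_error(nb_wald_de(list(counts = counts[, c(1, 4)],
    condition = factor(c("treated", "control")), gene_ids = letters[1:3])),
    "2 replicates")
})

test_that("the Wald interval covers a known fold change", {
  # one spiked gene (linear FC 4, mean count ~1000) among stable background
  covered <- sapply(1:200, function(s) {
    set.seed(3000 + s)
    G <- 60
    muC <- rep(1000, G); muT <- rep(1000, G)
    muT[1] <- 4 * 1000; muC[1] <- 1000
    counts <- cbind(
      sapply(1:3, function(i) rnbinom(G, mu = muT, size = muT / 3)),
      sapply(1:3, function(i) rnbinom(G, mu = muC, size = muC / 3)))
    cm <- list(counts = counts,
               condition = factor(rep(c("treated", "control"), each = 3),
                                  levels = c("control", "treated")),
               gene_ids = sprintf("g%d", 1:G))
    de <- nb_wald_de(cm)
    abs(de$lfc_hat[1] - 2) <= 1.96 * de$se[1]
  })
  expect_gte(mean(covered), 0.9)
})

test_that("re-inference tracks the replicate consensus and flattens the null peak", {
  lay <- sample_primary_layers(default_omega, bank, 5000, seed = 51)
  base <- simulate_base_expression(5000, seed = 52)
  cm <- simulate_count_experiment(lay, bank, base, 3, count_model(), seed = 53)
  de <- nb_wald_de(cm)
  sig <- compose_lfc(lay, bank)
  strong <- abs(sig$lfc) >= 1 & base$mu_tilde >= 50
  # the estimate agrees with the consensus of the replicate signatures that
  # actually generated the treated counts; replicate modality flips keep it
  # farther from the parent signature
  consensus <- rowMeans(cm$replicate_lfc)
  expect_gt(cor(de$lfc_hat[strong], consensus[strong]), 0.9)
  # the sharp simulated peak of near-zero LFCs is flattened by re-inference
  expect_lt(mean(abs(de$lfc_hat) < 0.05), mean(abs(sig$lfc) < 0.05))
})

test_that("count experiments are reproducible and well-formed", {
  lay <- sample_primary_layers(default_omega, bank, 300, seed = 16)
  base <- simulate_base_expression(300, seed = 17)
  a <- simulate_count_experiment(lay, bank, base, 3,
                                 count_model(total_reads = 1e6), seed = 18)
  b <- simulate_count_experiment(lay, bank, base, 3,
                                 count_model(total_reads = 1e6), seed = 18)
  expect_identical(a, b)
  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts[1, 1]) || all(a$counts == round(a$counts)))
  expect_equal(dim(a$counts), c(300L, 6L))
  expect_equal(as.vector(table(a$condition)), c(3L, 3L))
})
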