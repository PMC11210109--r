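bank <- default_realistic_bank()

test_that("symmetric transition matrix matches its closed form", {
  L <- symmetric_transition_matrix(connectivity_model(1, 0))
  expect_equal(unclass(L), matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3,
                                  dimnames = dimnames(L)), tolerance = 1e-15)
  L0 <- symmetric_transition_matrix(connectivity_model(0, 0))
  expect_equal(L0[1, ], c(to1 = 0.5, to2 = 0, to3 = 0.5))
  expect_equal(L0[2, 2], 1)
  # hand-evaluated row at (c = 0.5, gamma = 0.02)
  L5 <- symmetric_transition_matrix(connectivity_model(0.5, 0.02))
  expect_equal(unname(L5[1, ]), c(0.7425, 0.01, 0.2475), tolerance = 1e-12)
  expect_equal(unname(rowSums(L5)), rep(1, 3), tolerance = 1e-15)
})

test_that("rows are stochastic across the whole (c, gamma) domain", {
  grid <- expand.grid(c = seq(-1, 1, length.out = 100),
                      g = seq(0, 0.5, length.out = 100))
  worst <- max(apply(grid, 1L, function(row) {
    L <- symmetric_transition_matrix(connectivity_model(row[1], row[2]))
    max(abs(rowSums(L) - 1)) + max(pmax(-L, 0)) + max(pmax(L - 1, 0))
  }))
  expect_lt(worst, 1e-12)
  expect_error(connectivity_model(1.2, 0), "\\[-1, 1\\]")
  expect_error(connectivity_model(0, 0.6), "\\[0, 0.5\\]")
})

test_that("modality transitions sample the matrix rows", {
  prim <- rep(1:3, each = 5)
  I3 <- diag(3)
  expect_identical(transition_modalities(prim, I3, seed = 1), as.integer(prim))
  allnull <- matrix(c(0, 1, 0), 3, 3, byrow = TRUE)
  expect_true(all(transition_modalities(prim, allnull, seed = 1) == 2L))
  expect_error(transition_modalities(prim, matrix(0.5, 3, 3)), "sum to 1")

  # (c=0, gamma=0): up genes split evenly between up and down
  L <- symmetric_transition_matrix(connectivity_model(0, 0))
  beta <- transition_modalities(rep(1L, 20000), L, seed = 2)
  se <- 3 * sqrt(0.25 / 20000)
  expect_lt(abs(mean(beta == 1L) - 0.5), se)
  expect_equal(sum(beta == 2L), 0)
  expect_lt(abs(mean(beta == 3L) - 0.5), se)
})

test_that("empirical transition frequencies match Lambda row-wise", {
  L <- symmetric_transition_matrix(connectivity_model(0.4, 0.1))
  G <- 50000
  for (a in 1:3) {
    beta <- transition_modalities(rep(a, G), L, seed = 10 + a)
    expect_gt(stats::chisq.test(tabulate(beta, 3L), p = L[a, ])$p.value, 0.001)
  }
})

test_that("deterministic sub-modality transition copies ranks on deregulated genes", {
  pri <- sample_primary_layers(c(0.3, 0.4, 0.3), bank, 5000, seed = 3)
  beta <- transition_modalities(pri$modality,
                                symmetric_transition_matrix(connectivity_model(0.6, 0.1)),
                                seed = 4)
  ups <- transition_submodalities(pri, beta, bank,
                                  submod_transition_config("deterministic"),
                                  seed = 5)
  both <- pri$modality != 2L & beta != 2L
  expect_identical(ups[both], pri$submodality[both])
  expect_true(all(ups >= 1L & ups <= 3L))
})

make_flat_bank <- function(n) {
  # n equal-proportion gamma sub-modalities with increasing means
  tail_cfg <- lapply(seq_len(n), function(k)
    list(family = "gamma", params = list(shape = 100, scale = k / 100),
         proportion = 1 / n))
  build_submodality_bank(list(
    up = tail_cfg,
    null = list(list(family = "gaussian", params = list(mean = 0, sd = 0.1),
                     proportion = 1)),
    down = tail_cfg))
}

test_that("stochastic sub-modality transition follows the binomial law", {
  b10 <- make_flat_bank(10)
  G <- 100000
  pri <- layer_set(rep(1L, G), rep(5L, G), rep(0.5, G))
  ups <- transition_submodalities(pri, rep(1L, G), b10,
                                  submod_transition_config("stochastic"),
                                  seed = 6)
  expect_gt(mean(ups), 4.95) # binomial mean n*p = tau = 5
  expect_lt(mean(ups), 5.05)

  # tau = n is the degenerate p = 1 case
  pri10 <- layer_set(rep(1L, 100), rep(10L, 100), rep(0.5, 100))
  expect_true(all(transition_submodalities(pri10, rep(1L, 100), b10,
                submod_transition_config("stochastic"), seed = 7) == 10L))
})

test_that("deterministic/stochastic transitions require equal bank sizes", {
  uneven <- build_submodality_bank(list(
    primary = list(
      up = list(list(family = "gamma", params = list(shape = 4, scale = 0.5),
                     proportion = 1)),
      null = list(list(family = "gaussian", params = list(mean = 0, sd = 0.1),
                       proportion = 1)),
      down = list(list(family = "gamma", params = list(shape = 4, scale = 0.5),
                       proportion = 1))),
    secondary = list(
      up = list(
        list(family = "gamma", params = list(shape = 4, scale = 0.25),
             proportion = 0.5),
        list(family = "gamma", params = list(shape = 4, scale = 0.6),
             proportion = 0.5)),
      null = list(list(family = "gaussian", params = list(mean = 0, sd = 0.1),
                       proportion = 1)),
      down = list(list(family = "gamma", params = list(shape = 4, scale = 0.5),
                       proportion = 1)))))
  pri <- layer_set(rep(1L, 10), rep(1L, 10), rep(0.5, 10))
  expect_error(
    transition_submodalities(pri, rep(1L, 10), uneven,
                             submod_transition_config("deterministic"), seed = 1),
    "equal sub-modality counts")
  # the copula strategy handles unequal counts
  ups <- transition_submodalities(pri, rep(1L, 10), uneven,
    submod_transition_config("copula", "gauss", 0.5), seed = 1)
  expect_true(all(ups %in% 1:2))
})

test_that("probability transitions implement the three strategies", {
  psi <- seq(0.01, 0.99, length.out = 50000)
  expect_identical(transition_probabilities(psi, prob_transition_config("deterministic")),
                   psi)
  rho <- transition_probabilities(psi, prob_transition_config("independent"),
                                  seed = 8)
  expect_gt(suppressWarnings(ks.test(rho, "punif")$p.value), 0.001)
  expect_lt(abs(cor(psi, rho)), 0.02)
  rho2 <- transition_probabilities(psi,
    prob_transition_config("copula", "gauss", 0.8), seed = 9)
  expect_lt(abs(cor(psi, rho2) - 0.8), 0.02)
})

test_that("extreme connectivities are identities or sign flips", {
  pri <- sample_primary_layers(c(0.2, 0.6, 0.2), bank, 4000, seed = 12)
  p <- compose_lfc(pri, bank)
  sec1 <- simulate_secondary(pri, connectivity_model(1, 0), bank, seed = 13)
  expect_equal(sec1$signature$lfc, p$lfc, tolerance = 1e-12)

  secm <- simulate_secondary(pri, connectivity_model(-1, 0), bank, seed = 14)
  dereg <- pri$modality != 2L
  expect_equal(secm$signature$lfc[dereg], -p$lfc[dereg], tolerance = 1e-12)
})

test_that("independent transitions at c = 0 leave no chimeric correlation", {
  rs <- sapply(1:5, function(k) {
    pri <- sample_primary_layers(default_omega, bank, 10000, seed = 20 + k)
    sec <- simulate_secondary(pri, connectivity_model(0, 0.02), bank,
                              submod_transition_config("independent"),
                              prob_transition_config("independent"),
                              seed = 40 + k)
    cor(compose_lfc(pri, bank)$lfc, sec$signature$lfc)
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("simulate_secondary is reproducible from its seed", {
  pri <- sample_primary_layers(default_omega, bank, 1000, seed = 30)
  a <- simulate_secondary(pri, connectivity_model(0.5, 0.02), bank, seed = 31)
  b <- simulate_secondary(pri, connectivity_model(0.5, 0.02), bank, seed = 31)
  expect_identical(a, b)
})
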