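test_that("error-indicator sampling matches its Bernoulli law", {
  set.seed(1)
  expect_identical(sample_epsilon(rep(0, 50)), integer(50))
  expect_identical(sample_epsilon(rep(1, 50)), rep(1L, 50))
  draws <- replicate(10000, sample_epsilon(0.3))
  expect_lt(abs(mean(draws) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("allocation probabilities follow pi/M restricted to the peptide's proteins", {
  expect_equal(allocation_probs(c(0.2, 0.8), c(1L, 1L), 1L), c(1, 0))
  expect_equal(allocation_probs(c(0.5, 0.5), c(1L, 1L), c(1L, 2L)), c(0.5, 0.5))
  expect_equal(allocation_probs(c(0.6, 0.4), c(2L, 1L), c(1L, 2L)),
               c(3 / 7, 4 / 7))
  # zero weight on the compatible set: uniform fallback
  expect_equal(allocation_probs(c(0, 0, 1), c(1L, 1L, 1L), c(1L, 2L)),
               c(0.5, 0.5, 0))
  # always a probability vector, zero outside psi
  set.seed(2)
  for (rep in 1:20) {
    P <- sample(2:6, 1)
    pi <- as.numeric(sample_pi(integer(P), rep(1, P)))
    m <- sample(1:4, P, replace = TRUE)
    psi <- sample.int(P, sample(1:P, 1))
    pr <- allocation_probs(pi, m, psi)
    expect_equal(sum(pr), 1)
    expect_true(all(pr[-psi] == 0) || length(psi) == P)
  }
})

test_that("peptide allocation conserves abundance and respects the error indicator", {
  set.seed(3)
  expect_identical(allocate_peptide(7L, 1L, c(0.5, 0.5)), integer(2))
  expect_identical(allocate_peptide(5L, 0L, c(1, 0)), c(5L, 0L))
  x <- allocate_peptide(1000L, 0L, c(3 / 7, 4 / 7))
  expect_identical(sum(x), 1000L)
  expect_lt(abs(x[1] - 1000 * 3 / 7), 3 * sqrt(1000 * 3 / 7 * 4 / 7))
})

test_that("pi draws match the Dirichlet conditional", {
  set.seed(4)
  expect_equal(sample_pi(0L, 5), 1)
  draws <- t(replicate(10000, sample_pi(c(90L, 10L), c(1, 1))))
  se <- sqrt(91 / 102 * (1 - 91 / 102) / 103) / sqrt(10000)
  expect_lt(abs(mean(draws[, 1]) - 91 / 102), 4 * se)
})

test_that("degenerate instances are forced by conservation", {
  # one isoform, one unique peptide: X = Y and pi = 1 at every draw
  pt <- make_peptides("a", 10, list("P1"))
  map <- apply_trivial_filter(pt)
  draws <- run_mcmc(map, build_prior(1), quick_config(seed = 1))
  expect_true(all(draws$x_chain == 10L))
  expect_true(all(draws$pi_chain == 1))

  # two exchangeable isoforms sharing one peptide: mean pi ~ 0.5
  pt <- make_peptides("a", 10, list(c("P1", "P2")))
  map <- apply_trivial_filter(pt)
  draws <- run_mcmc(map, build_prior(2),
                    run_config(iterations = 6000, burn_in = 1000, seed = 2))
  expect_equal(unname(colMeans(draws$pi_chain)), c(0.5, 0.5), tolerance = 0.04)
})

test_that("abundance is conserved at every iteration in both modes", {
  set.seed(5)
  pt <- make_peptides(sprintf("p%d", 1:6), c(4, 9, 2, 7, 1, 30),
                      list("P1", c("P1", "P2"), c("P2", "P3"), "P3",
                           c("P4", "P5"), "P5"),
                      pep = c(0, 0.3, 0.6, 0.1, 0.9, 0.2))
  map <- apply_trivial_filter(pt)
  prior <- build_prior(nrow(map$proteins))

  fdr_draws <- run_mcmc(map, prior, quick_config(mode = "fdr", seed = 6))
  expect_true(all(rowSums(fdr_draws$x_chain) == sum(pt$abundance)))
  expect_true(all(fdr_draws$kept_abundance == sum(pt$abundance)))

  pep_draws <- run_mcmc(map, prior, quick_config(mode = "pep", seed = 6))
  expect_identical(unname(rowSums(pep_draws$x_chain)),
                   as.numeric(pep_draws$kept_abundance))
  expect_true(any(pep_draws$kept_abundance < sum(pt$abundance)))
})

test_that("chains are reproducible and independent of thread count", {
  pt <- make_peptides(sprintf("p%d", 1:5), c(3, 8, 2, 5, 4),
                      list(c("P1", "P2"), "P2", c("P3", "P4"), "P4", "P5"),
                      pep = c(0.2, 0.1, 0.4, 0, 0.3))
  map <- apply_trivial_filter(pt)
  expect_gt(length(map$blocks), 1L)
  prior <- build_prior(nrow(map$proteins))
  for (mode in c("fdr", "pep")) {
    d1 <- run_mcmc(map, prior, quick_config(mode = mode, seed = 9, threads = 1))
    d2 <- run_mcmc(map, prior, quick_config(mode = mode, seed = 9, threads = 2))
    d3 <- run_mcmc(map, prior, quick_config(mode = mode, seed = 9, threads = 1))
    expect_identical(d1$pi_chain, d2$pi_chain)
    expect_identical(d1$x_chain, d2$x_chain)
    expect_identical(d1$pi_chain, d3$pi_chain)
  }
})

test_that("presence probability decreases with the peptide's error probability", {
  # isoform supported by a single unique peptide: Pr(X > 0) = Pr(eps = 0)
  probs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    pt <- make_peptides("a", 5, list("P1"), pep = p)
    map <- apply_trivial_filter(pt)
    draws <- run_mcmc(map, build_prior(1),
                      run_config(mode = "pep", iterations = 3000,
                                 burn_in = 500, seed = 11))
    prob_present(draws$x_chain[, 1])
  }, 0)
  expect_true(all(diff(probs) <= 0))
  expect_equal(probs[1], 1)
  expect_equal(probs[5], 0)
})

test_that("MCMC posterior means match the exact stationary law on tiny instances", {
  cases <- list(
    list(y = c(3L, 2L), psi = list(c(1L, 2L), 2L), P = 2,
         pep = c(0, 0), mode = "fdr"),
    list(y = c(2L, 3L, 1L), psi = list(1L, c(1L, 2L), 2L), P = 2,
         pep = c(0, 0, 0), mode = "fdr"),
    list(y = c(2L, 1L), psi = list(c(1L, 2L), 2L), P = 2,
         pep = c(0.3, 0.1), mode = "pep"),
    list(y = c(2L, 2L), psi = list(c(1L, 2L), c(2L, 3L)), P = 3,
         pep = c(0, 0), mode = "fdr"),
    list(y = c(3L, 2L, 1L), psi = list(c(1L, 2L), c(2L, 3L), 3L), P = 3,
         pep = c(0.2, 0.5, 0.1), mode = "pep")
  )
  for (cs in cases) {
    ids <- sprintf("P%d", seq_len(cs$P))
    pt <- make_peptides(sprintf("pep%d", seq_along(cs$y)), cs$y,
                        lapply(cs$psi, function(s) ids[s]), pep = cs$pep)
    map <- apply_trivial_filter(pt)
    # map orders proteins by sorted id == index order here
    expect_identical(map$proteins$protein_id, ids)
    m <- map$proteins$m_detected
    delta <- rep(1, cs$P)
    nodes <- if (cs$P == 2) 80 else 40
    exact <- oracle_stationary(cs$y, cs$psi, m, delta,
                               pep = if (cs$mode == "pep") cs$pep else rep(0, length(cs$y)),
                               n_nodes = nodes)
    draws <- run_mcmc(map, build_prior(cs$P),
                      run_config(mode = cs$mode, iterations = 22000,
                                 burn_in = 2000, seed = 21))
    for (p in seq_len(cs$P)) {
      se <- batch_se(draws$pi_chain[, p])
      expect_lt(abs(mean(draws$pi_chain[, p]) - exact$mean_pi[p]),
                max(3 * se, 1e-4))
    }
  }
})
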