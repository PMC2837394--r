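test_that("Dirichlet priors over models have the documented counts", {
  expect_equal(default_model_prior(3), c(1, 1, 1))
  expect_equal(default_model_prior(1), 1)

  two64 <- family_partition(paste0("m", 1:128), rep(c("a", "b"), each = 64))
  a <- family_uniform_prior(two64)
  expect_true(all(a == 1 / 64))
  # singleton families reduce to the default unit counts
  singles <- family_partition(paste0("m", 1:4), paste0("f", 1:4))
  expect_true(all(family_uniform_prior(singles) == 1))
  # aggregated family prior counts are always exactly 1
  withr::with_seed(7, fam <- sample(c("x", "y", "z"), 30, replace = TRUE))
  part <- family_partition(paste0("m", 1:30), fam)
  agg <- tapply(family_uniform_prior(part), part$family, sum)
  expect_equal(as.numeric(agg), rep(1, 3), tolerance = 1e-12)
})

test_that("safe Dirichlet draws stay on the simplex even for tiny shapes", {
  withr::with_seed(8, {
    for (i in 1:50) {
      r <- groupbms:::rdirichlet_safe(rep(1 / 64, 448))
      expect_true(all(r > 0))
      expect_lt(abs(sum(r) - 1), 1e-12)
    }
    # moments sanity for a small-shape Dirichlet: E[r_1] = a1 / sum(a)
    draws <- t(replicate(4000, groupbms:::rdirichlet_safe(c(0.05, 0.1, 0.85))))
    expect_equal(colMeans(draws), c(0.05, 0.1, 0.85), tolerance = 0.03)
  })
})

test_that("Gibbs sampler satisfies its structural invariants", {
  sim <- simulate_group_evidence(10, true_freqs = c(0.5, 0.3, 0.2),
                                 margin = 6, noise_sd = 1, seed = 9)
  post <- gibbs_sample(sim$evidence, n_total = 1500, burn_in = 500, seed = 9)
  expect_equal(nrow(post$r_samples), 1000)
  expect_true(all(abs(rowSums(post$r_samples) - 1) < 1e-10))
  expect_true(all(abs(rowSums(post$g) - 1) < 1e-10))
  expect_simplex(post$expected_r, tol = 1e-10)
  expect_lte(sum(post$exceedance), 1 + 1e-12)
  expect_gt(sum(post$exceedance), 0.999)
  expect_equal(post$seed, 9L)
  # exact reproducibility from the recorded seed
  again <- gibbs_sample(sim$evidence, n_total = 1500, burn_in = 500, seed = 9)
  expect_identical(post$r_samples, again$r_samples)
  expect_error(gibbs_sample(sim$evidence, n_total = 100, burn_in = 100), "exceed")
})

test_that("single-model inference is degenerate at frequency one", {
  L <- matrix(c(-3, -5), 2, 1, dimnames = list(c("s1", "s2"), "only"))
  post <- gibbs_sample(L, n_total = 300, burn_in = 100, seed = 1)
  expect_true(all(post$r_samples == 1))
  expect_equal(unname(post$exceedance), 1)
  expect_equal(unname(post$expected_r), 1)
})

# independent per-row softmax for the decisive check below
row_softmax_oracle <- function(L) {
  t(apply(L, 1, function(x) exp(x) / sum(exp(x))))
}

test_that("decisive evidence reduces Gibbs to the conjugate Dirichlet posterior", {
  counts <- c(7, 10)
  L <- decisive_evidence(counts, margin = 12)
  post <- gibbs_sample(L, n_total = 6000, burn_in = 1000, seed = 11)
  oracle <- (counts + 1) / (sum(counts) + length(counts))
  tol <- pmax(3 * post$mcse_r, 1e-4)
  expect_true(all(abs(post$expected_r - oracle) < tol))
  # assignments are pinned by the decisive margins
  expect_true(all(abs(post$g - row_softmax_oracle(L)) < 1e-4))
})

test_that("flat evidence preserves the Dirichlet prior", {
  L <- matrix(0, 6, 3, dimnames = list(paste0("s", 1:6), paste0("m", 1:3)))
  alpha0 <- c(2, 1, 1)
  post <- gibbs_sample(L, alpha0 = alpha0, n_total = 8000, burn_in = 2000, seed = 12)
  expect_equal(unname(post$expected_r), alpha0 / sum(alpha0),
               tolerance = 0.02)
})

test_that("independent chains agree within combined Monte-Carlo error", {
  sim <- simulate_group_evidence(15, true_freqs = c(0.6, 0.4), margin = 3,
                                 noise_sd = 1, seed = 13)
  a <- gibbs_sample(sim$evidence, n_total = 6000, burn_in = 1000, seed = 101)
  b <- gibbs_sample(sim$evidence, n_total = 6000, burn_in = 1000, seed = 202)
  comb <- sqrt(a$mcse_r^2 + b$mcse_r^2)
  expect_true(all(abs(a$expected_r - b$expected_r) < 3 * comb + 1e-3))
})

test_that("exceedance is the strict-argmax frequency of the draws", {
  # two columns: the exceedances are complementary
  withr::with_seed(14, {
    x <- runif(500)
    two <- cbind(a = x, b = 1 - x)
  })
  ex2 <- exceedance_from_samples(two)
  expect_equal(sum(ex2), 1)
  expect_equal(ex2[["a"]], mean(x > 0.5))

  # constant draws with a unique maximum
  const <- matrix(rep(c(0.2, 0.5, 0.3), each = 10), 10, 3)
  expect_equal(unname(exceedance_from_samples(const)), c(0, 1, 0))

  # exact ties count for no column
  tied <- matrix(0.5, 4, 2)
  expect_equal(unname(exceedance_from_samples(tied)), c(0, 0))

  # symmetric Dirichlet draws are equi-exceedant
  withr::with_seed(15, {
    sym <- t(replicate(6000, groupbms:::rdirichlet_safe(c(1, 1, 1))))
  })
  expect_equal(unname(exceedance_from_samples(sym)), rep(1 / 3, 3),
               tolerance = 0.03)
  expect_error(exceedance_from_samples(matrix(numeric(0), 0, 2)), "draw")
})

test_that("family aggregation of frequency draws behaves correctly", {
  sim <- simulate_group_evidence(12, true_freqs = c(0.5, 0.3, 0.2),
                                 margin = 8, seed = 16)
  post <- gibbs_sample(sim$evidence, n_total = 2000, burn_in = 500, seed = 16)

  single <- family_partition(paste0("m", 1:3), rep("all", 3))
  fs <- family_posterior(post, single)
  expect_true(all(abs(fs$s_samples - 1) < 1e-10))

  part <- family_partition(paste0("m", 1:3), c("one", "two", "two"))
  f2 <- family_posterior(post, part)
  expect_equal(unname(f2$expected_s[1] + f2$expected_s[2]), 1, tolerance = 1e-10)
  expect_equal(unname(f2$expected_s[2]),
               unname(post$expected_r[2] + post$expected_r[3]), tolerance = 1e-12)
  bad <- family_partition(c("m1", "m2"), c("a", "b"))
  expect_error(family_posterior(post, bad), "Partition")
})

test_that("bms_rfx front end wires priors, partitions and tidiers together", {
  sim <- simulate_group_evidence(10, true_freqs = c(0.7, 0.2, 0.1),
                                 margin = 10, seed = 17)
  part <- family_partition(paste0("m", 1:3), c("one", "rest", "rest"))
  fit <- bms_rfx(sim$evidence, partition = part, prior = "family-uniform",
                 n_samples = 2000, burn_in = 500, seed = 17)
  expect_equal(unname(fit$posterior$alpha0), c(1, 1 / 2, 1 / 2))
  td <- tidy(fit)
  expect_equal(names(td), c("model", "expected_freq", "exceedance", "mcse"))
  tf <- tidy(fit, "family")
  expect_equal(tf$family, c("one", "rest"))
  expect_equal(sum(tf$expected_freq), 1, tolerance = 1e-10)
  g <- glance(fit)
  expect_equal(g$method, "gibbs")
  expect_true(g$best_family %in% c("one", "rest"))
})
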