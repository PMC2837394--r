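test_that("Occam's window applies the posterior odds-ratio rule", {
  # limits: pi near 0 keeps every model with nonzero mass, pi = 1 only the best
  p <- c(0.5, 0.3, 0.2)
  expect_equal(occams_window(p, pi_occ = 1e-12)$included, 1:3)
  expect_equal(occams_window(p, pi_occ = 1)$included, 1L)
  # the rule is the ratio to the best model, not an absolute cut
  probs <- c(0.5, 0.3, 0.03)
  ow <- occams_window(probs, pi_occ = 1 / 20)
  expected <- which(probs / max(probs) > 1 / 20)
  expect_equal(ow$included, expected)
  expect_equal(sum(ow$weights), 1)
  expect_equal(ow$window_size, length(expected))
  # narrowing the window never adds components
  for (pi2 in c(0.01, 0.1, 0.5, 1)) {
    expect_lte(occams_window(probs, pi2)$window_size,
               occams_window(probs, 0.005)$window_size)
  }
  expect_error(occams_window(numeric(0)), "non-empty")
  expect_error(occams_window(p, pi_occ = 0), "pi_occ")
  expect_error(occams_window(p, pi_occ = 1.5), "pi_occ")
})

test_that("a single-model window reproduces that model's Gaussian", {
  posts <- toy_posterior_grid(
    1, models = list(m1 = c("a", "b")),
    means = list(m1 = c(0.7, -0.3)), sds = list(m1 = 0.2))
  d <- bma_group(posts, c(m1 = 1), mode = "ffx", n_samples = 6000, seed = 31)
  s <- summarize_density(d)
  expect_equal(s$mean, c(0.7, -0.3), tolerance = 0.02)
  expect_equal(apply(d$theta_samples, 2, sd), c(a = 0.2, b = 0.2),
               tolerance = 0.03)
  expect_equal(s$zero_mass, c(0, 0))
  # closed-form quantile check
  expect_equal(s$lower[1], qnorm(0.025, 0.7, 0.2), tolerance = 0.05)
  expect_equal(s$upper[1], qnorm(0.975, 0.7, 0.2), tolerance = 0.05)
})

test_that("two-model mixtures match closed-form moments and zero mass", {
  w <- 0.7
  posts <- toy_posterior_grid(
    1,
    models = list(m1 = c("a"), m2 = c("a", "b")),
    means = list(m1 = c(1, 0), m2 = c(-1, 0.5)), sds = list(m1 = 0.1, m2 = 0.1))
  d <- bma_subject(posts, c(m1 = w, m2 = 1 - w), subject = 1, mode = "ffx",
                   n_samples = 20000, pi_occ = 1e-9, seed = 32)
  s <- summarize_density(d)
  # mixture-moment oracle for parameter "a"
  expect_equal(s$mean[1], w * 1 + (1 - w) * (-1), tolerance = 0.02)
  # "b" is free only in m2 (weight 1 - w): delta mass at zero is w
  expect_equal(s$zero_mass[2], w, tolerance = 0.015)
  expect_equal(mean(d$theta_samples[, "b"] == 0), s$zero_mass[2])
  # bimodal equal-weight mixture has mean near the midpoint
  d2 <- bma_subject(posts, c(m1 = 0.5, m2 = 0.5), subject = 1, mode = "ffx",
                    n_samples = 20000, pi_occ = 1e-9, seed = 33)
  expect_equal(summarize_density(d2)$mean[1], 0, tolerance = 0.02)
  expect_gt(mean(d2$theta_samples[, "a"] > 0.5), 0.4)
  expect_gt(mean(d2$theta_samples[, "a"] < -0.5), 0.4)
})

test_that("group averaging matches the subject-average of weighted means", {
  withr::with_seed(34, {
    mu1 <- runif(2, -1, 1); mu2 <- runif(2, -1, 1)
  })
  posts <- toy_posterior_grid(
    3,
    models = list(m1 = c("a", "b"), m2 = c("a", "b")),
    means = list(m1 = mu1, m2 = mu2), sds = list(m1 = 0.15, m2 = 0.15))
  w <- c(m1 = 0.6, m2 = 0.4)
  d <- bma_group(posts, w, mode = "ffx", n_samples = 20000, pi_occ = 1e-9,
                 seed = 34)
  closed <- 0.6 * mu1 + 0.4 * mu2  # identical subjects
  mcse <- apply(d$theta_samples, 2, sd) / sqrt(nrow(d$theta_samples))
  expect_true(all(abs(summarize_density(d)$mean - closed) < 3 * mcse + 1e-3))

  # RFX weights: identical g rows must reproduce the FFX moments
  g <- rbind(w, w, w)
  colnames(g) <- c("m1", "m2")
  d_rfx <- bma_group(posts, g, mode = "rfx", n_samples = 20000,
                     pi_occ = 1e-9, seed = 35)
  expect_true(all(abs(summarize_density(d_rfx)$mean - closed) < 0.02))
})

test_that("group zero mass requires every subject to fix the parameter", {
  # "b" free only in m2; under RFX with independent per-subject draws the
  # group average is exactly zero only when all subjects draw m1
  posts <- toy_posterior_grid(
    2,
    models = list(m1 = c("a"), m2 = c("a", "b")),
    means = list(m1 = c(1, 0), m2 = c(1, 1)), sds = list(m1 = 0.1, m2 = 0.1))
  g <- matrix(0.5, 2, 2, dimnames = list(NULL, c("m1", "m2")))
  d <- bma_group(posts, g, mode = "rfx", n_samples = 20000, pi_occ = 1e-9,
                 seed = 36)
  expect_equal(d$zero_mass[["b"]], 0.25, tolerance = 0.015)
  # under FFX the single shared draw makes it 0.5
  d_ffx <- bma_group(posts, c(m1 = 0.5, m2 = 0.5), mode = "ffx",
                     n_samples = 20000, pi_occ = 1e-9, seed = 37)
  expect_equal(d_ffx$zero_mass[["b"]], 0.5, tolerance = 0.015)
})

test_that("per-subject RFX windows can differ across subjects", {
  posts <- toy_posterior_grid(
    2,
    models = list(m1 = c("a"), m2 = c("a", "b")),
    means = list(m1 = c(1, 0), m2 = c(-1, 0.5)), sds = list(m1 = 0.1, m2 = 0.1))
  g <- rbind(c(0.99, 0.01),   # subject 1: m2 outside a 1/20 window
             c(0.5, 0.5))     # subject 2: both inside
  colnames(g) <- c("m1", "m2")
  d <- bma_group(posts, g, mode = "rfx", n_samples = 2000, pi_occ = 1 / 20,
                 seed = 38)
  expect_equal(d$window_sizes, c(1L, 2L))
})

test_that("density summaries satisfy their invariants", {
  posts <- toy_posterior_grid(
    1, models = list(m1 = c("a", "b")),
    means = list(m1 = c(0, 0)), sds = list(m1 = 1))
  d <- bma_subject(posts, c(m1 = 1), subject = 1, n_samples = 10000,
                   mode = "ffx", seed = 39)
  s <- summarize_density(d)
  expect_equal(s$p_positive, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(s$mean, c(0, 0), tolerance = 0.03)

  # all parameters fixed at zero: total zero mass
  none <- toy_posterior_grid(
    1, models = list(m0 = character(0)),
    means = list(m0 = c(0, 0)), sds = list(m0 = 1))
  d0 <- bma_subject(none, c(m0 = 1), subject = 1, n_samples = 500,
                    mode = "ffx", seed = 40)
  expect_equal(unname(d0$zero_mass), c(1, 1))
  expect_true(all(d0$theta_samples == 0))
  expect_equal(summarize_density(d0)$zero_mass, c(1, 1))
  d_small <- bma_subject(none, c(m0 = 1), subject = 1, n_samples = 50,
                         mode = "ffx", seed = 41)
  expect_error(summarize_density(d_small), "100")  # too few samples
})

test_that("posterior grids are validated", {
  # non-PSD covariance is rejected at draw time
  bad_cov <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  cells <- list(list(list(mean = c(0.1, 0.2), cov = bad_cov, free = c(1, 1))))
  posts <- subject_posteriors(c("a", "b"), "s1", "m1", cells)
  expect_error(
    bma_subject(posts, c(m1 = 1), subject = 1, mode = "ffx", n_samples = 200),
    "positive semi-definite")
  # masked parameters must be zeroed
  expect_error(
    subject_posteriors(c("a", "b"), "s1", "m1",
                       list(list(list(mean = c(0.1, 0.2), cov = diag(c(1, 0)),
                                      free = c(1, 0))))),
    "zero mean")
  # incomplete grids are rejected
  expect_error(
    subject_posteriors(c("a"), "s1", c("m1", "m2"),
                       list(list(list(mean = 0, cov = matrix(1), free = 1)))),
    "complete")
})
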