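test_that("joint log evidence is the per-column sum over subjects", {
  expect_equal(joint_log_evidence(rbind(s1 = c(a = 1.5, b = -2))),
               c(a = 1.5, b = -2))
  L <- rbind(s1 = c(a = 0, b = -1), s2 = c(a = 0, b = -1))
  expect_equal(joint_log_evidence(L), c(a = 0, b = -2))
  withr::with_seed(1, {
    L <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), paste0("m", 1:4)))
  })
  # brute-force summation oracle
  oracle <- vapply(1:4, function(j) sum(vapply(1:5, function(n) L[n, j], numeric(1))),
                   numeric(1))
  expect_equal(unname(joint_log_evidence(L)), oracle)
})

test_that("model posterior is a log-sum-exp softmax with prior support", {
  expect_equal(model_posterior(c(0, 0)), c(0.5, 0.5))
  # Bayes factor 20 with uniform prior gives posterior 20/21 > 0.95
  p <- model_posterior(c(log(20), 0))
  expect_equal(p[1], 20 / 21, tolerance = 1e-12)
  expect_gte(p[1], 0.95)
  # brute-force normalisation oracle
  le <- c(0, -1, -2)
  expect_equal(model_posterior(le), exp(le) / sum(exp(le)))
  # invariance to adding a constant
  expect_equal(model_posterior(le + 123.4), model_posterior(le))
  # no overflow for large log evidences
  big <- c(1e4, 1e4 - 3, -1e4)
  expect_simplex(model_posterior(big))
  expect_error(model_posterior(c(0, NA)), "finite")
  expect_error(model_posterior(c(0, 0), prior = c(0.5, 0.4)), "sum to 1")
})

test_that("Bayes factors multiply across subjects into the group Bayes factor", {
  expect_equal(bayes_factor(0, 0), 1)
  expect_equal(bayes_factor(log(20), 0), 20)
  expect_equal(bayes_factor(0, log(4)), 0.25)
  expect_equal(bayes_factor(1.3, 0.2), 1 / bayes_factor(0.2, 1.3))

  # N subjects each with BF 2 -> GBF 2^N
  N <- 6
  L <- matrix(c(rep(log(2), N), rep(0, N)), N, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(group_bayes_factor(L, "a", "b"), 2^N)
  # consistency with the joint evidence
  withr::with_seed(2, L2 <- matrix(rnorm(12), 4, 3))
  colnames(L2) <- c("x", "y", "z")
  jle <- joint_log_evidence(L2)
  expect_equal(group_bayes_factor(L2, 1, 3), unname(bayes_factor(jle[1], jle[3])))
  # single subject reduces to the plain Bayes factor
  expect_equal(group_bayes_factor(L2[1, , drop = FALSE], 1, 2),
               unname(bayes_factor(L2[1, 1], L2[1, 2])))
  expect_warning(group_bayes_factor(L2, 2, 2), "itself")
})

test_that("posterior odds are prior odds times the Bayes factor", {
  expect_equal(posterior_odds(1, 20), 20)
  expect_equal(posterior_odds(0.5, 4), 2)
  expect_equal(posterior_odds(0.37, 5.2) / 0.37, 5.2)
  expect_error(posterior_odds(0, 2), "positive")
  expect_error(posterior_odds(1, -1), "positive")
})

test_that("family-uniform model prior equalises family prior mass", {
  part <- family_partition(paste0("m", 1:4), c("x", "y", "y", "y"))
  pr <- family_uniform_model_prior(part)
  expect_equal(unname(pr), c(1 / 2, 1 / 6, 1 / 6, 1 / 6))
  # equal family sizes reduce to a flat prior
  eq <- family_partition(paste0("m", 1:4), c("x", "x", "y", "y"))
  expect_equal(unname(family_uniform_model_prior(eq)), rep(0.25, 4))
  # family marginals are all 1/K for arbitrary partitions
  withr::with_seed(3, {
    fam <- sample(letters[1:3], 20, replace = TRUE)
  })
  part2 <- family_partition(paste0("m", 1:20), fam)
  pr2 <- family_uniform_model_prior(part2)
  marg <- tapply(pr2, part2$family, sum)
  expect_equal(as.numeric(marg), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("family posteriors aggregate model posteriors", {
  single <- family_partition(c("a", "b"), c("all", "all"))
  fs <- ffx_family_posterior(c(a = 0.4, b = 0.6), single)
  expect_equal(fs$posterior, 1)
  expect_equal(fs$alternative_prob, 0)

  part <- family_partition(paste0("m", 1:3), c("one", "two", "two"))
  fs2 <- ffx_family_posterior(c(m1 = 0.6, m2 = 0.3, m3 = 0.1), part)
  expect_equal(fs2$posterior, c(0.6, 0.4))
  expect_equal(fs2$log_posterior[1], 0)

  # group-by-sum oracle on random posteriors
  withr::with_seed(4, {
    x <- runif(12)
    post <- setNames(x / sum(x), paste0("m", 1:12))
    fam <- sample(c("u", "v", "w"), 12, replace = TRUE)
  })
  part3 <- family_partition(names(post), fam)
  fs3 <- ffx_family_posterior(post, part3)
  oracle <- vapply(family_names(part3),
                   function(f) sum(post[part3$model[part3$family == f]]),
                   numeric(1))
  expect_equal(fs3$posterior, unname(oracle))
  expect_error(ffx_family_posterior(c(a = 0.5, b = 0.4), single), "sum to 1")
})

test_that("FFX model ranking is invariant to the comparison set", {
  withr::with_seed(5, {
    L <- matrix(rnorm(8 * 10, sd = 2), 8, 10,
                dimnames = list(paste0("s", 1:8), paste0("m", 1:10)))
    fit_full <- bms_ffx(L)
    post_full <- setNames(fit_full$models$posterior, fit_full$models$model)
    for (i in 1:5) {
      keep <- sort(sample(setdiff(1:10, c(2, 7)), 5))
      sub <- L[, c(2, 7, keep)]
      fit_sub <- bms_ffx(sub)
      post_sub <- setNames(fit_sub$models$posterior, fit_sub$models$model)
      expect_equal(post_sub[["m2"]] / post_sub[["m7"]],
                   post_full[["m2"]] / post_full[["m7"]],
                   tolerance = 1e-9)
    }
  })
})

test_that("bms_ffx with family-uniform prior is unbiased under flat evidence", {
  L <- matrix(0, 4, 8, dimnames = list(paste0("s", 1:4), paste0("m", 1:8)))
  part <- family_partition(paste0("m", 1:8),
                           rep(c("big", "small"), c(6, 2)))
  fit <- bms_ffx(L, partition = part, prior = "family-uniform")
  expect_equal(fit$families$posterior, c(0.5, 0.5), tolerance = 1e-12)
  # under a flat *model* prior the big family would soak up 6/8
  fit_flat <- bms_ffx(L, partition = part)
  expect_equal(fit_flat$families$posterior, c(6 / 8, 2 / 8), tolerance = 1e-12)
})

test_that("bms_ffx reports log posteriors normalised to the best family", {
  withr::with_seed(6, {
    L <- matrix(rnorm(3 * 6, sd = 5), 3, 6,
                dimnames = list(paste0("s", 1:3), paste0("m", 1:6)))
  })
  part <- family_partition(paste0("m", 1:6), rep(c("a", "b", "c"), each = 2))
  fit <- bms_ffx(L, partition = part)
  expect_equal(max(fit$families$log_posterior), 0)
  expect_simplex(fit$models$posterior, tol = 1e-10)
  expect_simplex(fit$families$posterior, tol = 1e-10)
  expect_equal(fit$families$alternative_prob, 1 - fit$families$posterior)
  expect_s3_class(tidy(fit, "family"), "tbl_df")
  expect_equal(glance(fit)$n_families, 3)
})

test_that("missing evidence cells are an error, not imputed", {
  L <- matrix(c(1, NA, 0, 2), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(bms_ffx(L), "s2.*a|a.*s2")
})
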