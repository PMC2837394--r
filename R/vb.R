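# Variational alternative to the Gibbs sampler: a fixed-point iteration on
# Dirichlet posterior counts with digamma-weighted assignment
# responsibilities. Fast and accurate when all prior counts are >= 1, but
# known to misbehave for the small fractional counts that family-uniform
# priors require — hence the prominent warning steering users to Gibbs.

#' Variational fixed-point update for model frequencies
#'
#' Iterates: responsibilities `g_nm` proportional to
#' `exp(L_nm + digamma(alpha_m) - digamma(sum(alpha)))` normalised per
#' subject, then `alpha = alpha0 + colSums(g)`, until the largest change in
#' `alpha` falls below `tol`. The approximate posterior over frequencies is
#' `Dirichlet(alpha)`.
#'
#' @inheritParams joint_log_evidence
#' @param alpha0 Dirichlet prior counts; defaults to unit counts.
#' @param tol Convergence tolerance on `max(abs(delta alpha))`.
#' @param max_iter Iteration cap; non-convergence warns and returns the
#'   best iterate.
#' @return List with `alpha` (posterior counts), `g` (responsibilities),
#'   `expected_r = alpha / sum(alpha)`, `n_iter`, `converged`.
#' @export
vb_update <- function(evidence, alpha0 = NULL, tol = 1e-6, max_iter = 500) {
  L <- as_evidence_matrix(evidence)
  alpha0 <- check_alpha0(alpha0, colnames(L))
  warn_small_alpha0(alpha0)
  N <- nrow(L)
  alpha <- alpha0 + N / length(alpha0)
  converged <- FALSE
  g <- NULL
  for (it in seq_len(max_iter)) {
    e_log_r <- digamma(alpha) - digamma(sum(alpha))
    g <- row_softmax_log(L + rep(e_log_r, each = N))
    alpha_new <- alpha0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "Variational update did not converge in %d iterations; returning the final iterate.",
      max_iter))
  }
  list(alpha = alpha, g = g, expected_r = alpha / sum(alpha),
       n_iter = it, converged = converged)
}

warn_small_alpha0 <- function(alpha0) {
  if (min(alpha0) < 1) {
    warn(paste(
      "Variational inference is unreliable for Dirichlet prior counts below 1",
      sprintf("(min alpha0 = %.4g here, as arises with family-uniform priors).", min(alpha0)),
      "Use method = \"gibbs\" for trustworthy posteriors.",
      sep = "\n"), class = "groupbms_vb_small_alpha0")
  }
}

#' Variational posterior in the sampler's result format
#'
#' Runs [vb_update()] and packages the result like [gibbs_sample()] output:
#' expected frequencies from the Dirichlet posterior counts, plus
#' `n_samples` Monte-Carlo draws from that Dirichlet (seeded) so that
#' exceedance probabilities and family aggregation work identically for
#' both methods.
#'
#' @inheritParams vb_update
#' @param seed Integer seed for the Dirichlet draws.
#' @param n_samples Number of Dirichlet draws used for exceedance and
#'   family summaries.
#' @return An `rfx_posterior` list (see [gibbs_sample()]).
#' @export
vb_posterior <- function(evidence, alpha0 = NULL, seed = 1, n_samples = 10000,
                         tol = 1e-6, max_iter = 500) {
  L <- as_evidence_matrix(evidence)
  fit <- vb_update(L, alpha0 = alpha0, tol = tol, max_iter = max_iter)
  n_samples <- check_count(n_samples, "n_samples")
  seed <- check_count(seed, "seed", min = 0L)
  r_samples <- withr::with_seed(seed, {
    t(vapply(seq_len(n_samples), function(i) rdirichlet_safe(fit$alpha),
             numeric(length(fit$alpha))))
  })
  colnames(r_samples) <- colnames(L)
  structure(
    list(
      r_samples = r_samples,
      g = fit$g,
      expected_r = setNames(fit$expected_r, colnames(L)),
      exceedance = exceedance_from_samples(r_samples),
      mcse_r = batch_mcse(r_samples),
      alpha0 = check_alpha0(alpha0, colnames(L)),
      alpha = fit$alpha,
      n_total = n_samples, burn_in = 0L, seed = seed,
      converged = fit$converged, n_iter = fit$n_iter,
      method = "vb"
    ),
    class = "rfx_posterior"
  )
}
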