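# Random-effects (RFX) group inference: each subject's generating model is a
# draw from unknown population frequencies r, with a Dirichlet prior over r
# and multinomial model assignments. The posterior over r is obtained by
# Gibbs sampling the conditionals: per-subject assignment probabilities given
# r (evidence-weighted, normalised in log space), one-hot assignment draws,
# and a conjugate Dirichlet update of r given the assignment counts.

#' Default Dirichlet prior over model frequencies
#'
#' Unit prior count for every model: each model behaves as if observed once
#' a priori, giving prior expected frequency `1/M`.
#'
#' @param M Number of models.
#' @return Numeric vector of `M` ones.
#' @export
default_model_prior <- function(M) {
  M <- check_count(M, "M")
  rep(1, M)
}

#' Family-uniform Dirichlet prior over model frequencies
#'
#' Prior count `alpha_m = 1/N_k` for a model in family `k` of size `N_k`,
#' so each family's total prior count is 1 and the implied prior over family
#' frequencies is the symmetric Dirichlet(1, ..., 1) — uniform on the family
#' simplex regardless of how unequal the family sizes are. Note these counts
#' drop below 1 as families grow, which is exactly the regime where the
#' variational method is unreliable and Gibbs sampling should be used.
#'
#' @param partition A `bms_partition`.
#' @return Named numeric vector of prior counts over the partition's models.
#' @export
family_uniform_prior <- function(partition) {
  sz <- family_sizes(partition)
  setNames(as.numeric(1 / sz[partition$family]), partition$model)
}

# One Dirichlet draw that stays away from exact zeros for shapes < 1.
# Shapes >= 1 use rgamma directly; shapes < 1 use the shape-boosting
# identity Gamma(a) == Gamma(a + 1) * U^(1/a) evaluated in log space, which
# avoids the underflow-to-zero that plain rgamma suffers for tiny shapes.
# Any residual zero is clamped to the smallest positive double before
# normalisation.
rdirichlet_safe <- function(alpha) {
  M <- length(alpha)
  lg <- numeric(M)
  small <- alpha < 1
  if (any(!small)) {
    lg[!small] <- log(rgamma(sum(!small), shape = alpha[!small], rate = 1))
  }
  if (any(small)) {
    a <- alpha[small]
    lg[small] <- log(rgamma(sum(small), shape = a + 1, rate = 1)) +
      log(runif(sum(small))) / a
  }
  r <- exp(lg - logsumexp(lg))
  r[r == 0 | !is.finite(r)] <- .Machine$double.xmin
  r / sum(r)
}

#' Gibbs sampler for posterior model frequencies
#'
#' Iterates the conditional updates of the Dirichlet-multinomial generative
#' model: (i) per-subject posterior assignment weights
#' `g_nm` proportional to `exp(L_nm) * r_m`, computed by subtracting the
#' per-subject row maximum of `L_nm + log r_m` before exponentiation;
#' (ii) a one-hot model assignment draw per subject; (iii) assignment
#' counts; (iv) a conjugate Dirichlet draw of `r` from prior counts plus
#' assignment counts. The initial `r` is drawn from the prior. Draws after
#' the burn-in are retained unthinned; Monte-Carlo standard errors are
#' reported from batch means.
#'
#' @inheritParams joint_log_evidence
#' @param alpha0 Dirichlet prior counts (length = number of models);
#'   defaults to [default_model_prior()].
#' @param n_total Total sweeps.
#' @param burn_in Sweeps discarded from the start of the chain
#'   (`n_total > burn_in >= 0`).
#' @param seed Integer seed; recorded in the result for exact reproduction.
#' @return A list with `r_samples` (retained draws, rows on the simplex),
#'   `g` (subjects x models posterior assignment probabilities averaged over
#'   retained sweeps), `expected_r`, `exceedance` (probability each model's
#'   frequency is strictly the largest), `mcse_r`, and the sampler settings.
#' @export
gibbs_sample <- function(evidence, alpha0 = NULL, n_total = 30000,
                         burn_in = 10000, seed = 1) {
  L <- as_evidence_matrix(evidence)
  N <- nrow(L); M <- ncol(L)
  alpha0 <- check_alpha0(alpha0, colnames(L))
  n_total <- check_count(n_total, "n_total")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  if (n_total <= burn_in) abort("`n_total` must exceed `burn_in`.")
  seed <- check_count(seed, "seed", min = 0L)

  S <- n_total - burn_in
  r_samples <- matrix(NA_real_, S, M, dimnames = list(NULL, colnames(L)))
  g_sum <- matrix(0, N, M, dimnames = dimnames(L))

  withr::with_seed(seed, {
    r <- rdirichlet_safe(alpha0)
    for (t in seq_len(n_total)) {
      logw <- L + rep(log(r), each = N)
      g <- row_softmax_log(logw)
      u <- runif(N)
      idx <- integer(N)
      for (n in seq_len(N)) {
        idx[n] <- min(M, 1L + findInterval(u[n], cumsum(g[n, ])))
      }
      beta <- tabulate(idx, nbins = M)
      r <- rdirichlet_safe(alpha0 + beta)
      if (t > burn_in) {
        r_samples[t - burn_in, ] <- r
        g_sum <- g_sum + g
      }
    }
  })

  g_bar <- g_sum / S
  structure(
    list(
      r_samples = r_samples,
      g = g_bar,
      expected_r = colMeans(r_samples),
      exceedance = exceedance_from_samples(r_samples),
      mcse_r = batch_mcse(r_samples),
      alpha0 = alpha0,
      n_total = n_total, burn_in = burn_in, seed = seed,
      method = "gibbs"
    ),
    class = "rfx_posterior"
  )
}

check_alpha0 <- function(alpha0, labels) {
  M <- length(labels)
  if (is.null(alpha0)) return(setNames(default_model_prior(M), labels))
  if (length(alpha0) != M) abort("`alpha0` length must match the number of models.")
  if (!is.numeric(alpha0) || any(!is.finite(alpha0)) || any(alpha0 <= 0)) {
    abort("`alpha0` must be strictly positive prior counts.")
  }
  if (!is.null(names(alpha0))) {
    if (!setequal(names(alpha0), labels)) abort("`alpha0` names do not match the model labels.")
    alpha0 <- alpha0[labels]
  } else {
    names(alpha0) <- labels
  }
  alpha0
}

#' Exceedance probabilities from posterior frequency draws
#'
#' Fraction of draws in which column `j` is the strict maximum: the
#' posterior belief that model (or family) `j` is more frequent in the
#' population than every alternative. With two columns this reduces to
#' `P(r_1 > r_2)` and the two exceedances sum to 1. Tied draws (possible
#' only for degenerate duplicated values) count towards no column.
#'
#' @param samples Draws-by-columns matrix of frequency vectors (rows on the
#'   probability simplex).
#' @return Named numeric vector of exceedance probabilities.
#' @export
exceedance_from_samples <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) abort("`samples` must contain at least one draw.")
  if (ncol(samples) == 1L) return(setNames(1, colnames(samples)))
  mx <- samples[cbind(seq_len(nrow(samples)),
                      max.col(samples, ties.method = "first"))]
  is_max <- samples == mx              # recycles mx down rows
  strict <- rowSums(is_max) == 1L
  setNames(colMeans(is_max & strict), colnames(samples))
}

#' Random-effects group inference on model (and family) frequencies
#'
#' Front end to the Gibbs sampler (default) or its variational alternative.
#' With `prior = "family-uniform"` the Dirichlet prior counts are set to
#' `1/N_k` per model so that family frequencies have a uniform prior; this
#' is required for unbiased family-level inference with unequal family
#' sizes. When a partition is supplied the family-level posterior (expected
#' family frequencies and family exceedance probabilities) is computed by
#' aggregating the retained frequency draws within families.
#'
#' @inheritParams joint_log_evidence
#' @param partition Optional `bms_partition` over the model columns.
#' @param prior `"flat"` (unit counts), `"family-uniform"` (requires
#'   `partition`), or a numeric vector of Dirichlet prior counts.
#' @param method `"gibbs"` (default) or `"vb"`. The variational method is
#'   fast for small model sets but inaccurate whenever any prior count is
#'   below 1 (it then warns and recommends Gibbs).
#' @param n_samples Total Gibbs sweeps (default 30000).
#' @param burn_in Discarded initial sweeps (default 10000).
#' @param seed Integer seed recorded in the result.
#' @param ... Further arguments to [vb_update()] (`tol`, `max_iter`).
#' @return A `bms_rfx` object; see [tidy()], [glance()], [autoplot()].
#' @examples
#' sim <- simulate_group_evidence(n_subjects = 12, true_freqs = c(0.7, 0.3),
#'                                margin = 8, seed = 5)
#' fit <- bms_rfx(sim$evidence, n_samples = 2000, burn_in = 500, seed = 5)
#' tidy(fit)
#' @export
bms_rfx <- function(evidence, partition = NULL, prior = c("flat", "family-uniform"),
                    method = c("gibbs", "vb"), n_samples = 30000,
                    burn_in = 10000, seed = 1, ...) {
  L <- as_evidence_matrix(evidence)
  method <- match.arg(method)
  if (is.character(prior)) {
    prior_type <- match.arg(prior)
    if (prior_type == "family-uniform") {
      if (is.null(partition)) abort("`prior = \"family-uniform\"` needs a `partition`.")
      check_partition(partition, colnames(L))
      alpha0 <- family_uniform_prior(partition)
    } else {
      alpha0 <- NULL
    }
  } else {
    prior_type <- "custom"
    alpha0 <- prior
  }

  post <- if (method == "gibbs") {
    gibbs_sample(L, alpha0 = alpha0, n_total = n_samples,
                 burn_in = burn_in, seed = seed)
  } else {
    vb_posterior(L, alpha0 = alpha0, seed = seed, n_samples = n_samples, ...)
  }

  families <- if (!is.null(partition)) family_posterior(post, partition) else NULL

  structure(
    list(posterior = post, families = families, partition = partition,
         prior_type = prior_type, method = method,
         n_subjects = nrow(L), model_labels = colnames(L)),
    class = "bms_rfx"
  )
}

#' Family-level posterior from model-frequency draws
#'
#' Aggregates each retained frequency draw within families
#' (`s_k = sum of r_m over models m in family k`) and computes expected
#' family frequencies and family exceedance probabilities from the
#' aggregated draws.
#'
#' @param post An `rfx_posterior` (from [gibbs_sample()] or [vb_posterior()])
#'   or a `bms_rfx` fit.
#' @param partition A `bms_partition` covering all models.
#' @return An `rfx_family_posterior` list with `s_samples`, `expected_s`,
#'   `exceedance`, `mcse_s`.
#' @export
family_posterior <- function(post, partition) {
  if (inherits(post, "bms_rfx")) post <- post$posterior
  if (!inherits(post, "rfx_posterior")) {
    abort("`post` must come from `gibbs_sample()`, `vb_posterior()` or `bms_rfx()`.")
  }
  ind <- family_indicator(partition, colnames(post$r_samples))
  s_samples <- post$r_samples %*% ind
  structure(
    list(
      s_samples = s_samples,
      expected_s = colMeans(s_samples),
      exceedance = exceedance_from_samples(s_samples),
      mcse_s = batch_mcse(s_samples),
      family_names = colnames(ind),
      sizes = as.integer(colSums(ind))
    ),
    class = "rfx_family_posterior"
  )
}

#' @export
print.bms_rfx <- function(x, ...) {
  p <- x$posterior
  cat(sprintf(
    "Random-effects model inference (%s): %d subjects, %d models (prior: %s)\n",
    x$method, x$n_subjects, length(x$model_labels), x$prior_type))
  ib <- which.max(p$expected_r)
  cat(sprintf("  best model: %s (expected frequency %.3f, exceedance %.3f)\n",
              x$model_labels[ib], p$expected_r[ib], p$exceedance[ib]))
  if (!is.null(x$families)) {
    f <- x$families
    fb <- which.max(f$expected_s)
    cat(sprintf("  best family: %s (expected frequency %.3f, exceedance %.3f)\n",
                f$family_names[fb], f$expected_s[fb], f$exceedance[fb]))
  }
  invisible(x)
}

#' Tidy an RFX fit
#'
#' @param x A `bms_rfx` object.
#' @param level `"model"` or `"family"`.
#' @param ... Unused.
#' @return A tibble with expected frequencies, exceedance probabilities and
#'   Monte-Carlo standard errors.
#' @method tidy bms_rfx
#' @export
tidy.bms_rfx <- function(x, level = c("model", "family"), ...) {
  level <- match.arg(level)
  if (level == "family") {
    if (is.null(x$families)) abort("No partition was supplied to `bms_rfx()`.")
    f <- x$families
    return(tibble::tibble(
      family = f$family_names, size = f$sizes,
      expected_freq = as.numeric(f$expected_s),
      exceedance = as.numeric(f$exceedance),
      mcse = as.numeric(f$mcse_s)
    ))
  }
  p <- x$posterior
  tibble::tibble(
    model = x$model_labels,
    expected_freq = as.numeric(p$expected_r),
    exceedance = as.numeric(p$exceedance),
    mcse = as.numeric(p$mcse_r)
  )
}

#' @method glance bms_rfx
#' @export
glance.bms_rfx <- function(x, ...) {
  p <- x$posterior
  ib <- which.max(p$expected_r)
  out <- tibble::tibble(
    n_subjects = x$n_subjects,
    n_models = length(x$model_labels),
    method = x$method,
    prior = x$prior_type,
    n_retained = nrow(p$r_samples),
    seed = p$seed,
    best_model = x$model_labels[ib],
    best_model_expected_freq = as.numeric(p$expected_r[ib]),
    best_model_exceedance = as.numeric(p$exceedance[ib])
  )
  if (!is.null(x$families)) {
    fb <- which.max(x$families$expected_s)
    out$best_family <- x$families$family_names[fb]
    out$best_family_expected_freq <- as.numeric(x$families$expected_s[fb])
    out$best_family_exceedance <- as.numeric(x$families$exceedance[fb])
  }
  out
}

#' @method autoplot bms_rfx
#' @export
autoplot.bms_rfx <- function(object, level = c("model", "family"), top = 20, ...) {
  level <- match.arg(level)
  if (level == "family" && is.null(object$families)) level <- "model"
  df <- tidy(object, level = level)
  df$item <- df[[1L]]
  df <- dplyr::slice_max(df, .data$expected_freq, n = top)
  long <- tidyr::pivot_longer(df[, c("item", "expected_freq", "exceedance")],
                              c("expected_freq", "exceedance"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$item, -.data$value),
                                     y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = level, y = NULL,
                  title = sprintf("RFX %s posterior summaries", level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
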