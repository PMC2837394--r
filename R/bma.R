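# Bayesian model averaging within a family: the marginal posterior over
# parameters is a mixture over models of subject-specific Gaussian
# posteriors, plus point mass at zero from models that fix a parameter to
# zero a priori. The mixture is evaluated by sampling: draw a model (per
# subject under RFX, one shared draw for all subjects under FFX), draw a
# parameter vector from that subject/model Gaussian, and average over
# subjects. Occam's window prunes negligible models for speed only.

#' Bundle per-subject, per-model Gaussian parameter posteriors
#'
#' @param parameters Character vector of shared parameter names (length P).
#' @param subjects,models Character vectors of subject ids and model labels.
#' @param cells Nested list `cells[[subject]][[model]]`, each a list with
#'   `mean` (length P), `cov` (P x P), and `free` (length P of 0/1; 0 means
#'   the model fixes that parameter to zero a priori). Masked-out rows and
#'   columns of `cov`, and masked-out means, must be zero.
#' @return A `subject_posteriors` object.
#' @export
subject_posteriors <- function(parameters, subjects, models, cells) {
  parameters <- as.character(parameters)
  subjects <- as.character(subjects)
  models <- as.character(models)
  P <- length(parameters)
  if (anyDuplicated(parameters)) abort("Parameter names must be unique.")
  if (length(cells) != length(subjects)) {
    abort("`cells` must have one entry per subject.")
  }
  for (n in seq_along(subjects)) {
    if (length(cells[[n]]) != length(models)) {
      abort(sprintf("Subject '%s' is missing model cells; the grid must be complete.",
                    subjects[n]))
    }
    for (m in seq_along(models)) {
      cell <- cells[[n]][[m]]
      if (!all(c("mean", "cov", "free") %in% names(cell))) {
        abort("Each cell needs `mean`, `cov` and `free`.")
      }
      if (length(cell$mean) != P || length(cell$free) != P ||
          !all(dim(cell$cov) == c(P, P))) {
        abort(sprintf("Dimension mismatch in cell (%s, %s).", subjects[n], models[m]))
      }
      if (max(abs(cell$cov - t(cell$cov))) > 1e-10) {
        abort(sprintf("Covariance not symmetric in cell (%s, %s).", subjects[n], models[m]))
      }
      fixed <- cell$free == 0
      if (any(cell$mean[fixed] != 0) ||
          any(cell$cov[fixed, , drop = FALSE] != 0) ||
          any(cell$cov[, fixed, drop = FALSE] != 0)) {
        abort(sprintf(
          "Masked-out parameters must have zero mean and covariance in cell (%s, %s).",
          subjects[n], models[m]))
      }
    }
    names(cells[[n]]) <- models
  }
  names(cells) <- subjects
  structure(list(parameters = parameters, subjects = subjects,
                 models = models, cells = cells),
            class = "subject_posteriors")
}

#' @export
print.subject_posteriors <- function(x, ...) {
  cat(sprintf("Subject parameter posteriors: %d subjects x %d models, %d parameters\n",
              length(x$subjects), length(x$models), length(x$parameters)))
  invisible(x)
}

#' Occam's window over a set of model probabilities
#'
#' Keeps model `j` when its posterior odds against the best model exceed
#' the minimal ratio: `p_j / max(p) > pi_occ`. The best model is always
#' retained; `pi_occ = 1` keeps only maximal models and values near 0 keep
#' everything with nonzero probability. Windowing is a computational
#' pruning device only — it changes which mixture components are sampled,
#' never the model posteriors themselves.
#'
#' @param post_probs Named or unnamed nonnegative weights over candidate
#'   models (need not be normalised).
#' @param pi_occ Minimal posterior odds ratio in (0, 1].
#' @return List with `included` (indices into `post_probs`), `weights`
#'   (renormalised over the window), `pi_occ`, `window_size`.
#' @examples
#' occams_window(c(0.5, 0.3, 0.03), pi_occ = 1 / 20)
#' @export
occams_window <- function(post_probs, pi_occ = 1 / 20) {
  if (length(post_probs) == 0L) abort("`post_probs` must be non-empty.")
  if (any(post_probs < 0) || sum(post_probs) <= 0) {
    abort("`post_probs` must be nonnegative with positive sum.")
  }
  if (pi_occ <= 0 || pi_occ > 1) abort("`pi_occ` must lie in (0, 1].")
  ratio <- post_probs / max(post_probs)
  included <- which(ratio > pi_occ | ratio == 1)
  w <- post_probs[included] / sum(post_probs[included])
  list(included = included, weights = w, pi_occ = pi_occ,
       window_size = length(included))
}

# Sampling factor for one Gaussian cell restricted to its free parameters.
# Symmetric eigendecomposition square root; tiny negative eigenvalues from
# numerically indefinite variational covariances are clamped to zero,
# genuinely negative ones are an error.
gaussian_factor <- function(cell, who = "") {
  free <- which(cell$free == 1)
  if (length(free) == 0L) {
    return(list(free = free, mu = numeric(0), A = matrix(0, 0, 0)))
  }
  C <- cell$cov[free, free, drop = FALSE]
  e <- eigen(C, symmetric = TRUE)
  mx <- max(abs(e$values), 0)
  if (any(e$values < -1e-6 * max(mx, 1))) {
    abort(sprintf("Covariance%s is not positive semi-definite.",
                  if (nzchar(who)) paste0(" in cell ", who) else ""))
  }
  lam <- pmax(e$values, 0)
  lam[lam < 1e-10 * mx] <- pmax(lam[lam < 1e-10 * mx], 0)
  list(free = free, mu = cell$mean[free],
       A = e$vectors %*% diag(sqrt(lam), length(lam)))
}

# k draws (rows) from the cell's Gaussian on its free parameters, zeros
# elsewhere; returns k x P.
draw_cell <- function(fac, k, P) {
  out <- matrix(0, k, P)
  pf <- length(fac$free)
  if (pf > 0L && k > 0L) {
    Z <- matrix(rnorm(k * pf), pf, k)
    out[, fac$free] <- t(fac$mu + fac$A %*% Z)
  }
  out
}

# Resolve a family argument (NULL = all models, labels, or indices) to
# model labels of the posterior set.
resolve_family <- function(family, models) {
  if (is.null(family)) return(models)
  if (is.numeric(family)) {
    if (any(family < 1 | family > length(models))) abort("Family index out of range.")
    return(models[family])
  }
  unknown <- setdiff(family, models)
  if (length(unknown)) {
    abort(sprintf("Family refers to unknown model(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  as.character(family)
}

# Restrict a weight vector to the family, renormalise, window, renormalise.
windowed_weights <- function(w, models, fam, pi_occ, who = "weights") {
  if (!is.null(names(w))) w <- w[models]
  wf <- w[match(fam, models)]
  if (sum(wf) <= 0) {
    abort(sprintf("All %s are zero on the requested family; nothing to average.", who))
  }
  ow <- occams_window(wf / sum(wf), pi_occ = pi_occ)
  list(models = fam[ow$included], weights = as.numeric(ow$weights),
       window_size = ow$window_size)
}

#' Group-level Bayesian model averaging within a family
#'
#' Draws `n_samples` group-average parameter vectors from the
#' family-restricted mixture posterior. Under `mode = "rfx"` each subject
#' draws their own model from their posterior assignment probabilities
#' (rows of the `g` matrix), windowed per subject; under `mode = "ffx"` one
#' shared model is drawn per sample from the group model posterior and
#' applied to every subject. Each subject then contributes a draw from the
#' subject/model Gaussian (exact zeros for parameters the model fixes), and
#' the subject draws are averaged. The posterior mass at exactly zero is
#' tracked analytically from the realised model draws, not from comparing
#' floating-point samples to zero.
#'
#' @param posts A `subject_posteriors` set.
#' @param weights Model weights: under `"ffx"` a probability vector over
#'   the model labels (e.g. `tidy(bms_ffx(...))$posterior`); under `"rfx"`
#'   a subjects x models matrix of per-subject model probabilities (the `g`
#'   matrix of [bms_rfx()]).
#' @param mode `"rfx"` or `"ffx"`.
#' @param family Models to average over: labels, indices, or `NULL` for the
#'   whole space.
#' @param n_samples Number of mixture samples (default 10000).
#' @param pi_occ Occam's-window minimal posterior odds ratio (default 1/20).
#' @param seed Integer seed.
#' @return A `bma_density` with `theta_samples` (`n_samples` x P, exact
#'   zeros where the drawn models fix parameters), `zero_mass`, and window
#'   metadata; see [summarize_density()], [tidy()], [autoplot()].
#' @export
bma_group <- function(posts, weights, mode = c("rfx", "ffx"), family = NULL,
                      n_samples = 10000, pi_occ = 1 / 20, seed = 1) {
  mode <- match.arg(mode)
  n_samples <- check_count(n_samples, "n_samples")
  seed <- check_count(seed, "seed", min = 0L)
  fam <- resolve_family(family, posts$models)
  N <- length(posts$subjects)
  P <- length(posts$parameters)

  masks <- t(vapply(fam, function(m) posts$cells[[1L]][[m]]$free, numeric(P)))

  withr::with_seed(seed, {
    theta <- matrix(0, n_samples, P,
                    dimnames = list(NULL, posts$parameters))
    all_fixed <- matrix(TRUE, n_samples, P)
    window_sizes <- integer(N)
    if (mode == "ffx") {
      if (is.matrix(weights)) abort("`mode = \"ffx\"` expects a single weight vector.")
      ww <- windowed_weights(weights, posts$models, fam, pi_occ)
      window_sizes[] <- ww$window_size
      draw <- sample.int(length(ww$models), n_samples, replace = TRUE,
                         prob = ww$weights)
      for (k in seq_along(ww$models)) {
        idx <- which(draw == k)
        if (!length(idx)) next
        m <- ww$models[k]
        all_fixed[idx, ] <- rep(masks[m, ] == 0, each = length(idx))
        for (n in seq_len(N)) {
          fac <- gaussian_factor(posts$cells[[n]][[m]],
                                 paste0("(", posts$subjects[n], ", ", m, ")"))
          theta[idx, ] <- theta[idx, ] + draw_cell(fac, length(idx), P) / N
        }
      }
    } else {
      if (!is.matrix(weights) || nrow(weights) != N) {
        abort("`mode = \"rfx\"` expects a subjects x models weight matrix (the `g` matrix).")
      }
      if (is.null(colnames(weights))) colnames(weights) <- posts$models
      for (n in seq_len(N)) {
        ww <- windowed_weights(setNames(weights[n, ], colnames(weights)),
                               posts$models, fam, pi_occ,
                               who = sprintf("weights of subject '%s'", posts$subjects[n]))
        window_sizes[n] <- ww$window_size
        draw <- sample.int(length(ww$models), n_samples, replace = TRUE,
                           prob = ww$weights)
        for (k in seq_along(ww$models)) {
          idx <- which(draw == k)
          if (!length(idx)) next
          m <- ww$models[k]
          all_fixed[idx, ] <- all_fixed[idx, ] &
            rep(masks[m, ] == 0, each = length(idx))
          fac <- gaussian_factor(posts$cells[[n]][[m]],
                                 paste0("(", posts$subjects[n], ", ", m, ")"))
          theta[idx, ] <- theta[idx, ] + draw_cell(fac, length(idx), P) / N
        }
      }
    }
  })

  # the group average is exactly zero only when every subject's drawn model
  # fixed the parameter
  theta[all_fixed] <- 0
  new_bma_density(theta, colMeans(all_fixed), mode, fam, pi_occ, seed,
                  window_sizes, scope = "group")
}

#' Within-subject Bayesian model averaging
#'
#' Mixture posterior for a single subject: per sample, draw a model from
#' the subject's windowed weights and a parameter vector from that model's
#' Gaussian (no averaging over subjects). Summary statistics of these
#' densities can be exported per subject and entered into standard
#' random-effects tests across subjects.
#'
#' @inheritParams bma_group
#' @param subject Subject id or index.
#' @return A `bma_density` for that subject.
#' @export
bma_subject <- function(posts, weights, subject, mode = c("rfx", "ffx"),
                        family = NULL, n_samples = 10000, pi_occ = 1 / 20,
                        seed = 1) {
  mode <- match.arg(mode)
  n_samples <- check_count(n_samples, "n_samples")
  seed <- check_count(seed, "seed", min = 0L)
  if (is.character(subject)) {
    n <- match(subject, posts$subjects)
    if (is.na(n)) abort(sprintf("Unknown subject '%s'.", subject))
  } else {
    n <- check_count(subject, "subject")
    if (n > length(posts$subjects)) abort("Subject index out of range.")
  }
  fam <- resolve_family(family, posts$models)
  P <- length(posts$parameters)

  w <- if (mode == "rfx") {
    if (!is.matrix(weights)) abort("`mode = \"rfx\"` expects a weight matrix.")
    if (is.null(colnames(weights))) colnames(weights) <- posts$models
    setNames(weights[n, ], colnames(weights))
  } else {
    if (is.matrix(weights)) abort("`mode = \"ffx\"` expects a single weight vector.")
    weights
  }
  ww <- windowed_weights(w, posts$models, fam, pi_occ)

  withr::with_seed(seed, {
    theta <- matrix(0, n_samples, P, dimnames = list(NULL, posts$parameters))
    fixed <- matrix(TRUE, n_samples, P)
    draw <- sample.int(length(ww$models), n_samples, replace = TRUE,
                       prob = ww$weights)
    for (k in seq_along(ww$models)) {
      idx <- which(draw == k)
      if (!length(idx)) next
      m <- ww$models[k]
      cell <- posts$cells[[n]][[m]]
      fixed[idx, ] <- rep(cell$free == 0, each = length(idx))
      fac <- gaussian_factor(cell, paste0("(", posts$subjects[n], ", ", m, ")"))
      theta[idx, ] <- draw_cell(fac, length(idx), P)
    }
  })
  theta[fixed] <- 0
  new_bma_density(theta, colMeans(fixed), mode, fam, pi_occ, seed,
                  ww$window_size, scope = posts$subjects[n])
}

new_bma_density <- function(theta, zero_mass, mode, family, pi_occ, seed,
                            window_sizes, scope) {
  structure(
    list(theta_samples = theta,
         zero_mass = setNames(as.numeric(zero_mass), colnames(theta)),
         mode = mode, family = family, pi_occ = pi_occ, seed = seed,
         window_sizes = window_sizes, scope = scope),
    class = "bma_density"
  )
}

#' @export
print.bma_density <- function(x, ...) {
  cat(sprintf(
    "BMA posterior density (%s, %s): %d samples, %d parameters, %d models in family\n",
    x$mode, x$scope, nrow(x$theta_samples), ncol(x$theta_samples),
    length(x$family)))
  cat(sprintf("  Occam's window (pi = %.4g): %s models\n", x$pi_occ,
              paste(unique(range(x$window_sizes)), collapse = "-")))
  invisible(x)
}

#' Summarise a BMA posterior density
#'
#' Per-parameter posterior mean, equal-tailed credible interval from sample
#' quantiles, probability mass at exactly zero, and `P(parameter > 0)`.
#'
#' @param d A `bma_density`.
#' @param level Credible level (default 0.95).
#' @return Tibble with one row per parameter.
#' @export
summarize_density <- function(d, level = 0.95) {
  theta <- d$theta_samples
  if (nrow(theta) < 100L) abort("Need at least 100 samples to summarise a density.")
  a <- (1 - level) / 2
  qs <- apply(theta, 2L, quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    parameter = colnames(theta),
    mean = unname(colMeans(theta)),
    lower = unname(qs[1L, ]),
    upper = unname(qs[2L, ]),
    zero_mass = as.numeric(d$zero_mass),
    p_positive = unname(colMeans(theta > 0))
  )
}

#' @rdname summarize_density
#' @param x A `bma_density`.
#' @param ... Unused.
#' @method tidy bma_density
#' @export
tidy.bma_density <- function(x, level = 0.95, ...) summarize_density(x, level)

#' @method glance bma_density
#' @export
glance.bma_density <- function(x, ...) {
  tibble::tibble(
    scope = x$scope, mode = x$mode,
    n_samples = nrow(x$theta_samples),
    n_parameters = ncol(x$theta_samples),
    family_size = length(x$family),
    mean_window_size = mean(x$window_sizes),
    pi_occ = x$pi_occ, seed = x$seed
  )
}

#' @method autoplot bma_density
#' @export
autoplot.bma_density <- function(object, parameters = NULL, bins = 60, ...) {
  theta <- object$theta_samples
  if (!is.null(parameters)) theta <- theta[, parameters, drop = FALSE]
  long <- tidyr::pivot_longer(tibble::as_tibble(theta),
                              dplyr::everything(),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "samples",
                  title = sprintf("BMA posterior (%s); spikes at 0 are models fixing the parameter",
                                  object$scope)) +
    ggplot2::theme_minimal()
}
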