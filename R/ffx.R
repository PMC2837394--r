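# Fixed-effects (FFX) group inference: every subject is assumed to use the
# same model, so the group evidence for model m is the product of the
# per-subject evidences and the group log evidence is a plain sum over
# subjects. All arithmetic stays in log space until probabilities are
# materialised; Table-style log posteriors can differ by hundreds of log
# units, which would underflow naively.

#' Joint (group) log evidence under fixed effects
#'
#' Sums log evidences over subjects for each model: the log of the product
#' of per-subject model evidences.
#'
#' @param evidence Subjects-by-models log-evidence table: a numeric matrix
#'   with model column names, or a data frame whose first column is the
#'   subject id.
#' @return Named numeric vector, one joint log evidence per model.
#' @examples
#' L <- rbind(s1 = c(a = 0, b = -1), s2 = c(a = 0, b = -1))
#' joint_log_evidence(L)
#' @export
joint_log_evidence <- function(evidence) {
  L <- as_evidence_matrix(evidence)
  colSums(L)
}

#' Posterior model probabilities from joint log evidence
#'
#' Bayes rule on the model level: softmax of joint log evidence plus log
#' prior, computed via log-sum-exp.
#'
#' @param joint_log_ev Numeric vector of (joint) log evidences.
#' @param prior Optional prior model probabilities (positive, summing to 1);
#'   defaults to uniform.
#' @return Probability vector summing to 1, names preserved.
#' @examples
#' model_posterior(c(m1 = log(20), m2 = 0))  # BF 20 -> 20/21
#' @export
model_posterior <- function(joint_log_ev, prior = NULL) {
  if (!is.numeric(joint_log_ev) || !all(is.finite(joint_log_ev))) {
    abort("`joint_log_ev` must be finite numeric.")
  }
  log_prior <- check_model_prior(prior, length(joint_log_ev), names(joint_log_ev))
  softmax_log(joint_log_ev + log_prior)
}

# Validate a model prior and return its log, aligned to `labels` when both
# are named. NULL means uniform.
check_model_prior <- function(prior, M, labels = NULL) {
  if (is.null(prior)) return(rep(-log(M), M))
  if (length(prior) != M) abort("`prior` length must match the number of models.")
  if (!is.numeric(prior) || any(prior <= 0)) abort("`prior` must be strictly positive.")
  if (abs(sum(prior) - 1) > 1e-8) abort("`prior` must sum to 1.")
  if (!is.null(names(prior)) && !is.null(labels)) {
    if (!setequal(names(prior), labels)) abort("`prior` names do not match the model labels.")
    prior <- prior[labels]
  }
  log(prior)
}

#' Bayes factor between two models
#'
#' Ratio of model evidences, `exp(log_ev_i - log_ev_j)`. With only two
#' models and uniform priors the favoured model's posterior exceeds 0.95
#' exactly when the Bayes factor exceeds 20 (the conventional "strong
#' evidence" boundary).
#'
#' @param log_ev_i,log_ev_j Log evidences of the two models (vectorised).
#' @param log Return the log Bayes factor instead.
#' @return Positive numeric (or its log).
#' @examples
#' bayes_factor(log(20), 0)
#' @export
bayes_factor <- function(log_ev_i, log_ev_j, log = FALSE) {
  if (!all(is.finite(log_ev_i)) || !all(is.finite(log_ev_j))) {
    abort("Log evidences must be finite.")
  }
  lbf <- log_ev_i - log_ev_j
  if (log) lbf else exp(lbf)
}

#' Group Bayes factor
#'
#' Product over subjects of the per-subject Bayes factors comparing models
#' `i` and `j`; equivalently the exponentiated sum of per-subject
#' log-evidence differences. The fixed-effects group comparison statistic.
#'
#' @inheritParams joint_log_evidence
#' @param i,j Model columns: labels or indices.
#' @param log Return the log group Bayes factor instead.
#' @return Positive numeric (or its log).
#' @export
group_bayes_factor <- function(evidence, i, j, log = FALSE) {
  L <- as_evidence_matrix(evidence)
  ii <- resolve_model(i, colnames(L))
  jj <- resolve_model(j, colnames(L))
  if (ii == jj) {
    warn("Comparing a model with itself; group Bayes factor is 1 by definition.")
  }
  bayes_factor(sum(L[, ii]), sum(L[, jj]), log = log)
}

resolve_model <- function(i, labels) {
  if (is.character(i)) {
    k <- match(i, labels)
    if (is.na(k)) abort(sprintf("Unknown model label '%s'.", i))
    return(k)
  }
  k <- check_count(i, "model index")
  if (k > length(labels)) abort("Model index out of range.")
  k
}

#' Posterior odds from prior odds and a Bayes factor
#'
#' @param prior_odds,bf Positive numerics (vectorised).
#' @return `bf * prior_odds`.
#' @examples
#' posterior_odds(1, 20)
#' @export
posterior_odds <- function(prior_odds, bf) {
  if (any(prior_odds <= 0) || any(bf <= 0)) {
    abort("`prior_odds` and `bf` must be strictly positive.")
  }
  bf * prior_odds
}

#' Family-uniform prior over models
#'
#' Model prior `p(m) = 1 / (K * N_k)` for a model in family `k` of size
#' `N_k`, so that each family's prior mass is exactly `1/K`. This is the
#' prior that removes dilution bias from family-level fixed-effects
#' inference when family sizes are unequal.
#'
#' @param partition A `bms_partition`.
#' @return Named probability vector over the partition's models.
#' @examples
#' p <- family_partition(c("a", "b", "c", "d"), c("x", "y", "y", "y"))
#' family_uniform_model_prior(p)  # 1/2, 1/6, 1/6, 1/6
#' @export
family_uniform_model_prior <- function(partition) {
  sz <- family_sizes(partition)
  K <- length(sz)
  pr <- 1 / (K * sz[partition$family])
  setNames(as.numeric(pr), partition$model)
}

#' Family posteriors by aggregation of model posteriors
#'
#' Sums posterior model probabilities within each family and reports the
#' alternative probability (one minus the family posterior) together with a
#' display log posterior normalised so the best family sits at 0.
#'
#' @param model_post Named probability vector over models (sums to 1).
#' @param partition A `bms_partition` covering exactly those models.
#' @return Tibble with columns `family`, `size`, `posterior`,
#'   `alternative_prob`, `log_posterior`.
#' @export
ffx_family_posterior <- function(model_post, partition) {
  if (abs(sum(model_post) - 1) > 1e-8) abort("`model_post` must sum to 1.")
  labels <- names(model_post) %||% partition$model
  ind <- family_indicator(partition, labels)
  post <- as.numeric(model_post %*% ind)
  tibble::tibble(
    family = colnames(ind),
    size = as.integer(colSums(ind)),
    posterior = post,
    alternative_prob = 1 - post,
    log_posterior = log(post) - max(log(post))
  )
}

#' Fixed-effects group model and family inference
#'
#' Full FFX pipeline from a log-evidence table: joint log evidences (sums
#' over subjects), posterior model probabilities under the chosen prior and,
#' when a partition is supplied, family posteriors with alternative
#' probabilities. Family aggregation is performed in log space so that
#' families whose posteriors underflow to 0 still report finite log
#' posteriors.
#'
#' @inheritParams joint_log_evidence
#' @param partition Optional `bms_partition` over the model columns.
#' @param prior `"uniform"`, `"family-uniform"` (requires `partition`), or a
#'   numeric prior probability vector over models.
#' @return A `bms_ffx` object; see [tidy()] and [glance()] methods.
#' @examples
#' L <- rbind(s1 = c(m1 = 3, m2 = 0), s2 = c(m1 = 2, m2 = 0))
#' fit <- bms_ffx(L)
#' tidy(fit)
#' @export
bms_ffx <- function(evidence, partition = NULL, prior = c("uniform", "family-uniform")) {
  L <- as_evidence_matrix(evidence)
  labels <- colnames(L)
  if (is.character(prior)) {
    prior_type <- match.arg(prior)
    if (prior_type == "family-uniform") {
      if (is.null(partition)) abort("`prior = \"family-uniform\"` needs a `partition`.")
      prior_vec <- family_uniform_model_prior(partition)
    } else {
      prior_vec <- NULL
    }
  } else {
    prior_type <- "custom"
    prior_vec <- prior
  }
  log_prior <- check_model_prior(prior_vec, ncol(L), labels)

  jle <- colSums(L)
  log_post_unnorm <- jle + log_prior
  log_norm <- logsumexp(log_post_unnorm)
  log_post <- log_post_unnorm - log_norm
  post <- exp(log_post)

  models <- tibble::tibble(
    model = labels,
    joint_log_evidence = as.numeric(jle),
    prior = exp(log_prior),
    posterior = as.numeric(post),
    log_posterior = as.numeric(log_post - max(log_post))
  )

  families <- NULL
  if (!is.null(partition)) {
    ind <- family_indicator(partition, labels)
    fam_log_post <- apply(ind, 2L, function(mask) logsumexp(log_post[mask == 1]))
    fam_post <- exp(fam_log_post)
    families <- tibble::tibble(
      family = colnames(ind),
      size = as.integer(colSums(ind)),
      prior = as.numeric(exp(log_prior) %*% ind),
      posterior = as.numeric(fam_post),
      alternative_prob = 1 - as.numeric(fam_post),
      log_posterior = as.numeric(fam_log_post - max(fam_log_post))
    )
  }

  structure(
    list(models = models, families = families, prior_type = prior_type,
         n_subjects = nrow(L), partition = partition),
    class = "bms_ffx"
  )
}

#' @export
print.bms_ffx <- function(x, ...) {
  cat(sprintf("Fixed-effects model inference: %d subjects, %d models (prior: %s)\n",
              x$n_subjects, nrow(x$models), x$prior_type))
  best <- x$models[which.max(x$models$posterior), ]
  cat(sprintf("  best model: %s (posterior %.3f)\n", best$model, best$posterior))
  if (!is.null(x$families)) {
    bf <- x$families[which.max(x$families$posterior), ]
    cat(sprintf("  best family: %s (posterior %.3f, alternative probability %.3g)\n",
                bf$family, bf$posterior, bf$alternative_prob))
  }
  invisible(x)
}

#' Tidy an FFX fit
#'
#' @param x A `bms_ffx` object.
#' @param level `"model"` or `"family"`.
#' @param ... Unused.
#' @return A tibble of per-model or per-family posterior quantities.
#' @method tidy bms_ffx
#' @export
tidy.bms_ffx <- function(x, level = c("model", "family"), ...) {
  level <- match.arg(level)
  if (level == "family") {
    if (is.null(x$families)) abort("No partition was supplied to `bms_ffx()`.")
    return(x$families)
  }
  x$models
}

#' @method glance bms_ffx
#' @export
glance.bms_ffx <- function(x, ...) {
  ib <- which.max(x$models$posterior)
  out <- tibble::tibble(
    n_subjects = x$n_subjects,
    n_models = nrow(x$models),
    prior = x$prior_type,
    best_model = x$models$model[ib],
    best_model_posterior = x$models$posterior[ib]
  )
  if (!is.null(x$families)) {
    fb <- which.max(x$families$posterior)
    out$n_families <- nrow(x$families)
    out$best_family <- x$families$family[fb]
    out$best_family_posterior <- x$families$posterior[fb]
  }
  out
}

#' @method autoplot bms_ffx
#' @export
autoplot.bms_ffx <- function(object, level = c("family", "model"), top = 20, ...) {
  level <- match.arg(level)
  if (level == "family" && is.null(object$families)) level <- "model"
  df <- if (level == "family") {
    dplyr::rename(object$families, item = "family")
  } else {
    dplyr::slice_max(dplyr::rename(object$models, item = "model"),
                     .data$posterior, n = top)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$item, -.data$posterior),
                                   y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = level, y = "posterior probability",
                  title = sprintf("FFX %s posteriors", level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
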