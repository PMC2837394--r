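# Synthetic-data generators mirroring the Dirichlet-multinomial generative
# model: each subject's generating model is drawn from known population
# frequencies, and that model receives a fixed log-evidence advantage
# (margin) over a common baseline of 0, plus optional Gaussian noise. Only
# evidence *differences* matter to any downstream inference, so the
# baseline is arbitrary.

#' Simulate a group log-evidence matrix with known structure
#'
#' Assigns each subject a generating model (multinomial draw from
#' `true_freqs`, or explicitly via `assignments`), gives that model log
#' evidence `margin` and all others 0, and adds independent Gaussian noise
#' of standard deviation `noise_sd` to every cell. A margin of 10 log units
#' makes the per-subject preference decisive (posterior weight above
#' 0.9999), which is what makes closed-form conjugate checks exact.
#'
#' @param n_subjects Number of subjects.
#' @param true_freqs Population model frequencies (simplex vector, length =
#'   number of models); ignored when `assignments` is given.
#' @param assignments Optional integer vector of generating-model indices,
#'   one per subject.
#' @param n_models Number of models; inferred from `true_freqs` or
#'   `assignments` when omitted.
#' @param margin Log-evidence advantage of the generating model (default 10).
#' @param noise_sd Standard deviation of additive Gaussian noise (default 0).
#' @param seed Integer seed; generators are fully seed-deterministic.
#' @param model_labels,subject_ids Optional labels.
#' @return List with `evidence` (wide tibble: subject column plus one
#'   column per model), `assignments` (true generating model per subject),
#'   and the resolved settings.
#' @examples
#' sim <- simulate_group_evidence(n_subjects = 20,
#'                                true_freqs = c(0.6, 0.25, 0.15), seed = 1)
#' table(sim$assignments)
#' @export
simulate_group_evidence <- function(n_subjects, true_freqs = NULL,
                                    assignments = NULL, n_models = NULL,
                                    margin = 10, noise_sd = 0, seed = 1,
                                    model_labels = NULL, subject_ids = NULL) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (margin < 0) abort("`margin` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(true_freqs) && is.null(assignments)) {
    abort("Give either `true_freqs` or `assignments`.")
  }
  if (!is.null(true_freqs)) {
    if (any(true_freqs < 0) || abs(sum(true_freqs) - 1) > 1e-8) {
      abort("`true_freqs` must be a probability vector.")
    }
  }
  M <- n_models %||% (if (!is.null(true_freqs)) length(true_freqs) else max(assignments))
  M <- check_count(M, "n_models")
  if (!is.null(assignments)) {
    if (length(assignments) != n_subjects) {
      abort("`assignments` must have one entry per subject.")
    }
    if (any(assignments < 1 | assignments > M)) abort("`assignments` out of range.")
  }
  model_labels <- model_labels %||% paste0("m", seq_len(M))
  subject_ids <- subject_ids %||% sprintf("s%02d", seq_len(n_subjects))

  withr::with_seed(seed, {
    if (is.null(assignments)) {
      assignments <- sample.int(M, n_subjects, replace = TRUE, prob = true_freqs)
    }
    L <- matrix(0, n_subjects, M, dimnames = list(subject_ids, model_labels))
    L[cbind(seq_len(n_subjects), assignments)] <- margin
    if (noise_sd > 0) {
      L <- L + matrix(rnorm(n_subjects * M, sd = noise_sd), n_subjects, M)
    }
  })

  list(evidence = evidence_tibble(L),
       assignments = setNames(as.integer(assignments), subject_ids),
       margin = margin, noise_sd = noise_sd, seed = seed)
}

#' The two-then-three model comparison-set example
#'
#' A 17-subject group in which model 1 is decisively preferred by 7
#' subjects and model 2 by the remaining 10, plus a second variant in which
#' an added third model — very similar to model 2 — splits model 2's
#' supporters 6/4. All preferences share the same decisive margin. Under
#' random effects the best model flips from model 2 (variant 1) to model 1
#' (variant 2), while fixed-effects rankings of models 1 and 2 are
#' unaffected: the canonical illustration of why inference about shared
#' model characteristics (families) is more robust than picking a single
#' best model.
#'
#' The enlarged comparison set keeps the original models' evidences intact:
#' the third model's four supporters simply prefer it over model 2 by the
#' same decisive margin (so their model-2 evidence stays at its old value).
#' Deleting the third column of the enlarged matrix recovers the two-model
#' matrix exactly, which is what makes the fixed-effects ranking of models
#' 1 and 2 provably identical across the two sets.
#'
#' @param margin Shared decisive log-evidence margin (default 10).
#' @return List with `two_model` and `three_model` evidence tibbles and the
#'   per-variant true assignments.
#' @export
worked_example_comparison_set <- function(margin = 10) {
  a2 <- rep(c(1L, 2L), c(7L, 10L))
  a3 <- rep(c(1L, 2L, 3L), c(7L, 6L, 4L))
  two <- simulate_group_evidence(17, assignments = a2, n_models = 2,
                                 margin = margin, noise_sd = 0, seed = 0)
  L3 <- cbind(as.matrix(two$evidence[, -1L]), m3 = 0)
  rownames(L3) <- two$evidence$subject
  L3[a3 == 3L, "m3"] <- L3[a3 == 3L, "m2"] + margin
  list(two_model = two$evidence, three_model = evidence_tibble(L3),
       assignments = list(two_model = a2, three_model = a3))
}

#' Parameter names of a model space
#'
#' The flattened parameter grid used by the BMA fixtures: one modulatory
#' parameter `"B:src->dst:<input>"` per directed connection and one driving
#' parameter `"C:region:<input>"` per region.
#'
#' @param space A `bms_model_space`.
#' @param input_label Name of the experimental input (default `"u1"`).
#' @return Character vector of parameter names.
#' @export
space_parameters <- function(space, input_label = "u1") {
  regions <- attr(space, "region_labels")
  if (is.null(regions)) abort("`space` must be a `bms_model_space`.")
  conn <- connection_strings(matrix(1L, length(regions), length(regions),
                                    dimnames = list(regions, regions)) - diag(length(regions)))
  c(paste0("B:", conn, ":", input_label),
    paste0("C:", regions, ":", input_label))
}

#' Simulate subject/model Gaussian parameter posteriors
#'
#' Builds a complete subjects x models grid of Gaussian posteriors over the
#' space's parameter grid. In each model, exactly the parameters licensed by
#' its modulation and input patterns are free; free parameters get mean =
#' true effect plus per-subject Gaussian jitter and diagonal covariance
#' `post_sd^2`, masked parameters are fixed at zero.
#'
#' @param space A `bms_model_space`.
#' @param n_subjects Number of subjects.
#' @param effect Named numeric vector of true values for a subset of the
#'   parameter names (see [space_parameters()]); unnamed parameters default
#'   to 0. Unknown names are an error.
#' @param post_sd Posterior standard deviation for free parameters.
#' @param jitter_sd Standard deviation of the between-subject jitter of the
#'   posterior means (defaults to `post_sd`).
#' @param seed Integer seed.
#' @param input_label Experimental input label used in parameter names.
#' @return A `subject_posteriors` grid, plus the true effect vector as the
#'   `"true_effect"` attribute.
#' @export
simulate_parameter_posteriors <- function(space, n_subjects, effect = NULL,
                                          post_sd = 0.1, jitter_sd = post_sd,
                                          seed = 1, input_label = "u1") {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (post_sd < 0 || jitter_sd < 0) abort("`post_sd` and `jitter_sd` must be >= 0.")
  seed <- check_count(seed, "seed", min = 0L)
  params <- space_parameters(space, input_label)
  P <- length(params)
  truth <- setNames(numeric(P), params)
  if (!is.null(effect)) {
    if (is.null(names(effect))) abort("`effect` must be a named vector.")
    unknown <- setdiff(names(effect), params)
    if (length(unknown)) {
      abort(sprintf("Unknown parameter name(s) in `effect`: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
    truth[names(effect)] <- effect
  }

  masks <- t(vapply(seq_len(nrow(space)), function(i) {
    as.numeric(c(
      # B parameters follow the row-major order of connection_strings over
      # the all-to-all matrix, which matches space_parameters()
      model_free_B(space$mod_pattern[[i]]),
      space$input_pattern[[i]]
    ))
  }, numeric(P)))

  subjects <- sprintf("s%02d", seq_len(n_subjects))
  withr::with_seed(seed, {
    cells <- lapply(seq_len(n_subjects), function(n) {
      jitter <- rnorm(P, sd = jitter_sd)
      lapply(seq_len(nrow(space)), function(i) {
        free <- masks[i, ]
        mu <- unname((truth + jitter) * free)
        list(mean = mu, cov = diag(post_sd^2 * free, P), free = free)
      })
    })
  })
  out <- subject_posteriors(params, subjects, space$label, cells)
  attr(out, "true_effect") <- truth
  out
}

# Free-mask over B parameters for one modulation matrix, in the row-major
# "src->dst" order used by space_parameters().
model_free_B <- function(M) {
  all_conn <- connection_strings(matrix(1L, nrow(M), ncol(M),
                                        dimnames = dimnames(M)) - diag(nrow(M)))
  on <- connection_strings(M)
  as.numeric(all_conn %in% on)
}
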