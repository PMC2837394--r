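# Readers and writers for the package's plain-text interchange formats:
# delimited evidence matrices, YAML/JSON family configs, a JSON archive of
# subject/model Gaussian posteriors, and JSON result bundles. Numbers are
# serialised with full precision for lossless round trips; parsing is
# locale-independent (decimal point only).

#' Read a subjects-by-models log-evidence table
#'
#' Expects delimited text with a header row of model labels and a leading
#' subject-id column. Any blank, non-numeric or non-finite cell is rejected
#' with a diagnostic naming the subject and model.
#'
#' @param path File path (comma- or tab-separated, by extension).
#' @return Wide tibble: `subject` column plus one numeric column per model.
#' @export
read_evidence <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) abort("Evidence file needs a subject column plus model columns.")
  names(df)[1L] <- "subject"
  for (j in seq(2L, ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(col))
    if (length(bad)) {
      abort(sprintf("Bad log evidence for subject '%s', model '%s' in %s.",
                    df[[1L]][bad[1L]], names(df)[j], path))
    }
    df[[j]] <- col
  }
  evidence_tibble(as_evidence_matrix(as.data.frame(df)))
}

#' Write a log-evidence table
#'
#' @param evidence Matrix or wide data frame (see [read_evidence()]).
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  L <- as_evidence_matrix(evidence)
  df <- evidence_tibble(L)
  df <- dplyr::mutate(df, dplyr::across(-"subject", ~formatC(.x, digits = 17, format = "g")))
  if (grepl("\\.tsv$", path)) readr::write_tsv(df, path) else readr::write_csv(df, path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a family-partition config
#'
#' A YAML (or JSON) mapping from family name to a list of model labels. The
#' reserved key `_remainder` may name a family that automatically collects
#' every model not listed elsewhere; without it the listed families must
#' cover the whole model set.
#'
#' @param path Config path (`.yaml`/`.yml` or `.json`).
#' @param model_labels All model labels of the space being partitioned.
#' @return A `bms_partition`.
#' @export
read_families <- function(path, model_labels) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || is.null(names(cfg))) {
    abort("Family config must map family names to model-label lists.")
  }
  remainder <- NULL
  if ("_remainder" %in% names(cfg)) {
    remainder <- as.character(cfg[["_remainder"]])
    cfg[["_remainder"]] <- NULL
  }
  partial <- lapply(cfg, function(x) as.character(unlist(x)))
  part <- complete_partition(partial, model_labels,
                             remainder_name = remainder %||% "other")
  if (is.null(remainder) && !all(family_names(part) %in% names(partial))) {
    abort("Family config does not cover every model and no `_remainder` family was declared.")
  }
  part
}

#' Write a family partition as YAML
#'
#' @param partition A `bms_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_families <- function(partition, path) {
  fams <- lapply(split(partition$model, partition$family), as.list)
  yaml::write_yaml(fams[family_names(partition)], path)
  invisible(path)
}

#' Read / write a subject-posterior archive
#'
#' JSON archive of per (subject, model) Gaussian parameter posteriors under
#' shared parameter names: top-level `parameters`, `subjects`, `models`,
#' and `posteriors[[subject]][[model]] = {mean, cov, free}`. The reader
#' validates that the grid is complete. Posteriors exported from other
#' DCM tooling should be converted to this layout.
#'
#' @param path Archive path.
#' @return A `subject_posteriors` object.
#' @export
read_subject_posteriors <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("parameters", "subjects", "models", "posteriors")
  if (!all(need %in% names(x))) {
    abort(sprintf("Archive must contain: %s.", paste(need, collapse = ", ")))
  }
  P <- length(x$parameters)
  cells <- lapply(x$subjects, function(s) {
    sub <- x$posteriors[[s]]
    if (is.null(sub)) abort(sprintf("Archive missing subject '%s'.", s))
    lapply(x$models, function(m) {
      cell <- sub[[m]]
      if (is.null(cell)) {
        abort(sprintf("Archive missing cell (%s, %s); the grid must be complete.", s, m))
      }
      cov <- if (is.matrix(cell$cov)) {
        cell$cov
      } else {
        matrix(as.numeric(unlist(cell$cov)), P, P, byrow = TRUE)
      }
      list(mean = as.numeric(cell$mean), cov = cov,
           free = as.numeric(cell$free))
    })
  })
  subject_posteriors(x$parameters, x$subjects, x$models, cells)
}

#' @rdname read_subject_posteriors
#' @param posts A `subject_posteriors` object.
#' @export
write_subject_posteriors <- function(posts, path) {
  out <- list(
    parameters = posts$parameters,
    subjects = posts$subjects,
    models = posts$models,
    posteriors = lapply(setNames(posts$subjects, posts$subjects), function(s) {
      lapply(setNames(posts$models, posts$models), function(m) {
        cell <- posts$cells[[s]][[m]]
        list(mean = cell$mean,
             cov = apply(cell$cov, 1L, identity, simplify = FALSE),
             free = cell$free)
      })
    })
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
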