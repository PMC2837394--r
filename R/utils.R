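# Numerical helpers shared across the inference modules. All evidence
# arithmetic stays in natural-log space until probabilities are materialised.

#' Log-sum-exp of a numeric vector
#'
#' Computes `log(sum(exp(x)))` without overflow for inputs with magnitude up
#' to at least 1e4, by subtracting the maximum before exponentiating.
#'
#' @param x Numeric vector of log-scale values.
#' @return A length-1 numeric.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Softmax computed in log space
#'
#' @param x Numeric vector of log-scale values.
#' @return Probability vector summing to 1.
#' @keywords internal
softmax_log <- function(x) {
  p <- exp(x - max(x))
  p / sum(p)
}

# Row-wise softmax of a matrix of log weights (per-subject normalisation).
row_softmax_log <- function(X) {
  mx <- apply(X, 1L, max)
  W <- exp(X - mx)
  W / rowSums(W)
}

# Validate a log-evidence input and return a named numeric matrix
# (subjects x models). Accepts a numeric matrix with dimnames or a data
# frame whose first column holds subject ids and remaining columns one
# numeric column per model.
as_evidence_matrix <- function(x, arg = "evidence") {
  if (is.matrix(x)) {
    L <- x
    if (is.null(rownames(L))) rownames(L) <- paste0("subject", seq_len(nrow(L)))
    if (is.null(colnames(L))) colnames(L) <- paste0("m", seq_len(ncol(L)))
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      abort(sprintf("`%s` needs a subject-id column plus at least one model column.", arg))
    }
    ids <- as.character(x[[1L]])
    L <- as.matrix(x[, -1L, drop = FALSE])
    if (!is.numeric(L)) {
      bad <- names(x)[-1L][!vapply(x[-1L], is.numeric, logical(1))]
      abort(sprintf("Non-numeric model column(s) in `%s`: %s", arg,
                    paste(bad, collapse = ", ")))
    }
    rownames(L) <- ids
  } else {
    abort(sprintf("`%s` must be a numeric matrix or a data frame.", arg))
  }
  storage.mode(L) <- "double"
  if (nrow(L) < 1L || ncol(L) < 1L) {
    abort(sprintf("`%s` must have at least one subject and one model.", arg))
  }
  if (anyDuplicated(colnames(L))) abort("Model labels must be unique.")
  if (anyDuplicated(rownames(L))) abort("Subject ids must be unique.")
  if (!all(is.finite(L))) {
    idx <- which(!is.finite(L), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Non-finite log evidence for subject '%s', model '%s'; every model must be fitted to every subject.",
      rownames(L)[idx[1L]], colnames(L)[idx[2L]]))
  }
  L
}

# Wide tibble view of an evidence matrix (subject column first).
evidence_tibble <- function(L) {
  tibble::as_tibble(cbind(
    tibble::tibble(subject = rownames(L)),
    tibble::as_tibble(L)
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# Monte-Carlo standard error of column means via non-overlapping batch means.
# Used instead of thinning: autocorrelation inflates the batch variance.
batch_mcse <- function(samples) {
  S <- nrow(samples)
  nb <- max(2L, floor(sqrt(S)))
  bs <- floor(S / nb)
  idx <- rep(seq_len(nb), each = bs)
  used <- seq_len(nb * bs)
  bm <- rowsum(samples[used, , drop = FALSE], idx) / bs
  apply(bm, 2L, stats::sd) / sqrt(nb)
}
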