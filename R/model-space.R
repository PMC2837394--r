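# Enumeration of DCM-style discrete model spaces: which regions receive the
# driving input (C-matrix pattern) crossed with which directed inter-regional
# connections are modulated (B-matrix pattern). Endogenous (A-matrix)
# connectivity is taken as fixed all-to-all and is metadata only, not part of
# the enumeration.
#
# Internal convention: a modulation matrix entry (i, j) means the connection
# FROM region j TO region i. All user-facing output names connections as
# "src->dst" strings so the internal storage convention can never leak into
# results.

#' Enumerate driving-input patterns
#'
#' All non-empty subsets of `R` regions, as rows of a binary matrix, in
#' binary-counting order with region 1 as the least-significant bit. A `1`
#' in column `j` means region `j` receives the driving input. Models with no
#' input at all are discounted, so there are `2^R - 1` patterns.
#'
#' @param R Number of regions (>= 1).
#' @param regions Optional character vector of region labels (length `R`).
#' @return Integer matrix with `2^R - 1` rows and `R` columns.
#' @examples
#' enumerate_input_patterns(3)
#' @export
enumerate_input_patterns <- function(R, regions = NULL) {
  R <- check_count(R, "R")
  regions <- region_labels(R, regions)
  codes <- seq_len(2^R - 1)
  pat <- t(vapply(codes, function(k) bits_of(k, R), integer(R)))
  colnames(pat) <- regions
  rownames(pat) <- apply(pat, 1L, function(b) paste(regions[b == 1L], collapse = ""))
  pat
}

#' Enumerate modulation patterns
#'
#' All subsets (including the empty one) of the `R(R-1)` directed
#' inter-regional connections, as binary `R x R` matrices with zero diagonal.
#' Patterns are ordered by binary counting over a row-major flattening of the
#' off-diagonal entries, so there are `2^(R(R-1))` of them and the first is
#' the empty pattern.
#'
#' @inheritParams enumerate_input_patterns
#' @return List of `2^(R*(R-1))` binary matrices.
#' @examples
#' length(enumerate_modulation_patterns(2))
#' @export
enumerate_modulation_patterns <- function(R, regions = NULL) {
  R <- check_count(R, "R")
  regions <- region_labels(R, regions)
  off <- which(t(!diag(R)))  # row-major positions of off-diagonal entries
  nC <- R * (R - 1L)
  lapply(seq_len(2^nC) - 1L, function(k) {
    b <- bits_of(k, nC)
    M <- matrix(0L, R, R, dimnames = list(regions, regions))
    tM <- t(M)
    tM[off] <- b
    t(tM)
  })
}

#' Build the full model space for R regions
#'
#' Crosses every non-empty input pattern with every modulation pattern
#' (input pattern outermost), giving `(2^R - 1) * 2^(R(R-1))` models. For
#' three regions this is the 7 x 64 = 448-model comparison set.
#'
#' @inheritParams enumerate_input_patterns
#' @return A `bms_model_space`: a tibble with columns `label`, `input`
#'   (region labels receiving input, e.g. `"P"`), `modulation`
#'   (`";"`-separated `"src->dst"` strings), and list-columns
#'   `input_pattern` / `mod_pattern` holding the binary structures.
#' @examples
#' space <- build_model_space(2, regions = c("P", "A"))
#' nrow(space)
#' @export
build_model_space <- function(R, regions = NULL) {
  R <- check_count(R, "R")
  regions <- region_labels(R, regions)
  inputs <- enumerate_input_patterns(R, regions)
  mods <- enumerate_modulation_patterns(R, regions)
  n <- nrow(inputs) * length(mods)
  grid <- tidyr::expand_grid(i_in = seq_len(nrow(inputs)), i_mod = seq_along(mods))
  space <- tibble::tibble(
    label = sprintf("model_%0*d", nchar(n), seq_len(n)),
    input = rownames(inputs)[grid$i_in],
    modulation = vapply(
      mods[grid$i_mod],
      function(M) paste(connection_strings(M), collapse = ";"), character(1)
    ),
    input_pattern = lapply(grid$i_in, function(i) inputs[i, ]),
    mod_pattern = mods[grid$i_mod]
  )
  structure(space, class = c("bms_model_space", class(space)),
            region_labels = regions)
}

#' @export
print.bms_model_space <- function(x, ...) {
  cat(sprintf("Model space: %d models over regions %s\n", nrow(x),
              paste(attr(x, "region_labels"), collapse = ", ")))
  NextMethod()
}

#' Export a model space as a plain table
#'
#' Writes a delimited table with columns `label`, `input` and `modulation`
#' (connections as `"src->dst"` strings), suitable for inspection and
#' re-reading elsewhere.
#'
#' @param space A `bms_model_space`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_model_space <- function(space, path) {
  readr::write_tsv(tibble::as_tibble(space)[, c("label", "input", "modulation")], path)
  invisible(path)
}

# "src->dst" names of the modulated connections of a pattern matrix, in the
# canonical row-major order of the internal (dst, src) storage.
connection_strings <- function(M) {
  regions <- rownames(M)
  idx <- which(t(M) == 1L, arr.ind = TRUE)  # t(): row = src, col = dst
  if (nrow(idx) == 0L) return(character(0))
  # restore row-major order over the original matrix
  ord <- order(idx[, 2L], idx[, 1L])
  paste0(regions[idx[ord, 1L]], "->", regions[idx[ord, 2L]])
}

region_labels <- function(R, regions) {
  if (is.null(regions)) return(paste0("R", seq_len(R)))
  regions <- as.character(regions)
  if (length(regions) != R || anyDuplicated(regions)) {
    abort("`regions` must be `R` unique labels.")
  }
  regions
}

# Little-endian bit expansion: bit 1 is the least-significant.
bits_of <- function(k, n) {
  as.integer(bitwAnd(bitwShiftR(as.integer(k), seq_len(n) - 1L), 1L))
}
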