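# Family partitions: disjoint, exhaustive, named subsets of a model space.
# A partition is a tibble (model, family) with the family ordering kept as an
# attribute; all inference code converts it to an indicator matrix.

#' Construct a family partition
#'
#' @param model Character vector of model labels (one entry per model).
#' @param family Character vector assigning each model to a family.
#' @param family_levels Optional ordering of family names; defaults to first
#'   appearance.
#' @return A `bms_partition` tibble with columns `model` and `family`.
#' @examples
#' family_partition(c("m1", "m2", "m3"), c("a", "b", "b"))
#' @export
family_partition <- function(model, family, family_levels = NULL) {
  model <- as.character(model)
  family <- as.character(family)
  if (length(model) != length(family)) {
    abort("`model` and `family` must have the same length.")
  }
  if (length(model) == 0L) abort("A partition needs at least one model.")
  if (anyDuplicated(model)) {
    abort(sprintf("Duplicated model label(s): %s",
                  paste(unique(model[duplicated(model)]), collapse = ", ")))
  }
  family_levels <- family_levels %||% unique(family)
  if (!all(family %in% family_levels)) {
    abort("`family_levels` must cover every family used.")
  }
  if (!all(family_levels %in% family)) {
    abort(sprintf("Empty family: %s",
                  paste(setdiff(family_levels, family), collapse = ", ")))
  }
  structure(
    tibble::tibble(model = model, family = family),
    class = c("bms_partition", class(tibble::tibble())),
    family_levels = family_levels
  )
}

#' @export
print.bms_partition <- function(x, ...) {
  sz <- family_sizes(x)
  cat(sprintf("Family partition: %d models in %d families (%s)\n",
              nrow(x), length(sz),
              paste(sprintf("%s=%d", names(sz), sz), collapse = ", ")))
  NextMethod()
}

#' Family names of a partition, in canonical order
#' @param partition A `bms_partition`.
#' @return Character vector of family names.
#' @export
family_names <- function(partition) {
  attr(partition, "family_levels") %||% unique(partition$family)
}

#' Number of models per family
#' @inheritParams family_names
#' @return Named integer vector `N_k` in canonical family order.
#' @export
family_sizes <- function(partition) {
  lv <- family_names(partition)
  vapply(lv, function(f) sum(partition$family == f), integer(1))
}

# Models x families 0/1 indicator, rows ordered to match `model_labels`.
# Errors unless the partition covers exactly the given labels.
family_indicator <- function(partition, model_labels) {
  check_partition(partition, model_labels)
  lv <- family_names(partition)
  fam <- partition$family[match(model_labels, partition$model)]
  ind <- matrix(0, length(model_labels), length(lv),
                dimnames = list(model_labels, lv))
  ind[cbind(seq_along(fam), match(fam, lv))] <- 1
  ind
}

check_partition <- function(partition, model_labels) {
  if (!inherits(partition, "bms_partition")) {
    abort("`partition` must be a `bms_partition` (see `family_partition()`).")
  }
  missing <- setdiff(model_labels, partition$model)
  extra <- setdiff(partition$model, model_labels)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "Partition does not match the model set%s%s.",
      if (length(missing)) sprintf("; unassigned: %s", paste(head(missing, 5), collapse = ", ")) else "",
      if (length(extra)) sprintf("; unknown: %s", paste(head(extra, 5), collapse = ", ")) else ""))
  }
  invisible(partition)
}

#' Partition a model space by input pattern
#'
#' One family per distinct driving-input pattern, named by the concatenated
#' labels of the receiving regions (e.g. `"P"`, `"PA"`). For the full
#' three-region space this yields 7 families of 64 models each.
#'
#' @param space A `bms_model_space` (or any tibble with `label` and `input`
#'   columns).
#' @return A `bms_partition`.
#' @export
partition_by_input <- function(space) {
  if (nrow(space) == 0L) abort("`space` must contain at least one model.")
  family_partition(space$label, space$input, family_levels = unique(space$input))
}

#' Partition a model space by forward/backward modulation flow
#'
#' Given a region hierarchy ordered from lowest to highest, counts the
#' modulated connections running up the hierarchy (forward, `f`) and down it
#' (backward, `b`) for each model, and assigns the family: `"F"` if `f > b`,
#' `"B"` if `b > f`, `"BAL"` if `f == b` with at least one modulated
#' connection, and `"None"` if nothing is modulated.
#'
#' @param space A `bms_model_space`.
#' @param hierarchy Character vector: a permutation of the space's region
#'   labels, lowest region first.
#' @return A `bms_partition` with families `F`, `B`, `BAL`, `None` (empty
#'   families dropped from the level set only if absent from the space).
#' @export
partition_by_flow <- function(space, hierarchy) {
  regions <- attr(space, "region_labels")
  if (is.null(regions)) abort("`space` must be a `bms_model_space`.")
  if (!setequal(hierarchy, regions) || length(hierarchy) != length(regions)) {
    abort("`hierarchy` must be a permutation of the space's region labels.")
  }
  rank <- match(regions, hierarchy)  # position in hierarchy, 1 = lowest
  fam <- vapply(space$mod_pattern, function(M) {
    idx <- which(M == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) return("None")
    # entry (i, j) is the connection j -> i: src = j, dst = i
    f <- sum(rank[idx[, 2L]] < rank[idx[, 1L]])
    b <- sum(rank[idx[, 2L]] > rank[idx[, 1L]])
    if (f > b) "F" else if (b > f) "B" else "BAL"
  }, character(1))
  lv <- intersect(c("F", "B", "BAL", "None"), unique(fam))
  family_partition(space$label, fam, family_levels = lv)
}

#' Complete a partial family specification
#'
#' Takes named, disjoint subsets of the model labels and appends a remainder
#' family holding any unassigned models, so the result is a valid partition.
#'
#' @param partial Named list of character vectors of model labels. May be
#'   empty.
#' @param model_labels All model labels in the space (or a `bms_model_space`).
#' @param remainder_name Name for the auto-created remainder family.
#' @return A `bms_partition` over all of `model_labels`.
#' @export
complete_partition <- function(partial, model_labels, remainder_name = "other") {
  if (inherits(model_labels, "bms_model_space") || is.data.frame(model_labels)) {
    model_labels <- model_labels$label
  }
  model_labels <- as.character(model_labels)
  if (length(partial) && is.null(names(partial))) {
    abort("`partial` must be a *named* list of model-label subsets.")
  }
  all_assigned <- unlist(partial, use.names = FALSE)
  if (anyDuplicated(all_assigned)) {
    abort(sprintf("Overlapping subsets: model(s) %s appear in more than one family.",
                  paste(unique(all_assigned[duplicated(all_assigned)]), collapse = ", ")))
  }
  unknown <- setdiff(all_assigned, model_labels)
  if (length(unknown)) {
    abort(sprintf("Unknown model label(s): %s", paste(head(unknown, 5), collapse = ", ")))
  }
  fam <- setNames(rep(NA_character_, length(model_labels)), model_labels)
  for (nm in names(partial)) fam[partial[[nm]]] <- nm
  lv <- names(partial)
  if (anyNA(fam)) {
    if (remainder_name %in% lv) {
      abort(sprintf("Remainder name '%s' clashes with an explicit family.", remainder_name))
    }
    fam[is.na(fam)] <- remainder_name
    lv <- c(lv, remainder_name)
  }
  family_partition(model_labels, unname(fam), family_levels = lv)
}
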