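# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately brute-force and independent of the package's implementation
# paths.

# All binary vectors of length n, as rows, by explicit cross product.
brute_binary_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

# Brute-force count of forward/backward/balanced/none over every subset of
# the directed connections among regions ranked 1..R (rank 1 = lowest).
# Independent of the package's pattern enumeration: works on the subset
# lattice of the connection list directly.
brute_flow_counts <- function(R) {
  conns <- subset(expand.grid(src = seq_len(R), dst = seq_len(R)), src != dst)
  n <- nrow(conns)
  counts <- c(F = 0L, B = 0L, BAL = 0L, None = 0L)
  for (k in seq_len(2^n) - 1L) {
    on <- which(as.logical(bitwAnd(bitwShiftR(k, seq_len(n) - 1L), 1L)))
    f <- sum(conns$src[on] < conns$dst[on])
    b <- sum(conns$src[on] > conns$dst[on])
    fam <- if (f + b == 0L) "None" else if (f > b) "F" else if (b > f) "B" else "BAL"
    counts[fam] <- counts[fam] + 1L
  }
  counts
}

# Decisive evidence matrix with fixed per-model counts: subjects in blocks.
decisive_evidence <- function(counts, margin = 10) {
  M <- length(counts)
  assign <- rep(seq_len(M), counts)
  L <- matrix(0, length(assign), M,
              dimnames = list(sprintf("s%02d", seq_along(assign)),
                              paste0("m", seq_len(M))))
  L[cbind(seq_along(assign), assign)] <- margin
  L
}

# Tiny two-region posterior grid used by the BMA tests: models labelled by
# which of the two parameters ("a", "b") they free.
toy_posterior_grid <- function(n_subjects, models, means, sds) {
  params <- c("a", "b")
  cells <- lapply(seq_len(n_subjects), function(n) {
    lapply(names(models), function(m) {
      free <- as.numeric(params %in% models[[m]])
      mu <- means[[m]] * free
      list(mean = mu, cov = diag(sds[[m]]^2 * free, 2), free = free)
    })
  })
  subject_posteriors(params, sprintf("s%d", seq_len(n_subjects)),
                     names(models), cells)
}

expect_simplex <- function(x, tol = 1e-10) {
  expect_true(all(x >= 0))
  expect_lt(abs(sum(x) - 1), tol)
}
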