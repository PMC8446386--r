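# Independent oracles used to freeze expected values: brute-force subset
# enumeration for Boolean-union closures and DFS path enumeration for
# reachability. Both are deliberately naive and separate from the package's
# fixpoint implementations.

brute_union_closure <- function(patterns) {
  m <- unique(as_patterns(patterns))
  n <- nrow(m)
  stopifnot(n <= 12)
  rows <- lapply(seq_len(2^n - 1L), function(mask) {
    sel <- which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
    as.integer(apply(m[sel, , drop = FALSE], 2L, max))
  })
  unique(do.call(rbind, rows))
}

brute_reachability <- function(A) {
  K <- nrow(A)
  R <- diag(K)
  reach_from <- function(i) {
    seen <- logical(K)
    stack <- which(A[i, ] == 1)
    while (length(stack) > 0) {
      j <- stack[[1]]; stack <- stack[-1]
      if (!seen[j]) {
        seen[j] <- TRUE
        stack <- c(stack, which(A[j, ] == 1))
      }
    }
    seen
  }
  for (i in seq_len(K)) R[i, reach_from(i)] <- 1
  storage.mode(R) <- "integer"
  R
}

# set equality of pattern matrices, ignoring row order
expect_same_patterns <- function(got, want) {
  g <- sort(apply(as_patterns(got), 1, paste0, collapse = ""))
  w <- sort(apply(as_patterns(want), 1, paste0, collapse = ""))
  expect_identical(g, w)
}

# expected TCV of every benchmark table cell, as exact fractions keyed by
# structure / distribution / Qt variant (values re-derived by hand from the
# published comparison tables before being frozen here)
expected_cell_tcv <- function() {
  frac <- function(num, den) num / den
  list(
    linear = list(
      average = c(cat1.a = frac(2, 5), cat2.a = frac(3, 5), cat2.b = frac(3, 5),
                  cat4.a = 1, cat4.b = 1),
      normal = c(cat1.a = frac(5, 10), cat2.a = frac(5, 10),
                 cat2.b = frac(5, 10), cat4.a = 1, cat4.b = 1)),
    convergent = list(
      average = c(cat2.a = frac(4, 6), cat2.b = frac(4, 6),
                  cat4.a = frac(5, 6), cat4.b = frac(5, 6),
                  cat5.a = 1, cat5.b = 1),
      normal = c(cat2.a = frac(17, 20), cat2.b = frac(17, 20),
                 cat4.a = frac(19, 20), cat4.b = frac(19, 20),
                 cat5.a = 1, cat5.b = 1)),
    divergent = list(
      average = c(cat2.a = frac(4, 7), cat2.b = frac(4, 7),
                  cat4.a = frac(6, 7), cat4.b = frac(6, 7),
                  cat6.a = 1, cat6.b = 1),
      normal = c(cat2.a = frac(104, 210), cat2.b = frac(104, 210),
                 cat4.a = frac(168, 210), cat4.b = frac(168, 210),
                 cat6.a = 1, cat6.b = 1)),
    unstructured = list(
      average = c(cat4.a = frac(6, 9), cat4.b = frac(6, 9),
                  cat6.a = frac(7, 9), cat6.b = frac(7, 9),
                  cat8.a = 1, cat8.b = 1),
      normal = c(cat4.a = frac(146, 270), cat4.b = frac(146, 270),
                 cat6.a = frac(184, 270), cat6.b = frac(184, 270),
                 cat8.a = 1, cat8.b = 1)),
    independent = list(
      average = c(cat8.a = frac(10, 16), cat8.b = frac(10, 16),
                  cat12.a = 1, cat12.b = 1, cat15.a = 1, cat15.b = 1),
      normal = c(cat8.a = frac(279, 480), cat8.b = frac(279, 480),
                 cat12.a = 1, cat12.b = 1, cat15.a = 1, cat15.b = 1),
      mvnormal = c(cat8.a = frac(453, 480), cat8.b = frac(453, 480),
                   cat12.a = 1, cat12.b = 1, cat15.a = 1, cat15.b = 1)))
}
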