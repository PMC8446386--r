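# Attribute patterns are stored as 0/1 rows (states x attributes, items x
# attributes), the usual R Q-matrix orientation. Internally a pattern is
# encoded as an integer bitmask with attribute 1 in the most significant
# position, so that numeric order agrees with lexicographic order on the
# "1100"-style strings.

#' Parse attribute patterns
#'
#' Converts compact pattern strings such as \code{"1100"} into 0/1 integer
#' matrices (one row per pattern), or validates matrices already in that form.
#'
#' @param x a character vector of 0/1 strings, a numeric vector (single
#'   pattern), or a 0/1 matrix with one pattern per row.
#' @param K expected number of attributes; inferred from \code{x} if missing.
#' @return an integer matrix with one pattern per row and columns
#'   \code{A1..AK}.
#' @examples
#' as_patterns(c("1100", "1010"))
#' @export
as_patterns <- function(x, K = NULL) {
  if (length(x) == 0L && !is.matrix(x))
    stop("no patterns supplied")
  if (is.character(x)) {
    bits <- lapply(x, function(s) {
      v <- strsplit(s, "", fixed = TRUE)[[1L]]
      if (!all(v %in% c("0", "1")))
        stop("pattern string must contain only 0 and 1: '", s, "'")
      as.integer(v)
    })
    len <- lengths(bits)
    if (length(unique(len)) > 1L)
      stop("patterns have differing lengths: ", paste(unique(len), collapse = ", "))
    m <- do.call(rbind, bits)
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.numeric(x)) {
    m <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret object of class '", class(x)[1L], "' as attribute patterns")
  }
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L)))
    stop("attribute patterns must be 0/1")
  if (!is.null(K) && ncol(m) != K)
    stop("patterns have ", ncol(m), " attributes, expected K = ", K)
  colnames(m) <- paste0("A", seq_len(ncol(m)))
  rownames(m) <- NULL
  m
}

#' Format patterns as compact strings
#'
#' @param x a pattern matrix (rows) or single pattern vector.
#' @return character vector like \code{"1100"}.
#' @export
pattern_strings <- function(x) {
  m <- as_patterns(x)
  apply(m, 1L, paste0, collapse = "")
}

# integer bitmask encoding; A1 is the most significant bit
.pat_encode <- function(m) {
  K <- ncol(m)
  as.integer(m %*% 2L^((K - 1L):0L))
}

.pat_decode <- function(codes, K) {
  m <- t(vapply(codes, function(code)
    as.integer(bitwAnd(bitwShiftR(code, (K - 1L):0L), 1L)), integer(K)))
  colnames(m) <- paste0("A", seq_len(K))
  m
}

# canonical order: mastered-attribute count, then lexicographic on the string
.pat_canonical_order <- function(m) {
  order(rowSums(m), .pat_encode(m))
}

.sort_patterns <- function(m) {
  m[.pat_canonical_order(m), , drop = FALSE]
}

# Boolean-union closure by fixpoint of pairwise unions over integer codes.
# Returns sorted codes. Never enumerates 2^n subsets.
.bool_union_closure <- function(codes) {
  S <- sort(unique(as.integer(codes)))
  repeat {
    u <- unique(as.vector(outer(S, S, bitwOr)))
    new <- setdiff(u, S)
    if (length(new) == 0L) break
    S <- c(S, new)
  }
  sort(S)
}

# state-set container: a canonical-ordered pattern matrix with a role
.state_set <- function(m, role = c("Qr", "Qs", "Qt_plus")) {
  role <- match.arg(role)
  m <- .sort_patterns(as_patterns(m))
  if (anyDuplicated(.pat_encode(m)))
    stop("state set contains duplicate patterns")
  zero <- any(rowSums(m) == 0L)
  if (role == "Qs" && !zero)
    stop("a Qs state set must contain the all-zero state")
  if (role != "Qs" && zero)
    stop("a ", role, " state set must not contain the all-zero state")
  structure(m, role = role, class = c("state_set", class(m)))
}

#' @export
print.state_set <- function(x, ...) {
  cat("State set (role ", attr(x, "role"), "), ", nrow(x), " patterns over ",
      ncol(x), " attributes:\n", sep = "")
  cat(" ", paste(pattern_strings(unclass(x)), collapse = " "), "\n")
  invisible(x)
}
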