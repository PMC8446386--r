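#' Test Q-matrices
#'
#' A test Q-matrix Qt holds the attribute vectors of the test items, one item
#' per row; repeated rows represent repeated item categories. When a
#' hierarchy is supplied, items outside its Qr set (i.e. inconsistent with
#' the prerequisite relation) trigger a warning but are retained.
#'
#' @param items pattern strings, a 0/1 matrix (rows = items), or a vector for
#'   a single item.
#' @param hierarchy optional \code{attribute_hierarchy} used to check item
#'   consistency.
#' @return an object of class \code{q_matrix} (an integer matrix,
#'   items x attributes).
#' @examples
#' q_matrix(c("100", "010", "101"))
#' @export
q_matrix <- function(items, hierarchy = NULL) {
  m <- as_patterns(items)
  if (nrow(m) == 0L) stop("a Q-matrix must contain at least one item")
  if (any(rowSums(m) == 0L))
    stop("Q-matrix items must be nonzero (an item must measure some attribute)")
  if (!is.null(hierarchy)) {
    if (hierarchy$K != ncol(m))
      stop("Q-matrix has ", ncol(m), " attributes but hierarchy has K = ",
           hierarchy$K)
    qr_codes <- .pat_encode(unclass(generate_items(hierarchy)))
    bad <- !(.pat_encode(m) %in% qr_codes)
    if (any(bad))
      warning("item(s) ", paste(pattern_strings(m[bad, , drop = FALSE]),
                                collapse = ", "),
              " are not consistent with the '", hierarchy$name, "' hierarchy")
  }
  rownames(m) <- NULL
  structure(m, class = c("q_matrix", class(m)))
}

#' @export
print.q_matrix <- function(x, ...) {
  tab <- table(pattern_strings(unclass(x)))
  cat("Q-matrix: ", nrow(x), " items, ", ncol(x), " attributes, ",
      length(tab), " distinct categor", if (length(tab) == 1L) "y" else "ies",
      "\n", sep = "")
  cat(" ", paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                 collapse = "  "), "\n")
  invisible(x)
}

#' Knowledge-state distributions
#'
#' A population distribution over knowledge states. Weights may be
#' proportions or integer ratio/count weights; integer weights are kept so
#' that downstream indices can be reported as exact fractions.
#'
#' @param states pattern strings or matrix of states (rows).
#' @param weights nonnegative weights, one per state.
#' @return an object of class \code{ks_distribution} with elements
#'   \code{states}, \code{weights}, \code{total} and \code{exact} (TRUE when
#'   the weights are integers).
#' @examples
#' ks_distribution(c("0000", "1000", "1100", "1110", "1111"), c(1, 2, 4, 2, 1))
#' @export
ks_distribution <- function(states, weights) {
  m <- as_patterns(states)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(m))
    stop("need one weight per state: ", nrow(m), " states, ",
         length(weights), " weights")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and nonnegative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  if (anyDuplicated(.pat_encode(m)))
    stop("duplicate states in distribution")
  structure(list(states = m, weights = weights, total = sum(weights),
                 exact = all(weights == round(weights))),
            class = "ks_distribution")
}

#' Uniform distribution over a state set
#'
#' @param qs a \code{state_set} (typically role \code{"Qs"}).
#' @return a \code{ks_distribution} with unit weight on every state.
#' @export
ks_uniform <- function(qs) {
  ks_distribution(unclass(qs), rep(1L, nrow(qs)))
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat("Knowledge-state distribution over", nrow(x$states), "states",
      if (x$exact) "(integer weights)" else "", "\n")
  p <- x$weights / x$total
  cat(paste(sprintf("  %s: %.4f", pattern_strings(x$states), p),
            collapse = "\n"), "\n")
  invisible(x)
}

# weight lookup by pattern code; absent states get weight 0
.dist_weight <- function(dist, codes) {
  dcodes <- .pat_encode(dist$states)
  idx <- match(codes, dcodes)
  w <- dist$weights[idx]
  w[is.na(idx)] <- 0
  w
}

#' Augment algorithm: knowledge states derivable from a test
#'
#' Closes the distinct item categories of a Q-matrix under Boolean union,
#' yielding the Qt+ set: every knowledge state whose presence in the
#' population the test can in principle pin down. Item multiplicity and
#' order are irrelevant.
#'
#' @param qt a \code{q_matrix} (or anything \code{\link{q_matrix}} accepts).
#' @return a \code{state_set} with role \code{"Qt_plus"}.
#' @examples
#' augment(q_matrix(c("100", "010", "101")))  # 5 derivable states
#' @export
augment <- function(qt) {
  if (!inherits(qt, "q_matrix")) qt <- q_matrix(qt)
  codes <- .bool_union_closure(.pat_encode(unclass(qt)))
  .state_set(.pat_decode(codes, ncol(qt)), role = "Qt_plus")
}

#' Theoretical construct validity of a test design
#'
#' TCV is the probability mass of the knowledge states that a test can
#' recover exactly from ideal responses: the states derivable from the
#' Q-matrix by the augment algorithm, plus the all-zero state. It is an
#' upper bound on the empirical pattern match ratio and needs no response
#' data.
#'
#' The \code{"standard"} variant includes the zero state, which makes TCV
#' coincide exactly with the ideal-response pattern match ratio
#' (\code{\link{pmr_irp}}). The \code{"literal"} variant sums only the
#' nonzero derivable states (the definition-by-intersection reading, kept
#' for fidelity to the published worked example); under a uniform
#' distribution it equals m/n rather than (m+1)/n.
#'
#' @param qt a \code{q_matrix}.
#' @param qs the knowledge-state universe, a \code{state_set} with role
#'   \code{"Qs"} (see [generate_states()]).
#' @param dist a \code{ks_distribution} over \code{qs}; \code{NULL} means
#'   uniform.
#' @param variant \code{"standard"} (default) or \code{"literal"}.
#' @return an object of class \code{tcv_result} with elements \code{value},
#'   \code{m} (size of the augmented set), \code{n} (size of Qs),
#'   \code{num}/\code{den} (exact fraction when the distribution has integer
#'   weights), \code{derived_states} and \code{variant}.
#' @examples
#' h <- canonical_hierarchy("independent", 3)
#' tcv(q_matrix(c("100", "010", "101")), generate_states(h))$value  # 0.75
#' @export
tcv <- function(qt, qs, dist = NULL, variant = c("standard", "literal")) {
  variant <- match.arg(variant)
  if (!inherits(qt, "q_matrix")) qt <- q_matrix(qt)
  stopifnot(inherits(qs, "state_set"))
  if (ncol(qt) != ncol(qs))
    stop("Q-matrix and state set disagree on the number of attributes")
  if (is.null(dist)) {
    dist <- ks_uniform(qs)
  } else {
    stopifnot(inherits(dist, "ks_distribution"))
    qs_codes <- .pat_encode(unclass(qs))
    extra <- setdiff(.pat_encode(dist$states), qs_codes)
    if (length(extra) > 0L)
      stop("distribution support contains states outside Qs: ",
           paste(pattern_strings(.pat_decode(extra, ncol(qs))), collapse = ", "))
  }

  qtp <- augment(qt)
  qtp_codes <- .pat_encode(unclass(qtp))
  qs_codes <- .pat_encode(unclass(qs))
  derived <- sort(intersect(qtp_codes, qs_codes))
  sel <- if (variant == "standard") c(0L, derived) else derived

  num <- sum(.dist_weight(dist, sel))
  den <- dist$total
  structure(list(value = num / den,
                 m = nrow(qtp), n = nrow(qs),
                 num = if (dist$exact) num else NA_real_,
                 den = if (dist$exact) den else NA_real_,
                 derived_states = .state_set(.pat_decode(derived, ncol(qs)),
                                             role = "Qt_plus"),
                 variant = variant),
            class = "tcv_result")
}

#' TCV under a uniform knowledge-state distribution
#'
#' For equally likely knowledge states the standard TCV reduces to the exact
#' fraction (m + 1)/n, with m the number of derivable states and n the size
#' of the state universe.
#'
#' @inheritParams tcv
#' @return a \code{tcv_result}; \code{num}/\code{den} hold the exact fraction.
#' @examples
#' h <- canonical_hierarchy("linear", 4)
#' tcv_uniform(q_matrix("1100"), generate_states(h))$value  # 2/5
#' @export
tcv_uniform <- function(qt, qs) {
  tcv(qt, qs, dist = NULL, variant = "standard")
}

#' @export
print.tcv_result <- function(x, ...) {
  cat("TCV (", x$variant, " variant) = ", format(x$value, digits = 6), sep = "")
  if (!is.na(x$num)) cat("  [", x$num, "/", x$den, "]", sep = "")
  cat("\n  derivable states m = ", x$m, ", knowledge states n = ", x$n, "\n",
      sep = "")
  invisible(x)
}
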