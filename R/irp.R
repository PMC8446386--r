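#' Ideal response of a knowledge state to an item
#'
#' The ideal (noiseless, conjunctive) response is 1 iff the state dominates
#' the item's attribute vector: \eqn{\prod_k \alpha_k^{q_k} = 1} with
#' \eqn{0^0 = 1}, i.e. every attribute the item requires is mastered.
#'
#' @param alpha knowledge state (0/1 vector or pattern string).
#' @param q item attribute vector of the same length.
#' @return 0 or 1.
#' @examples
#' ideal_response("100", "100")  # 1
#' ideal_response("100", "010")  # 0
#' @export
ideal_response <- function(alpha, q) {
  a <- as_patterns(alpha)
  b <- as_patterns(q)
  if (ncol(a) != ncol(b))
    stop("state has ", ncol(a), " attributes but item has ", ncol(b))
  as.integer(all(a >= b))
}

#' Ideal response pattern matrix
#'
#' Tabulates the ideal response of every knowledge state to every item.
#' Rows follow the item order of \code{qt} (repeated items give repeated
#' rows); columns follow the state order of \code{qs}. Column i is the
#' ideal response pattern (IRP) of state i.
#'
#' @param qs a \code{state_set} (or pattern input) of knowledge states.
#' @param qt a \code{q_matrix} (or pattern input) of items.
#' @return 0/1 integer matrix, items x states, dimnames = pattern strings.
#' @export
irp_matrix <- function(qs, qt) {
  S <- as_patterns(if (inherits(qs, "state_set")) unclass(qs) else qs)
  Q <- as_patterns(if (inherits(qt, "q_matrix")) unclass(qt) else qt)
  if (ncol(S) != ncol(Q))
    stop("states and items disagree on the number of attributes")
  scode <- .pat_encode(S)
  qcode <- .pat_encode(Q)
  # state >= item  <=>  item's bits are a subset of the state's bits
  M <- outer(qcode, scode, function(q, s) as.integer(bitwAnd(s, q) == q))
  dimnames(M) <- list(item = pattern_strings(Q), state = pattern_strings(S))
  M
}

#' Partition knowledge states by ideal response pattern
#'
#' Groups the states of \code{qs} into classes with identical IRPs under the
#' test \code{qt}. Each class has a unique minimal member, computed
#' constructively as the Boolean union of all item categories its members
#' answer ideally (an element of the augmented set Qt+), or the zero state
#' for the class whose IRP is all zero. States within a class are
#' indistinguishable from ideal responses; only the representative itself
#' can be recovered exactly. The number of classes is |Qt+| + 1 whenever
#' the test items are hierarchy-consistent.
#'
#' @inheritParams irp_matrix
#' @return an object of class \code{irp_partition}: a list with
#'   \code{classes} (each a list with \code{members}, \code{representative},
#'   \code{irp}), \code{n_classes}, and the inputs.
#' @export
partition_states <- function(qs, qt) {
  S <- as_patterns(if (inherits(qs, "state_set")) unclass(qs) else qs)
  Q <- as_patterns(if (inherits(qt, "q_matrix")) unclass(qt) else qt)
  if (ncol(S) != ncol(Q))
    stop("states and items disagree on the number of attributes")
  K <- ncol(S)
  # repeated item categories cannot split classes; partition on distinct items
  Qd <- unique(Q)
  M <- irp_matrix(S, Qd)                       # distinct items x states
  key <- apply(M, 2L, paste0, collapse = "")
  scode <- .pat_encode(S)
  qcode <- .pat_encode(Qd)

  groups <- split(seq_len(nrow(S)), key)
  classes <- lapply(groups, function(ix) {
    irp <- M[, ix[1L]]
    solved <- qcode[irp == 1L]
    rep_code <- if (length(solved) == 0L) 0L else Reduce(bitwOr, solved)
    members <- .sort_patterns(S[ix, , drop = FALSE])
    rep_bits <- .pat_decode(rep_code, K)[1L, ]
    # the representative must itself belong to the class and lie below
    # every member (maximum-lower-bound property)
    stopifnot(rep_code %in% .pat_encode(members),
              all(bitwAnd(.pat_encode(members), rep_code) == rep_code))
    list(members = members, representative = rep_bits, irp = unname(irp))
  })
  # order classes canonically by representative
  reps <- do.call(rbind, lapply(classes, `[[`, "representative"))
  classes <- classes[.pat_canonical_order(reps)]
  names(classes) <- vapply(classes, function(cl)
    paste0(cl$representative, collapse = ""), character(1L))
  structure(list(classes = classes, n_classes = length(classes),
                 qs = S, qt = Q),
            class = "irp_partition")
}

#' @export
print.irp_partition <- function(x, ...) {
  cat("IRP partition:", x$n_classes, "classes over", nrow(x$qs),
      "knowledge states\n")
  for (cl in x$classes) {
    cat("  ", paste0(cl$representative, collapse = ""), " <- {",
        paste(pattern_strings(cl$members), collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Pattern match ratio under ideal responses
#'
#' The fraction of the population whose knowledge state can be recovered
#' exactly from ideal (noiseless) responses: the total probability of the
#' IRP-class representatives. This equals the standard-variant TCV for
#' every test and distribution, which is what makes TCV computable at the
#' design stage.
#'
#' @inheritParams irp_matrix
#' @param dist a \code{ks_distribution} over \code{qs}; \code{NULL} = uniform.
#' @return a proportion in [0, 1].
#' @examples
#' h <- canonical_hierarchy("independent", 3)
#' qs <- generate_states(h)
#' pmr_irp(qs, q_matrix(c("100", "010", "101")))  # 0.75
#' @export
pmr_irp <- function(qs, qt, dist = NULL) {
  part <- partition_states(qs, qt)
  if (is.null(dist)) {
    dist <- ks_distribution(part$qs, rep(1L, nrow(part$qs)))
  } else {
    stopifnot(inherits(dist, "ks_distribution"))
    extra <- setdiff(.pat_encode(dist$states), .pat_encode(part$qs))
    if (length(extra) > 0L)
      stop("distribution support contains states outside Qs")
  }
  reps <- do.call(rbind, lapply(part$classes, `[[`, "representative"))
  rep_codes <- sort(.pat_encode(reps))
  sum(.dist_weight(dist, rep_codes)) / dist$total
}
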