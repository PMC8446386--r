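#' Attribute hierarchies
#'
#' An attribute hierarchy is a prerequisite relation over K binary attributes,
#' given as a K x K adjacency matrix A with \code{A[i, j] = 1} meaning
#' attribute i is a direct prerequisite of attribute j. The relation must be
#' acyclic (a DAG) with a zero diagonal.
#'
#' @param adjacency K x K 0/1 matrix.
#' @param name optional label (e.g. \code{"linear"}, \code{"custom"}).
#' @return an object of class \code{attribute_hierarchy} with elements
#'   \code{K}, \code{adjacency} and \code{name}.
#' @seealso [canonical_hierarchy()], [reachability()], [generate_states()]
#' @export
hierarchy <- function(adjacency, name = "custom") {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  A <- adjacency
  storage.mode(A) <- "integer"
  if (!all(A %in% c(0L, 1L)))
    stop("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0L))
    stop("adjacency diagonal must be zero (an attribute cannot require itself)")
  K <- nrow(A)
  if (any(diag(.transitive_closure(A)) != 0L))
    stop("invalid hierarchy: the prerequisite relation contains a cycle")
  dimnames(A) <- list(paste0("A", seq_len(K)), paste0("A", seq_len(K)))
  structure(list(K = K, adjacency = A, name = name),
            class = "attribute_hierarchy")
}

# Boolean transitive closure (non-reflexive) by iterated products
.transitive_closure <- function(A) {
  K <- nrow(A)
  Tm <- A
  B <- A
  for (i in seq_len(K)) {
    B <- 1L * ((B %*% A) > 0L)
    Tnew <- 1L * ((Tm + B) > 0L)
    if (identical(Tnew, Tm)) break
    Tm <- Tnew
  }
  Tm
}

#' @export
print.attribute_hierarchy <- function(x, ...) {
  edges <- which(x$adjacency == 1L, arr.ind = TRUE)
  cat("Attribute hierarchy '", x$name, "' (K = ", x$K, ")\n", sep = "")
  if (nrow(edges) == 0L) {
    cat("  no prerequisite edges (independent attributes)\n")
  } else {
    cat("  edges:", paste(sprintf("%d->%d", edges[, 1L], edges[, 2L]),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reachability matrix of a hierarchy
#'
#' The reachability matrix R is the reflexive-transitive Boolean closure of
#' the adjacency matrix: \code{R[i, j] = 1} iff attribute j requires attribute
#' i (directly, indirectly, or i = j). Its columns are the minimal
#' hierarchy-consistent items anchoring each attribute.
#'
#' @param h an \code{attribute_hierarchy}.
#' @return K x K 0/1 integer matrix.
#' @examples
#' reachability(canonical_hierarchy("linear", 4))
#' @export
reachability <- function(h) {
  stopifnot(inherits(h, "attribute_hierarchy"))
  R <- 1L * ((diag(h$K) + .transitive_closure(h$adjacency)) > 0L)
  dimnames(R) <- dimnames(h$adjacency)
  R
}

#' All hierarchy-consistent items (the Qr set)
#'
#' Generates every nonzero attribute vector consistent with the hierarchy:
#' the Boolean unions of nonempty subsets of the reachability matrix columns.
#' Computed by fixpoint iteration of pairwise unions rather than subset
#' enumeration.
#'
#' @param h an \code{attribute_hierarchy}.
#' @return a \code{state_set} (role \code{"Qr"}), one item per row, in
#'   canonical order (mastery count, then lexicographic).
#' @export
generate_items <- function(h) {
  stopifnot(inherits(h, "attribute_hierarchy"))
  R <- reachability(h)
  cols <- t(R)                      # row r = attribute vector of column r of R
  codes <- .bool_union_closure(.pat_encode(cols))
  .state_set(.pat_decode(codes, h$K), role = "Qr")
}

#' All knowledge states (the Qs set)
#'
#' The knowledge-state universe is Qr plus the all-zero state (no attribute
#' mastered).
#'
#' @param h an \code{attribute_hierarchy}.
#' @return a \code{state_set} (role \code{"Qs"}) in canonical order.
#' @examples
#' generate_states(canonical_hierarchy("linear", 4))  # 5 states
#' @export
generate_states <- function(h) {
  qr <- generate_items(h)
  .state_set(rbind(integer(h$K), unclass(qr)), role = "Qs")
}

#' Canonical hierarchy structures
#'
#' The five standard hierarchy forms used in cognitive-diagnosis research.
#' For K = 4 they yield knowledge-state universes of size 5 (linear),
#' 6 (convergent), 7 (divergent), 9 (unstructured) and 16 (independent).
#' In the convergent form attribute 4 requires both attribute 2 and
#' attribute 3; in the divergent form attributes 2 and 3 branch from 1 and
#' attribute 4 follows 3; in the unstructured form attributes 2, 3, 4 each
#' require only attribute 1.
#'
#' @param name one of \code{"linear"}, \code{"convergent"}, \code{"divergent"},
#'   \code{"unstructured"}, \code{"independent"}.
#' @param K number of attributes. All five forms are defined for K = 4;
#'   \code{"linear"} and \code{"independent"} generalize to any K >= 2.
#' @return an \code{attribute_hierarchy}.
#' @examples
#' nrow(generate_states(canonical_hierarchy("divergent", 4)))  # 7
#' @export
canonical_hierarchy <- function(name = c("linear", "convergent", "divergent",
                                         "unstructured", "independent"),
                                K = 4L) {
  name <- match.arg(name)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  edges <- switch(name,
    independent  = cbind(integer(0), integer(0)),
    linear       = cbind(seq_len(K - 1L), seq_len(K - 1L) + 1L),
    convergent   = {
      if (K != 4L) stop("the convergent structure is defined for K = 4")
      rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L))
    },
    divergent    = {
      if (K != 4L) stop("the divergent structure is defined for K = 4")
      rbind(c(1L, 2L), c(1L, 3L), c(3L, 4L))
    },
    unstructured = {
      if (K != 4L) stop("the unstructured structure is defined for K = 4")
      cbind(1L, 2L:4L)
    })
  A <- matrix(0L, K, K)
  if (nrow(edges) > 0L) A[edges] <- 1L
  hierarchy(A, name = name)
}
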