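#' DINA item parameters
#'
#' Slip and guess probabilities of the DINA (deterministic input, noisy
#' "and" gate) model, shared by all items. Identifiability requires
#' 1 - s > g.
#'
#' @param slip probability of answering incorrectly despite mastering all
#'   required attributes, in [0, 1).
#' @param guess probability of answering correctly without the required
#'   attributes, in [0, 1); defaults to \code{slip} (symmetric noise).
#' @return an object of class \code{dina_params}.
#' @export
dina_params <- function(slip, guess = slip) {
  if (!is.numeric(slip) || length(slip) != 1L || slip < 0 || slip >= 1)
    stop("slip must be a single probability in [0, 1)")
  if (!is.numeric(guess) || length(guess) != 1L || guess < 0 || guess >= 1)
    stop("guess must be a single probability in [0, 1)")
  if (slip + guess >= 1)
    stop("need slip + guess < 1 for an identifiable DINA model")
  structure(list(slip = slip, guess = guess), class = "dina_params")
}

#' DINA item response probability
#'
#' P(X = 1 | alpha) = (1 - s)^eta * g^(1 - eta) with eta the ideal response
#' of the state to the item.
#'
#' @param alpha knowledge state.
#' @param q item attribute vector.
#' @param params a \code{dina_params}.
#' @return probability of a correct response.
#' @examples
#' dina_prob("110", "110", dina_params(0.15, 0.02))  # 0.85
#' @export
dina_prob <- function(alpha, q, params) {
  stopifnot(inherits(params, "dina_params"))
  eta <- ideal_response(alpha, q)
  (1 - params$slip)^eta * params$guess^(1 - eta)
}

#' Examinee populations
#'
#' A population assigns an integer examinee count to each knowledge state.
#'
#' @param states pattern strings or matrix (rows = states).
#' @param counts nonnegative integer counts, one per state.
#' @return an object of class \code{examinee_population} with \code{states},
#'   \code{counts} and total size \code{N}.
#' @export
examinee_population <- function(states, counts) {
  m <- as_patterns(states)
  counts <- as.numeric(counts)
  if (length(counts) != nrow(m))
    stop("need one count per state")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (anyDuplicated(.pat_encode(m)))
    stop("duplicate states in population")
  structure(list(states = m, counts = as.integer(counts),
                 N = as.integer(sum(counts))),
            class = "examinee_population")
}

#' @export
print.examinee_population <- function(x, ...) {
  cat("Examinee population: N =", x$N, "over", nrow(x$states), "states\n")
  cat(paste(sprintf("  %s: %d", pattern_strings(x$states), x$counts),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Simulate noisy item responses
#'
#' Generates observed responses by flipping each examinee's ideal response
#' on each item independently with probability \code{slip} (a symmetric
#' noise rule: the flip acts as a slip when the ideal response is 1 and as
#' a guess when it is 0, so the generating process is DINA with g = s).
#'
#' @param pop an \code{examinee_population}.
#' @param qt a \code{q_matrix}.
#' @param slip flip probability in [0, 0.5).
#' @param seed optional integer; when given, the RNG state is set for this
#'   call and restored afterwards.
#' @return a list of class \code{response_set} with \code{responses}
#'   (N x items 0/1 matrix) and \code{true_states} (N x K matrix).
#' @export
simulate_responses <- function(pop, qt, slip, seed = NULL) {
  stopifnot(inherits(pop, "examinee_population"))
  if (!inherits(qt, "q_matrix")) qt <- q_matrix(qt)
  if (!is.numeric(slip) || length(slip) != 1L || slip < 0 || slip >= 0.5)
    stop("slip must be a single value in [0, 0.5)")
  if (ncol(pop$states) != ncol(qt))
    stop("population and Q-matrix disagree on the number of attributes")
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  idx <- rep(seq_len(nrow(pop$states)), pop$counts)
  true_states <- pop$states[idx, , drop = FALSE]
  eta <- t(irp_matrix(true_states, qt))          # N x items ideal responses
  flips <- matrix(stats::runif(length(eta)) < slip, nrow = nrow(eta))
  responses <- abs(eta - flips)
  storage.mode(responses) <- "integer"
  dimnames(responses) <- list(NULL, pattern_strings(unclass(qt)))
  structure(list(responses = responses, true_states = true_states),
            class = "response_set")
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Maximum-likelihood classification under the DINA model
#'
#' Assigns each examinee the knowledge state in \code{qs} maximizing the
#' DINA likelihood of the observed responses. Likelihood ties - which arise
#' exactly between states in the same ideal-response class when s = g - are
#' broken toward the minimal-mastery state of the tied set, i.e. the class's
#' maximum-lower-bound representative (see [partition_states()]). With
#' s = g the argmax reduces to minimum Hamming distance between the observed
#' pattern and the state's IRP, which is computed in exact integer
#' arithmetic so ties are deterministic.
#'
#' @param responses N x items 0/1 matrix (or a \code{response_set}).
#' @param qs candidate states, a \code{state_set} with role \code{"Qs"}.
#' @param qt the test \code{q_matrix} (item order matching the columns of
#'   \code{responses}).
#' @param params a \code{dina_params}.
#' @return N x K integer matrix of estimated states.
#' @export
mle_classify <- function(responses, qs, qt, params) {
  if (inherits(responses, "response_set")) responses <- responses$responses
  stopifnot(is.matrix(responses), inherits(params, "dina_params"))
  if (!inherits(qt, "q_matrix")) qt <- q_matrix(qt)
  S <- .sort_patterns(as_patterns(if (inherits(qs, "state_set"))
    unclass(qs) else qs))
  if (ncol(responses) != nrow(qt))
    stop("responses have ", ncol(responses), " items but Q-matrix has ",
         nrow(qt))
  X <- responses
  storage.mode(X) <- "integer"
  E <- t(irp_matrix(S, qt))                      # states x items eta matrix
  if (params$slip == params$guess) {
    # Hamming distance d(x, eta): |x| + |eta| - 2 x.eta ; integer ties are
    # exact and which.min picks the first (minimal-mastery) state
    D <- outer(rowSums(E), rowSums(X), `+`) - 2L * tcrossprod(E, X)
    best <- apply(D, 2L, which.min)
  } else {
    L <- .dina_loglik(X, E, params)              # states x N
    best <- apply(L, 2L, which.max)
  }
  est <- S[best, , drop = FALSE]
  rownames(est) <- NULL
  est
}

# log-likelihood of each candidate eta row for each response row; zero
# probabilities are floored so that impossible observations give a large
# finite penalty instead of 0 * -Inf artifacts in the matrix products
.dina_loglik <- function(X, E, params) {
  s <- params$slip; g <- params$guess
  lg <- function(p) log(max(p, 1e-300))
  A <- X * lg(1 - s) + (1 - X) * lg(s)           # terms where eta = 1
  B <- X * lg(g) + (1 - X) * lg(1 - g)           # terms where eta = 0
  E %*% t(A) + (1 - E) %*% t(B)
}

#' Pattern match ratio
#'
#' The fraction of examinees whose estimated knowledge state equals the true
#' state in every attribute.
#'
#' @param true_states N x K 0/1 matrix (or pattern strings).
#' @param estimated_states matrix of the same shape.
#' @return proportion in [0, 1].
#' @export
pmr <- function(true_states, estimated_states) {
  a <- as_patterns(true_states)
  b <- as_patterns(estimated_states)
  if (!all(dim(a) == dim(b)))
    stop("true and estimated state matrices must have the same shape")
  mean(rowSums(a != b) == 0L)
}
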