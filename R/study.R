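# Simulation study: five K = 4 hierarchy structures, two or three examinee
# distributions each, several item-category mixes per structure, test length
# 20, flip noise 0.15 / 0.02, 30 replications per cell.

#' Build an examinee population for a study condition
#'
#' The population size is always 30 examinees per knowledge state
#' (N = 30 |Qs|). The \code{"average"} distribution puts exactly 30 in each
#' state; a ratio distribution scales its integer weights to the same total,
#' which must land on integer counts.
#'
#' @param structure an \code{attribute_hierarchy} or canonical structure name.
#' @param dist \code{"average"}, or a list with \code{states} (pattern
#'   strings) and \code{weights} (integer ratio weights) covering all of Qs.
#' @param per_state examinees per state used to fix the total (default 30).
#' @return an \code{examinee_population}.
#' @examples
#' build_population("linear",
#'   list(states = c("0000", "1111", "1000", "1110", "1100"),
#'        weights = c(1, 1, 2, 2, 4)))
#' @export
build_population <- function(structure, dist = "average", per_state = 30L) {
  h <- if (inherits(structure, "attribute_hierarchy")) structure
       else canonical_hierarchy(structure)
  qs <- generate_states(h)
  N <- per_state * nrow(qs)
  if (identical(dist, "average"))
    return(examinee_population(unclass(qs), rep(per_state, nrow(qs))))
  stopifnot(is.list(dist), !is.null(dist$states), !is.null(dist$weights))
  states <- as_patterns(dist$states, K = h$K)
  w <- as.numeric(dist$weights)
  if (length(w) != nrow(states)) stop("one weight per state required")
  if (!setequal(.pat_encode(states), .pat_encode(unclass(qs))))
    stop("ratio distribution must cover exactly the states of Qs")
  counts <- w * N / sum(w)
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("ratio weights do not scale to integer counts for N = ", N)
  examinee_population(states, round(counts))
}

#' Build a test Q-matrix from item categories and ratios
#'
#' Expands distinct item categories into a full-length test: category j is
#' repeated \code{test_length * ratios[j] / sum(ratios)} times, which must be
#' a whole number.
#'
#' @param categories distinct item attribute vectors (pattern strings or
#'   matrix rows).
#' @param ratios positive integer mixing ratios, one per category; default
#'   equal.
#' @param test_length total number of items (default 20).
#' @return a \code{q_matrix} with \code{test_length} rows, category order
#'   preserved.
#' @examples
#' build_qt(c("1000", "1110"), c(1, 3))  # 5 + 15 items
#' @export
build_qt <- function(categories, ratios = NULL, test_length = 20L) {
  cats <- as_patterns(categories)
  if (anyDuplicated(.pat_encode(cats))) stop("item categories must be distinct")
  if (is.null(ratios)) ratios <- rep(1L, nrow(cats))
  ratios <- as.numeric(ratios)
  if (length(ratios) != nrow(cats))
    stop("need one ratio per category: ", nrow(cats), " categories, ",
         length(ratios), " ratios")
  if (any(ratios <= 0)) stop("ratios must be positive")
  mult <- test_length * ratios / sum(ratios)
  if (any(abs(mult - round(mult)) > 1e-9))
    stop("ratios ", paste(ratios, collapse = ":"),
         " do not divide a test of length ", test_length,
         " into whole item counts")
  q_matrix(cats[rep(seq_len(nrow(cats)), round(mult)), , drop = FALSE])
}

#' Default study design
#'
#' Enumerates every cell of the benchmark simulation: structure, examinee
#' distribution and item-category mix with its two ratio variants (labelled
#' \code{a} and \code{b}). Each element describes one cell; crossing with the
#' slip levels happens in [run_study()].
#'
#' The 15-category variant-\code{b} mix allocates the 20 items to the 15
#' categories by largest-remainder rounding of its ratio weights (ties to
#' earlier categories), since 15 categories cannot share 20 items in the
#' nominal proportions exactly.
#'
#' @return a list of condition cells, each a list with \code{structure},
#'   \code{dist_name}, \code{dist}, \code{qt_name}, \code{categories},
#'   \code{ratios}.
#' @export
study_design <- function() {
  dists <- list(
    linear = list(
      average = "average",
      normal = list(states = c("0000", "1111", "1000", "1110", "1100"),
                    weights = c(1, 1, 2, 2, 4))),
    convergent = list(
      average = "average",
      normal = list(states = c("0000", "1111", "1000", "1110", "1100", "1010"),
                    weights = c(1, 1, 2, 2, 7, 7))),
    divergent = list(
      average = "average",
      normal = list(states = c("0000", "1111", "1000", "1110", "1100", "1011",
                               "1010"),
                    weights = c(10, 10, 21, 21, 42, 42, 64))),
    unstructured = list(
      average = "average",
      normal = list(states = c("0000", "1111", "1000", "1011", "1100", "1101",
                               "1010", "1110", "1001"),
                    weights = c(16, 16, 22, 22, 27, 27, 43, 43, 54))),
    independent = list(
      average = "average",
      normal = list(states = c("0000", "1111", "1000", "0111", "0100", "1011",
                               "0010", "1101", "0001", "1110", "1100", "0011",
                               "1010", "0101", "1001", "0110"),
                    weights = c(5, 5, 14, 14, 24, 24, 34, 34, 34, 34,
                                38, 38, 43, 43, 48, 48)),
      mvnormal = list(states = c("0000", "1111", "1000", "0111", "0100", "1011",
                                 "0010", "1101", "0001", "1110", "1100", "0011",
                                 "1010", "0101", "1001", "0110"),
                      weights = c(64, 50, 77, 3, 19, 3, 8, 17, 0, 103,
                                  90, 0, 28, 3, 13, 2))))
  qts <- list(
    linear = list(
      cat1.a = list(c("1100"), 1),
      cat2.a = list(c("1000", "1110"), c(1, 1)),
      cat2.b = list(c("1000", "1110"), c(1, 3)),
      cat4.a = list(c("1000", "1100", "1110", "1111"), c(1, 1, 1, 1)),
      cat4.b = list(c("1000", "1100", "1110", "1111"), c(2, 8, 8, 2))),
    convergent = list(
      cat2.a = list(c("1100", "1010"), c(1, 1)),
      cat2.b = list(c("1100", "1010"), c(1, 3)),
      cat4.a = list(c("1000", "1100", "1010", "1110"), c(1, 1, 1, 1)),
      cat4.b = list(c("1000", "1100", "1010", "1110"), c(2, 8, 8, 2)),
      cat5.a = list(c("1000", "1100", "1010", "1110", "1111"), rep(1, 5)),
      cat5.b = list(c("1000", "1100", "1010", "1110", "1111"),
                    c(2, 4, 8, 4, 2))),
    divergent = list(
      cat2.a = list(c("1100", "1011"), c(1, 1)),
      cat2.b = list(c("1100", "1011"), c(1, 3)),
      cat4.a = list(c("1000", "1100", "1010", "1111"), c(1, 1, 1, 1)),
      cat4.b = list(c("1000", "1100", "1010", "1111"), c(2, 8, 8, 2)),
      cat6.a = list(c("1000", "1100", "1010", "1011", "1110", "1111"),
                    c(2, 4, 4, 4, 4, 2)),
      cat6.b = list(c("1000", "1100", "1010", "1011", "1110", "1111"),
                    c(2, 3, 5, 5, 3, 2))),
    unstructured = list(
      cat4.a = list(c("1000", "1010", "1101", "1011"), c(1, 1, 1, 1)),
      cat4.b = list(c("1000", "1010", "1101", "1011"), c(2, 8, 8, 2)),
      cat6.a = list(c("1000", "1100", "1001", "1101", "1011", "1111"),
                    c(2, 4, 4, 4, 4, 2)),
      cat6.b = list(c("1000", "1100", "1001", "1101", "1011", "1111"),
                    c(2, 3, 5, 5, 3, 2)),
      cat8.a = list(c("1000", "1100", "1010", "1001", "1110", "1101", "1011",
                      "1111"), c(2, 2, 2, 4, 4, 2, 2, 2)),
      cat8.b = list(c("1000", "1100", "1010", "1001", "1110", "1101", "1011",
                      "1111"), c(1, 1, 3, 5, 5, 3, 1, 1))),
    independent = list(
      cat8.a = list(c("1000", "0010", "1100", "1001", "1110", "1101", "1011",
                      "1111"), c(2, 2, 2, 4, 4, 2, 2, 2)),
      cat8.b = list(c("1000", "0010", "1100", "1001", "1110", "1101", "1011",
                      "1111"), c(1, 1, 3, 5, 5, 3, 1, 1)),
      cat12.a = list(c("1000", "0100", "0010", "0001", "1100", "1010", "1001",
                       "0101", "0110", "0011", "1110", "1111"),
                     c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1)),
      cat12.b = list(c("1000", "0100", "0010", "0001", "1100", "1010", "1001",
                       "0101", "0110", "0011", "1110", "1111"),
                     c(1, 1, 1, 1, 3, 3, 3, 3, 1, 1, 1, 1)),
      cat15.a = list(c("1000", "0100", "0010", "0001", "1100", "1010", "1001",
                       "0110", "0101", "0011", "1110", "1101", "1011", "0111",
                       "1111"),
                     c(1, 1, 1, 1, 1, 1, 2, 4, 2, 1, 1, 1, 1, 1, 1)),
      # largest-remainder allocation of the nominal 1:1:1:2:...:2:1:1:1 mix
      cat15.b = list(c("1000", "0100", "0010", "0001", "1100", "1010", "1001",
                       "0110", "0101", "0011", "1110", "1101", "1011", "0111",
                       "1111"),
                     c(1, 1, 1, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1))))
  cells <- list()
  for (structure in names(qts)) {
    for (dist_name in names(dists[[structure]])) {
      for (qt_name in names(qts[[structure]])) {
        spec <- qts[[structure]][[qt_name]]
        cells[[length(cells) + 1L]] <- list(
          structure = structure,
          dist_name = dist_name,
          dist = dists[[structure]][[dist_name]],
          qt_name = qt_name,
          categories = spec[[1L]],
          ratios = spec[[2L]])
      }
    }
  }
  cells
}

#' Run one simulation condition
#'
#' Computes the design-stage indices (TCV, PMR under ideal responses) and
#' the empirical PMR over repeated noisy administrations: simulate flip-noise
#' responses, classify by DINA maximum likelihood with s = g = slip, score
#' the exact-match rate, and average over replications. Replication r uses
#' seed \code{base_seed + r}.
#'
#' @param structure hierarchy or canonical structure name.
#' @param dist \code{"average"} or a ratio list (see [build_population()]).
#' @param categories,ratios item-category mix (see [build_qt()]).
#' @param slip flip probability.
#' @param reps number of replications (default 30).
#' @param base_seed integer seed base.
#' @param per_state examinees per knowledge state (default 30).
#' @param test_length number of items (default 20).
#' @return a one-row data.frame: \code{tcv}, \code{pmr_irp}, \code{mean_pmr},
#'   \code{sd_pmr}, \code{n_examinees}, \code{reps}.
#' @examples
#' run_condition("linear", "average", "1100", 1, slip = 0.15, reps = 3,
#'               base_seed = 1)
#' @export
run_condition <- function(structure, dist, categories, ratios = NULL,
                          slip = 0.15, reps = 30L, base_seed = 1L,
                          per_state = 30L, test_length = 20L) {
  h <- if (inherits(structure, "attribute_hierarchy")) structure
       else canonical_hierarchy(structure)
  qs <- generate_states(h)
  qt <- build_qt(categories, ratios, test_length = test_length)
  pop <- build_population(h, dist, per_state = per_state)
  kdist <- ks_distribution(pop$states, pop$counts)
  tcv_val <- tcv(qt, qs, kdist)$value
  irp_val <- pmr_irp(qs, qt, kdist)
  params <- dina_params(slip)
  pmrs <- vapply(seq_len(reps), function(r) {
    sim <- simulate_responses(pop, qt, slip, seed = base_seed + r)
    est <- mle_classify(sim, qs, qt, params)
    pmr(sim$true_states, est)
  }, numeric(1L))
  data.frame(tcv = tcv_val, pmr_irp = irp_val,
             mean_pmr = mean(pmrs), sd_pmr = stats::sd(pmrs),
             n_examinees = pop$N, reps = reps)
}

#' Run the full simulation study
#'
#' Crosses the design cells with the slip levels and runs each condition.
#' Each condition gets its own deterministic seed derived from \code{seed}.
#'
#' @param design list of cells as produced by [study_design()] (the default).
#' @param slips noise levels (default \code{c(0.15, 0.02)}).
#' @param reps replications per condition (default 30).
#' @param seed base seed.
#' @param per_state,test_length forwarded to [run_condition()].
#' @return a long-format data.frame, one row per condition x slip, with the
#'   identifiers and the [run_condition()] results.
#' @export
run_study <- function(design = study_design(), slips = c(0.15, 0.02),
                      reps = 30L, seed = 1L, per_state = 30L,
                      test_length = 20L) {
  rows <- list()
  cond_id <- 0L
  for (cell in design) {
    for (slip in slips) {
      cond_id <- cond_id + 1L
      res <- run_condition(cell$structure, cell$dist, cell$categories,
                           cell$ratios, slip = slip, reps = reps,
                           base_seed = seed + cond_id * 1000L,
                           per_state = per_state, test_length = test_length)
      rows[[cond_id]] <- cbind(
        data.frame(structure = cell$structure, distribution = cell$dist_name,
                   qt = cell$qt_name, slip = slip, stringsAsFactors = FALSE),
        res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lay a study result out like a benchmark comparison table
#'
#' Pivots the long results of [run_study()] for one structure into the
#' familiar layout: rows = distributions, columns = item-category mixes,
#' cells showing TCV and mean PMR at each slip level.
#'
#' @param results data.frame from [run_study()].
#' @param structure structure name to display.
#' @return a character matrix (distributions x Q-matrix variants).
#' @export
format_study_table <- function(results, structure) {
  sub <- results[results$structure == structure, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no results for structure '", structure, "'")
  dists <- unique(sub$distribution)
  qts <- unique(sub$qt)
  out <- matrix("", length(dists), length(qts),
                dimnames = list(dists, qts))
  for (d in dists) for (q in qts) {
    cell <- sub[sub$distribution == d & sub$qt == q, , drop = FALSE]
    if (nrow(cell) == 0L) next
    parts <- sprintf("PMR(s=%.2f)=%.4f", cell$slip, cell$mean_pmr)
    out[d, q] <- paste0("TCV=", format(round(cell$tcv[1L], 4)), " ",
                        paste(parts, collapse = " "))
  }
  out
}
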