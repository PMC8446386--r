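# File formats: CSV for matrices and distributions (header A1..AK /
# pattern,weight), JSON for hierarchies, Q-matrices with multiplicities and
# run manifests, YAML for study configs. All readers validate and report the
# offending row/column.

#' Read and write attribute hierarchies
#'
#' JSON files hold \code{{"K": int, "edges": [[i, j], ...], "name": str}}
#' with 1-based attribute indices; CSV files hold the K x K adjacency matrix
#' with an \code{A1..AK} header.
#'
#' @param path file path; format chosen by extension (\code{.json} or
#'   \code{.csv}).
#' @return an \code{attribute_hierarchy}.
#' @export
read_hierarchy <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    K <- as.integer(obj$K)
    A <- matrix(0L, K, K)
    edges <- obj$edges
    if (!is.null(edges) && length(edges) > 0L) {
      if (is.list(edges))
        edges <- do.call(rbind, lapply(edges, function(e) as.integer(unlist(e))))
      edges <- matrix(as.integer(edges), ncol = 2L)
      if (any(edges < 1L) || any(edges > K))
        stop("hierarchy edges must use 1-based attribute indices in 1..", K)
      A[edges] <- 1L
    }
    hierarchy(A, name = if (is.null(obj$name)) "custom" else obj$name)
  } else {
    A <- .read_binary_csv(path)
    if (nrow(A) != ncol(A))
      stop("adjacency CSV must be square: got ", nrow(A), " x ", ncol(A))
    hierarchy(A)
  }
}

#' @rdname read_hierarchy
#' @param h an \code{attribute_hierarchy} to write (JSON).
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "attribute_hierarchy"))
  edges <- which(h$adjacency == 1L, arr.ind = TRUE)
  dimnames(edges) <- NULL
  obj <- list(K = h$K,
              edges = if (nrow(edges)) unname(apply(edges, 1L, as.list)) else list(),
              name = h$name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

# strict 0/1 CSV reader with row/column diagnostics
.read_binary_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0L) {
    r <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    c <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop("non-binary entry '", m[bad[1L]], "' in ", path,
         " at data row ", r, ", column ", colnames(m)[c])
  }
  storage.mode(m) <- "integer"
  m
}

#' Read and write Q-matrices
#'
#' CSV files hold one item per row under an \code{A1..AK} header. JSON files
#' hold an array of \code{{"pattern": "1100", "count": 8}} objects, expanded
#' to \code{count} identical items in order.
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @return a \code{q_matrix}.
#' @export
read_qmatrix <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(obj$pattern))
      stop("Q-matrix JSON must be an array of {pattern, count} objects")
    counts <- if (is.null(obj$count)) rep(1L, length(obj$pattern))
              else as.integer(obj$count)
    if (any(counts < 1L)) stop("item counts must be positive")
    q_matrix(rep(obj$pattern, counts))
  } else {
    q_matrix(.read_binary_csv(path))
  }
}

#' @rdname read_qmatrix
#' @param qm a \code{q_matrix}.
#' @param format \code{"csv"} (rows, lossless item order) or \code{"json"}
#'   (distinct patterns with multiplicities).
#' @export
write_qmatrix <- function(qm, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(qm, "q_matrix"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(unclass(qm)), path, row.names = FALSE)
  } else {
    pats <- pattern_strings(unclass(qm))
    tab <- table(factor(pats, levels = unique(pats)))
    jsonlite::write_json(
      data.frame(pattern = names(tab), count = as.integer(tab)),
      path)
  }
  invisible(path)
}

#' Read and write knowledge-state distributions
#'
#' CSV with columns \code{pattern} (e.g. \code{"1100"}) and \code{weight}
#' (counts or proportions).
#'
#' @param path file path.
#' @return a \code{ks_distribution}.
#' @export
read_distribution <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("pattern", "weight") %in% names(df)))
    stop("distribution CSV needs columns 'pattern' and 'weight'")
  ks_distribution(df$pattern, df$weight)
}

#' @rdname read_distribution
#' @param dist a \code{ks_distribution}.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "ks_distribution"))
  utils::write.csv(data.frame(pattern = pattern_strings(dist$states),
                              weight = dist$weights),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration
#'
#' YAML with top-level keys \code{slips}, \code{reps}, \code{seed} and
#' \code{cells}, each cell holding \code{structure}, \code{dist}
#' (\code{"average"} or \code{states}/\code{weights}), \code{categories} and
#' \code{ratios}. The packaged default design is returned when \code{path}
#' is \code{NULL}.
#'
#' @param path YAML file, or \code{NULL} for the built-in design.
#' @return a list with \code{cells}, \code{slips}, \code{reps}, \code{seed}.
#' @export
read_study_config <- function(path = NULL) {
  if (is.null(path))
    return(list(cells = study_design(), slips = c(0.15, 0.02),
                reps = 30L, seed = 1L))
  cfg <- yaml::read_yaml(path)
  cells <- lapply(cfg$cells, function(cell) {
    dist <- cell$dist
    if (!identical(dist, "average"))
      dist <- list(states = unlist(dist$states),
                   weights = as.numeric(unlist(dist$weights)))
    list(structure = cell$structure,
         dist_name = if (identical(dist, "average")) "average"
                     else if (!is.null(cell$dist_name)) cell$dist_name
                     else "ratio",
         dist = dist,
         qt_name = if (is.null(cell$qt_name)) "qt" else cell$qt_name,
         categories = unlist(cell$categories),
         ratios = if (is.null(cell$ratios)) NULL else as.numeric(unlist(cell$ratios)))
  })
  list(cells = cells,
       slips = if (is.null(cfg$slips)) c(0.15, 0.02) else as.numeric(cfg$slips),
       reps = if (is.null(cfg$reps)) 30L else as.integer(cfg$reps),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Random test-design instances
#'
#' Draws a random DAG hierarchy on K attributes, a random nonempty test
#' Q-matrix from its consistent items (with random multiplicities), and a
#' random population distribution over its states (uniform, Dirichlet-like
#' continuous, or spiked on a few states). Used to exercise the
#' TCV = PMR-under-ideal-responses identity across the whole design space.
#'
#' @param K number of attributes (2..6).
#' @param seed integer seed; identical seeds give identical instances.
#' @return a list with \code{hierarchy}, \code{qt}, \code{dist}, \code{qs}.
#' @export
fixture_random_instance <- function(K, seed) {
  stopifnot(K >= 2L, K <= 6L)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  # random DAG: random topological order, edges only forward
  ord <- sample(K)
  A <- matrix(0L, K, K)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    if (stats::runif(1) < 0.35) A[ord[i], ord[j]] <- 1L
  h <- hierarchy(A, name = "random")
  qr <- generate_items(h)
  qs <- generate_states(h)
  n_cat <- sample(seq_len(min(6L, nrow(qr))), 1L)
  cats <- unclass(qr)[sample(nrow(qr), n_cat), , drop = FALSE]
  mult <- sample(1:3, n_cat, replace = TRUE)
  qt <- q_matrix(cats[rep(seq_len(n_cat), mult), , drop = FALSE])
  kind <- sample(c("uniform", "dirichlet", "spiked"), 1L)
  w <- switch(kind,
    uniform = rep(1, nrow(qs)),
    dirichlet = stats::rgamma(nrow(qs), shape = 1),
    spiked = {
      w0 <- rep(0.01, nrow(qs))
      w0[sample(nrow(qs), min(3L, nrow(qs)))] <- 1
      w0
    })
  list(hierarchy = h, qt = qt,
       dist = ks_distribution(unclass(qs), w), qs = qs)
}

#' Write a run manifest
#'
#' Records what produced a set of results: seed, package version, timestamp,
#' per-condition seeds and the configuration itself (embedded verbatim so the
#' manifest round-trips losslessly through JSON).
#'
#' @param path output JSON path.
#' @param seed base seed.
#' @param config the configuration list used for the run.
#' @param condition_seeds optional named vector of per-condition seeds.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config = NULL, condition_seeds = NULL) {
  manifest <- list(
    package = "tcvcd",
    version = as.character(utils::packageVersion("tcvcd")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    condition_seeds = if (is.null(condition_seeds)) NULL
                      else as.list(condition_seeds),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
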