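test_that("DINA response probabilities and parameter validation", {
  p <- dina_params(0.15, 0.02)
  expect_equal(dina_prob("110", "110", p), 0.85)
  expect_equal(dina_prob("100", "110", p), 0.02)
  expect_error(dina_params(1.0), "probability")
  expect_error(dina_params(-0.1), "probability")
  expect_error(dina_params(0.6, 0.5), "identifiable")

  # noiseless limit reduces to the ideal response
  p0 <- dina_params(0, 0)
  for (a in c("00", "10", "01", "11")) for (q in c("10", "01", "11"))
    expect_equal(dina_prob(a, q, p0), ideal_response(a, q))
})

test_that("simulation flips ideal responses at the requested rate", {
  h <- canonical_hierarchy("linear", 4)
  qs <- generate_states(h)
  qt <- build_qt(c("1000", "1100", "1110", "1111"), c(1, 1, 1, 1))
  pop <- build_population(h, "average")

  # slip 0: responses equal the IRP of the true state
  sim <- simulate_responses(pop, qt, slip = 0, seed = 1)
  eta <- t(irp_matrix(sim$true_states, qt))
  expect_identical(sim$responses, {
    e <- eta; dimnames(e) <- dimnames(sim$responses); storage.mode(e) <- "integer"; e
  })

  # slip 0.15, 20 items: mean flips per examinee near 3
  sim <- simulate_responses(pop, qt, slip = 0.15, seed = 2)
  flips <- rowSums(sim$responses != t(irp_matrix(sim$true_states, qt)))
  expect_lt(abs(mean(flips) - 3), 3 * sqrt(20 * .15 * .85 / pop$N))

  expect_error(simulate_responses(pop, qt, slip = 1), "0.5")
  # reproducible given the seed
  s1 <- simulate_responses(pop, qt, 0.15, seed = 9)
  s2 <- simulate_responses(pop, qt, 0.15, seed = 9)
  expect_identical(s1$responses, s2$responses)
})

test_that("noiseless classification lands on the IRP-class representative", {
  for (nm in c("linear", "convergent", "independent")) {
    h <- canonical_hierarchy(nm, 4)
    qs <- generate_states(h)
    qt <- build_qt(if (nm == "linear") "1100" else c("1100", "1010"))
    pop <- build_population(h, "average")
    sim <- simulate_responses(pop, qt, slip = 0, seed = 3)
    est <- mle_classify(sim, qs, qt, dina_params(0.15))
    # each examinee maps to the representative of its true state's class
    part <- partition_states(qs, qt)
    rep_of <- new.env()
    for (cl in part$classes)
      for (s in pattern_strings(cl$members))
        assign(s, cl$representative, envir = rep_of)
    want <- t(vapply(pattern_strings(sim$true_states),
                     function(s) get(s, envir = rep_of), integer(4)))
    expect_equal(unname(est), unname(want))
    # hence PMR equals the ideal-response PMR exactly
    expect_identical(pmr(sim$true_states, est),
                     pmr_irp(qs, qt, ks_distribution(pop$states, pop$counts)))
  }
})

test_that("Hamming shortcut picks a likelihood-maximizing state when s = g", {
  h <- canonical_hierarchy("divergent", 4)
  qs <- generate_states(h)
  qt <- build_qt(c("1100", "1011"), c(1, 1))
  pop <- build_population(h, "average")
  sim <- simulate_responses(pop, qt, slip = 0.15, seed = 11)
  est <- mle_classify(sim, qs, qt, dina_params(0.15, 0.15))
  # independent likelihood oracle built from per-item DINA probabilities
  loglik <- function(x, state) {
    sum(vapply(seq_len(nrow(qt)), function(j) {
      pj <- dina_prob(state, unclass(qt)[j, ], dina_params(0.15, 0.15))
      log(if (x[j] == 1) pj else 1 - pj)
    }, numeric(1)))
  }
  for (i in seq(1, pop$N, by = 17)) {
    ll_all <- vapply(seq_len(nrow(qs)),
                     function(s) loglik(sim$responses[i, ], unclass(qs)[s, ]),
                     numeric(1))
    expect_equal(loglik(sim$responses[i, ], est[i, ]), max(ll_all),
                 tolerance = 1e-12)
  }
})

test_that("general log-likelihood route classifies asymmetric-noise data", {
  # with g << s a state below the truth explains missing successes better
  h <- canonical_hierarchy("linear", 4)
  qs <- generate_states(h)
  qt <- build_qt(c("1000", "1100", "1110", "1111"))
  # deterministic response: ideal pattern of (1110) -> recovered exactly
  x <- matrix(irp_matrix(as_patterns("1110"), qt)[, 1], nrow = 1)
  est <- mle_classify(x, qs, qt, dina_params(0.15, 0.02))
  expect_identical(unname(est[1, ]), c(1L, 1L, 1L, 0L))
})

test_that("smaller slip brings PMR closer to TCV, reaching it at zero", {
  h <- canonical_hierarchy("convergent", 4)
  qs <- generate_states(h)
  qt <- build_qt(c("1100", "1010"))
  pop <- build_population(h, "average")
  tcv_val <- tcv(qt, qs, ks_distribution(pop$states, pop$counts))$value
  gaps <- vapply(c(0, 0.02, 0.15), function(s) {
    ms <- vapply(1:10, function(r) {
      sim <- simulate_responses(pop, qt, s, seed = 500 + r)
      pmr(sim$true_states, mle_classify(sim, qs, qt, dina_params(s)))
    }, numeric(1))
    tcv_val - mean(ms)
  }, numeric(1))
  expect_identical(gaps[1], 0)            # slip 0 is exact
  expect_true(all(diff(gaps) > -1e-9))    # monotone in expectation
  expect_true(all(gaps >= -1e-12))        # never above the bound
})

test_that("pmr counts exact whole-vector matches", {
  a <- as_patterns(c("1100", "1110", "0000"))
  expect_identical(pmr(a, a), 1)
  expect_identical(pmr(a, as_patterns(c("0011", "0001", "1111"))), 0)
  b <- a; b[2, 4] <- 1L
  expect_equal(pmr(a, b), 2 / 3)
  expect_error(pmr(a, a[1:2, ]), "shape")
})
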