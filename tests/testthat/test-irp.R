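test_that("ideal responses follow the dominance rule", {
  expect_identical(ideal_response("100", "100"), 1L)
  expect_identical(ideal_response("100", "010"), 0L)
  expect_identical(ideal_response("110", "111"), 0L)
  for (s in c("0000", "1010", "1111"))
    expect_identical(ideal_response(s, s), 1L)
  expect_error(ideal_response("10", "100"), "attributes")
})

test_that("the worked three-attribute IRP matrix is reproduced exactly", {
  qs <- generate_states(canonical_hierarchy("independent", 3))
  # the published state order: 000,100,010,001,110,101,011,111
  states <- as_patterns(c("000", "100", "010", "001", "110", "101", "011",
                          "111"))
  qt <- q_matrix(c("100", "010", "101"))
  M <- irp_matrix(states, qt)
  want <- rbind(c(0, 1, 0, 0, 1, 1, 0, 1),
                c(0, 0, 1, 0, 1, 0, 1, 1),
                c(0, 0, 0, 0, 0, 1, 0, 1))
  expect_equal(unname(M), want, ignore_attr = TRUE)
  # package canonical state order carries the same columns
  expect_same_patterns(unclass(qs), states)
})

test_that("single-item IRP row over the linear states", {
  qs <- generate_states(canonical_hierarchy("linear", 4))
  M <- irp_matrix(qs, q_matrix("1100"))
  expect_equal(unname(M[1, ]), c(0, 0, 1, 1, 1))
  # the zero state answers nothing
  expect_true(all(M[, 1] == 0))
})

test_that("IRP is monotone in the dominance order on states", {
  inst <- fixture_random_instance(K = 5, seed = 99)
  M <- irp_matrix(inst$qs, inst$qt)
  codes <- apply(unclass(inst$qs), 1, paste0, collapse = "")
  S <- unclass(inst$qs)
  for (i in seq_len(nrow(S))) for (j in seq_len(nrow(S))) {
    if (all(S[i, ] >= S[j, ]))
      expect_true(all(M[, i] >= M[, j]), info = paste(codes[i], codes[j]))
  }
})

test_that("partition classes match the worked example", {
  qs <- generate_states(canonical_hierarchy("independent", 3))
  qt <- q_matrix(c("100", "010", "101"))
  p <- partition_states(qs, qt)
  expect_equal(p$n_classes, 6L)
  expect_equal(p$n_classes, nrow(augment(qt)) + 1L)
  # (001) shares the zero class; (011) shares (010)'s class
  zero_class <- p$classes[["000"]]
  expect_same_patterns(zero_class$members, c("000", "001"))
  expect_same_patterns(p$classes[["010"]]$members, c("010", "011"))
  # representatives are minimal members of their class
  for (cl in p$classes) {
    expect_true(paste0(cl$representative, collapse = "") %in%
                  pattern_strings(cl$members))
    for (r in seq_len(nrow(cl$members)))
      expect_true(all(cl$members[r, ] >= cl$representative))
  }
})

test_that("partition is exhaustive, disjoint, with |Qt+|+1 classes", {
  for (seed in 301:320) {
    inst <- fixture_random_instance(K = 3 + (seed %% 3), seed = seed)
    p <- partition_states(inst$qs, inst$qt)
    expect_equal(p$n_classes, nrow(augment(inst$qt)) + 1L)
    all_members <- do.call(rbind, lapply(p$classes, `[[`, "members"))
    expect_same_patterns(all_members, unclass(inst$qs))
    expect_equal(nrow(all_members), nrow(inst$qs))
  }
})

test_that("a test spanning the reachability columns separates every state", {
  h <- canonical_hierarchy("divergent", 4)
  qs <- generate_states(h)
  qt <- q_matrix(t(reachability(h)))
  p <- partition_states(qs, qt)
  expect_equal(p$n_classes, nrow(qs))
  expect_true(all(vapply(p$classes, function(cl) nrow(cl$members),
                         integer(1)) == 1L))
})

test_that("pmr_irp matches the published checks", {
  qs3 <- generate_states(canonical_hierarchy("independent", 3))
  expect_identical(pmr_irp(qs3, q_matrix(c("100", "010", "101"))), 3 / 4)

  # perfect test: every distribution gives 1
  h <- canonical_hierarchy("linear", 4)
  qs <- generate_states(h)
  qt <- q_matrix(t(reachability(h)))
  d <- ks_distribution(unclass(qs), c(5, 1, 9, 2, 3))
  expect_identical(pmr_irp(qs, qt, d), 1)

  # divergent two-category test under the benchmark ratio distribution
  hd <- canonical_hierarchy("divergent", 4)
  qsd <- generate_states(hd)
  dd <- ks_distribution(c("0000", "1111", "1000", "1110", "1100", "1011",
                          "1010"),
                        c(10, 10, 21, 21, 42, 42, 64))
  expect_identical(pmr_irp(qsd, q_matrix(c("1100", "1011")), dd), 104 / 210)
})
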