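test_that("populations scale ratio weights to 30 examinees per state", {
  pop <- build_population("linear", "average")
  expect_equal(pop$N, 150L)
  expect_true(all(pop$counts == 30L))

  pop <- build_population("linear",
    list(states = c("0000", "1111", "1000", "1110", "1100"),
         weights = c(1, 1, 2, 2, 4)))
  expect_equal(pop$N, 150L)
  got <- stats::setNames(pop$counts, pattern_strings(pop$states))
  expect_equal(got[c("0000", "1111", "1000", "1110", "1100")],
               c("0000" = 15L, "1111" = 15L, "1000" = 30L, "1110" = 30L,
                 "1100" = 60L))

  # printed multivariate-normal counts already total 30 x 16
  cells <- study_design()
  mvn <- Filter(function(c) c$dist_name == "mvnormal", cells)[[1]]
  pop <- build_population("independent", mvn$dist)
  expect_equal(pop$N, 480L)

  expect_error(build_population("linear",
    list(states = c("0000", "1111", "1000", "1110", "1100"),
         weights = c(1, 1, 1, 1, 3))),
    "integer counts")
  expect_error(build_population("linear",
    list(states = c("0000", "1111", "1000", "1110"), weights = c(1, 1, 1, 1))),
    "cover exactly")
})

test_that("build_qt expands categories by their ratios to the test length", {
  qt <- build_qt(c("1000", "1110"), c(1, 3))
  tab <- table(pattern_strings(unclass(qt)))
  expect_equal(as.integer(tab[c("1000", "1110")]), c(5L, 15L))

  qt <- build_qt(c("1000", "1100", "1110", "1111"), c(2, 8, 8, 2))
  expect_equal(unname(table(pattern_strings(unclass(qt)))[
    c("1000", "1100", "1110", "1111")]), c(2L, 8L, 8L, 2L),
    ignore_attr = TRUE)

  qt <- build_qt("1100")
  expect_equal(nrow(qt), 20L)
  expect_equal(unique(pattern_strings(unclass(qt))), "1100")

  expect_error(build_qt(c("1000", "1110"), c(1, 2)), "whole item counts")
  expect_error(build_qt(c("1000", "1000")), "distinct")
  expect_error(build_qt(c("1000", "1110"), c(1, 2, 3)), "one ratio per")
})

test_that("every design cell reproduces its published TCV exactly", {
  want <- expected_cell_tcv()
  for (cell in study_design()) {
    h <- canonical_hierarchy(cell$structure)
    qs <- generate_states(h)
    qt <- build_qt(cell$categories, cell$ratios)
    pop <- build_population(h, cell$dist)
    d <- ks_distribution(pop$states, pop$counts)
    got <- tcv(qt, qs, d)$value
    expect_identical(
      got, want[[cell$structure]][[cell$dist_name]][[cell$qt_name]],
      info = paste(cell$structure, cell$dist_name, cell$qt_name))
  }
})

test_that("design cells satisfy the benchmark invariants", {
  cells <- study_design()
  expect_length(cells, 64L)
  for (cell in cells) {
    qt <- build_qt(cell$categories, cell$ratios)
    expect_equal(nrow(qt), 20L)
    # categories are hierarchy-consistent
    expect_silent(q_matrix(cell$categories,
                           hierarchy = canonical_hierarchy(cell$structure)))
  }
})

test_that("run_condition returns design indices plus simulated PMR", {
  res <- run_condition("linear", "average", "1100", slip = 0.15, reps = 5,
                       base_seed = 77)
  expect_identical(res$tcv, 2 / 5)
  expect_identical(res$pmr_irp, 2 / 5)
  expect_lt(abs(res$mean_pmr - 0.4), 0.05)
  expect_equal(res$n_examinees, 150L)

  # slip 0: empirical PMR equals TCV with zero variance
  res0 <- run_condition("divergent", "average", c("1100", "1011"), c(1, 3),
                        slip = 0, reps = 3, base_seed = 77)
  expect_identical(res0$mean_pmr, res0$tcv)
  expect_identical(res0$sd_pmr, 0)

  # deterministic given the base seed
  r1 <- run_condition("convergent", "average", c("1100", "1010"), slip = 0.15,
                      reps = 3, base_seed = 5)
  r2 <- run_condition("convergent", "average", c("1100", "1010"), slip = 0.15,
                      reps = 3, base_seed = 5)
  expect_identical(r1, r2)
})

test_that("a smoke-size study run keeps the TCV column and layout", {
  design <- Filter(function(c) c$structure == "linear", study_design())
  res <- run_study(design, slips = 0.15, reps = 2, seed = 3)
  expect_equal(nrow(res), 10L)
  expect_identical(res$tcv[res$distribution == "average" & res$qt == "cat1.a"],
                   2 / 5)
  tab <- format_study_table(res, "linear")
  expect_equal(dim(tab), c(2L, 5L))
  expect_match(tab["average", "cat1.a"], "TCV=0.4")
})
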