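test_that("kinetic coupling yield matches the independent ODE oracle", {
  skip_if_not_installed("deSolve")
  m <- yield_model_kinetic()
  for (r in c(4000 / 850, 850 / 13, 2, 10, 100)) {
    expect_equal(m$per_coupling(r * 10, 10), ode_yield(r), tolerance = 1e-4)
  }
})

test_that("coupling yield obeys the limit and ordering contracts", {
  m <- yield_model_kinetic()
  expect_equal(m$per_coupling(100, 0), 1)            # uncontested acceptor
  expect_gt(m$per_coupling(1e7, 1), 0.999)           # r -> Inf limit
  # r = 2: x^2 + x = 1 has the closed-form root (sqrt(5) - 1) / 2
  expect_equal(m$per_coupling(10, 5), (sqrt(5) - 1) / 2, tolerance = 1e-9)
  expect_error(m$per_coupling(5, 10), "ordering")
  expect_error(m$per_coupling(5, 5), "ordering")
  # monotone in the rrv ratio
  ys <- vapply(c(1.5, 2, 5, 20, 100), function(r) m$per_coupling(r, 1),
               numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("overall yield is the product over couplings; single BBL gives 1", {
  m <- yield_model_kinetic()
  expect_equal(compute_overall_yield(c(0)), 1)
  expect_equal(compute_overall_yield(c(263, 51, 0), m),
               m$per_coupling(263, 51) * m$per_coupling(51, 0))
  expect_error(compute_overall_yield(c(51, 263, 0), m), "ordering")
})

test_that("the linear trisaccharide fixture returns the published ordering", {
  sc <- fixture_scenario("lacnac_3")
  plans <- search_no_fragments(sc$target, sc$library)
  expect_length(plans, 1L)
  expect_equal(plans[[1]]$rrvs, c(263, 51, 0))
  expect_equal(plan_sizes(plans[[1]]), c(2L, 2L, 2L))
  # reassigning the RRVs so the required order would ascend kills the plan
  lib2 <- sc$library
  lib2[["9"]]$rrv <- 51
  lib2[["10"]]$rrv <- 263
  expect_length(search_no_fragments(sc$target, lib2), 0L)
})

test_that("precursor matches are excluded from the no-fragment mode", {
  sc <- fixture_scenario("globoH_132")
  # the Globo-H library only routes via a Lev deprotection, so no one-pot
  expect_length(search_no_fragments(sc$target, sc$library), 0L)
})

test_that("search_no_fragments equals brute-force tiling on random instances", {
  checked <- 0L
  nonempty <- 0L
  for (s in 1:60) {
    tree <- random_tree(sample(2:6, 1), seed = 1000 + s)
    lib <- random_library(tree, sample(5:25, 1), seed = 2000 + s)
    got <- plan_signatures(search_no_fragments(tree, lib))
    want <- oracle_onepot_signatures(tree, lib)
    expect_equal(got, want)
    checked <- checked + 1L
    if (length(want)) nonempty <- nonempty + 1L
  }
  expect_equal(checked, 60L)
  expect_gt(nonempty, 5L)  # the generator must exercise solvable cases
})

test_that("plans partition the residues, descend strictly and are deterministic", {
  for (s in 1:15) {
    tree <- random_tree(sample(3:6, 1), seed = 3000 + s)
    lib <- random_library(tree, 20, seed = 4000 + s)
    plans <- search_no_fragments(tree, lib)
    for (p in plans) {
      ids <- sort(unlist(lapply(p$steps, `[[`, "ids")))
      expect_equal(ids, sort(as.integer(names(tree$residues))))
      expect_true(all(diff(p$rrvs) < 0))
      expect_equal(p$rrvs[length(p$rrvs)], 0)
      expect_lte(p$n_bbls, 4L)
    }
    again <- search_no_fragments(tree, lib)
    expect_identical(plan_signatures(plans), plan_signatures(again))
    if (length(plans) > 1L) {
      expect_true(all(diff(vapply(plans, `[[`, numeric(1),
                                  "overall_yield")) <= 1e-12))
    }
  }
})

test_that("increasing a donor/acceptor ratio never lowers the overall yield", {
  m <- yield_model_kinetic()
  base <- compute_overall_yield(c(800, 100, 0), m)
  expect_gte(compute_overall_yield(c(1600, 100, 0), m), base)
  expect_gte(compute_overall_yield(c(800, 50, 0), m),
             compute_overall_yield(c(800, 100, 0), m) - 1e-12)
})

test_that("max_bbls is honoured and warned about past the side-reaction limit", {
  sc <- fixture_scenario("lacnac_3")
  expect_length(search_no_fragments(sc$target, sc$library, max_bbls = 2L), 0L)
  expect_warning(search_no_fragments(sc$target, sc$library, max_bbls = 5L),
                 "side reactions")
  expect_error(search_no_fragments(sc$target, sc$library, max_bbls = 0L),
               "max_bbls")
})
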