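test_that("Globo-H decomposes as [1+3+2] with the published fragment RRVs", {
  sc <- fixture_scenario("globoH_132")
  plans <- fragment_search(sc$target, sc$library)
  expect_gt(length(plans), 0L)
  top <- plans[[1]]
  expect_equal(plan_sizes(top), c(1L, 3L, 2L))
  expect_equal(top$strategy, "onepot_fragments")
  f2 <- top$fragments[[2]]
  expect_equal(f2$rrvs, c(4000, 850, 13))
  expect_equal(f2$effective_rrv, 13)  # reducing-end BBL of the fragment
  # the masked fucose attachment is deprotected after fragment synthesis
  expect_length(f2$post_synthesis_deprotections, 1L)
  expect_equal(f2$post_synthesis_deprotections[[1]]$token, "OLev")
  expect_equal(f2$post_synthesis_deprotections[[1]]$position, 2)
  # assembly: 72,000 -> 13 -> 0
  expect_equal(top$effective_rrvs, c(72000, 13, 0))
  expect_equal(top$role_classes, c("large", "medium", "zero"))
})

test_that("every fragment holds 1-3 BBLs and partitions the residues", {
  for (nm in c("globoH_132", "heparin_122", "lacnac_3")) {
    sc <- fixture_scenario(nm)
    for (p in fragment_search(sc$target, sc$library)) {
      ids <- sort(unlist(lapply(p$fragments, `[[`, "ids")))
      expect_equal(ids, sort(as.integer(names(sc$target$residues))))
      for (f in p$fragments) {
        expect_true(f$n_bbls >= 1L && f$n_bbls <= 3L)
        expect_true(all(diff(f$rrvs) < 0))  # internal one-pot descent
      }
    }
  }
})

test_that("fragment-mode sizes match the published strategies", {
  sc <- fixture_scenario("heparin_122")
  plans <- fragment_search(sc$target, sc$library)
  expect_gt(length(plans), 0L)
  expect_equal(plan_sizes(plans[[1]]), c(1L, 2L, 2L))
  sc2 <- fixture_scenario("ssea4_213")
  plans2 <- fragment_search(sc2$target, sc2$library)
  expect_equal(plan_sizes(plans2[[1]]), c(2L, 1L, 3L))
})

test_that("fragment boundaries only occur at masked or free-single-BBL joints", {
  for (s in 1:8) {
    tree <- random_tree(sample(4:8, 1), seed = 5000 + s)
    lib <- random_library(tree, 20, seed = 6000 + s)
    for (p in fragment_search(tree, lib)) {
      for (f in p$fragments) {
        ext <- glycoplan:::.external_links(tree, f$ids)
        need <- sum(lengths(ext))
        if (f$n_bbls > 1L) {
          # multi-BBL fragment: every external joint must be deprotected later
          expect_equal(length(f$post_synthesis_deprotections), need)
        }
        # an RRV-0 step only terminates the root fragment
        if (!(tree$root %in% f$ids)) expect_true(all(f$rrvs > 0))
      }
    }
  }
})

test_that("connection scheduling assigns ordinal role classes", {
  # two fragments, reducing-end fragment RRV 0, donor fragment RRV unknown
  mk_frag <- function(ids, root_id, rrv, eff = rrv) {
    structure(list(ids = ids, root_id = root_id,
                   steps = list(list(ids = ids,
                                     match = list(bbl_index = "x",
                                                  kind = "perfect",
                                                  deprotections = list()),
                                     rrv = rrv)),
                   rrvs = rrv, bbl_sizes = length(ids), n_bbls = 1L,
                   fragment_yield = 1,
                   post_synthesis_deprotections = list(),
                   midpot_deprotections = list(),
                   effective_rrv = eff,
                   effective_rrv_source = "reducing-end BBL"),
              class = "synthesis_fragment")
  }
  tree <- parse_glycan("Gal(b1-3)Gal(b1-4)Glc")
  f1 <- mk_frag(1L, 1L, 50, eff = NA_real_)
  f2 <- mk_frag(c(2L, 3L), 3L, 0)
  sched <- schedule_connection(list(f1, f2), tree)
  expect_equal(sched$strategy, "distinct_leaving_groups")  # eff unknown
  expect_equal(sched$role_classes, c("large", "zero"))
  # known effective RRVs: one-pot assembly
  f1b <- mk_frag(1L, 1L, 50)
  sched2 <- schedule_connection(list(f1b, f2), tree)
  expect_equal(sched2$strategy, "onepot_fragments")
  expect_equal(sched2$role_classes, c("large", "zero"))
  expect_equal(sched2$effective_rrvs, c(50, 0))
  # explicit one-pot request with unorderable RRVs is infeasible
  f1c <- mk_frag(1L, 1L, 0)
  f2c <- mk_frag(c(2L, 3L), 3L, 40)
  expect_error(schedule_connection(list(f1c, f2c), tree,
                                   strategy = "onepot_fragments"),
               "infeasible")
})

test_that("four chain fragments get large/medium/small/zero; five go hybrid", {
  # linear chains so that every fragment sits on the major chain
  mk <- function(k) {
    txt <- paste0(paste(rep("Gal(b1-3)", k - 1), collapse = ""), "Glc")
    tree <- parse_glycan(txt)
    frags <- lapply(seq_len(k), function(i) {
      structure(list(ids = i, root_id = i,
                     steps = list(list(ids = i,
                                       match = list(bbl_index = paste0("b", i),
                                                    kind = "perfect",
                                                    deprotections = list()),
                                       rrv = k - i)),
                     rrvs = k - i, bbl_sizes = 1L, n_bbls = 1L,
                     fragment_yield = 1,
                     post_synthesis_deprotections = list(),
                     midpot_deprotections = list(),
                     effective_rrv = (k - i) * 10,
                     effective_rrv_source = "reducing-end BBL"),
                class = "synthesis_fragment")
    })
    frags[[k]]$effective_rrv <- 0
    schedule_connection(frags, tree)
  }
  s4 <- mk(4)
  expect_equal(s4$role_classes, c("large", "medium", "small", "zero"))
  s5 <- mk(5)
  expect_equal(s5$strategy, "hybrid")
})

test_that("effective fragment RRV defaults to the reducing-end BBL, with overrides", {
  sc <- fixture_scenario("globoH_132")
  f2 <- fragment_search(sc$target, sc$library)[[1]]$fragments[[2]]
  expect_equal(effective_rrv_of_fragment(f2), 13)
  expect_equal(effective_rrv_of_fragment(f2, override = 20), 20)
  expect_equal(effective_rrv_of_fragment(f2, model = function(f) 2 * f$rrvs[1]),
               8000)
})
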