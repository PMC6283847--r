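# A fully protected galactose donor and variants used across cases.
gal_bbl <- function(index = "g", rrv = 100, ...) {
  subs <- c("2" = "OBn", "3" = "OBn", "4" = "OBn", "6" = "OBn")
  over <- unlist(list(...))
  subs[names(over)] <- over
  building_block(index, paste0("Gal-", index),
                 glycan_tree(list(residue(1, "Gal", anomeric = "b",
                                          substituents = subs))),
                 rrv = rrv)
}

leaf_state <- function() glycan_tree(list(residue(7, "Gal", anomeric = "b")))

test_that("a fully protected BBL perfectly matches a leaf state", {
  m <- match_state(gal_bbl(), leaf_state())
  expect_equal(m$kind, "perfect")
  expect_length(m$deprotections, 0L)
  expect_equal(unname(m$residue_mapping[["7"]]), 1L)
})

test_that("a Lev-masked position gives a precursor match with that deprotection", {
  bbl <- gal_bbl("lev", "2" = "OLev")
  m <- match_state(bbl, leaf_state(), child_links = list("7" = 2L))
  expect_equal(m$kind, "precursor")
  expect_equal(m$deprotections[[1]]$position, 2)
  expect_equal(m$deprotections[[1]]$token, "OLev")
})

test_that("matching rejects the documented failure modes", {
  # free hydroxyl at a position with no child: not fully protected
  expect_null(match_state(gal_bbl("oh", "3" = "OH"), leaf_state()))
  # child link masked by a permanent group
  expect_null(match_state(gal_bbl(), leaf_state(), list("7" = 2L)))
  # duplicated removable token across two child links: deprotection ambiguous
  bbl <- gal_bbl("dup", "3" = "OLev", "6" = "OLev")
  expect_null(match_state(bbl, leaf_state(), list("7" = c(3L, 6L))))
  # but the same token at a non-child position does not break uniqueness
  bbl2 <- gal_bbl("ok", "3" = "OLev", "6" = "OLev")
  m <- match_state(bbl2, leaf_state(), list("7" = 3L))
  expect_equal(m$kind, "precursor")
  # sugar type / anomeric mismatch
  glc_state <- glycan_tree(list(residue(7, "Glc", anomeric = "b")))
  expect_null(match_state(gal_bbl(), glc_state))
  a_state <- glycan_tree(list(residue(7, "Gal", anomeric = "a")))
  expect_null(match_state(gal_bbl(), a_state))
  # size mismatch is a contract violation, not a quiet no-match
  two <- glycoplan:::induced_state(parse_glycan("Gal(b1-4)Glc"), c(1, 2))
  expect_error(match_state(gal_bbl(), two), "residue count")
})

test_that("multi-residue internal linkage disagreement gives no match", {
  lac13 <- parse_glycan("Gal(b1-3)Glc")
  lac14_bbl <- building_block("L", "lac", glycan_tree(list(
    residue(1, "Gal", pid = 2, anomeric = "b", link = 4,
            substituents = c("2" = "OBn", "3" = "OBn", "4" = "OBn",
                             "6" = "OBn")),
    residue(2, "Glc", anomeric = "b",
            substituents = c("2" = "OBn", "3" = "OBn", "6" = "OBn")))),
    rrv = 50)
  expect_null(match_state(lac14_bbl,
                          glycoplan:::induced_state(lac13, c(1, 2))))
  lac14 <- parse_glycan("Gal(b1-4)Glc")
  expect_equal(match_state(lac14_bbl,
                           glycoplan:::induced_state(lac14, c(1, 2)))$kind,
               "perfect")
})

test_that("candidate_list equals per-BBL brute force on random instances", {
  for (s in 1:25) {
    tree <- random_tree(sample(2:8, 1), seed = 300 + s)
    lib <- random_library(tree, sample(5:20, 1), seed = 600 + s)
    # random connected state cut from the tree
    start <- sample(as.integer(names(tree$residues)), 1)
    S <- start
    while (length(S) < 3L && runif(1) < 0.6) {
      kids <- setdiff(unlist(lapply(S, function(i) tree_kids(tree, i))), S)
      if (!length(kids)) break
      S <- c(S, sample(c(kids, kids), 1))
    }
    state <- glycoplan:::induced_state(tree, S)
    cl <- oracle_child_links(tree, S)
    got <- candidate_list(lib, state, cl)
    # oracle: plain loop + manual ordering contract
    hits <- list()
    for (bb in lib) {
      if (glycoplan:::n_residues(bb$tree) != length(S)) next
      m <- match_state(bb, state, cl)
      if (!is.null(m)) { m$rrv <- bb$rrv; hits[[length(hits) + 1L]] <- m }
    }
    expect_length(got, length(hits))
    if (length(hits)) {
      kind <- vapply(hits, `[[`, character(1), "kind")
      rrv <- vapply(hits, `[[`, numeric(1), "rrv")
      idx <- vapply(hits, `[[`, character(1), "bbl_index")
      want <- hits[order(kind != "perfect", -rrv, idx)]
      expect_equal(vapply(got, `[[`, character(1), "bbl_index"),
                   vapply(want, `[[`, character(1), "bbl_index"))
      # each BBL appears at most once
      expect_false(anyDuplicated(vapply(got, `[[`, character(1),
                                        "bbl_index")) > 0)
    }
  }
})

test_that("removing a BBL from the library never adds matches", {
  tree <- random_tree(5, seed = 42)
  lib <- random_library(tree, 15, seed = 43)
  S <- as.integer(names(tree$residues))[1]
  state <- glycoplan:::induced_state(tree, S)
  cl <- oracle_child_links(tree, S)
  full <- vapply(candidate_list(lib, state, cl), `[[`, character(1),
                 "bbl_index")
  for (drop in names(lib)) {
    sub <- bbl_library(unname(lib[setdiff(names(lib), drop)]))
    reduced <- vapply(candidate_list(sub, state, cl), `[[`, character(1),
                      "bbl_index")
    expect_true(all(reduced %in% full))
  }
})

test_that("empty library yields an empty candidate list", {
  expect_length(candidate_list(bbl_library(list()), leaf_state()), 0L)
})
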