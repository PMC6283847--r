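test_that("minimal glycan strings parse to the right topology", {
  t1 <- parse_glycan("Gal(b1-4)Glc")
  expect_equal(length(t1$residues), 2L)
  root <- glycoplan:::tree_residue(t1, t1$root)
  expect_equal(root$sugar_type, "Glc")
  leaves <- leaf_residues(t1)
  expect_length(leaves, 1L)
  expect_equal(leaves[[1]]$sugar_type, "Gal")
  expect_equal(leaves[[1]]$link, 4L)
  expect_equal(leaves[[1]]$anomeric, "b")

  t2 <- parse_glycan("Glc")
  expect_equal(length(t2$residues), 1L)
  expect_equal(leaf_residues(t2)[[1]]$id, t2$root)
})

test_that("branched strings give ordered children and two leaves", {
  t <- parse_glycan("Man(a1-3)[Man(a1-6)]Gal(b1-4)Glc")
  gal <- Filter(function(r) r$sugar_type == "Gal", t$residues)[[1]]
  kids <- glycoplan:::tree_children(t, gal$id)
  expect_length(kids, 2L)
  links <- vapply(kids, function(k) glycoplan:::tree_residue(t, k)$link,
                  integer(1))
  expect_equal(links, c(3L, 6L))  # deterministic child order
  expect_length(leaf_residues(t), 2L)
})

test_that("malformed input fails with an informative parse error", {
  expect_error(parse_glycan("Gal(b1-4)Qux"), "Qux")
  expect_error(parse_glycan("Gal(b1-4"), "parse error")
  expect_error(parse_glycan("Gal(z1-4)Glc"), "parse error|Gal")
  expect_error(parse_glycan("[Gal(b1-3)]"), "parse error")
  # duplicate attachment position on one parent
  expect_error(parse_glycan("Man(a1-3)[Man(a1-3)]Gal"), "same position")
})

test_that("JSON dialect round-trips and rejects broken structures", {
  t <- parse_glycan("Fuc(a1-2)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc")
  js <- glycan_to_json(t)
  t2 <- glycan_from_json(js)
  expect_equal(serialize_glycan(t2), serialize_glycan(t))
  # duplicate id
  bad <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  bad$residues[[2]]$id <- bad$residues[[1]]$id
  expect_error(glycan_from_json(jsonlite::toJSON(bad, auto_unbox = TRUE,
                                                 null = "null")),
               "duplicate")
  # cycle: root points at a descendant
  bad2 <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  root_pos <- which(vapply(bad2$residues, function(r) is.null(r$pid),
                           logical(1)))
  bad2$residues[[root_pos]]$pid <- bad2$residues[[1]]$id
  bad2$residues[[root_pos]]$link <- 4
  expect_error(glycan_from_json(jsonlite::toJSON(bad2, auto_unbox = TRUE,
                                                 null = "null")),
               "root|cycle")
})

test_that("parse/serialize is the identity on random trees", {
  for (s in 1:12) {
    t <- random_tree(sample(2:8, 1), seed = s)
    t2 <- parse_glycan(serialize_glycan(t))
    expect_equal(serialize_glycan(t2), serialize_glycan(t))
    expect_equal(length(t2$residues), length(t$residues))
  }
})

test_that("major chain is the longest leaf-to-root path with stated tie-breaks", {
  lin <- parse_glycan("Gal(b1-3)Gal(b1-4)Gal(b1-4)Glc")
  expect_length(major_chain(lin), 4L)
  expect_equal(major_chain(lin)[4], lin$root)

  # depth-3 branch beats depth-2 branch
  t <- parse_glycan("Gal(b1-3)Gal(b1-3)[Man(a1-6)]Gal(b1-4)Glc")
  expect_length(major_chain(t), 4L)

  # equal depth: the link-3 branch wins over link-6
  t2 <- parse_glycan("Man(a1-3)[Gal(b1-6)]Glc")
  mc <- major_chain(t2)
  expect_equal(glycoplan:::tree_residue(t2, mc[1])$link, 3L)
})

test_that("major chain length satisfies the recursive property on random trees", {
  for (s in 1:10) {
    t <- random_tree(sample(3:10, 1), seed = 100 + s)
    # brute force: enumerate all leaf-to-root paths
    depth_of <- function(id) {
      d <- 1L
      r <- glycoplan:::tree_residue(t, id)
      while (!is.na(r$pid)) {
        d <- d + 1L
        r <- glycoplan:::tree_residue(t, r$pid)
      }
      d
    }
    leaves <- vapply(leaf_residues(t), `[[`, integer(1), "id")
    expect_equal(length(major_chain(t)), max(vapply(leaves, depth_of,
                                                    integer(1))))
  }
})

test_that("residue validation enforces vocabulary and positions", {
  expect_error(residue(1, "Xyl"), "unknown sugar")
  expect_error(residue(1, "Gal", link = 5L), "2,3,4,6")
  expect_error(residue(1, "Gal", substituents = c("2" = "OMe")),
               "invalid substituent token")
  expect_error(residue(1, "Fuc", substituents = c("6" = "OBn")),
               "position")
  # HexNAc: position 2 takes amine tokens only
  expect_error(residue(1, "GlcNAc", substituents = c("2" = "OBn")),
               "invalid substituent token")
  r <- residue(1, "GlcNAc", substituents = c("2" = "NHTroc"))
  expect_equal(r$sub[["2"]], "NHTroc")
  expect_equal(r$sugar_class, "HexNAc")
})

test_that("every residue is on the major chain or hangs off it", {
  for (s in 1:6) {
    t <- random_tree(sample(4:9, 1), seed = 200 + s)
    mc <- major_chain(t)
    off <- setdiff(as.integer(names(t$residues)), mc)
    for (id in off) {
      # walking up from any off-chain residue must reach the chain
      r <- glycoplan:::tree_residue(t, id)
      while (!is.na(r$pid) && !(r$pid %in% mc)) {
        r <- glycoplan:::tree_residue(t, r$pid)
      }
      expect_false(is.na(r$pid))
    }
  }
})
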