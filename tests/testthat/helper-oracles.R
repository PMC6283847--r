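# Shared fixtures and independent oracles used across the test files.

# --- random structure generators -------------------------------------------

random_tree <- function(n, seed) {
  set.seed(seed)
  types <- c("Gal", "Glc", "Man", "GalNAc", "GlcNAc")
  res <- list(residue(1L, sample(types, 1), anomeric = sample(c("a", "b"), 1)))
  for (i in seq_len(n - 1L) + 1L) {
    repeat {
      pid <- sample(seq_len(i - 1L), 1)
      parent <- res[[pid]]
      taken <- vapply(res, function(r)
        if (!is.na(r$pid) && r$pid == pid) r$link else NA_integer_, integer(1))
      free <- setdiff(o_positions(parent$sugar_type), taken[!is.na(taken)])
      if (length(free)) break
    }
    st <- sample(types, 1)
    res[[i]] <- residue(i, st, pid = pid, anomeric = sample(c("a", "b"), 1),
                        link = if (length(free) == 1L) free else sample(free, 1))
  }
  glycan_tree(res)
}

# A library with plausible candidates: BBLs cut out of the tree with
# randomized protection patterns, plus unrelated distractors.
random_library <- function(tree, n_bbls, seed) {
  set.seed(seed)
  ids <- as.integer(names(tree$residues))
  removables <- c("OLev", "OClAc", "OPMB", "OTBDPS")
  permanents <- c("OBn", "OBz", "OAc")
  bbls <- list()
  for (b in seq_len(n_bbls)) {
    # grow a connected subset from a random residue
    start <- sample(ids, 1)
    S <- start
    while (length(S) < 3L && runif(1) < 0.5) {
      kids <- setdiff(unlist(lapply(S, function(i) tree_kids(tree, i))), S)
      if (!length(kids)) break
      S <- c(S, if (length(kids) == 1L) kids else sample(kids, 1))
    }
    state <- glycoplan:::induced_state(tree, S)
    # half the blocks are tailored exact perfect matches for their cut (so
    # solvable instances occur); the rest carry randomized protections
    tailored <- runif(1) < 0.5
    cl <- oracle_child_links(tree, S)
    res <- lapply(state$residues, function(r) {
      internal <- vapply(glycoplan:::tree_children(state, r$id), function(k)
        glycoplan:::tree_residue(state, k)$link, integer(1))
      for (p in setdiff(o_positions(r$sugar_type), internal)) {
        r$sub[[as.character(p)]] <- if (tailored) {
          if (p %in% cl[[as.character(r$id)]]) "OH" else sample(permanents, 1)
        } else {
          u <- runif(1)
          if (u < 0.4) "OH"
          else if (u < 0.75) sample(permanents, 1)
          else sample(removables, 1)
        }
      }
      if (r$sugar_class == "HexNAc") r$sub[["2"]] <- sample(amine_tokens(), 1)
      if (!tailored && runif(1) < 0.15) {
        r$anomeric <- sample(c("a", "b"), 1)  # may create a mismatch
      }
      r
    })
    root_here <- tree$root %in% S
    rrv <- if (root_here && runif(1) < 0.7) 0
           else round(exp(runif(1, 0, log(72000))), 1)
    bbls[[b]] <- building_block(paste0("B", b), paste0("rand-", b),
                                glycan_tree(unname(res)), rrv = rrv)
  }
  bbl_library(bbls)
}

tree_kids <- function(tree, id) tree$children[[as.character(id)]]

# --- independent partition enumeration (oracle) ----------------------------

# all partitions of the full residue set into connected blocks of size <=
# max_block, via lowest-unassigned-id block growth over the undirected
# adjacency (independent of the planner's root-guided recursion)
oracle_partitions <- function(tree, max_block = 3L) {
  ids <- sort(as.integer(names(tree$residues)))
  adj <- lapply(ids, function(i) {
    r <- glycoplan:::tree_residue(tree, i)
    c(if (!is.na(r$pid)) r$pid, tree_kids(tree, i))
  })
  names(adj) <- as.character(ids)
  out <- list()
  recurse <- function(unassigned, acc) {
    if (!length(unassigned)) {
      out[[length(out) + 1L]] <<- acc
      return()
    }
    seedid <- min(unassigned)
    # connected subsets of `unassigned` containing seedid
    subsets <- list(seedid)
    queue <- list(seedid)
    while (length(queue)) {
      S <- queue[[1]]; queue <- queue[-1]
      if (length(S) < max_block) {
        nb <- setdiff(intersect(unlist(adj[as.character(S)]), unassigned), S)
        for (x in nb) {
          S2 <- sort(c(S, x))
          key <- paste(S2, collapse = ",")
          if (!key %in% vapply(subsets, function(s)
            paste(sort(s), collapse = ","), character(1))) {
            subsets[[length(subsets) + 1L]] <- S2
            queue[[length(queue) + 1L]] <- S2
          }
        }
      }
    }
    for (S in subsets) recurse(setdiff(unassigned, S), c(acc, list(S)))
  }
  recurse(ids, list())
  out
}

# child links of a block within the full tree (attachments below the block)
oracle_child_links <- function(tree, S) {
  cl <- list()
  for (id in S) {
    for (k in tree_kids(tree, id)) {
      if (!(k %in% S)) {
        cl[[as.character(id)]] <- c(cl[[as.character(id)]],
                                    glycoplan:::tree_residue(tree, k)$link)
      }
    }
  }
  cl
}

# brute-force one-pot plan enumeration: every tiling x BBL assignment that
# satisfies perfect matching, strict RRV descent along block edges, global
# distinctness, root block RRV 0, and the step budget
oracle_onepot_signatures <- function(tree, library, max_bbls = 4L) {
  sigs <- character(0)
  for (part in oracle_partitions(tree)) {
    if (length(part) > max_bbls) next
    block_of <- integer(0)
    for (i in seq_along(part)) block_of[as.character(part[[i]])] <- i
    choices <- lapply(part, function(S) {
      state <- glycoplan:::induced_state(tree, S)
      cl <- oracle_child_links(tree, S)
      hits <- list()
      for (bb in library) {
        if (glycoplan:::n_residues(bb$tree) != length(S)) next
        m <- match_state(bb, state, cl)
        if (!is.null(m) && m$kind == "perfect") {
          hits[[length(hits) + 1L]] <- list(idx = bb$index, rrv = bb$rrv)
        }
      }
      hits
    })
    if (any(!vapply(choices, length, integer(1)))) next
    parent_block <- vapply(seq_along(part), function(i) {
      root_res <- part[[i]][vapply(part[[i]], function(id) {
        p <- glycoplan:::tree_residue(tree, id)$pid
        is.na(p) || !(p %in% part[[i]])
      }, logical(1))]
      p <- glycoplan:::tree_residue(tree, root_res)$pid
      if (is.na(p)) NA_integer_ else block_of[[as.character(p)]]
    }, integer(1))
    grid <- expand.grid(lapply(choices, seq_along))
    for (g in seq_len(nrow(grid))) {
      pick <- lapply(seq_along(part), function(i)
        choices[[i]][[grid[g, i]]])
      rrvs <- vapply(pick, `[[`, numeric(1), "rrv")
      root_block <- which(is.na(parent_block))
      if (rrvs[root_block] != 0) next
      if (anyDuplicated(rrvs)) next
      ok <- all(vapply(seq_along(part), function(i) {
        p <- parent_block[i]
        is.na(p) || rrvs[i] > rrvs[p]
      }, logical(1)))
      if (!ok) next
      sigs <- c(sigs, paste(sort(vapply(seq_along(part), function(i)
        paste0(pick[[i]]$idx, ":", paste(sort(part[[i]]), collapse = ",")),
        character(1))), collapse = "|"))
    }
  }
  sort(unique(sigs))
}

plan_signatures <- function(plans) {
  sort(unique(vapply(plans, function(p)
    paste(sort(vapply(p$steps, function(st)
      paste0(st$match$bbl_index, ":", paste(sort(st$ids), collapse = ",")),
      character(1))), collapse = "|"), character(1))))
}

# numeric ODE oracle for the kinetic coupling yield (competing activation)
ode_yield <- function(r) {
  f <- function(t, y, parms) {
    denom <- parms$r * y[1] + y[2]
    list(c(-parms$r * y[1] / denom, -y[2] / denom))
  }
  out <- deSolve::ode(y = c(1, 1), times = seq(0, 1, length.out = 201),
                      func = f, parms = list(r = r))
  unname(1 - out[nrow(out), 2])
}
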