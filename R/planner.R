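#' One-pot synthesis search (no fragmentation)
#'
#' Depth-first, in-order search of the query tree against the building
#' block library. Each returned plan tiles the query residues with
#' disjoint connected states, every state perfectly matched by a library
#' BBL (masked hydroxyls are never deprotected in this mode, so precursor
#' matches are excluded), the reducing-end state matched by an RRV-0
#' acceptor, and the step RRVs strictly descending from the non-reducing
#' end so the one-pot addition order is chemoselective. Plans are ranked
#' by computed overall yield (descending), with deterministic tie-breaks.
#'
#' @param tree Query [glycan_tree()].
#' @param library A [bbl_library()].
#' @param max_bbls Maximum number of BBLs in a plan (default 4; more
#'   steps invite promoter side reactions).
#' @param yield_model A `yield_model` for ranking.
#' @param removable Selectively-deprotectable tokens (used only in
#'   fragment mode; kept for a uniform signature).
#' @return List of `synthesis_plan` objects; empty when no route exists.
#'   Each plan has `steps` (list of `(ids, match, rrv, n_residues)` from
#'   non-reducing end to reducing end), `rrvs`, `sizes` (residues per
#'   step), `overall_yield` and `n_bbls`.
#' @export
search_no_fragments <- function(tree, library, max_bbls = 4L,
                                yield_model = yield_model_kinetic(),
                                removable = removable_pgs()) {
  if (max_bbls < 1L) stop("max_bbls must be >= 1")
  if (max_bbls > 4L) {
    warning("more than 4 one-pot steps risks promoter side reactions")
  }
  sols <- .solve_subtree(tree, tree$root, library, max_bbls,
                         allow_precursor = FALSE, masked_links = list(),
                         removable = removable)
  plans <- list()
  for (s in sols) {
    root_state <- s$steps[[length(s$steps)]]
    if (root_state$rrv != 0) next
    rrvs <- vapply(s$steps, `[[`, numeric(1), "rrv")
    if (anyDuplicated(rrvs)) next  # one-pot needs a strict global order
    ord <- order(-rrvs)
    plans[[length(plans) + 1L]] <- .make_plan(s$steps[ord], yield_model)
  }
  .rank_plans(plans)
}

.make_plan <- function(steps, yield_model) {
  rrvs <- vapply(steps, `[[`, numeric(1), "rrv")
  sizes <- vapply(steps, function(st) length(st$ids), integer(1))
  structure(list(steps = steps, rrvs = rrvs, sizes = sizes,
                 n_bbls = length(steps),
                 overall_yield = compute_overall_yield(rrvs, yield_model)),
            class = "synthesis_plan")
}

.plan_signature <- function(p) {
  paste(vapply(p$steps, function(st)
    paste0(st$match$bbl_index, ":", paste(sort(st$ids), collapse = ",")),
    character(1)), collapse = "|")
}

.rank_plans <- function(plans) {
  if (!length(plans)) return(plans)
  sig <- vapply(plans, .plan_signature, character(1))
  plans <- plans[!duplicated(sig)]
  y <- vapply(plans, `[[`, numeric(1), "overall_yield")
  nb <- vapply(plans, `[[`, integer(1), "n_bbls")
  sig <- vapply(plans, .plan_signature, character(1))
  plans[order(-y, nb, sig)]
}

#' @export
print.synthesis_plan <- function(x, ...) {
  cat("<synthesis_plan> ", x$n_bbls, " BBL(s), overall yield ",
      sprintf("%.1f%%", 100 * x$overall_yield), "\n", sep = "")
  for (st in x$steps) {
    cat(sprintf("  RRV %10.4g  BBL %-6s (%d residue%s%s)\n", st$rrv,
                st$match$bbl_index, length(st$ids),
                if (length(st$ids) > 1) "s" else "",
                if (st$match$kind == "precursor") ", precursor" else ""))
  }
  invisible(x)
}

# Core recursive search. Returns a list of partial solutions for the
# subtree rooted at `root_id`; each solution is list(steps = list of
# list(ids, match, rrv), root_rrv). Child-subtree solutions combine with
# the state containing `root_id` by cartesian product, pruned by the
# strict RRV descent along state edges and by the step budget.
# `masked_links` marks positions (per residue id) where an out-of-scope
# attachment must be masked by a unique removable group (fragment mode).
.solve_subtree <- function(tree, root_id, library, max_bbls,
                           allow_precursor, masked_links, removable) {
  sols <- list()
  for (S in .connected_sets(tree, root_id, 3L)) {
    # hanging subtrees below the state
    hang <- list()  # root ids of subtrees hanging below the state
    cl <- list()
    for (id in S) {
      for (k in tree_children(tree, id)) {
        if (!(k %in% S)) {
          hang[[length(hang) + 1L]] <- k
          cl[[as.character(id)]] <- c(cl[[as.character(id)]],
                                      tree_residue(tree, k)$link)
        }
      }
      m <- masked_links[[as.character(id)]]
      if (length(m)) cl[[as.character(id)]] <- c(cl[[as.character(id)]], m)
    }
    state <- induced_state(tree, S)
    cands <- candidate_list(library, state, cl, removable)
    if (!allow_precursor) {
      cands <- Filter(function(m) m$kind == "perfect", cands)
    } else {
      # masked positions must actually be masked, not free: matches that
      # leave a masked position as OH are rejected
      need <- unlist(lapply(S, function(id) masked_links[[as.character(id)]]))
      if (length(need)) {
        cands <- Filter(function(m) {
          # every masked-link position must appear among the deprotections
          # of the residue that owns it (i.e. be masked, not free)
          all(vapply(S, function(id) {
            ml <- masked_links[[as.character(id)]]
            if (!length(ml)) return(TRUE)
            all(ml %in% .masked_positions_of(m, id))
          }, logical(1)))
        }, cands)
      }
    }
    if (!length(cands)) next
    # solve each hanging subtree independently
    kid_sols <- lapply(hang, function(k)
      .solve_subtree(tree, k, library, max_bbls, allow_precursor,
                     masked_links, removable))
    if (length(kid_sols) && any(!vapply(kid_sols, length, integer(1)))) next
    for (m in cands) {
      v <- m$rrv
      combos <- list(list(steps = list(), n = 0L))
      for (ks in kid_sols) {
        new_combos <- list()
        for (co in combos) {
          for (s in ks) {
            if (s$root_rrv <= v) next  # child state must outrank its parent
            n <- co$n + length(s$steps)
            if (n > max_bbls - 1L) next
            new_combos[[length(new_combos) + 1L]] <-
              list(steps = c(co$steps, s$steps), n = n)
          }
        }
        combos <- new_combos
        if (!length(combos)) break
      }
      for (co in combos) {
        steps <- c(co$steps,
                   list(list(ids = S, match = m, rrv = v)))
        sols[[length(sols) + 1L]] <- list(steps = steps, root_rrv = v)
      }
    }
  }
  sols
}

# positions of query residue `qid` masked (deprotected later) under match m
.masked_positions_of <- function(m, qid) {
  if (!length(m$deprotections)) return(integer(0))
  owner <- vapply(m$deprotections, `[[`, integer(1), "residue")
  pos <- vapply(m$deprotections, `[[`, numeric(1), "position")
  pos[owner == as.integer(qid)]
}

# all connected subsets of the subtree rooted at `root_id` that contain
# root_id, with size <= max_size; each returned as an integer id vector
.connected_sets <- function(tree, root_id, max_size) {
  out <- list()
  grow <- function(set, frontier) {
    out[[length(out) + 1L]] <<- set
    if (length(set) >= max_size) return()
    for (i in seq_along(frontier)) {
      f <- frontier[i]
      # extend with f; to avoid duplicates only frontier nodes at index >= i
      # stay available together with f's children
      grow(c(set, f),
           c(frontier[seq_along(frontier) > i], tree_children(tree, f)))
    }
  }
  grow(root_id, tree_children(tree, root_id))
  out
}
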