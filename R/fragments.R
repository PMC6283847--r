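#' Hierarchical one-pot search with fragment decomposition
#'
#' Splits the query glycan into connected fragments of 1-3 building
#' blocks, plans each fragment as its own one-pot sequence (precursor
#' matches allowed: a masked hydroxyl may be deprotected between steps),
#' and schedules fragment assembly. A position where a *child fragment*
#' attaches must survive the fragment's own synthesis: on a multi-BBL
#' fragment it must be masked by a unique selectively-removable group and
#' is deprotected after the fragment is made; on a single-BBL fragment it
#' may simply be a free hydroxyl. The deprotected fragment is reused as a
#' building block whose effective RRV defaults to that of its
#' reducing-end BBL.
#'
#' @param tree Query [glycan_tree()].
#' @param library A [bbl_library()].
#' @param max_bbls_per_fragment Maximum BBLs per fragment (default 3).
#' @param max_path_fragments Cap on the number of fragments along any
#'   root-to-leaf path, to bound the combinatorics (default 3).
#' @param yield_model A `yield_model`.
#' @param removable Selectively-deprotectable tokens.
#' @return List of `fragment_plan` objects ranked by overall yield. Each
#'   has `fragments` (post-order assembly schedule), `sizes` (residues per
#'   top-level addition), `strategy`, `role_classes`, `overall_yield`.
#' @export
fragment_search <- function(tree, library, max_bbls_per_fragment = 3L,
                            max_path_fragments = 3L,
                            yield_model = yield_model_kinetic(),
                            removable = removable_pgs()) {
  partitions <- .enumerate_partitions(tree, tree$root, max_path_fragments,
                                      max_block = 3L * max_bbls_per_fragment)
  plans <- list()
  for (part in partitions) {
    frag_opts <- lapply(part, function(blk)
      .plan_fragment(tree, blk, library, max_bbls_per_fragment, yield_model,
                     removable,
                     is_root_fragment = tree$root %in% blk))
    if (any(!vapply(frag_opts, length, integer(1)))) next
    # cartesian product over per-fragment plan choices
    combos <- list(list())
    for (fo in frag_opts) {
      combos <- unlist(lapply(combos, function(co)
        lapply(fo, function(f) c(co, list(f)))), recursive = FALSE)
      if (length(combos) > 5000L) combos <- combos[seq_len(5000L)]
    }
    for (fr in combos) {
      fp <- .assemble_fragment_plan(fr, tree, yield_model)
      if (!is.null(fp)) plans[[length(plans) + 1L]] <- fp
    }
  }
  .rank_fragment_plans(plans)
}

# all partitions of the subtree below root_id into connected blocks,
# given a budget of blocks remaining along the current path
.enumerate_partitions <- function(tree, root_id, path_budget, max_block) {
  if (path_budget < 1L) return(list())
  out <- list()
  for (S in .connected_sets(tree, root_id, max_block)) {
    hang <- integer(0)
    for (id in S) {
      hang <- c(hang, setdiff(tree_children(tree, id), S))
    }
    if (!length(hang)) {
      out[[length(out) + 1L]] <- list(S)
      next
    }
    kid_parts <- lapply(hang, function(k)
      .enumerate_partitions(tree, k, path_budget - 1L, max_block))
    if (any(!vapply(kid_parts, length, integer(1)))) next
    combos <- list(list(S))
    for (kp in kid_parts) {
      combos <- unlist(lapply(combos, function(co)
        lapply(kp, function(p) c(co, p))), recursive = FALSE)
    }
    out <- c(out, combos)
  }
  out
}

# induced standalone tree for a block (out-of-block parent cut)
.block_tree <- function(tree, ids) induced_state(tree, ids)

# per-block external child links: block residue id -> positions where
# other blocks attach below this block
.external_links <- function(tree, ids) {
  cl <- list()
  for (id in ids) {
    for (k in tree_children(tree, id)) {
      if (!(k %in% ids)) {
        cl[[as.character(id)]] <- c(cl[[as.character(id)]],
                                    tree_residue(tree, k)$link)
      }
    }
  }
  cl
}

# all internal plans for one fragment block; returns list of fragment
# objects (class "synthesis_fragment")
.plan_fragment <- function(tree, ids, library, max_bbls, yield_model,
                           removable, is_root_fragment = FALSE) {
  btree <- .block_tree(tree, ids)
  ext <- .external_links(tree, ids)
  frags <- list()
  add <- function(steps) {
    rrvs <- vapply(steps, `[[`, numeric(1), "rrv")
    if (anyDuplicated(rrvs)) return()
    # an RRV-0 block is a reducing-end acceptor with no leaving group: it
    # can only terminate the fragment that holds the glycan root
    root_rrv <- rrvs[vapply(steps, function(st) btree$root %in% st$ids,
                            logical(1))]
    if (is_root_fragment && root_rrv != 0) return()
    if (!is_root_fragment && any(rrvs == 0)) return()
    ord <- order(-rrvs)
    steps <- steps[ord]; rrvs <- rrvs[ord]
    post <- list(); mid <- list()
    for (st in steps) {
      for (d in st$match$deprotections) {
        ep <- ext[[as.character(d$residue)]]
        if (length(ep) && d$position %in% ep) {
          post[[length(post) + 1L]] <- d
        } else {
          mid[[length(mid) + 1L]] <- d
        }
      }
    }
    root_step <- steps[[which(vapply(steps, function(st)
      btree$root %in% st$ids, logical(1)))]]
    frags[[length(frags) + 1L]] <<- structure(
      list(ids = sort(as.integer(ids)), root_id = btree$root, steps = steps,
           rrvs = rrvs,
           bbl_sizes = vapply(steps, function(st) length(st$ids), integer(1)),
           n_bbls = length(steps),
           fragment_yield = compute_overall_yield(rrvs, yield_model),
           post_synthesis_deprotections = post,
           midpot_deprotections = mid,
           effective_rrv = root_step$rrv,
           effective_rrv_source = "reducing-end BBL"),
      class = "synthesis_fragment")
  }
  # multi-step (or single) plans with external positions masked
  for (s in .solve_subtree(btree, btree$root, library, max_bbls,
                           allow_precursor = TRUE, masked_links = ext,
                           removable = removable)) {
    add(s$steps)
  }
  # single-BBL fragment used directly: external positions may be free
  if (length(ids) <= 3L) {
    for (m in candidate_list(library, btree, ext, removable)) {
      add(list(list(ids = as.integer(ids), match = m, rrv = m$rrv)))
    }
  }
  sig <- vapply(frags, function(f)
    paste(vapply(f$steps, function(st) paste0(st$match$bbl_index, ":",
      paste(sort(st$ids), collapse = ","), ":",
      paste(vapply(st$match$deprotections, function(d)
        paste0(d$residue, ".", d$position), character(1)), collapse = "+")),
      character(1)), collapse = "|"), character(1))
  frags[!duplicated(sig)]
}

# turn a set of planned fragments covering the tree into a fragment_plan,
# or NULL when the assembly ordering is impossible
.assemble_fragment_plan <- function(fragments, tree, yield_model) {
  sched <- tryCatch(
    schedule_connection(fragments, tree, yield_model = yield_model),
    error = function(e) NULL)
  sched
}

#' Schedule the connection of planned fragments
#'
#' Builds the fragment tree, finds the major chain (longest leaf-to-root
#' path) of the target, and chooses a connection strategy:
#' `onepot_fragments` when at most 4 fragments lie on the major chain and
#' their effective RRVs admit a strictly descending one-pot order (role
#' classes large / medium / small / zero assigned along the chain);
#' `hybrid` when more than 4 fragments lie on the major chain (one-pot and
#' distinct-leaving-group steps combined); otherwise
#' `distinct_leaving_groups`, a stepwise post-order schedule in which each
#' connection activates one fragment selectively via its leaving group.
#'
#' @param fragments List of `synthesis_fragment` objects partitioning the
#'   tree (as produced inside [fragment_search()]).
#' @param tree The query [glycan_tree()].
#' @param strategy `"auto"` or one of the three strategies; requesting
#'   `onepot_fragments` when the effective RRVs cannot be ordered raises a
#'   strategy-infeasible error.
#' @param yield_model A `yield_model` used for connection couplings; a
#'   coupling driven by a distinct leaving group (stepwise/hybrid) is
#'   taken as selective, yield 1.
#' @return A `fragment_plan` object.
#' @export
schedule_connection <- function(fragments, tree,
                                strategy = c("auto", "onepot_fragments",
                                             "distinct_leaving_groups",
                                             "hybrid"),
                                yield_model = yield_model_kinetic()) {
  strategy <- match.arg(strategy)
  ids_all <- sort(unlist(lapply(fragments, `[[`, "ids")))
  if (!identical(ids_all, sort(as.integer(names(tree$residues))))) {
    stop("fragments must partition the residues of the tree")
  }
  owner <- integer(0)
  for (i in seq_along(fragments)) owner[as.character(fragments[[i]]$ids)] <- i
  parent_frag <- vapply(fragments, function(f) {
    p <- tree_residue(tree, f$root_id)$pid
    if (is.na(p)) NA_integer_ else owner[[as.character(p)]]
  }, integer(1))
  root_frag <- which(is.na(parent_frag))
  # post-order assembly schedule over the fragment tree
  kids <- lapply(seq_along(fragments), function(i) {
    k <- which(parent_frag == i)
    k[order(vapply(k, function(j)
      tree_residue(tree, fragments[[j]]$root_id)$link, integer(1)),
      vapply(k, function(j) fragments[[j]]$root_id, integer(1)))]
  })
  post <- integer(0)
  visit <- function(i) {
    for (k in kids[[i]]) visit(k)
    post <<- c(post, i)
  }
  visit(root_frag)

  chain <- major_chain(tree)
  on_chain <- which(vapply(fragments, function(f)
    any(f$ids %in% chain), logical(1)))
  # order chain fragments from the non-reducing end of the chain inward
  chain_order <- on_chain[order(vapply(fragments[on_chain], function(f)
    min(match(f$ids, chain), na.rm = TRUE), integer(1)))]
  effs <- vapply(fragments, function(f)
    if (is.null(f$effective_rrv)) NA_real_ else f$effective_rrv, numeric(1))

  # one-pot feasibility: effective RRVs strictly descending along every
  # fragment-tree edge, all distinct, final acceptor 0
  known <- !anyNA(effs)
  onepot_ok <- known && !anyDuplicated(effs) &&
    effs[root_frag] == 0 &&
    all(vapply(seq_along(fragments), function(i) {
      p <- parent_frag[i]
      is.na(p) || effs[i] > effs[p]
    }, logical(1)))

  chosen <- strategy
  if (strategy == "auto") {
    chosen <- if (length(on_chain) > 4L) "hybrid"
              else if (onepot_ok) "onepot_fragments"
              else "distinct_leaving_groups"
  } else if (strategy == "onepot_fragments" && !onepot_ok) {
    stop("strategy infeasible: fragment effective RRVs cannot be ordered ",
         "strictly descending to a reducing-end 0")
  } else if (strategy == "hybrid" && length(on_chain) <= 4L &&
             strategy != "auto") {
    # allowed, but normally chosen only when the chain holds > 4 fragments
  }

  classes <- rep(NA_character_, length(fragments))
  classes[chain_order] <- .role_classes(length(chain_order))
  rrv_cat <- ifelse(is.na(effs), NA_character_,
                    ifelse(effs == 0, "zero",
                           as.character(classify_rrv_category(pmax(effs, 1e-9)))))
  rrv_cat[!is.na(effs) & effs == 0] <- "zero"

  # connection couplings: consecutive additions in descending effective-RRV
  # order for the one-pot strategy; selective (yield 1) otherwise
  conn_yield <- 1
  if (chosen == "onepot_fragments" && onepot_ok && length(fragments) > 1L) {
    seq_rrv <- sort(effs, decreasing = TRUE)
    conn_yield <- compute_overall_yield(seq_rrv, yield_model)
  }
  fy <- vapply(fragments, `[[`, numeric(1), "fragment_yield")
  assembly <- if (onepot_ok) order(-effs) else post
  structure(list(
    fragments = fragments[assembly],
    assembly_order = assembly,
    post_order = post,
    strategy = chosen,
    role_classes = classes[assembly],
    rrv_categories = rrv_cat[assembly],
    effective_rrvs = effs[assembly],
    sizes = vapply(fragments[assembly], function(f)
      length(f$ids), integer(1)),
    n_fragments = length(fragments),
    n_bbls = sum(vapply(fragments, `[[`, integer(1), "n_bbls")),
    overall_yield = prod(fy) * conn_yield),
    class = "fragment_plan")
}

# ordinal role classes for k fragments on the major chain
.role_classes <- function(k) {
  if (k == 0L) return(character(0))
  if (k == 1L) return("zero")
  full <- c("large", "medium", "small")
  c(full[seq_len(min(k - 1L, 3L))], rep("small", max(0L, k - 4L)), "zero")
}

#' @export
print.fragment_plan <- function(x, ...) {
  cat("<fragment_plan> ", x$n_fragments, " fragment(s), strategy ",
      x$strategy, ", overall yield ",
      sprintf("%.1f%%", 100 * x$overall_yield), "\n", sep = "")
  for (i in seq_along(x$fragments)) {
    f <- x$fragments[[i]]
    cat(sprintf("  fragment %d [%d residue(s), %d BBL(s)] eff RRV %.4g%s\n",
                i, length(f$ids), f$n_bbls, f$effective_rrv,
                if (!is.na(x$role_classes[i]))
                  paste0("  class ", x$role_classes[i]) else ""))
    for (st in f$steps) {
      cat(sprintf("    RRV %10.4g  BBL %s\n", st$rrv, st$match$bbl_index))
    }
    if (length(f$post_synthesis_deprotections)) {
      dp <- vapply(f$post_synthesis_deprotections, function(d)
        paste0(d$token, "@", d$position), character(1))
      cat("    deprotect after synthesis: ", paste(dp, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

.fragment_plan_signature <- function(p) {
  paste(vapply(p$fragments, function(f)
    paste0(paste(f$ids, collapse = ","), "=",
           paste(vapply(f$steps, function(st) st$match$bbl_index,
                        character(1)), collapse = "+")),
    character(1)), collapse = "|")
}

.rank_fragment_plans <- function(plans) {
  if (!length(plans)) return(plans)
  sig <- vapply(plans, .fragment_plan_signature, character(1))
  plans <- plans[!duplicated(sig)]
  y <- vapply(plans, `[[`, numeric(1), "overall_yield")
  nf <- vapply(plans, `[[`, integer(1), "n_fragments")
  sig <- vapply(plans, .fragment_plan_signature, character(1))
  plans[order(-y, nf, sig)]
}

#' Residues added per top-level step of a plan
#'
#' For a one-pot plan, the residue count of each BBL in addition order;
#' for a multi-fragment plan, the residue count of each fragment in
#' assembly order; for a plan that collapsed to a single fragment, the
#' residue counts of that fragment's BBLs (the final pot *is* the
#' fragment's one-pot). This is the "[1 + 3 + 2]"-style strategy notation.
#'
#' @param plan A `synthesis_plan` or `fragment_plan`.
#' @return Integer vector.
#' @export
plan_sizes <- function(plan) {
  if (inherits(plan, "synthesis_plan")) return(plan$sizes)
  if (inherits(plan, "fragment_plan")) {
    if (plan$n_fragments == 1L) return(plan$fragments[[1]]$bbl_sizes)
    return(plan$sizes)
  }
  stop("plan must be a synthesis_plan or fragment_plan")
}

#' Effective RRV of a planned fragment
#'
#' After a fragment is synthesized and its masked attachment position
#' deprotected, it is reused as a building block. Its effective RRV
#' defaults to the RRV of its reducing-end BBL (flagged as such in the
#' fragment record); a measured value or a model prediction can override
#' the default.
#'
#' @param fragment A `synthesis_fragment`.
#' @param override Optional numeric measured/known value.
#' @param model Optional function `fragment -> rrv` (e.g. wrapping an
#'   [rrv_fit()] prediction on the deprotected structure's features).
#' @return A single non-negative number.
#' @export
effective_rrv_of_fragment <- function(fragment, override = NULL, model = NULL) {
  if (!is.null(override)) return(as.numeric(override))
  if (!is.null(model)) return(as.numeric(model(fragment)))
  fragment$effective_rrv
}
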