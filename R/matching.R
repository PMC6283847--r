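#' Match a building block against the current search state
#'
#' Decides whether a building block (BBL) perfectly or precursor-matches a
#' connected group of query residues (the *current state*). Sugar types,
#' anomeric forms and internal linkages must agree exactly. At every state
#' position where the query attaches a sub-structure below the state (a
#' *child link*), the BBL must expose a free hydroxyl (perfect) or mask the
#' position with a protecting group that can be removed selectively and is
#' unique among the BBL's child-link positions (precursor). Every other
#' substituent position must be protected (non-OH): a BBL matching a leaf
#' state must be fully protected.
#'
#' @param bbl A [building_block()].
#' @param state A [glycan_tree()] of the state residues (use
#'   [induced_state()] to cut one out of a query); residue count must equal
#'   the BBL's residue count.
#' @param child_links Named list: state residue id -> integer vector of
#'   positions where the query attaches children below the state. Residues
#'   with no such children may be omitted.
#' @param removable Tokens considered selectively deprotectable
#'   (default [removable_pgs()]).
#' @return A `match_result` (list with `kind` = `"perfect"`/`"precursor"`,
#'   `bbl_index`, `residue_mapping` named int vector query id -> BBL id,
#'   and `deprotections`, a list of `(position, token)` pairs), or `NULL`
#'   when the BBL does not match.
#' @export
match_state <- function(bbl, state, child_links = list(),
                        removable = removable_pgs()) {
  if (!inherits(bbl, "building_block")) stop("bbl must be a building_block")
  if (!inherits(state, "glycan_tree")) stop("state must be a glycan_tree")
  if (n_residues(bbl$tree) != n_residues(state)) {
    stop("state size (", n_residues(state), ") must equal BBL residue count (",
         n_residues(bbl$tree), ")")
  }
  mapping <- .map_trees(state, bbl$tree, state$root, bbl$tree$root)
  if (is.null(mapping)) return(NULL)

  deprot <- list()
  # positions, across the whole BBL, where the query attaches sub-structures:
  # tokens there must be unique for selective deprotection to be unambiguous
  cl_tokens <- character(0)
  for (qid in names(mapping)) {
    bres <- tree_residue(bbl$tree, mapping[[qid]])
    cl <- child_links[[qid]]
    if (is.null(cl)) cl <- integer(0)
    internal <- vapply(tree_children(bbl$tree, bres$id),
                       function(k) tree_residue(bbl$tree, k)$link, integer(1))
    if (length(intersect(cl, internal))) {
      stop("child link position ", intersect(cl, internal)[1],
           " of state residue ", qid, " collides with an internal bond")
    }
    pos_all <- o_positions(bres$sugar_type)
    if (length(setdiff(cl, pos_all))) return(NULL)  # position absent on this sugar
    for (p in setdiff(pos_all, internal)) {
      tok <- bres$sub[[as.character(p)]]
      if (p %in% cl) {
        cl_tokens <- c(cl_tokens, tok)
        if (tok != "OH") {
          if (!tok %in% removable) return(NULL)
          deprot[[length(deprot) + 1L]] <- list(residue = as.integer(qid),
                                                position = p, token = tok)
        }
      } else {
        if (tok == "OH") return(NULL)  # stray free hydroxyl
      }
    }
    # sialic acid units never accept sub-structures in this model
    if (bres$sugar_class == "SA" && length(cl)) return(NULL)
  }
  masked <- cl_tokens[cl_tokens != "OH"]
  if (anyDuplicated(masked)) return(NULL)  # deprotection would be ambiguous
  structure(list(kind = if (length(deprot)) "precursor" else "perfect",
                 bbl_index = bbl$index,
                 residue_mapping = vapply(mapping, identity, integer(1)),
                 deprotections = deprot),
            class = "match_result")
}

# recursive isomorphism from query-state subtree to BBL subtree; children are
# paired by parent link position (unique among siblings). Returns named
# integer mapping (query id -> bbl id) or NULL.
.map_trees <- function(qt, bt, qid, bid) {
  q <- tree_residue(qt, qid); b <- tree_residue(bt, bid)
  if (q$sugar_type != b$sugar_type) return(NULL)
  # anomeric configuration of the outgoing bond (or reducing end): compare
  # when the query specifies it
  if (!is.na(q$anomeric) && !is.na(b$anomeric) && q$anomeric != b$anomeric) {
    return(NULL)
  }
  qk <- tree_children(qt, qid); bk <- tree_children(bt, bid)
  if (length(qk) != length(bk)) return(NULL)
  mapping <- stats::setNames(list(b$id), as.character(q$id))
  if (length(qk)) {
    qlinks <- vapply(qk, function(k) tree_residue(qt, k)$link, integer(1))
    blinks <- vapply(bk, function(k) tree_residue(bt, k)$link, integer(1))
    if (!setequal(qlinks, blinks)) return(NULL)
    for (i in seq_along(qk)) {
      j <- which(blinks == qlinks[i])
      sub <- .map_trees(qt, bt, qk[i], bk[j])
      if (is.null(sub)) return(NULL)
      mapping <- c(mapping, sub)
    }
  }
  mapping
}

#' All library matches for a state
#'
#' Applies [match_state()] to every building block of the library and
#' returns the matches in deterministic order: perfect matches first, then
#' by descending RRV, then by index.
#'
#' @param library A [bbl_library()].
#' @inheritParams match_state
#' @return List of `match_result` objects (possibly empty). Each carries
#'   an `rrv` field copied from its building block.
#' @export
candidate_list <- function(library, state, child_links = list(),
                           removable = removable_pgs()) {
  out <- list()
  for (b in library) {
    if (n_residues(b$tree) != n_residues(state)) next
    m <- match_state(b, state, child_links, removable)
    if (!is.null(m)) {
      m$rrv <- b$rrv
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out)) return(out)
  kind <- vapply(out, `[[`, character(1), "kind")
  rrv <- vapply(out, `[[`, numeric(1), "rrv")
  idx <- vapply(out, `[[`, character(1), "bbl_index")
  out[order(kind != "perfect", -rrv, idx)]
}
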