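#' Create a glycan residue
#'
#' A residue is one monosaccharide unit of a glycan tree or building block.
#' Positions are 1-based ring positions; the anomeric carbon (1, or 2 for
#' sialic acid) carries the leaving group on a donor or the aglycon on the
#' reducing end and is never a substituent slot. Position 2 of a HexNAc
#' holds its amine substituent (NHAc on targets; NHTroc/NPhth/N3 on
#' protected building blocks) and is never a glycosylation site.
#'
#' @param id Integer identifier, unique within a tree.
#' @param sugar_type One of [sugar_types()].
#' @param pid Integer id of the parent residue (the acceptor side, toward the
#'   reducing end), or `NA` for the root.
#' @param anomeric `"a"` or `"b"`: anomeric configuration of the bond to the
#'   parent (or of the reducing end); may be `NA` for an unspecified root.
#' @param link Integer position on the parent to which this residue is
#'   attached (e.g. 4 in `b1-4`); `NA` for the root.
#' @param substituents Named character vector, names = ring positions,
#'   values = substituent tokens (see [pg_vocab()]). Missing positions
#'   default to `"OH"` (and `"NHAc"` at position 2 of a HexNAc).
#' @return A list of class `glycan_residue`.
#' @export
#' @examples
#' residue(1, "Gal", pid = 2, anomeric = "b", link = 4)
residue <- function(id, sugar_type, pid = NA_integer_, anomeric = NA_character_,
                    link = NA_integer_, substituents = character(0)) {
  cls <- sugar_class(sugar_type)
  if (!is.na(anomeric) && !anomeric %in% c("a", "b")) {
    stop("anomeric form must be 'a' or 'b', got: ", anomeric)
  }
  if (!is.na(link) && !link %in% c(2L, 3L, 4L, 6L)) {
    stop("parent link position must be one of 2,3,4,6, got: ", link)
  }
  pos <- o_positions(sugar_type)
  sub <- stats::setNames(rep("OH", length(pos)), as.character(pos))
  if (cls == "HexNAc") sub <- c(sub, "2" = "NHAc")
  if (length(substituents)) {
    if (is.null(names(substituents))) stop("substituents must be named by position")
    extra <- setdiff(names(substituents), names(sub))
    if (length(extra) && cls != "SA") {
      stop("invalid substituent position(s) for ", sugar_type, ": ",
           paste(extra, collapse = ", "))
    }
    sub[names(substituents)] <- substituents
  }
  vocab <- pg_vocab()$hex
  for (p in names(sub)) {
    tok <- sub[[p]]
    ok <- if (cls == "HexNAc" && p == "2") tok %in% amine_tokens()
          else tok %in% c(vocab, removable_pgs())
    if (!ok && cls != "SA") {
      stop("invalid substituent token '", tok, "' at position ", p,
           " of ", sugar_type)
    }
  }
  structure(
    list(id = as.integer(id), pid = as.integer(pid), sugar_type = sugar_type,
         sugar_class = cls, anomeric = anomeric,
         apos = if (cls == "SA") 2L else 1L,
         link = as.integer(link), sub = sub),
    class = "glycan_residue"
  )
}

#' Assemble residues into a glycan tree
#'
#' The tree is rooted at the reducing end. Exactly one residue must have
#' `pid = NA`; every other `pid` must name an existing residue; the graph
#' must be acyclic and connected. Children of a residue are ordered by
#' parent link position, then id, so traversal is deterministic.
#'
#' @param residues List of [residue()] objects.
#' @return An object of class `glycan_tree` with elements `residues`
#'   (named by id), `root` (root id) and `children` (adjacency list of
#'   child ids, named by id).
#' @export
glycan_tree <- function(residues) {
  ids <- vapply(residues, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("duplicate residue id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(residues) <- as.character(ids)
  pids <- vapply(residues, `[[`, integer(1), "pid")
  root <- ids[is.na(pids)]
  if (length(root) != 1L) stop("glycan tree must have exactly one root, found ",
                               length(root))
  orphan <- setdiff(pids[!is.na(pids)], ids)
  if (length(orphan)) stop("pid refers to missing residue(s): ",
                           paste(orphan, collapse = ", "))
  children <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (r in residues) {
    if (!is.na(r$pid)) {
      children[[as.character(r$pid)]] <- c(children[[as.character(r$pid)]], r$id)
    }
  }
  # deterministic child order: by link position, then id
  for (k in names(children)) {
    kids <- children[[k]]
    if (length(kids) > 1L) {
      links <- vapply(kids, function(i) residues[[as.character(i)]]$link, integer(1))
      if (anyDuplicated(links)) {
        stop("residue ", k, " has two children at the same position ",
             links[duplicated(links)][1])
      }
      children[[k]] <- kids[order(links, kids)]
    }
  }
  # cycle / connectivity check by walking down from the root
  seen <- character(0)
  stack <- as.character(root)
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur %in% seen) stop("cycle detected at residue ", cur)
    seen <- c(seen, cur)
    stack <- c(stack, as.character(children[[cur]]))
  }
  if (length(seen) != length(ids)) {
    stop("glycan tree is not connected; unreachable residue(s): ",
         paste(setdiff(as.character(ids), seen), collapse = ", "))
  }
  structure(list(residues = residues, root = as.integer(root),
                 children = children),
            class = "glycan_tree")
}

n_residues <- function(tree) length(tree$residues)

tree_children <- function(tree, id) tree$children[[as.character(id)]]

tree_residue <- function(tree, id) tree$residues[[as.character(id)]]

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> ", n_residues(x), " residue(s), root = ",
      tree_residue(x, x$root)$sugar_type, " (id ", x$root, ")\n", sep = "")
  cat("  ", serialize_glycan(x), "\n", sep = "")
  invisible(x)
}

## ---- text dialect ----------------------------------------------------------

# Tokens: residue names with optional linkage "(a1-4)"; branches in square
# brackets precede the residue they attach to; leftmost = non-reducing end,
# rightmost residue (no linkage) = reducing-end root.
.tokenize_glycan <- function(text) {
  s <- gsub("\\s+", "", text)
  pat <- "\\[|\\]|[A-Za-z0-9]+(\\([ab][12]-[0-9]\\))?"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  toks <- regmatches(s, gregexpr(pat, s, perl = TRUE))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] == -1 || covered != nchar(s)) {
    # find the first uncovered character for a useful message
    mask <- rep(FALSE, nchar(s))
    if (m[1] != -1) {
      for (i in seq_along(m)) mask[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
    }
    bad <- which(!mask)[1]
    stop("glycan parse error near '", substr(s, bad, min(nchar(s), bad + 5)),
         "' (offset ", bad, ")")
  }
  toks
}

#' Parse a glycan from text
#'
#' Accepts either the IUPAC-condensed style dialect, e.g.
#' `"Fuc(a1-2)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc"`, or (when the string starts
#' with `{`) the JSON tree dialect whose records mirror the library fields
#' (id/pid/sugar_type/anomeric/link/substituents). In the text dialect the
#' rightmost residue is the reducing-end root; `X(a1-4)Y` makes `X` a child
#' of `Y` attached at position 4; bracketed groups attach to the residue
#' that follows them.
#'
#' @param text A glycan string, or a JSON string / path to a JSON file.
#' @return A [glycan_tree()].
#' @export
#' @examples
#' parse_glycan("Gal(b1-4)Glc")
parse_glycan <- function(text) {
  if (length(text) != 1L || !is.character(text)) stop("text must be a single string")
  if (grepl("^\\s*\\{", text) || (file.exists(text) && grepl("\\.json$", text))) {
    return(glycan_from_json(text))
  }
  toks <- .tokenize_glycan(text)
  next_id <- 0L
  # pending: list of list(node_ids, root_local_id, anomeric, apos, link)
  make_res <- function(tok) {
    mm <- regmatches(tok, regexec("^([A-Za-z0-9]+?)(\\(([ab])([12])-([0-9])\\))?$", tok))[[1]]
    name <- mm[2]
    if (!name %in% sugar_types()) {
      stop("glycan parse error: unknown sugar '", name, "' in token '", tok, "'")
    }
    if (mm[3] == "") {
      list(name = name, anomeric = NA_character_, apos = NA_integer_, link = NA_integer_)
    } else {
      list(name = name, anomeric = mm[4], apos = as.integer(mm[5]),
           link = as.integer(mm[6]))
    }
  }
  # recursive descent over the token stream
  i <- 1L
  all_res <- list()   # accumulated argument lists for residue()
  parse_chain <- function(inside_bracket) {
    pending <- list()  # subtrees waiting for their parent
    repeat {
      if (i > length(toks)) {
        if (inside_bracket) stop("glycan parse error: unclosed '['")
        stop("glycan parse error: chain ends without a root residue")
      }
      tok <- toks[[i]]
      if (tok == "[") {
        i <<- i + 1L
        pending[[length(pending) + 1L]] <- parse_chain(TRUE)
      } else if (tok == "]") {
        stop("glycan parse error: unexpected ']'")
      } else {
        r <- make_res(tok)
        i <<- i + 1L
        next_id <<- next_id + 1L
        my_id <- next_id
        all_res[[length(all_res) + 1L]] <<- list(
          id = my_id, sugar_type = r$name, anomeric = r$anomeric, link = r$link)
        for (p in pending) {
          all_res[[p$root_pos]]$pid <<- my_id
        }
        pending <- list()
        if (is.na(r$link)) {
          # root of this chain level
          if (inside_bracket) stop("glycan parse error: bracket group residue '",
                                   tok, "' lacks a linkage")
          if (i <= length(toks)) stop("glycan parse error: trailing token '",
                                      toks[[i]], "' after root")
          return(list(root_pos = length(all_res)))
        }
        # linked residue: it becomes pending for the next residue...
        if (i <= length(toks) && toks[[i]] == "]") {
          if (!inside_bracket) stop("glycan parse error: unexpected ']'")
          i <<- i + 1L
          return(list(root_pos = length(all_res)))
        }
        pending[[length(pending) + 1L]] <- list(root_pos = length(all_res))
      }
    }
  }
  parse_chain(FALSE)
  res <- lapply(all_res, function(a) {
    residue(a$id, a$sugar_type,
            pid = if (is.null(a$pid)) NA_integer_ else a$pid,
            anomeric = a$anomeric, link = a$link)
  })
  glycan_tree(res)
}

#' Serialize a glycan tree to the text dialect
#'
#' Children are written in ascending parent-link-position order: the
#' lowest-position child continues the chain inline, the rest appear in
#' square brackets. `parse_glycan(serialize_glycan(t))` reproduces `t`
#' up to residue renumbering.
#'
#' @param tree A [glycan_tree()].
#' @return A single string.
#' @export
serialize_glycan <- function(tree) {
  ser <- function(id) {
    r <- tree_residue(tree, id)
    kids <- tree_children(tree, id)
    pre <- ""
    if (length(kids)) {
      parts <- vapply(kids, function(k) {
        kr <- tree_residue(tree, k)
        paste0(ser(k), "(", kr$anomeric, kr$apos, "-", kr$link, ")")
      }, character(1))
      pre <- paste0(parts[1],
                    if (length(parts) > 1)
                      paste0("[", parts[-1], "]", collapse = "") else "")
    }
    paste0(pre, r$sugar_type)
  }
  ser(tree$root)
}

## ---- JSON dialect ----------------------------------------------------------

#' Read a glycan tree from the JSON dialect
#'
#' @param x JSON string or path to a `.json` file with a top-level
#'   `residues` array; each record has `id`, `pid` (null for the root),
#'   `sugar_type`, `anomeric`, `link`, and optional `substituents`
#'   (object position -> token).
#' @return A [glycan_tree()].
#' @export
glycan_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(obj$residues)) stop("JSON glycan must have a 'residues' array")
  res <- lapply(obj$residues, function(r) {
    subs <- character(0)
    if (!is.null(r$substituents)) {
      subs <- vapply(r$substituents, as.character, character(1))
    }
    residue(r$id, r$sugar_type,
            pid = if (is.null(r$pid)) NA_integer_ else as.integer(r$pid),
            anomeric = if (is.null(r$anomeric)) NA_character_ else r$anomeric,
            link = if (is.null(r$link)) NA_integer_ else as.integer(r$link),
            substituents = subs)
  })
  glycan_tree(res)
}

#' Write a glycan tree to the JSON dialect
#' @param tree A [glycan_tree()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
glycan_to_json <- function(tree, path = NULL) {
  recs <- lapply(tree$residues, function(r) {
    list(id = r$id, pid = if (is.na(r$pid)) NULL else r$pid,
         sugar_type = r$sugar_type,
         anomeric = if (is.na(r$anomeric)) NULL else r$anomeric,
         link = if (is.na(r$link)) NULL else r$link,
         substituents = as.list(r$sub))
  })
  js <- jsonlite::toJSON(list(residues = unname(recs)), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

## ---- queries ---------------------------------------------------------------

#' Leaf residues of a glycan tree
#'
#' Residues with no child residue, in ascending id order.
#'
#' @param tree A [glycan_tree()].
#' @return List of `glycan_residue` objects.
#' @export
leaf_residues <- function(tree) {
  ids <- sort(as.integer(names(Filter(function(k) length(k) == 0L, tree$children))))
  lapply(ids, function(i) tree_residue(tree, i))
}

#' Major chain of a glycan tree
#'
#' The longest path from a leaf residue to the root residue, used to
#' schedule fragment assembly. Ties are broken toward the child with the
#' smallest parent link position, then the smallest id, so the result is
#' deterministic.
#'
#' @param tree A [glycan_tree()].
#' @return Integer vector of residue ids, leaf first, root last.
#' @export
major_chain <- function(tree) {
  best <- function(id) {
    kids <- tree_children(tree, id)
    if (!length(kids)) return(list(len = 1L, path = id))
    cand <- lapply(kids, best)
    lens <- vapply(cand, `[[`, integer(1), "len")
    links <- vapply(kids, function(k) tree_residue(tree, k)$link, integer(1))
    pick <- order(-lens, links, kids)[1]
    list(len = cand[[pick]]$len + 1L, path = c(cand[[pick]]$path, id))
  }
  best(tree$root)$path
}

# ids of the subtree rooted at id (inclusive), in DFS order
subtree_ids <- function(tree, id) {
  out <- integer(0)
  stack <- id
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    out <- c(out, cur)
    stack <- c(tree_children(tree, cur), stack)
  }
  out
}

# induced glycan_tree on a connected id set; the residue whose pid falls
# outside `ids` (or the tree root) becomes the state's root and keeps its
# anomeric/link fields so matching can compare the outgoing bond
induced_state <- function(tree, ids) {
  ids <- as.integer(ids)
  res <- lapply(ids, function(i) {
    r <- tree_residue(tree, i)
    if (!is.na(r$pid) && !(r$pid %in% ids)) {
      r$pid <- NA_integer_  # keeps link/anomeric for boundary comparison
    }
    r
  })
  glycan_tree(res)
}
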