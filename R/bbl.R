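#' Create a building block
#'
#' A building block (BBL) is a protected thioglycoside of 1-3 residues
#' with a measured or predicted relative reactivity value (RRV). A
#' reducing-end acceptor has RRV 0.
#'
#' @param index Library key (character or integer; stored as character).
#' @param name IUPAC-style display name.
#' @param tree A [glycan_tree()] of 1-3 residues; the root is the
#'   reducing-end residue carrying the leaving group.
#' @param rrv Non-negative relative reactivity value (dimensionless,
#'   relative to the reference donor).
#' @param rrv_source `"measured"` or `"predicted"`.
#' @param leaving_group Anomeric leaving-group token; thio-tolyl by default.
#' @return An object of class `building_block`.
#' @export
building_block <- function(index, name, tree, rrv,
                           rrv_source = c("measured", "predicted"),
                           leaving_group = "STol") {
  rrv_source <- match.arg(rrv_source)
  if (!inherits(tree, "glycan_tree")) stop("tree must be a glycan_tree")
  if (!n_residues(tree) %in% 1:3) {
    stop("a building block must contain 1 to 3 residues, got ", n_residues(tree))
  }
  if (!is.numeric(rrv) || length(rrv) != 1L || is.na(rrv) || rrv < 0) {
    stop("rrv must be a single non-negative number")
  }
  # sialic acid is only usable as the terminal unit of a sialyl di/tri-
  # saccharide; a lone SA residue is never a workable donor
  sa <- vapply(tree$residues, function(r) r$sugar_class == "SA", logical(1))
  if (any(sa)) {
    if (n_residues(tree) < 2L) {
      stop("a lone sialic acid residue cannot be a building block; ",
           "use a sialyl disaccharide")
    }
    leaves <- vapply(leaf_residues(tree), `[[`, integer(1), "id")
    sa_ids <- as.integer(names(tree$residues)[sa])
    if (!all(sa_ids %in% leaves)) {
      stop("sialic acid must be the non-reducing terminal unit of the block")
    }
  }
  structure(list(index = as.character(index), name = name, tree = tree,
                 rrv = as.numeric(rrv), rrv_source = rrv_source,
                 leaving_group = leaving_group),
            class = "building_block")
}

#' @export
print.building_block <- function(x, ...) {
  cat("<building_block> ", x$index, ": ", x$name, "\n  ",
      serialize_glycan(x$tree), "-", x$leaving_group,
      "  RRV = ", format(x$rrv), " (", x$rrv_source, ")\n", sep = "")
  invisible(x)
}

#' Assemble building blocks into a library
#'
#' @param bbls List of [building_block()] objects with unique indices.
#' @return Object of class `bbl_library` (a list of building blocks,
#'   named by index).
#' @export
bbl_library <- function(bbls) {
  idx <- vapply(bbls, `[[`, character(1), "index")
  if (anyDuplicated(idx)) {
    stop("duplicate building-block index: ", idx[duplicated(idx)][1])
  }
  structure(stats::setNames(bbls, idx), class = "bbl_library")
}

#' @export
print.bbl_library <- function(x, ...) {
  cat("<bbl_library> ", length(x), " building block(s)\n", sep = "")
  for (b in x) {
    cat(sprintf("  %-6s RRV %10.4g  %s\n", b$index, b$rrv,
                serialize_glycan(b$tree)))
  }
  invisible(x)
}

## ---- CSV / JSON library formats -------------------------------------------

.bbl_csv_cols <- c("index", "name", "rrv", "rrv_source", "leaving_group",
                   "residue_id", "residue_pid", "sugar_type", "anomeric",
                   "link", "sub2", "sub3", "sub4", "sub6")

#' Write a building-block library to CSV
#'
#' One row per residue; block-level columns (`index`, `name`, `rrv`,
#' `rrv_source`, `leaving_group`) are repeated on each row of the block.
#' Substituent columns `sub2..sub6` hold the token at that ring position
#' (empty when the position does not exist or is an internal glycosidic
#' bond); for a HexNAc, `sub2` holds the amine token.
#'
#' @param library A [bbl_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bbl_csv <- function(library, path) {
  rows <- list()
  for (b in library) {
    for (r in b$tree$residues) {
      row <- data.frame(index = b$index, name = b$name, rrv = b$rrv,
                        rrv_source = b$rrv_source,
                        leaving_group = b$leaving_group,
                        residue_id = r$id, residue_pid = r$pid,
                        sugar_type = r$sugar_type, anomeric = r$anomeric,
                        link = r$link,
                        sub2 = NA_character_, sub3 = NA_character_,
                        sub4 = NA_character_, sub6 = NA_character_,
                        stringsAsFactors = FALSE)
      for (p in names(r$sub)) row[[paste0("sub", p)]] <- r$sub[[p]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df[, .bbl_csv_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a building-block library from CSV
#'
#' @param path CSV file written in the layout of [write_bbl_csv()].
#' @return A [bbl_library()].
#' @export
read_bbl_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.bbl_csv_cols, names(df))
  if (length(missing)) {
    stop("library CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  bbls <- lapply(split(df, factor(df$index, levels = unique(df$index))),
                 function(g) {
    res <- lapply(seq_len(nrow(g)), function(i) {
      row <- g[i, ]
      subs <- character(0)
      for (p in c("2", "3", "4", "6")) {
        tok <- blank_to_na(row[[paste0("sub", p)]])
        if (!is.na(tok)) subs[p] <- tok
      }
      residue(as.integer(row$residue_id), row$sugar_type,
              pid = if (is.na(blank_to_na(row$residue_pid))) NA_integer_
                    else as.integer(row$residue_pid),
              anomeric = blank_to_na(row$anomeric),
              link = if (is.na(blank_to_na(row$link))) NA_integer_
                     else as.integer(row$link),
              substituents = subs)
    })
    building_block(g$index[1], g$name[1], glycan_tree(res),
                   rrv = as.numeric(g$rrv[1]), rrv_source = g$rrv_source[1],
                   leaving_group = g$leaving_group[1])
  })
  bbl_library(unname(bbls))
}

#' Write a building-block library to nested JSON
#' @inheritParams write_bbl_csv
#' @return `path`, invisibly (or the JSON string when `path` is `NULL`).
#' @export
write_bbl_json <- function(library, path = NULL) {
  recs <- lapply(unname(library), function(b) {
    list(index = b$index, name = b$name, rrv = b$rrv,
         rrv_source = b$rrv_source, leaving_group = b$leaving_group,
         residues = lapply(unname(b$tree$residues), function(r) {
           list(id = r$id, pid = if (is.na(r$pid)) NULL else r$pid,
                sugar_type = r$sugar_type,
                anomeric = if (is.na(r$anomeric)) NULL else r$anomeric,
                link = if (is.na(r$link)) NULL else r$link,
                substituents = as.list(r$sub))
         }))
  })
  js <- jsonlite::toJSON(list(bbls = recs), auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a building-block library from nested JSON
#' @param path JSON file (or string) in the layout of [write_bbl_json()].
#' @return A [bbl_library()].
#' @export
read_bbl_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$bbls)) stop("library JSON must have a 'bbls' array")
  bbls <- lapply(obj$bbls, function(b) {
    res <- lapply(b$residues, function(r) {
      subs <- if (is.null(r$substituents)) character(0)
              else vapply(r$substituents, as.character, character(1))
      residue(r$id, r$sugar_type,
              pid = if (is.null(r$pid)) NA_integer_ else as.integer(r$pid),
              anomeric = if (is.null(r$anomeric)) NA_character_ else r$anomeric,
              link = if (is.null(r$link)) NA_integer_ else as.integer(r$link),
              substituents = subs)
    })
    building_block(b$index, b$name, glycan_tree(res), rrv = b$rrv,
                   rrv_source = b$rrv_source, leaving_group = b$leaving_group)
  })
  bbl_library(bbls)
}
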