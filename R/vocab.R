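#' Controlled vocabularies for sugars and protecting groups
#'
#' The planner operates on a fixed chemical vocabulary: six-carbon sugars
#' (hexoses and N-acetyl-hexosamines), sialic acid, and the protecting-group
#' tokens used to mask ring hydroxyls of thioglycoside building blocks.
#'
#' @name glycoplan-vocab
NULL

# sugar type -> sugar class lookup; Fuc is a 6-deoxy hexose
.SUGAR_CLASS <- c(
  Gal = "Hex", Glc = "Hex", Man = "Hex", Fuc = "Hex",
  GalNAc = "HexNAc", GlcNAc = "HexNAc", Neu5Ac = "SA"
)

#' Sugar types known to the data model
#' @return Character vector of sugar type tokens.
#' @export
sugar_types <- function() names(.SUGAR_CLASS)

#' Sugar class of a sugar type
#'
#' @param sugar_type Character vector of sugar type tokens.
#' @return Character vector with elements in `c("Hex", "HexNAc", "SA")`.
#' @export
#' @examples
#' sugar_class(c("Gal", "GlcNAc", "Neu5Ac"))
sugar_class <- function(sugar_type) {
  bad <- setdiff(sugar_type, names(.SUGAR_CLASS))
  if (length(bad)) {
    stop("unknown sugar type(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(names(.SUGAR_CLASS), collapse = ", "))
  }
  unname(.SUGAR_CLASS[sugar_type])
}

#' Protecting-group vocabulary
#'
#' The 11 hydroxyl substituent tokens (free OH plus 10 protecting groups)
#' available at ring positions of a hexose, and the 3 amine protecting
#' groups available at position 2 of a HexNAc virtual building block.
#'
#' @return A list with elements `hex` (11 tokens) and `amine` (3 tokens).
#' @export
#' @examples
#' pg_vocab()$hex
pg_vocab <- function() {
  list(
    hex = c("OH", "OAc", "OBn", "OBz", "OClAc", "OLev",
            "NO2Bz", "OPMB", "OTBDPS", "OTBS", "OTIPS"),
    amine = c("NHTroc", "NPhth", "N3")
  )
}

#' Protecting groups that can be removed selectively
#'
#' Tokens considered selectively deprotectable in the presence of the
#' permanent groups (benzyl ethers, benzoates, acetates). Used by the
#' precursor-match rule: a masked coupling position must carry one of
#' these, uniquely within the building block. User-extensible because
#' orthogonality depends on the rest of the protection scheme.
#'
#' @return Character vector of tokens.
#' @export
removable_pgs <- function() {
  c("OLev", "OClAc", "OPMB", "NO2Bz", "OTBDPS", "OTBS", "OTIPS", "Fmoc")
}

# ring positions that can carry an O-substituent, by sugar type
.O_POSITIONS <- list(
  Gal = c(2L, 3L, 4L, 6L), Glc = c(2L, 3L, 4L, 6L), Man = c(2L, 3L, 4L, 6L),
  Fuc = c(2L, 3L, 4L),                      # 6-deoxy
  GalNAc = c(3L, 4L, 6L), GlcNAc = c(3L, 4L, 6L),
  Neu5Ac = integer(0)                       # never matched on substituents
)

#' Substituent positions of a sugar type
#'
#' O-substituent ring positions for a given sugar type. HexNAc sugars
#' additionally carry an amine substituent at position 2 (not a
#' glycosylation site; see [residue()]).
#'
#' @param sugar_type Single sugar type token.
#' @return Integer vector of ring positions.
#' @export
o_positions <- function(sugar_type) {
  sugar_class(sugar_type)  # validates
  .O_POSITIONS[[sugar_type]]
}

#' Amine tokens accepted at position 2 of a HexNAc residue
#' @return Character vector (the virtual-library amine vocabulary plus NHAc).
#' @export
amine_tokens <- function() c("NHAc", pg_vocab()$amine)
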