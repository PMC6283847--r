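#' Enumerate virtual hexose building blocks
#'
#' All protecting-group combinations of the three hexose types (Gal, Glc,
#' Man) with any of the 11 substituent tokens at each of the four ring
#' positions R2, R3, R4, R6: exactly 3 x 11^4 = 43,923 distinct
#' structures, in deterministic order. All virtual BBLs are thio-tolyl
#' glycosides.
#'
#' @return data.frame with columns `key`, `sugar_type`, `anomeric`,
#'   `pg2`, `pg3`, `pg4`, `pg6`, `leaving_group`.
#' @export
enumerate_hex <- function() {
  v <- pg_vocab()$hex
  g <- expand.grid(pg6 = v, pg4 = v, pg3 = v, pg2 = v,
                   sugar_type = c("Gal", "Glc", "Man"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("sugar_type", "pg2", "pg3", "pg4", "pg6")]
  g$anomeric <- "b"
  g$leaving_group <- "STol"
  g$key <- sprintf("%s|%s|%s|%s|%s", g$sugar_type, g$pg2, g$pg3, g$pg4, g$pg6)
  g[, c("key", "sugar_type", "anomeric", "pg2", "pg3", "pg4", "pg6",
        "leaving_group")]
}

#' Enumerate virtual N-acetyl-hexosamine building blocks
#'
#' GalNAc and GlcNAc with an amine protecting group (NHTroc, NPhth or N3)
#' at position 2 and any of the 11 substituent tokens at R3, R4, R6:
#' exactly 2 x 3 x 11^3 = 7,986 structures.
#'
#' @return data.frame in the layout of [enumerate_hex()].
#' @export
enumerate_hexnac <- function() {
  v <- pg_vocab()
  g <- expand.grid(pg6 = v$hex, pg4 = v$hex, pg3 = v$hex, pg2 = v$amine,
                   sugar_type = c("GalNAc", "GlcNAc"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("sugar_type", "pg2", "pg3", "pg4", "pg6")]
  g$anomeric <- "b"
  g$leaving_group <- "STol"
  g$key <- sprintf("%s|%s|%s|%s|%s", g$sugar_type, g$pg2, g$pg3, g$pg4, g$pg6)
  g[, c("key", "sugar_type", "anomeric", "pg2", "pg3", "pg4", "pg6",
        "leaving_group")]
}

## ---- SMILES templates ------------------------------------------------------

.SMILES_FRAG <- c(
  OH = "O", OAc = "OC(C)=O", OBn = "OCc1ccccc1", OBz = "OC(=O)c1ccccc1",
  OClAc = "OC(=O)CCl", OLev = "OC(=O)CCC(C)=O",
  NO2Bz = "OC(=O)c1ccc(cc1)[N+](=O)[O-]", OPMB = "OCc1ccc(OC)cc1",
  OTBDPS = "O[Si](c1ccccc1)(c1ccccc1)C(C)(C)C", OTBS = "O[Si](C)(C)C(C)(C)C",
  OTIPS = "O[Si](C(C)C)(C(C)C)C(C)C",
  NHAc = "NC(C)=O", NHTroc = "NC(=O)OCC(Cl)(Cl)Cl",
  NPhth = "N1C(=O)c2ccccc2C1=O", N3 = "N=[N+]=[N-]")

#' SMILES of a virtual building block
#'
#' Assembles a (non-stereo) SMILES string from a pyranose ring template
#' per sugar class with the substituent fragments attached at R2, R3, R4
#' and R6 and a thio-tolyl anomeric leaving group. Stereochemistry is not
#' encoded; the string is a structural key for fingerprinting, not a full
#' stereochemical record.
#'
#' @param sugar_type,pg2,pg3,pg4,pg6 Structure fields as in
#'   [enumerate_hex()] rows (`pg2` is the amine token for a HexNAc).
#' @return A SMILES string.
#' @export
vbbl_smiles <- function(sugar_type, pg2, pg3, pg4, pg6) {
  f <- function(tok) {
    s <- .SMILES_FRAG[[tok]]
    if (is.null(s)) stop("no SMILES fragment for token ", tok)
    paste0("(", s, ")")
  }
  # C1(anomeric, STol) - C2 - C3 - C4 - C5(-C6H2-PG6) - O5 - back to C1
  paste0("C1(Sc2ccc(C)cc2)", "C", f(pg2), "C", f(pg3), "C", f(pg4),
         "C(C", .SMILES_FRAG[[pg6]], ")O1")
}

## ---- fingerprints and Tanimoto screen --------------------------------------

#' Structural token fingerprint
#'
#' Default fingerprint: the set of structural tokens of a building block
#' (sugar type and class, anomeric form, position:substituent pairs,
#' adjacent-position substituent pairs as short paths, and internal
#' linkages for multi-residue blocks). Works on [building_block()] objects
#' and on enumeration rows (lists with `sugar_type`, `anomeric`,
#' `pg2..pg6`). Any function returning a character set can replace it in
#' [tanimoto_screen()]; the backend used is recorded in the screen output.
#'
#' @param x A building block or an enumeration-row list.
#' @return Character vector (a set) of tokens.
#' @export
fp_tokens <- function(x) {
  row_tokens <- function(st, an, pgs) {
    pos <- c("2", "3", "4", "6")
    pgs <- pgs[!is.na(pgs)]
    toks <- c(paste0("type:", st), paste0("class:", sugar_class(st)),
              paste0("ano:", an),
              paste0("pg", names(pgs), ":", pgs))
    # short paths over adjacent ring positions
    keep <- intersect(pos, names(pgs))
    if (length(keep) > 1L) {
      for (i in seq_len(length(keep) - 1L)) {
        a <- keep[i]; b <- keep[i + 1L]
        toks <- c(toks, paste0("path:", a, pgs[[a]], "-", b, pgs[[b]]))
      }
    }
    toks
  }
  if (inherits(x, "building_block")) {
    toks <- character(0)
    for (r in x$tree$residues) {
      pgs <- r$sub
      toks <- c(toks, row_tokens(r$sugar_type, r$anomeric, pgs))
      if (!is.na(r$pid)) {
        toks <- c(toks, paste0("link:", r$sugar_type, r$anomeric, r$apos,
                               "-", r$link))
      }
    }
    return(unique(toks))
  }
  x <- as.list(x)
  unique(row_tokens(x$sugar_type, x$anomeric,
                    stats::setNames(c(x$pg2, x$pg3, x$pg4, x$pg6),
                                    c("2", "3", "4", "6"))))
}

#' Tanimoto similarity of two token sets
#'
#' @param a,b Character vectors treated as sets.
#' @return `|intersect| / |union|`, in [0, 1] (1 for two empty sets).
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Screen a virtual library against the training set by similarity
#'
#' Computes, for every virtual building block, the maximum Tanimoto
#' similarity to any training building block, and for each threshold the
#' fraction of virtual BBLs at or above it (the coverage). The coverage
#' fractions depend on the fingerprint backend, which is therefore
#' pluggable and recorded in the result.
#'
#' @param virtual List (or data.frame of enumeration rows) of virtual
#'   building blocks.
#' @param training Non-empty list of training [building_block()]s (or
#'   enumeration-row lists).
#' @param thresholds Similarity thresholds (default 0.75, 0.80, 0.85).
#' @param fp Fingerprint function (default [fp_tokens()]).
#' @return List with `max_similarity` (numeric per virtual BBL),
#'   `coverage` (named fractions per threshold), and `fingerprint` (the
#'   backend name).
#' @export
tanimoto_screen <- function(virtual, training,
                            thresholds = c(0.75, 0.80, 0.85),
                            fp = fp_tokens) {
  vlist <- .as_fp_list(virtual)
  tlist <- .as_fp_list(training)
  if (!length(tlist)) stop("training set must not be empty")
  vfp <- lapply(vlist, fp)
  tfp <- lapply(tlist, fp)
  vocab <- unique(c(unlist(vfp), unlist(tfp)))
  tomat <- function(fps) {
    m <- matrix(0L, nrow = length(fps), ncol = length(vocab))
    for (i in seq_along(fps)) m[i, match(fps[[i]], vocab)] <- 1L
    m
  }
  V <- tomat(vfp); Tm <- tomat(tfp)
  inter <- V %*% t(Tm)
  sizes_v <- rowSums(V); sizes_t <- rowSums(Tm)
  uni <- outer(sizes_v, sizes_t, `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  max_sim <- apply(sim, 1, max)
  cov <- vapply(thresholds, function(t) mean(max_sim >= t), numeric(1))
  list(max_similarity = max_sim,
       coverage = stats::setNames(cov, format(thresholds)),
       fingerprint = deparse(substitute(fp))[1])
}

.as_fp_list <- function(x) {
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
  } else if (inherits(x, "bbl_library")) {
    unname(as.list(x))
  } else {
    x
  }
}

#' Attach predicted RRVs to enumerated virtual building blocks
#'
#' Builds feature rows for each enumerated structure from a feature
#' provider and predicts RRVs with a fitted model. The default provider
#' is the deterministic structural surrogate ([shift_profile()] /
#' [descriptor_profile()]); a table of externally computed shifts and
#' descriptors can be supplied instead via a custom provider.
#'
#' @param fit An [rrv_fit()].
#' @param vbbls data.frame of enumeration rows ([enumerate_hex()] /
#'   [enumerate_hexnac()]).
#' @param provider Function mapping one enumeration row (list) to a named
#'   numeric vector of shift slots and `md_*` descriptors.
#' @return `vbbls` with a `predicted_rrv` column appended.
#' @export
predict_virtual <- function(fit, vbbls, provider = surrogate_features) {
  feats <- lapply(seq_len(nrow(vbbls)), function(i)
    provider(as.list(vbbls[i, , drop = FALSE])))
  fm <- do.call(rbind, feats)
  raw <- cbind(vbbls[, c("sugar_type", "anomeric", "pg2", "pg3", "pg4",
                         "pg6")],
               as.data.frame(fm))
  raw$index <- vbbls$key
  vbbls$predicted_rrv <- predict(fit, raw)
  vbbls
}

#' Deterministic surrogate feature provider for virtual building blocks
#'
#' @param row Enumeration-row list (`sugar_type`, `anomeric`, `pg2..pg6`).
#' @return Named numeric vector of the 13 shift slots and `md_*` columns.
#' @export
surrogate_features <- function(row) {
  pgs <- list(pg2 = row$pg2, pg3 = row$pg3, pg4 = row$pg4, pg6 = row$pg6)
  c(shift_profile(row$sugar_type, row$anomeric, pgs),
    descriptor_profile(row$sugar_type, row$anomeric, pgs))
}
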