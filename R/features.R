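#' Feature configuration for RRV prediction
#'
#' Controls which feature blocks enter the design matrix and how each is
#' encoded. Blocks: `bp` (basic properties: sugar type, sugar class,
#' anomeric state, protecting group per position), `cs` (the 13 ring
#' chemical shifts H1..H6-2, C1..C6, in ppm), `md` (molecular descriptor
#' columns, any names starting with `md_`).
#'
#' @param blocks Character subset of `c("bp", "cs", "md")`.
#' @param cs_mode `"normalized"` (per-slot min-max over the training set),
#'   `"binarized"` (fixed-width bin indicators over the training range:
#'   0.2 ppm for 1H, 2.0 ppm for 13C), or `"both"`.
#' @param h_bin,c_bin Bin widths in ppm for the binarized shift encoding.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(blocks = c("bp", "cs", "md"),
                           cs_mode = c("both", "normalized", "binarized"),
                           h_bin = 0.2, c_bin = 2.0) {
  blocks <- match.arg(blocks, c("bp", "cs", "md"), several.ok = TRUE)
  cs_mode <- match.arg(cs_mode)
  structure(list(blocks = blocks, cs_mode = cs_mode,
                 h_bin = h_bin, c_bin = c_bin),
            class = "feature_config")
}

.SHIFT_SLOTS <- c("H1", "H2", "H3", "H4", "H5", "H6_1", "H6_2",
                  "C1", "C2", "C3", "C4", "C5", "C6")

.bp_levels <- function() {
  v <- pg_vocab()
  list(sugar_type = c("Gal", "Glc", "Man", "GalNAc", "GlcNAc"),
       sugar_class = c("Hex", "HexNAc"),
       anomeric = c("a", "b"),
       pg2 = c(v$hex, v$amine, "NHAc"),
       pg3 = v$hex, pg4 = v$hex, pg6 = v$hex)
}

#' One-hot encode the basic properties of one building block
#'
#' @param props Named list or one-row data.frame with `sugar_type`,
#'   `anomeric` (`"a"`/`"b"`), and `pg2`, `pg3`, `pg4`, `pg6` substituent
#'   tokens (`pg2` is the amine token for a HexNAc); `sugar_class` is
#'   derived.
#' @return Named numeric vector of 0/1 indicators; each categorical field
#'   contributes exactly one 1.
#' @export
#' @examples
#' encode_basic(list(sugar_type = "Gal", anomeric = "b",
#'                   pg2 = "OBn", pg3 = "OBn", pg4 = "OH", pg6 = "OBz"))
encode_basic <- function(props) {
  props <- as.list(props)
  props$sugar_class <- sugar_class(props$sugar_type)
  lv <- .bp_levels()
  out <- numeric(0)
  for (f in names(lv)) {
    val <- props[[f]]
    if (is.null(val) || is.na(val)) stop("basic property '", f, "' is missing")
    if (!val %in% lv[[f]]) {
      stop("unknown token '", val, "' for ", f, "; allowed: ",
           paste(lv[[f]], collapse = ", "))
    }
    v <- stats::setNames(as.numeric(lv[[f]] == val),
                         paste0(f, "_", lv[[f]]))
    out <- c(out, v)
  }
  out
}

#' Encode ring chemical shifts over a training table
#'
#' Fits the per-slot statistics on the rows given (the training set) and
#' returns the encoded matrix. `normalized` is per-slot min-max into
#' [0, 1] (a constant slot encodes to 0 by convention); `binarized` is a
#' fixed-width bin indicator per occupied bin of the training range (a
#' constant slot gives a single always-on bin).
#'
#' @param shifts Matrix/data.frame with the 13 columns
#'   `H1..H6_2, C1..C6` (ppm).
#' @param mode `"normalized"`, `"binarized"` or `"both"`.
#' @param h_bin,c_bin Bin widths (ppm).
#' @return Numeric matrix with named columns.
#' @export
encode_shifts <- function(shifts, mode = c("normalized", "binarized", "both"),
                          h_bin = 0.2, c_bin = 2.0) {
  mode <- match.arg(mode)
  enc <- .fit_shift_encoder(as.data.frame(shifts), h_bin, c_bin)
  .apply_shift_encoder(enc, as.data.frame(shifts), mode)
}

.fit_shift_encoder <- function(df, h_bin, c_bin) {
  missing <- setdiff(.SHIFT_SLOTS, names(df))
  if (length(missing)) stop("shift table lacks slot(s): ",
                            paste(missing, collapse = ", "))
  enc <- list(h_bin = h_bin, c_bin = c_bin, slots = list())
  for (s in .SHIFT_SLOTS) {
    x <- df[[s]]
    if (any(!is.na(x) & !is.finite(x))) stop("non-finite shift in slot ", s)
    mean_s <- mean(x, na.rm = TRUE)
    if (is.nan(mean_s)) mean_s <- 0
    has_na <- anyNA(x)
    x <- ifelse(is.na(x), mean_s, x)
    w <- if (startsWith(s, "H")) h_bin else c_bin
    lo <- floor(min(x) / w) * w
    hi <- ceiling(max(x) / w + 1e-9) * w
    if (hi <= lo) hi <- lo + w
    enc$slots[[s]] <- list(min = min(x), max = max(x), impute = mean_s,
                           has_na = has_na,
                           breaks = seq(lo, hi, by = w))
  }
  enc
}

.apply_shift_encoder <- function(enc, df, mode) {
  n <- nrow(df)
  cols <- list()
  clipped <- 0L
  for (s in .SHIFT_SLOTS) {
    sl <- enc$slots[[s]]
    x <- df[[s]]
    if (any(!is.na(x) & !is.finite(x))) stop("non-finite shift in slot ", s)
    na <- is.na(x)
    x[na] <- sl$impute
    if (mode %in% c("normalized", "both")) {
      rng <- sl$max - sl$min
      z <- if (rng <= 0) rep(0, n) else (x - sl$min) / rng
      clipped <- clipped + sum(z < 0 | z > 1)
      cols[[paste0("cs_", s, "_n")]] <- pmin(1, pmax(0, z))
    }
    if (mode %in% c("binarized", "both")) {
      br <- sl$breaks
      bin <- findInterval(x, br, rightmost.closed = TRUE)
      bin <- pmin(pmax(bin, 1L), length(br) - 1L)  # clip out-of-range rows
      for (b in seq_len(length(br) - 1L)) {
        cols[[sprintf("cs_%s_bin%02d", s, b)]] <- as.numeric(bin == b)
      }
    }
    if (sl$has_na) cols[[paste0("cs_", s, "_imputed")]] <- as.numeric(na)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(df)
  attr(m, "clipped") <- clipped
  m
}

#' Assemble an RRV regression dataset
#'
#' Joins a building-block library (its single-residue Hex/HexNAc members;
#' sialic acids are excluded from RRV modelling) with a chemical-shift
#' table and a molecular-descriptor table, both keyed by BBL index, into a
#' dataset ready for [rrv_fit()]. Raw values are kept; encoding and
#' rescaling are fitted on the training rows at fit/CV time so folds never
#' leak statistics.
#'
#' @param library A [bbl_library()], or `NULL` when `data` is given.
#' @param shift_table data.frame with column `index` plus the 13 slots
#'   `H1..H6_2, C1..C6`.
#' @param descriptor_table data.frame with column `index` plus numeric
#'   descriptor columns (1D/2D descriptors; stored with an `md_` prefix).
#' @param config A [feature_config()].
#' @param data Alternatively, a pre-built raw data.frame with columns
#'   `index, sugar_type, anomeric, pg2, pg3, pg4, pg6`, the shift slots,
#'   `md_*` columns and `rrv` (as produced by [generate_rrv_dataset()]).
#' @return Object of class `rrv_dataset` with elements `raw` (data.frame),
#'   `config`, `md_cols` and `truth` (generator ground truth, or `NULL`).
#' @export
rrv_dataset <- function(library = NULL, shift_table = NULL,
                        descriptor_table = NULL,
                        config = feature_config(), data = NULL) {
  if (is.null(data)) {
    if (is.null(library)) stop("either a library or a raw data.frame is required")
    rows <- list()
    for (b in library) {
      if (n_residues(b$tree) != 1L) next
      r <- b$tree$residues[[1]]
      # SA BBLs (and sugars outside the modelling vocabulary) are excluded
      if (!r$sugar_type %in% .bp_levels()$sugar_type) next
      sub <- function(p) if (p %in% names(r$sub)) r$sub[[p]] else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        index = b$index, sugar_type = r$sugar_type,
        anomeric = r$anomeric, pg2 = sub("2"), pg3 = sub("3"),
        pg4 = sub("4"), pg6 = sub("6"), rrv = b$rrv,
        stringsAsFactors = FALSE)
    }
    data <- do.call(rbind, rows)
    join <- function(tbl, what) {
      if (is.null(tbl)) return(NULL)
      miss <- setdiff(data$index, tbl$index)
      if (length(miss)) stop(what, " table lacks index(es): ",
                             paste(miss, collapse = ", "))
      tbl[match(data$index, tbl$index), , drop = FALSE]
    }
    st <- join(shift_table, "shift")
    if (!is.null(st)) data <- cbind(data, st[, .SHIFT_SLOTS, drop = FALSE])
    dt <- join(descriptor_table, "descriptor")
    if (!is.null(dt)) {
      md <- dt[, setdiff(names(dt), "index"), drop = FALSE]
      names(md) <- ifelse(startsWith(names(md), "md_"), names(md),
                          paste0("md_", names(md)))
      data <- cbind(data, md)
    }
    rownames(data) <- NULL
  }
  if (!"rrv" %in% names(data)) stop("dataset requires an 'rrv' column")
  if (any(!is.finite(data$rrv)) || any(data$rrv <= 0)) {
    stop("target error: every training RRV must be positive and finite ",
         "(ln transform)")
  }
  data$sugar_class <- sugar_class(data$sugar_type)
  data$ln_rrv <- log(data$rrv)
  md_cols <- grep("^md_", names(data), value = TRUE)
  if ("cs" %in% config$blocks && !all(.SHIFT_SLOTS %in% names(data))) {
    stop("config requests the cs block but shift slots are absent")
  }
  if ("md" %in% config$blocks && !length(md_cols)) {
    stop("config requests the md block but no md_* columns are present")
  }
  structure(list(raw = data, config = config, md_cols = md_cols,
                 truth = attr(data, "truth", exact = TRUE)),
            class = "rrv_dataset")
}

#' @export
print.rrv_dataset <- function(x, ...) {
  cat("<rrv_dataset> ", nrow(x$raw), " building blocks; blocks: ",
      paste(x$config$blocks, collapse = "+"),
      "; RRV range ", format(min(x$raw$rrv)), "-", format(max(x$raw$rrv)),
      "\n", sep = "")
  invisible(x)
}

## ---- fitted encoder (train-only statistics) -------------------------------

# Fit the full design-matrix encoder on the given rows of the dataset.
fit_encoder <- function(dataset, rows = seq_len(nrow(dataset$raw))) {
  raw <- dataset$raw[rows, , drop = FALSE]
  cfg <- dataset$config
  enc <- list(config = cfg, md_cols = dataset$md_cols)
  if ("cs" %in% cfg$blocks) {
    enc$cs <- .fit_shift_encoder(raw, cfg$h_bin, cfg$c_bin)
  }
  if ("md" %in% cfg$blocks) {
    enc$md <- lapply(stats::setNames(nm = dataset$md_cols), function(cn) {
      x <- raw[[cn]]
      if (any(!is.finite(x))) stop("non-finite descriptor in ", cn)
      list(min = min(x), max = max(x))
    })
  }
  enc
}

# Apply a fitted encoder; returns the [0,1] design matrix.
encode_rows <- function(enc, dataset, rows = seq_len(nrow(dataset$raw))) {
  raw <- dataset$raw[rows, , drop = FALSE]
  cfg <- enc$config
  parts <- list()
  if ("bp" %in% cfg$blocks) {
    bp <- t(vapply(seq_len(nrow(raw)), function(i)
      encode_basic(raw[i, c("sugar_type", "anomeric",
                            "pg2", "pg3", "pg4", "pg6")]),
      encode_basic(list(sugar_type = "Gal", anomeric = "a", pg2 = "OH",
                        pg3 = "OH", pg4 = "OH", pg6 = "OH"))))
    parts$bp <- bp
  }
  if ("cs" %in% cfg$blocks) {
    parts$cs <- .apply_shift_encoder(enc$cs, raw, cfg$cs_mode)
  }
  if ("md" %in% cfg$blocks) {
    absent <- setdiff(enc$md_cols, names(raw))
    if (length(absent)) {
      stop("rows lack descriptor column(s): ", paste(absent, collapse = ", "))
    }
    md <- vapply(enc$md_cols, function(cn) {
      st <- enc$md[[cn]]
      x <- raw[[cn]]
      rng <- st$max - st$min
      z <- if (rng <= 0) rep(0, nrow(raw)) else (x - st$min) / rng
      pmin(1, pmax(0, z))
    }, numeric(nrow(raw)))
    if (nrow(raw) == 1L) md <- matrix(md, nrow = 1,
                                      dimnames = list(NULL, enc$md_cols))
    parts$md <- md
  }
  m <- do.call(cbind, parts)
  rownames(m) <- NULL
  m
}
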