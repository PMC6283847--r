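#' Deterministic ring-shift profile of a protected monosaccharide
#'
#' Group-contribution surrogate for the 13 ring chemical shifts
#' (H1..H6-2, C1..C6, ppm) of a protected thioglycoside: a per-sugar base
#' profile plus an additive increment for the substituent at each
#' position (acyl groups shift the geminal proton strongly downfield,
#' ethers mainly the carbon, silyl groups weakly). Used by the synthetic
#' data generator (plus noise) and as the documented surrogate feature
#' provider for virtual building blocks; it is a surrogate, not an NMR
#' prediction.
#'
#' @param sugar_type,anomeric,pgs Sugar type, `"a"`/`"b"`, and named
#'   substituent tokens for positions `2,3,4,6` (`pg2` = amine token for a
#'   HexNAc).
#' @return Named numeric vector over the 13 slots.
#' @export
shift_profile <- function(sugar_type, anomeric, pgs) {
  base_H <- c(H1 = 4.65, H2 = 3.55, H3 = 3.75, H4 = 3.95, H5 = 3.60,
              H6_1 = 3.72, H6_2 = 3.64)
  base_C <- c(C1 = 86.5, C2 = 71.5, C3 = 74.0, C4 = 69.5, C5 = 77.0,
              C6 = 62.0)
  if (anomeric == "a") { base_H["H1"] <- 5.45; base_C["C1"] <- 87.5 }
  if (sugar_class(sugar_type) == "HexNAc") base_C["C2"] <- 54.0
  if (sugar_type == "Man") { base_H["H2"] <- 4.05; base_C["C2"] <- 70.5 }
  if (sugar_type == "Gal") { base_H["H4"] <- 4.25; base_C["C4"] <- 67.5 }
  sh <- c(base_H, base_C)
  acyl <- c("OAc", "OBz", "OClAc", "OLev", "NO2Bz")
  ether <- c("OBn", "OPMB")
  silyl <- c("OTBDPS", "OTBS", "OTIPS")
  slot_of <- function(p) {
    if (p == "6") list(H = c("H6_1", "H6_2"), C = "C6")
    else list(H = paste0("H", p), C = paste0("C", p))
  }
  for (p in c("2", "3", "4", "6")) {
    tok <- pgs[[paste0("pg", p)]]
    if (is.null(tok) || is.na(tok)) next
    s <- slot_of(p)
    if (tok %in% acyl) { sh[s$H] <- sh[s$H] + 1.15; sh[s$C] <- sh[s$C] + 1.8 }
    else if (tok %in% ether) { sh[s$H] <- sh[s$H] + 0.25; sh[s$C] <- sh[s$C] + 6.5 }
    else if (tok %in% silyl) { sh[s$H] <- sh[s$H] + 0.18; sh[s$C] <- sh[s$C] + 1.2 }
    else if (tok %in% c("NHTroc", "NPhth", "N3", "NHAc", "Fmoc")) {
      sh[s$H] <- sh[s$H] + 0.40
    }
  }
  sh
}

#' Deterministic structure-derived descriptor profile
#'
#' Surrogate 1D/2D molecular descriptors computed from the substituent
#' tokens: molecular-weight sum, aromatic ring count, acyl/ether/silyl
#' counts, rotatable-bond proxy and a crude hydrophobicity sum.
#'
#' @inheritParams shift_profile
#' @return Named numeric vector (`md_*`).
#' @export
descriptor_profile <- function(sugar_type, anomeric, pgs) {
  mass <- c(OH = 17, OAc = 59, OBn = 107, OBz = 121, OClAc = 93, OLev = 115,
            NO2Bz = 166, OPMB = 137, OTBDPS = 255, OTBS = 131, OTIPS = 173,
            NHAc = 58, NHTroc = 190, NPhth = 146, N3 = 42, Fmoc = 239)
  arom <- c(OBn = 1, OBz = 1, NO2Bz = 1, OPMB = 1, OTBDPS = 2, NPhth = 1,
            Fmoc = 2)
  logp <- c(OH = -0.7, OAc = 0.2, OBn = 1.8, OBz = 1.6, OClAc = 0.4,
            OLev = 0.1, NO2Bz = 1.2, OPMB = 1.7, OTBDPS = 4.5, OTBS = 2.9,
            OTIPS = 3.4, NHAc = -0.5, NHTroc = 1.1, NPhth = 1.0, N3 = 0.5,
            Fmoc = 3.2)
  toks <- unlist(pgs[paste0("pg", c("2", "3", "4", "6"))])
  toks <- toks[!is.na(toks)]
  g <- function(tb) sum(tb[toks], na.rm = TRUE)
  acyl <- c("OAc", "OBz", "OClAc", "OLev", "NO2Bz")
  silyl <- c("OTBDPS", "OTBS", "OTIPS")
  c(md_mw = 180 + g(mass) + 124,  # core + aglycon thio-tolyl
    md_naromring = g(arom) + 1,
    md_nacyl = sum(toks %in% acyl),
    md_nether = sum(toks %in% c("OBn", "OPMB")),
    md_nsilyl = sum(toks %in% silyl),
    md_rotb = sum(toks != "OH") * 2 + 2,
    md_logp = 0.5 + g(logp))
}

# ground-truth additive effects of the generator (ln RRV scale)
.truth_tables <- function() {
  list(
    intercept = 5.1,
    type_eff = c(Gal = 0.55, Glc = 0.10, Man = -0.10, GalNAc = -0.65,
                 GlcNAc = -0.85),
    anomeric_eff = c(a = -0.20, b = 0.20),
    pg_eff = c(OH = 1.15, OBn = 0.80, OPMB = 0.65, OTBDPS = 0.15,
               OTBS = 0.10, OTIPS = 0.05, OAc = -0.70, OBz = -0.85,
               OLev = -0.60, OClAc = -0.95, NO2Bz = -1.20),
    amine_eff = c(NHAc = -0.20, NHTroc = -0.45, NPhth = -0.75, N3 = 0.15),
    md_beta = c(md_x1 = 0.60, md_x2 = -0.40)
  )
}

#' Generate a synthetic RRV training dataset with known ground truth
#'
#' Draws `n` protected monosaccharide building blocks (sugar type,
#' anomeric form, protecting-group pattern), computes surrogate shifts
#' and descriptors via [shift_profile()] / [descriptor_profile()] (plus
#' measurement noise), and sets
#' `ln(RRV) = intercept + type + anomeric + sum(pg effects) + md weights + e`,
#' `e ~ N(0, sigma)`, with free hydroxyls arming and acyl groups
#' disarming, so generated RRVs span roughly 1 to 72,000 on a log scale
#' (values are clipped to that range; clips are reported). The additive
#' ground truth is stored in the returned dataset's `truth` field for
#' parameter-recovery tests.
#'
#' @param n Number of building blocks (default 117, the size of the
#'   hexose/hexosamine training library).
#' @param seed RNG seed; identical seeds give identical datasets.
#' @param sigma Noise standard deviation on the ln scale (default 0.3).
#' @param noise_descriptors Number of pure-noise `md_noise*` columns.
#' @param structural_descriptors Include the deterministic
#'   structure-derived descriptor block (collinear with the
#'   protecting-group indicators; disable for identifiable
#'   weight-recovery studies).
#' @param latent_descriptors Include the independent latent descriptors
#'   `md_x1`, `md_x2` that carry ground-truth weight.
#' @param config [feature_config()] stored with the dataset; defaults to
#'   the normalized shift encoding, since the generating model is linear
#'   in the normalized slots (the binarized encoding exists for real
#'   data, whose shift-reactivity relation need not be linear).
#' @param type_probs Sampling weights over the five sugar types.
#' @return An [rrv_dataset()] whose `truth` element records the generating
#'   weights.
#' @export
generate_rrv_dataset <- function(n = 117, seed = 1, sigma = 0.3,
                                 noise_descriptors = 3,
                                 structural_descriptors = TRUE,
                                 latent_descriptors = TRUE,
                                 config = feature_config(cs_mode = "normalized"),
                                 type_probs = c(Gal = 0.30, Glc = 0.20,
                                                Man = 0.15, GalNAc = 0.175,
                                                GlcNAc = 0.175)) {
  stopifnot(sigma >= 0, n >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tt <- .truth_tables()
  hexv <- pg_vocab()$hex
  pg_w <- c(OH = 0.10, OAc = 0.14, OBn = 0.30, OBz = 0.14, OClAc = 0.04,
            OLev = 0.06, NO2Bz = 0.04, OPMB = 0.06, OTBDPS = 0.04,
            OTBS = 0.04, OTIPS = 0.04)
  rows <- list()
  clipped <- 0L
  for (i in seq_len(n)) {
    st <- sample(names(type_probs), 1, prob = type_probs)
    an <- sample(c("a", "b"), 1)
    cls <- sugar_class(st)
    pgs <- list(
      pg2 = if (cls == "HexNAc") sample(names(tt$amine_eff), 1)
            else sample(hexv, 1, prob = pg_w[hexv]),
      pg3 = sample(hexv, 1, prob = pg_w[hexv]),
      pg4 = sample(hexv, 1, prob = pg_w[hexv]),
      pg6 = sample(hexv, 1, prob = pg_w[hexv]))
    sh <- shift_profile(st, an, pgs) +
      stats::rnorm(13, 0, rep(c(0.08, 0.8), c(7, 6)))
    md <- numeric(0)
    if (structural_descriptors) {
      md <- descriptor_profile(st, an, pgs)
      md["md_mw"] <- md["md_mw"] + stats::rnorm(1, 0, 2)
    }
    if (latent_descriptors) {
      md <- c(md, md_x1 = stats::rnorm(1), md_x2 = stats::rnorm(1))
    }
    if (noise_descriptors > 0) {
      nz <- stats::rnorm(noise_descriptors)
      names(nz) <- paste0("md_noise", seq_len(noise_descriptors))
      md <- c(md, nz)
    }
    ln <- tt$intercept + tt$type_eff[[st]] + tt$anomeric_eff[[an]] +
      (if (cls == "HexNAc") tt$amine_eff[[pgs$pg2]] else tt$pg_eff[[pgs$pg2]]) +
      tt$pg_eff[[pgs$pg3]] + tt$pg_eff[[pgs$pg4]] + tt$pg_eff[[pgs$pg6]] +
      (if (latent_descriptors) sum(tt$md_beta * md[c("md_x1", "md_x2")]) else 0) +
      stats::rnorm(1, 0, sigma)
    lo <- log(1); hi <- log(72000)
    if (ln < lo || ln > hi) { clipped <- clipped + 1L; ln <- min(max(ln, lo), hi) }
    rows[[i]] <- data.frame(index = sprintf("S%03d", i), sugar_type = st,
                            anomeric = an, pg2 = pgs$pg2, pg3 = pgs$pg3,
                            pg4 = pgs$pg4, pg6 = pgs$pg6,
                            as.list(sh), as.list(md), rrv = exp(ln),
                            stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows)
  if (clipped) message(clipped, " RRV value(s) clipped to [1, 72000]")
  truth <- c(tt, list(sigma = sigma, seed = seed, clipped = clipped))
  ds <- rrv_dataset(config = config, data = raw)
  ds$truth <- truth
  ds
}

#' Generate a descriptor-design dataset for feature-selection studies
#'
#' A lean dataset whose design matrix is a pure molecular-descriptor
#' block: `n_informative` standard-normal columns carrying ground-truth
#' weights and `n_noise` pure-noise columns with weight zero, so wrapper
#' feature selection can be scored against a known informative set.
#' Categorical fields are held constant (single sugar type) and the
#' feature config restricts to the `md` block, keeping the wrapper's
#' CV-times-candidates loop cheap.
#'
#' @param n Rows (default 60).
#' @param seed RNG seed.
#' @param n_informative,n_noise Column counts.
#' @param sigma Noise SD on the ln(RRV) scale (0 = noiseless, exactly
#'   realizable by a linear model).
#' @return An [rrv_dataset()] whose `truth` lists `informative` and
#'   `noise` column names and the weight vector `beta`.
#' @export
generate_selection_dataset <- function(n = 60, seed = 1, n_informative = 4,
                                       n_noise = 10, sigma = 0) {
  stopifnot(n_informative >= 1, n_noise >= 0, sigma >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  inf_names <- paste0("md_inf", seq_len(n_informative))
  noise_names <- if (n_noise) paste0("md_noise", seq_len(n_noise))
                 else character(0)
  X <- matrix(stats::rnorm(n * (n_informative + n_noise)), nrow = n,
              dimnames = list(NULL, c(inf_names, noise_names)))
  beta <- stats::setNames(
    rep_len(c(1.2, -1.0, 0.8, -0.6), n_informative), inf_names)
  ln <- 5 + as.numeric(X[, inf_names, drop = FALSE] %*% beta) +
    stats::rnorm(n, 0, sigma)
  ln <- pmin(pmax(ln, log(1)), log(72000))
  raw <- data.frame(index = sprintf("F%03d", seq_len(n)),
                    sugar_type = "Gal", anomeric = "b",
                    pg2 = "OBn", pg3 = "OBn", pg4 = "OBn", pg6 = "OBn",
                    X, rrv = exp(ln), stringsAsFactors = FALSE)
  ds <- rrv_dataset(config = feature_config(blocks = "md"), data = raw)
  ds$truth <- list(informative = paste0(inf_names),
                   noise = noise_names, beta = beta, sigma = sigma,
                   seed = seed)
  ds
}

## ---- named planner scenarios ----------------------------------------------

# shorthand: residue with protections; pgs named by position
.res <- function(id, st, pid = NA, an = NA, link = NA, ...) {
  residue(id, st, pid = pid, anomeric = an, link = link,
          substituents = unlist(list(...)))
}

.mono <- function(index, st, rrv, an, ..., name = NULL,
                  source = "measured") {
  building_block(index, name %||% paste0(st, "-", index),
                 glycan_tree(list(.res(1, st, an = an, ...))),
                 rrv = rrv, rrv_source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in planner scenarios
#'
#' Named worked examples: a target glycan plus a small building-block
#' library shaped so the planner must reproduce the published RRV
#' ordering. Protecting-group layouts are constructed; what is pinned is
#' the residue composition, the linkage pattern and the quoted RRVs.
#'
#' * `"lacnac_3"`: oligo-LacNAc hexasaccharide from three LacNAc
#'   disaccharide BBLs, one-pot order (263, 51, 0).
#' * `"ssea4_213"`: SSEA-4 hexasaccharide, `[2+1+3]` one-pot with a sialyl
#'   disaccharide donor (1462), a monosaccharide (32.0) and a
#'   trisaccharide reducing-end acceptor (0).
#' * `"heparin_122"`: pentasaccharide, `[1+2+2]` one-pot (132, 18.2, 0).
#' * `"globoH_132"`: Globo-H hexasaccharide, `[1+3+2]` fragment strategy:
#'   fucose BBL (72,000), a trisaccharide fragment built one-pot from
#'   RRVs (4000, 850, 13) with a Lev-masked attachment position
#'   deprotected afterwards (effective RRV 13), and a disaccharide
#'   reducing-end acceptor (0).
#'
#' @param name Scenario name.
#' @return List with `name`, `target` ([glycan_tree()]), `library`
#'   ([bbl_library()]) and `expected` (quoted RRV order and strategy
#'   sizes).
#' @export
fixture_scenario <- function(name) {
  scenarios <- c("lacnac_3", "ssea4_213", "heparin_122", "globoH_132")
  if (!name %in% scenarios) {
    stop("unknown scenario '", name, "'; available: ",
         paste(scenarios, collapse = ", "))
  }
  switch(name,
    lacnac_3 = .scenario_lacnac(),
    ssea4_213 = .scenario_ssea4(),
    heparin_122 = .scenario_heparin(),
    globoH_132 = .scenario_globoh())
}

.scenario_lacnac <- function() {
  # Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc
  target <- parse_glycan("Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc")
  lacnac <- function(index, rrv, gal3, root = FALSE) {
    gal <- .res(1, "Gal", pid = 2, an = "b", link = 4,
                "2" = "OBn", "3" = gal3, "4" = "OBz", "6" = "OBn")
    glcnac <- .res(2, "GlcNAc", an = if (root) "b" else "b",
                   "2" = "NHTroc", "3" = "OBn", "6" = "OBz")
    building_block(index, paste0("LacNAc-", index),
                   glycan_tree(list(gal, glcnac)), rrv = rrv)
  }
  library <- bbl_library(list(
    lacnac("9", 263, gal3 = "OBn"),
    lacnac("10", 51, gal3 = "OH"),
    lacnac("11", 0, gal3 = "OH", root = TRUE)))
  list(name = "lacnac_3", target = target, library = library,
       expected = list(rrvs = c(263, 51, 0), sizes = c(2L, 2L, 2L)))
}

.scenario_ssea4 <- function() {
  # Neu5Ac(a2-3)Gal(b1-3)GalNAc(b1-3)Gal(a1-4)Gal(b1-4)Glc
  target <- parse_glycan("Neu5Ac(a2-3)Gal(b1-3)GalNAc(b1-3)Gal(a1-4)Gal(b1-4)Glc")
  sialyl <- building_block("1", "sialyl-lactosamine donor", glycan_tree(list(
    .res(1, "Neu5Ac", pid = 2, an = "a", link = 3),
    .res(2, "Gal", an = "b", "2" = "OBz", "4" = "OBn", "6" = "OBn"))),
    rrv = 1462)
  galnac <- .mono("2", "GalNAc", 32.0, an = "b",
                  "2" = "NHTroc", "3" = "OH", "4" = "OBn", "6" = "OBn")
  acceptor <- building_block("3", "lactose acceptor", glycan_tree(list(
    .res(1, "Gal", pid = 2, an = "a", link = 4,
         "2" = "OBn", "3" = "OH", "4" = "OBn", "6" = "OBn"),
    .res(2, "Gal", pid = 3, an = "b", link = 4,
         "2" = "OBz", "3" = "OBn", "6" = "OBn"),
    .res(3, "Glc", an = "b", "2" = "OBz", "3" = "OBn", "6" = "OBn"))),
    rrv = 0)
  list(name = "ssea4_213", target = target,
       library = bbl_library(list(sialyl, galnac, acceptor)),
       expected = list(rrvs = c(1462, 32.0, 0), sizes = c(2L, 1L, 3L)))
}

.scenario_heparin <- function() {
  # GlcNAc(a1-4)Glc(b1-4)GlcNAc(a1-4)Glc(b1-4)GlcNAc
  target <- parse_glycan("GlcNAc(a1-4)Glc(b1-4)GlcNAc(a1-4)Glc(b1-4)GlcNAc")
  mono5 <- .mono("5", "GlcNAc", 132, an = "a",
                 "2" = "N3", "3" = "OBn", "4" = "OBn", "6" = "OAc")
  di6 <- building_block("6", "disaccharide donor", glycan_tree(list(
    .res(1, "Glc", pid = 2, an = "b", link = 4,
         "2" = "OBz", "3" = "OBn", "4" = "OH", "6" = "OBn"),
    .res(2, "GlcNAc", an = "a", "2" = "N3", "3" = "OBn", "6" = "OAc"))),
    rrv = 18.2)
  di7 <- building_block("7", "reducing-end disaccharide", glycan_tree(list(
    .res(1, "Glc", pid = 2, an = "b", link = 4,
         "2" = "OBz", "3" = "OBn", "4" = "OH", "6" = "OBn"),
    .res(2, "GlcNAc", an = "b", "2" = "N3", "3" = "OBn", "6" = "OAc"))),
    rrv = 0)
  list(name = "heparin_122", target = target,
       library = bbl_library(list(mono5, di6, di7)),
       expected = list(rrvs = c(132, 18.2, 0), sizes = c(1L, 2L, 2L)))
}

.scenario_globoh <- function() {
  # Fuc(a1-2)Gal(b1-3)GalNAc(b1-3)Gal(a1-4)Gal(b1-4)Glc
  target <- parse_glycan("Fuc(a1-2)Gal(b1-3)GalNAc(b1-3)Gal(a1-4)Gal(b1-4)Glc")
  fuc <- .mono("F1", "Fuc", 72000, an = "a",
               "2" = "OBn", "3" = "OBn", "4" = "OBn")
  gal_lev <- .mono("G1", "Gal", 4000, an = "b",
                   "2" = "OLev", "3" = "OBn", "4" = "OBn", "6" = "OBn")
  galnac <- .mono("N1", "GalNAc", 850, an = "b",
                  "2" = "NHTroc", "3" = "OH", "4" = "OBn", "6" = "OBn")
  gal_acc <- .mono("G2", "Gal", 13, an = "a",
                   "2" = "OBz", "3" = "OH", "4" = "OBn", "6" = "OBn")
  lactose <- building_block("A1", "lactose reducing-end acceptor",
    glycan_tree(list(
      .res(1, "Gal", pid = 2, an = "b", link = 4,
           "2" = "OBn", "3" = "OBn", "4" = "OH", "6" = "OBn"),
      .res(2, "Glc", an = "b", "2" = "OBz", "3" = "OBn", "6" = "OBn"))),
    rrv = 0)
  list(name = "globoH_132", target = target,
       library = bbl_library(list(fuc, gal_lev, galnac, gal_acc, lactose)),
       expected = list(
         fragment_sizes = c(1L, 3L, 2L),
         fragment2_rrvs = c(4000, 850, 13),
         top_rrvs = c(72000, 13, 0)))
}
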