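---
title: "Planning programmable one-pot oligosaccharide syntheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning programmable one-pot oligosaccharide syntheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoplan)
```

# The problem

Programmable one-pot glycosylation builds an oligosaccharide by adding
protected thioglycoside building blocks (BBLs) sequentially to one
vessel, most reactive first. The reactivity of each donor is summarized
by its relative reactivity value (RRV), measured against a reference
donor and tuned over orders of magnitude (roughly 1 to 72,000 in
practice) by the protecting-group pattern: electron-donating ethers
(Bn, PMB) arm a donor, electron-withdrawing acyl groups (Bz, Ac, ClAc,
NO2Bz) disarm it. A route is chemically sensible only if the RRVs
strictly descend from the first donor to the final reducing-end
acceptor (RRV = 0): at every addition the incoming donor must be
activated preferentially over the growing chain, which is itself still
a thioglycoside. `glycoplan` searches a BBL library for such routes,
decomposes large targets into fragments, and predicts RRVs for
enumerated "virtual" BBLs that have not been measured.

# Data model

A glycan is a rooted tree whose root is the reducing-end residue; an
edge `X(b1-4)Y` makes `X` (the donor side) a child of `Y` attached at
ring position 4 with beta anomeric configuration. Positions are
1-based ring positions; the anomeric carbon (1, or 2 for sialic acid)
carries the leaving group or aglycon and is never a substituent slot.
Supported sugar types are Gal, Glc, Man, Fuc (hexoses; Fuc is 6-deoxy
so position 6 does not exist), GalNAc, GlcNAc (position 2 carries the
amine substituent and is never glycosylated), and Neu5Ac. Sialic acid
is only admitted as the terminal unit of a sialyl di-/trisaccharide
BBL: it is too unreactive and hindered to serve as a first donor, so
its RRV is carried by the reducing-end sugar of the disaccharide.

Child order (by attachment position, then id) and all search
tie-breaks are deterministic, so identical inputs always produce
byte-identical plans.

# Matching rules

For a connected *state* of the query with the same residue count as a
BBL, the BBL matches only if sugar types, anomeric forms and internal
linkages agree exactly. Then, position by position:

* a position where the query attaches a sub-structure below the state
  (a *child link*) must carry either a free hydroxyl (**perfect**
  match) or a selectively-removable protecting group (**precursor**
  match), the latter recorded as a pending deprotection;
* every other position must be protected — a stray free hydroxyl would
  compete in later couplings, so a BBL matching a leaf state must be
  fully protected;
* a masked token must be *unique* among the BBL's child-link positions,
  otherwise the selective deprotection would be ambiguous. The same
  token at a non-child-link position is harmless and does not break
  uniqueness.

The default selectively-removable set is `r paste(removable_pgs(),
collapse = ", ")`; it is an argument, not a constant, because
orthogonality depends on the rest of the protection scheme.

# One-pot search

`search_no_fragments()` performs the depth-first in-order search: each
residue accumulates a candidate list, and moving to a parent combines
the parent-state candidates with the child-subtree candidate sets by
cartesian product, pruning on strict RRV descent along every edge, a
global strict order (ties give no chemoselectivity), an RRV-0 match for
the root state, and the step budget. `max_bbls` defaults to 4 and the
function warns beyond it, because with more steps the activator
(N-iodosuccinimide in practice) increasingly drives side reactions.
Precursor matches are excluded in this mode — no mid-pot deprotections.

## Yield model

The published record of this method does not include its yield
formula, so ranking uses an explicit model of our own and labels every
yield as model-dependent. The default treats each addition as competing
second-order activation: donor D1 and the growing acceptor D2 compete
for one equivalent of activator with rate ratio
`r = RRV(D1)/RRV(D2)`. Integrating `dD1/dD2 = r·D1/D2` from equimolar
loading until one equivalent is consumed gives `D2^r + D2 = 1`, and the
donor conversion — taken as the coupling yield — is the root of
`x^r + x = 1` (solved by `uniroot` to 1e-12; closed form `(√5−1)/2` at
r = 2; exactly 1 when the acceptor has RRV 0, since nothing competes).
The overall yield is the product over consecutive couplings. The model
is monotone in the RRV ratio and approaches 1 as the ratio grows, which
is the property the ranking actually uses; absolute values should not
be read as experimental predictions. Unit tests pin the closed form
against an independent numerical integration of the competing-rate
ODEs. The model is pluggable (`yield_model` argument), so a calibrated
lookup can replace it.

# Fragment planning

`fragment_search()` partitions the target into connected fragments of
1-3 BBLs each (more steps per pot degrade yield), plans each fragment
internally with precursor matches allowed, and schedules assembly.
Positions where a *child fragment* attaches must survive the owning
fragment's synthesis: on a multi-BBL fragment they must be masked by a
unique removable group and are listed as post-synthesis deprotections;
a single-BBL fragment may expose them as free hydroxyls, since it
undergoes no prior couplings. An RRV-0 BBL is a reducing-end acceptor
with no leaving group, so it may only terminate the fragment containing
the glycan root. The deprotected fragment re-enters planning as a BBL
whose *effective RRV* defaults to that of its reducing-end BBL — the
position where measured values exist suggests this is how such
fragments behave — and can be overridden by a measurement or a model
prediction (`effective_rrv_of_fragment()`).

Assembly follows the post-order traversal of the fragment tree. When at
most four fragments lie on the major chain (the longest leaf-to-root
path) and their effective RRVs admit a strictly descending order ending
at 0, the fragments themselves assemble one-pot with ordinal role
classes large / medium / small / zero along the chain; the
corresponding RRV bins (> 15,000; 1,000-15,000; 0-1,000; 0) are
reported alongside. With more than four chain fragments the strategy is
hybrid (one-pot plus distinct leaving groups); otherwise fragments are
connected stepwise, each activated selectively via its leaving group —
those couplings are treated as non-competitive (factor 1) in the yield
product, because orthogonal activation removes the RRV competition.
To bound the combinatorics, at most 3 fragments are explored along any
root-to-leaf path by default (`max_path_fragments`).

# RRV prediction

`rrv_fit()` fits an epsilon-SVR on `ln(RRV)`: RRVs are roughly
log-normal, and the additive chemistry (each protecting group arming or
disarming multiplicatively) lives naturally on the log scale. Features
come in three blocks: one-hot basic properties (sugar type, sugar
class, anomeric state, protecting group per position), the 13 ring
chemical shifts (H1-H6-2, C1-C6, ppm, ingested from a table — the
package never computes NMR shifts), and molecular descriptor columns
(1D/2D, ingested or surrogate). Shifts are min-max normalized per slot
and/or binarized into fixed-width bins (0.2 ppm for ¹H, 2.0 ppm for
¹³C — the bin widths are a package choice, as no canonical widths are
published); a constant slot normalizes to 0 and yields a single
always-on bin; missing slots (e.g. H6 of a 6-deoxy sugar) are imputed
with the training mean and flagged by an indicator column. All encoder
statistics are fitted on training rows only and stored with the model,
and cross-validation refits them inside every fold — a test asserts
that the fold encoder genuinely differs from the full-data encoder, so
the non-leaky path cannot silently regress.

Defaults are a linear kernel with C = 1 and epsilon = 0.001. No
canonical hyperparameters are published for this problem; we verified
against an ordinary-least-squares oracle on synthetic data that C = 1
tracks the attainable ln-scale accuracy closely, while larger C
overfits the high-dimensional binarized encoding. All three of kernel,
C and epsilon are exposed.

`cv_evaluate()` reports PCC, MAE and RAE
(`Σ|ŷ−y| / Σ|ȳ−y|`; exactly 1 for the mean predictor) on both the
back-transformed RRV scale and the ln scale. The two PCCs answer
different questions: raw-scale Pearson is dominated by the handful of
largest RRVs and fluctuates strongly between datasets even for the
generating model itself, while ln-scale PCC is the stable measure of
fit quality on the modelling scale. Quality bands in our tests are
therefore asserted on the ln-scale PCC and the RRV-scale RAE.
Classification accuracy over the planning bins (> 15,000;
1,000-15,000; 0-1,000) is reported because the one-pot order only needs
the right bin, not the exact value.

`select_features_backward()` implements the wrapper: starting from the
full encoded set, repeatedly drop the single feature whose removal
raises the stratified 5-fold CV PCC most (or lowers it least),
evaluated on the regression target (ln scale) with per-fold encoder
refits. Ties among candidate drops remove the lexicographically last
name. The path is walked down to one feature and the smallest set
within `tol = 1e-4` of the maximal CV PCC is returned — near-perfect
fits make smaller PCC differences pure numerical jitter, and an exact
argmax would keep redundant features. A `keep` argument pins features
that must survive regardless (e.g. to retain complete sugar-type
information).

# Virtual building blocks

`enumerate_hex()` and `enumerate_hexnac()` materialize every
protecting-group combination: 3 hexose types × 11 tokens at each of
R2, R3, R4, R6 (43,923), and 2 HexNAc types × 3 amine groups × 11³
(7,986) — 51,909 structures, all thio-tolyl glycosides, in
deterministic order. Non-stereo SMILES strings are assembled from a
pyranose template with per-token fragments. Predicted RRVs are
attached by `predict_virtual()` through a *feature provider*; the
shipped provider is the deterministic structural surrogate
(`shift_profile()` / `descriptor_profile()` — additive
group-contribution tables, clearly a surrogate, not an NMR or
descriptor calculation), and a table of externally computed features
can be supplied instead.

`tanimoto_screen()` computes, for each virtual BBL, the maximum
Tanimoto similarity (`|A∩B| / |A∪B|`) to the training library and the
coverage fraction at each threshold (0.75 / 0.80 / 0.85 by default).
Coverage fractions depend entirely on the fingerprint; the default is a
structural token fingerprint (sugar type/class, anomeric form,
position:substituent tokens, adjacent-position paths, internal
linkages), the backend is a plain function argument, and the backend
used is recorded in the output. Published coverage numbers obtained
with other fingerprints on other libraries are not comparable across
backends and are not reproduced here.

# Synthetic data: what it does and does not show

`generate_rrv_dataset()` draws protected monosaccharides (five sugar
types, realistic protecting-group frequencies), builds their shifts and
descriptors from the group-contribution surrogate plus measurement
noise, and sets `ln(RRV)` to an additive ground truth — intercept,
sugar-type and anomeric effects, one effect per protecting-group token
(free OH arming ~+1.15, NO2Bz disarming ~−1.20 on the ln scale), and
weights on two latent descriptors — plus Gaussian noise `σ` (default
0.3), clipped to RRV ∈ [1, 72,000] with clips reported. The default
n = 117 mirrors the size of the real hexose/hexosamine training
library. The stored truth enables parameter-recovery tests: with the
identifiable configuration (basic properties + latent descriptors;
the shift block and the structure-derived descriptor counts are
deliberately excluded there because they are constructed to be
collinear with the protecting-group indicators, which makes individual
weights unidentifiable without changing predictions), the fitted
coefficient direction matches the truth with cosine ≥ 0.95 at σ = 0.1
across ten seeds. `generate_selection_dataset()` provides the lean
descriptor-only design (default 4 informative + 10 pure-noise columns,
n = 60) used to score feature selection against known labels.

What passing these tests shows: the search, matching, scheduling,
encoding, CV protocol, selection and screening machinery are correct
under a known data-generating process. What they do not show: that a
linear SVR on these feature blocks predicts *real* RRVs at any
particular accuracy — real shift-reactivity relations are not additive
group contributions, real descriptor blocks are far wider, and real
libraries are not drawn i.i.d. from a token frequency table. The
planner scenarios pin residue composition, linkage pattern and the
published RRVs; their protecting-group layouts are constructed so the
intended route is admissible (the heparin-like scenario additionally
substitutes GlcNAc/Glc for the amino/uronic sugars, which are outside
the supported vocabulary).

# Problem sizes in the test suite

The suite checks the planner against a brute-force tiling oracle on
520 random instances (trees ≤ 6 residues, libraries ≤ 25 BBLs), the
kinetic yield model against an independent ODE integration, LOOCV at
the full n = 117 study size, and feature selection across ten generator
seeds; these sizes were chosen to exercise every code path while
keeping the default suite around a minute.

# Known limitations

* No stereochemical outcome prediction, no solvent/temperature/promoter
  modelling, and no feasibility judgment beyond RRV ordering — steric
  effects that defeat in-silico ranking are expected and documented for
  this class of methods.
* Yields are ranking scores from an explicit kinetic idealization.
* Virtual-BBL features come from a labelled surrogate unless the user
  supplies computed shift/descriptor tables.
* Protecting-group positions outside {2,3,4,6} (e.g. sialic acid 8/9)
  are not modelled; SA units are matched only as terminal disaccharide
  units.
* The fragment enumeration cap (3 fragments per root-to-leaf path) can
  in principle hide deeper decompositions of very large targets; raise
  `max_path_fragments` to explore them.
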