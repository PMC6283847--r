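# glycoplan

Route planning for the **programmable one-pot synthesis of
oligosaccharides**, with machine-learned reactivity prediction for
virtual building blocks.

In programmable one-pot glycosylation, protected thioglycoside building
blocks (BBLs) are added sequentially to a single vessel, most reactive
first. Each BBL's reactivity is summarized by its **relative reactivity
value (RRV)**, a dimensionless number measured against a reference
donor; a workable route requires strictly descending RRVs from the
non-reducing end to the reducing-end acceptor (RRV = 0). Choosing a
compatible set of BBLs from a library — and, for larger targets,
splitting the glycan into fragments that are each made one-pot, then
deprotected and reassembled — is a combinatorial search problem.
`glycoplan` is a desk tool for synthetic carbohydrate chemists that:

* models glycans as rooted residue trees (reducing end = root) with an
  IUPAC-condensed text parser and a JSON record format;
* decides whether a BBL **perfectly matches** a query state (free
  hydroxyl at every branching position, fully protected elsewhere) or
  **precursor matches** it (a branching position masked by a unique,
  selectively removable protecting group such as Lev);
* searches the library depth-first for one-pot plans
  (`search_no_fragments()`), ranked by an explicit, pluggable coupling
  yield model — the default treats each coupling as competing
  second-order activation, giving a per-coupling yield equal to the
  root of `x^r + x = 1` with `r = RRV_donor / RRV_acceptor`;
* plans hierarchically (`fragment_search()`): fragments of 1-3 BBLs,
  post-synthesis deprotection of masked attachment points, and a
  post-order assembly schedule whose fragments are classed
  large / medium / small / zero along the major chain;
* fits an epsilon-SVR on `ln(RRV)` from structural features — one-hot
  basic properties, the 13 ring NMR shifts (`H1..H6-2`, `C1..C6`),
  molecular descriptors — with leakage-free cross-validation
  (`rrv_fit()`, `cv_evaluate()`) and backward greedy wrapper feature
  selection (`select_features_backward()`);
* enumerates the full virtual BBL library (3 × 11⁴ = 43,923 hexose and
  2 × 3 × 11³ = 7,986 HexNAc structures, 51,909 in total), attaches
  predicted RRVs, and screens them against a training library by
  Tanimoto fingerprint similarity (`tanimoto_screen()`);
* ships synthetic generators with known ground truth
  (`generate_rrv_dataset()`, `fixture_scenario()`) so every component
  is testable offline.

## Worked example

The built-in `globoH_132` scenario is a hexasaccharide whose library
only admits a hierarchical route — one branch position is masked by a
levulinoyl group, so no single one-pot plan exists and the planner
returns a [1 + 3 + 2] fragment strategy:

```r
library(glycoplan)
sc <- fixture_scenario("globoH_132")
sc$target
#> <glycan_tree> 6 residue(s), root = Glc (id 6)
#>   Fuc(a1-2)Gal(b1-3)GalNAc(b1-3)Gal(a1-4)Gal(b1-4)Glc
plans <- fragment_search(sc$target, sc$library)
plans[[1]]
#> <fragment_plan> 3 fragment(s), strategy onepot_fragments, overall yield 71.2%
#>   fragment 1 [1 residue(s), 1 BBL(s)] eff RRV 7.2e+04  class large
#>     RRV    7.2e+04  BBL F1
#>   fragment 2 [3 residue(s), 3 BBL(s)] eff RRV 13  class medium
#>     RRV       4000  BBL G1
#>     RRV        850  BBL N1
#>     RRV         13  BBL G2
#>     deprotect after synthesis:  OLev@2
#>   fragment 3 [2 residue(s), 1 BBL(s)] eff RRV 0  class zero
#>     RRV          0  BBL A1
```

Fragment 2 is itself a one-pot sequence (RRVs 4000 → 850 → 13); after
its synthesis the Lev group at position 2 is removed, the fragment is
reused as a building block with effective RRV 13 (that of its
reducing-end BBL), and the three fragments assemble one-pot in the
order 72,000 → 13 → 0. The overall yield (71.2% here) is a product of
per-coupling yields under the default kinetic model and should be read
as a ranking score, not an experimental prediction.

Training and evaluating the RRV predictor on a synthetic library of 117
building blocks (the size of the real hexose/hexosamine training set):

```r
ds <- generate_rrv_dataset(n = 117, seed = 1, sigma = 0.3)
fit <- rrv_fit(ds)
fit
#> <rrv_fit> eps-SVR (linear kernel, C = 1, eps = 0.001) on ln(RRV)
#>   n = 117 training BBLs, 82 features
#>   training PCC (ln scale): 0.9907
cv_evaluate(ds, "loocv")
#> <rrv_eval> LOOCV: n = 117, features = 82
#>   RRV scale:  PCC 0.8787  MAE 326.15  RAE 0.2511
#>   ln scale:   PCC 0.9645  MAE 0.3977  RAE 0.2785
#>   category accuracy 0.949 (per-category PCC: low 0.77, medium 0.94, high NA)
```

The PCC/MAE/RAE columns mirror the standard report layout for RRV
predictors; the three-bin category accuracy refers to the planning bins
high (> 15,000), medium (1,000-15,000] and low [0-1,000].

## Command line

A thin wrapper over the package functions:

```sh
GP=$(Rscript -e 'cat(system.file("cli/glycoplan.R", package = "glycoplan"))')
Rscript $GP fixtures --scenario lacnac_3 --out fixtures/
Rscript $GP plan --target fixtures/target.glycan --library fixtures/library.csv --out plans.json
Rscript $GP enumerate --class hex --out hex.csv       # 43,923 rows
```

Subcommands: `plan`, `fixtures`, `enumerate`, `train`, `evaluate`,
`select-features`, `predict`. Every run writes a provenance JSON and is
byte-reproducible under a fixed seed; all computation is local.

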