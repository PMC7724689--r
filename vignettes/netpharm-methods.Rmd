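---
title: "Methods: network-pharmacology screening at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology screening at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The problem

Multi-herb traditional-medicine formulas act through many compounds hitting
many protein targets at once. Network pharmacology makes that tractable by
chaining four standard steps: (1) screen each herb's catalogued compounds by
pharmacokinetic (ADME) criteria to a candidate set; (2) collect and
normalize the candidates' predicted protein targets; (3) intersect them with
independently curated disease targets and study the overlap as a scored
protein–protein interaction (PPI) network; (4) test the overlap for
over-represented annotation terms and pathways. In published studies every
step leans on a live web database (compound catalogues, identifier mappers,
disease-gene resources, interaction and annotation servers), which makes the
analyses impossible to re-run or test offline. netpharm re-implements the
pipeline over local tables and pairs it with a synthetic-data generator that
plants known ground truth, so each stage is verifiable at desk scale.

# Stage models and parameters

## Pharmacokinetic screening (`passes_filter`, `select_candidates`)

Two screening rules coexist because herb catalogues differ:

* TCMSP-style rows carry oral bioavailability OB (percent of an oral dose
  reaching circulation), Caco-2 permeability (in-vitro absorption
  surrogate, unitless) and drug-likeness DL (similarity to known drugs, in
  [0,1]). Defaults: OB ≥ 30, Caco-2 ≥ 0.4, DL ≥ 0.18, all inclusive.
* BATMAN-style rows carry a target-prediction score and an adjusted
  P-value. Defaults: score ≥ 20 (inclusive) and adjusted P < 0.05
  (strict).

Inclusivity follows how the operators are conventionally written: "≥"
thresholds are closed, "<" is open. A row missing a field its rule needs is
an error, never a silent pass or fail. Candidates are deduplicated across
herbs by a case-folded, whitespace-stripped name key with provenance
merged; Greek letters are preserved, so a sterol and its β-prefixed isomer
remain distinct candidates even when a catalogue assigns them one compound
ID (the packaged ten-row example table shows exactly this collision: 9
unique names, 8 unique IDs).

## Formula masses (`parse_formula`, `molecular_mass`)

Formulas are parsed from Hill-style strings, accepting the underscore
subscript markup some exports use (`C_29_H_50_O`). The embedded weight
table fixes IUPAC 2005-era standard atomic weights for average masses and
principal-isotope masses for monoisotopic mode, because that pairing
reproduces the package's worked-example masses to 3 decimals. Both modes
are exposed and no auto-detection is attempted: reference tables in this
field mix conventions silently (the worked example's mineral rows are
average masses while its sterol rows are monoisotopic). Display rounding is
half-up to 3 decimals; full precision is kept internally, and mass is
exactly additive over formula concatenation in both modes. One caveat the
tests respect: monoisotopic ≤ average holds for the organic elements but
*not* for iron, whose principal isotope (⁵⁶Fe, 55.9349 Da) outweighs the
abundance-weighted standard weight (55.845 Da).

## Target sets (`normalize_genes`, `union_targets`, `venn`)

Raw target names are mapped to official symbols through a caller-supplied
two-column table (the published workflow delegates this to a protein
knowledgebase; here it is an explicit input). Unmapped names are excluded
from downstream sets and reported separately — silence would bias the
union. Symbols are upper-cased exact strings; no alias resolution is
attempted beyond the supplied table. Unions keep first-seen order and merge
provenance. The Venn summary reports `pct_of_b = 100·|A∩B|/|B|` rounded
half-up to 2 decimals (so an intersection of 29 against 321 disease targets
prints 9.03). An empty disease set is an error because the percentage is
undefined.

## PPI network (`build_graph`, `topology`, `network_summary`)

The graph is undirected and unweighted for every metric; the combined score
in [0,1] is used only as a confidence cut (default 0.4, the usual "medium
confidence"). Duplicate edges keep the maximum score; self-loops are
dropped; universe nodes without surviving edges are kept unless
`drop_isolated`. Metrics per node: degree; unnormalized shortest-path
betweenness (equal splitting among equal-length geodesics; a normalized
column is also emitted since conventions differ); Wasserman–Faust
component-scaled closeness `(r/(n−1))·(r/Σd)` with `r` the number of other
reachable nodes, which is 0 exactly for isolated nodes and robust on
disconnected graphs; and the k-core index. The summary reports
`avg_degree = 2E/N`, the mean geodesic over *connected* unordered pairs
(with the excluded-pair count logged — on a possibly disconnected graph the
unrestricted mean is undefined), and mean local clustering with 0 assigned
to degree-<2 nodes. Published network summary triplets from web platforms
are not reproduction targets: they depend on the platform's snapshot and on
undocumented conventions (one published triplet is internally inconsistent
with its own node/edge counts), so correctness is established against
brute-force oracles instead.

## Over-representation (`hypergeom_p`, `bh_fdr`, `enrich`)

For a query of `n` genes inside an annotation universe of `N`, a term of
size `K` overlapping the query in `k` genes gets the upper hypergeometric
tail `P[X ≥ k]`, summed in log space. The background universe is the
annotation table's own gene universe, not a whole genome — web platforms
make this choice silently; here it is explicit, and query genes outside the
universe are excluded from `n` and reported. Terms with `k = 0` are not
tested and do not count in the Benjamini–Hochberg family (matching
platform outputs that list only overlapping terms); a `test_all` flag
restores the all-terms family since that changes the FDR. BH runs within
each namespace (cellular component, molecular function, biological
process, pathways) separately, mirroring the per-category files platforms
export. BH is not idempotent — its only fixed points are constant vectors —
so the tested contract is `bh(p) ≥ p`, monotonicity, permutation
equivariance and agreement with a reference implementation.

# What the synthetic generator emulates

Each generator allocates planted memberships *first* and randomizes
identities and field values *second*, so planted counts are recovered
exactly by the corresponding stage, not approximately:

* `gen_ingredients` — per-herb tables whose defaults mirror the worked
  study shape (47 + 17 + 10 rows; 3 + 2 + 5 planted passers with one
  compound shared between two herbs, so screening plus dedup yields 9).
  Field values are uniform: OB ~ U(0,100), Caco-2 ~ U(−1,2), DL ~ U(0,1),
  score ~ U(0,60), adjusted P ~ U(0,0.2); passers are re-drawn inside the
  passing region and every non-passer is forced to fail one random
  criterion.
* `gen_target_maps` — per-herb target sets of exact sizes (default
  58/46/27) with an exact union (default 71): each union gene gets one
  owning herb under quota, then herbs top up to size.
* `gen_disease_lists` — two sources of exact sizes (245/93) and exact
  pairwise overlap (17 → union 321), with an exact planted overlap against
  the drug-target set (29, hence 9.03%); non-overlap disease genes are
  fresh symbols disjoint from the drug set by construction.
* `gen_ppi` — G(n,m) with exactly `m` distinct non-self edges, scores
  U(0.15, 0.999); `planted_module` wires a clique whose edges score above
  the confidence cut so the module survives thresholding (coreness of a
  planted 5-clique is provably ≥ 4).
* `gen_annotations` — decoy terms sample uniformly; planted terms
  oversample query genes with weight `enrichment_factor` (factor 1 is the
  null table). Expected overlap `K·fq/(fq + N − q)` is recorded as truth.

What the generator does **not** emulate: real catalogues' correlated ADME
fields, scale-free PPI degree distributions, the GO DAG (terms are flat
sets), and realistic term-size or score distributions beyond the stated
uniforms. A green end-to-end test therefore establishes that the machinery
recovers planted structure exactly — it does not validate any biological
claim about a real formula or disease.

# Numerical and design choices

* Rounding is half-up (0.0005 → 0.001) wherever a displayed value is
  asserted; base R's round-half-even would flip boundary digits.
* Deterministic tie-breaks everywhere a ranking is exported: hubs by
  degree desc, betweenness desc, symbol asc; enrichment rows by FDR asc,
  overlap desc, term asc. Reruns of the pipeline on identical inputs are
  byte-identical (seeds are parameters; generators restore the caller's
  RNG state).
* The flat run config is JSON rather than YAML — same keys, flat shape —
  because the frozen dependency set has a JSON parser but no YAML parser.
* Degenerate inputs fail loudly with the stage name attached
  (`[stage venn] ...`), since a count-shaped pipeline that silently
  propagates empties produces plausible-looking nonsense.
* In a single synthetic bundle the planted enriched term's size is drawn
  from the term-size range, so a small draw (K ≈ 5) may legitimately miss
  rank 1; recovery is therefore asserted as a replicated property (factor
  8, 200 seeds, ≥ 95% rank-1) rather than per bundle.

# Known limitations

* No structure handling (SMILES/InChI), no GO DAG propagation, no alias
  resolution beyond the supplied mapping, no live database access by
  design.
* Closeness and betweenness conventions differ across tools; the emitted
  normalized betweenness column and the documented closeness formula are
  the interoperability surface.
* The percentage and mass roundings are reporting conventions; downstream
  numeric work should use the full-precision values the objects carry.
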