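---
title: "Degree-based topological indices and QSPR screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and QSPR screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoqspr)
```

## The model

A hydrogen-suppressed molecular graph \(G = (V, E)\) keeps one vertex per
heavy atom and one edge per bond, with no bond orders: single, double,
triple and aromatic bonds all contribute exactly one edge, and the degree
\(d_u\) of an atom is its number of distinct heavy-atom neighbours. Every
index in this package is *edge-additive*: a sum over the edges of a
symmetric function of the two endpoint degrees,

\[ TI(G) \;=\; \sum_{uv \in E(G)} F(d_u, d_v). \]

The nine instances of \(F\) are

| id  | name                     | per-edge weight \(F(a,b)\) |
|-----|--------------------------|-----------------------------|
| M1  | first Zagreb             | \(a+b\)                     |
| M2  | second Zagreb            | \(ab\)                      |
| mM2 | modified second Zagreb   | \(1/(ab)\)                  |
| H   | harmonic                 | \(2/(a+b)\)                 |
| F   | forgotten                | \(a^2+b^2\)                 |
| HM  | hyper-Zagreb             | \((a+b)^2\)                 |
| SD  | symmetric division       | \(a/b + b/a\)               |
| FRR | first revised Randić     | see below                   |
| SRR | second revised Randić    | \((d_h - d_l + 1)/\sqrt{d_h d_l}\) |

where \(d_h \ge d_l\) are the higher and lower endpoint degrees. When the
degrees are equal the SRR contribution reduces to \(1/d\) per edge, which
follows directly from the formula and is made explicit here because it is
easy to get wrong by treating the "higher" and "lower" vertex as distinct.

Because each weight depends only on the unordered degree pair, indices are
computable from the **edge partition**: the multiset of edges grouped by
canonical degree pair \((\text{low}, \text{high})\) with a count per class.
`edge_partition()` derives it from a graph; `as_edge_partition()` accepts a
partition entered directly from a printed table. `index_from_partition()`
(count-weighted sum) is the production path; `index_brute_force()` (plain
sum over edges) is retained as an independent route so the two can
cross-check each other in the test suite. M1, M2, F and HM are
integer-valued on every graph, and the identity \(HM = F + 2\,M2\) holds
edge by edge — both facts are used as validity oracles throughout.

## The two FRR variants

The first revised Randić index is defined as
\(\sum 1/(ab + a + b)\) (`frr_variant = "as_stated"`). That definition,
however, cannot reproduce the reference values shipped with the benchmark
drug set: for naphazoline it gives 1.861 against a tabulated 4.074. The
tabulated column is reconciled to within about 0.3 % relative by

\[ \mathrm{FRR}_{tab}(G) = \sum_{uv \in E} \frac{1}{\sqrt{2\,(d_u d_v + d_u + d_v)}} \]

(`frr_variant = "as_tabulated"`), with the residual scatter consistent with
per-class terms having been rounded to three decimals before summation in
the source calculations. Both variants are exposed; neither is silently
preferred: computation defaults to the definition as stated, validation
against the reference table defaults to the tabulated variant, and every
report records which variant produced it.

## The benchmark drug set

`load_eye_drugs()` returns twenty drugs used against ocular infections.
Each record carries a curated free-base SMILES, six measured
physicochemical properties — molecular weight (MW, g/mol), boiling point
(BP, °C), enthalpy of vaporization (EV, kJ/mol), flash point (FP, °C),
molar refraction (MR) and molar volume (MV) — and the published reference
values of the nine indices. Measurements quoted as value ± tolerance keep
the central value for regression (the uncertainty is carried alongside,
never propagated). The source table labels MR and MV "cubic meters per
mole"; the values are on the conventional cm³/mol scale and the manifest
preserves the label while flagging it.

SMILES curation was gated on the integer-valued indices: a structure is
accepted when its computed M1, M2, F and HM reproduce the printed reference
integers, since those leave no rounding ambiguity. Seventeen of the twenty
standard free-base structures pass that gate directly. The remaining rows
exposed errata in the reference table itself, which exhaustive enumeration
of all edge partitions with maximum degree 4 can prove rather than guess:

* **Tetrahydrozoline** — the printed HM (521) violates \(HM = F + 2\,M2\)
  (F 196 and M2 95 force 386); the printed FRR/SRR are likewise
  irreconcilable. Cells flagged suspect.
* **Ciprofloxacin** — no graph with maximum degree 4 matches more than five
  of the row's nine cells, so the row is internally inconsistent. The
  fixture ships the true structure and flags the whole row.
* **Amoxicillin** — the printed row (including SRR = 27.267 exactly) is
  reproduced by exactly one partition, which corresponds to the true graph
  with the thiazolidine S–C bond removed and one extra terminal atom —
  evidently how the structure was drawn in the source. The fixture ships
  that source-consistent variant, labelled synthetic in the manifest; its SD
  cell (printed 71.66 vs the partition's 71.17, a digit transposition)
  stays flagged.
* **Oxymetazoline, Antazoline, Dexamethasone, Azithromycin, Tobramycin,
  Moxifloxacin** — the unique (or exhaustively bounded) partition matching
  the classical cells pins down the correct FRR/SRR/SD values; the printed
  cells that disagree are flagged suspect with per-cell notes.

Suspect cells are annotated by `validate_against_reference()`, never
auto-corrected: the fixture preserves the reference table verbatim.

## Comparison tolerances

The reference table truncates or loosely rounds its float columns (3.5556
prints as 3.55; 7.8667 prints as 7.88), so a naive absolute tolerance
rejects even rows that are exactly right. The validator therefore compares

* M1, M2, F, HM — exactly (integers);
* mM2, H, SD, SRR — at \(5\times10^{-3} + 10^{-d}\) where \(d\) is the
  number of printed decimals (one unit in the last printed place plus a
  small absolute guard);
* FRR — under the `as_tabulated` variant at 0.5 % relative, the accuracy
  with which that reconstruction tracks the printed column; under
  `as_stated` the column mismatch is structural and every FRR row is
  annotated as a known formula/table discrepancy.

These display/validation tolerances never touch computation, which is
carried in full double precision; `round_half_up()` is applied only at the
reporting boundary (base R's `round()` rounds half to even, which does not
match how screening tables are typically printed).

## The QSPR layer

`fit_simple_linear()` fits property \(= c + m \cdot\) index by ordinary
least squares (`stats::lm`) and reports the screening statistics: N,
intercept, slope, Pearson r, \(r^2\), the regression F statistic
\(r^2 (N-2)/(1-r^2)\) on (1, N−2) degrees of freedom, and its upper-tail
p-value. Significance is declared at the standard p < 0.05 (the source
prose inverts the inequality in words while its tables mark p ≤ 0.0012 as
significant; the standard convention is used here). No multiple-testing
correction is applied across the 54 fits, matching the screening design
being reproduced; treat the p-values as descriptive.

`fit_all()` has two predictor modes. `index_source = "table2"` regresses on
the published index values — the reproduction mode, since those (partly
rounded) numbers are what the source screening actually used.
`index_source = "computed"` recomputes indices from the structures — the
scientific mode. Coefficients can differ in the fourth significant figure
between modes for the rounded columns (mM2, H, SD, FRR, SRR). Inputs with
fewer than three observations or zero variance are rejected outright rather
than returning \(r = \pm 1\). `best_index_report()` breaks exact ties in r
by the canonical index order M1 … SRR.

One published headline number does not survive recomputation: the
correlation between M1 and molar refraction evaluates to 0.9576 from the
published tables, while the source prints 0.9573 — consistent with that
value having been back-derived from the rounded \(r^2\)
(\(\sqrt{0.9163} = 0.9572\)). The acceptance check for that cell uses an
absolute 5 × 10⁻³ instead of printed precision.

## The random-graph generator

`random_mol_graph()` grows a uniform-attachment spanning tree and then adds
up to `extra_edges` chords, rejecting any edge that would push a vertex
past `max_degree` (default 4, the valence ceiling observed in
hydrogen-suppressed organic skeletons). It emulates what matters for the
index calculus — connected simple graphs with bounded degrees, a realistic
tree-plus-few-rings shape and all degree pairs exercised — and nothing
else: there are no element labels, no valence rules per element, no
aromatic-ring statistics. Passing the randomized identity tests (handshake,
partition completeness, \(M1 = \sum d^2\), \(HM = F + 2\,M2\),
partition ≡ brute-force to 1e-9 relative) therefore certifies the index
engine on arbitrary bounded-degree graphs, not the realism of any chemical
space. The test suite runs 500 seeded graphs of 4–28 vertices in the
end-to-end identity check and smaller ensembles (40–200 graphs) in the unit
tests; those sizes make the whole suite complete in well under a minute
while covering every degree-pair class many times over.

## Degenerate inputs and edge cases

* Graphs must be simple and connected with ≥ 2 vertices and ≥ 1 edge;
  self-loops, duplicate edges and disconnected inputs raise typed errors
  (`topoqspr_invalid_structure`, `topoqspr_disconnected_structure`).
* Multi-component SMILES (salts) are an error unless `strip_salts = TRUE`,
  which keeps the largest component; isolated single-atom counter-ions
  count as components.
* Stereochemistry and formal charges in SMILES are accepted and ignored —
  only 2-D connectivity is retained.
* `max_degree < 2` in the generator raises `topoqspr_generation_error`.

## Known limitations

The indices are blind to element identity, bond order and geometry: two
structures with the same heavy-atom skeleton get identical descriptors.
The QSPR layer is strictly one-predictor linear regression — no
multivariate models, regularization, cross-validation, or
applicability-domain analysis — so the correlations quantify association
within this twenty-drug set, not predictive performance on new chemistry.
Distance-based descriptors (Wiener-type) and heteroatom-weighted variants
are out of scope.
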