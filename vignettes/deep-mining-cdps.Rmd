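---
title: "Deep mining cyclic dipeptides from molecular networks: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep mining cyclic dipeptides from molecular networks: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpmine)
```

## The annotation problem

Feature-based molecular networking (FBMN) turns an LC–MS/MS experiment into
a graph: nodes are features (precursor m/z, retention time, an MS/MS
spectrum), edges link features with similar fragmentation, and connected
components collect structural analogs. Cyclic dipeptides
(2,5-diketopiperazines, CDPs) form tight clusters in such networks because
analogs share low-mass residue reporter ions, but they are poorly served by
the two standard annotation layers: spectral-library matching covers few
CDPs, and de novo sequencing engines only model linear backbones — a CDP,
whose protonated mass is the residue sum plus a proton (one water short of
the linear dipeptide), comes back labelled "dehydrated". This package
encodes the third layer an analyst otherwise performs by hand: exact-mass
candidate enumeration, diagnostic-ion evidence, and residue-exchange mass
deltas walked along network edges.

## Mass model

All arithmetic is integer element counts (`element_counts`) times
monoisotopic atomic masses (CODATA/IUPAC, ≥ 6 d.p., embedded as constants).
Two conventions matter and are fixed package-wide:

* **Protonation adds a proton**, `m_p = m_H − m_e = 1.007276 Da`, not an H
  atom. This is the only convention that reproduces published accurate
  masses at 4 d.p. (e.g. C₁₁H₁₆N₂O₅ → 257.1132).
* **Cations are electron-corrected**: a fragment whose ion composition is
  given directly (immonium, the Pro 98.06 companion) is its mass minus one
  electron.

Reported theoretical m/z use 4 d.p.; comparisons against 2-d.p. literature
values use round-half-up (`round_half_up()`), because base R's
round-half-even disagrees at .5 boundaries.

The residue library holds the 20 canonical residues plus three unnatural
ones tied to their parents by fixed composition deltas: Hyp = Pro + O,
MeEGlu = Glu + CH₂, PyroGlu = Glu − H₂O. Leu and Ile are deliberately kept
as distinct entries with identical composition; every operation downstream
must therefore tolerate exact mass ties. Users extend the library through a
config mapping (code → formula/diagnostics), never by editing code.

## Fragment rules

Published CDP identifications cite diagnostic ions ad hoc, compound by
compound. We instead fix one declarative rule table and apply it uniformly:

| rule | applies to | form |
|---|---|---|
| precursor | all | `[M+H]+` |
| ring losses | all | −H₂O, −CO, −(CO+H₂O) |
| immonium | every residue | residue − CO + H, cation |
| companion ion | Pro | C₅H₈NO⁺ (98.06) |
| side-chain loss | Tyr | −C₇H₆O |
| methyl-ester losses | MeEGlu | −CH₃OH, −(CH₃OH+CO) |
| side-chain iminium | Ile | 86.10, 69.07 (optional discriminators) |

This reproduces every diagnostic used in the published reasoning while
remaining extensible; the Ile ions are encoded as *optional* diagnostics
because Leu/Ile immonium masses are identical and the side-chain ions are
not a guaranteed discriminator. For linear peptides the model is standard
b/y arithmetic (`b_i = Σ first i residues + m_p`;
`y_i = Σ last i residues + H₂O + m_p`), emitting `b_1..b_{n−1}` and
`y_1..y_n` so that a single residue yields its protonated mass as `y_1`.

## Evidence scoring and tiers

The literature states which ions were decisive but not a numeric rule. We
formalize it as `score = 2·imm + 1·loss + 1·diag` over matched fragments
(greedy nearest-m/z matching at 0.02 Da, one peak per predicted ion,
deterministic tie-break toward the lower predicted m/z) with tiers:

* **confident** — both residues' immonium ions matched, or one immonium
  plus ≥ 2 neutral losses;
* **candidate** — ≥ 2 matched ions besides the precursor;
* **weak** — otherwise, and always when the precursor is outside the 10 ppm
  window.

The immonium weight is doubled because immonium ions are what the published
identifications treat as decisive; all weights and cut-offs are
configurable. Intensities are retained for reporting but do not enter the
score — the underlying reasoning is presence/absence.

## Propagation

`build_delta_rules()` tabulates every pairwise residue exchange as a signed
composition delta (oriented lighter → heavier, zero-mass Leu/Ile excluded).
`propagate()` runs breadth-first from the seed annotations over intra-cluster
edges: a neighbor whose precursor mass difference matches a rule within
0.01 Da (the upstream feature-finding m/z tolerance) yields a residue-
exchanged candidate, accepted only if its *own* spectrum scores at least
`candidate`. Seeds are never overwritten; iteration reaches a fixpoint;
conflicting proposals keep the highest score and exact ties are emitted for
both candidates, marked unresolved. Because published cross-cluster
reasoning is limited to the water deficit of pyroglutamate analogs, a second
pass over node *pairs* across clusters is restricted to a configurable delta
whitelist (H₂O by default) rather than opening all deltas network-wide.

## De novo revision and isomers

A de novo dipeptide carrying a −18.01 Da tag (±0.02) — or whose node mass
already equals residues + proton — is rescored as the cyclic form;
pyroglutamate formation is the competing explanation of the same mass
deficit, so when a Glu is present the PyroGlu alternative is scored too and
the better-supported candidate wins. The revision additionally requires the
node's cluster to already contain a CDP annotation (cluster context is the
analyst's cue); otherwise the linear call stands. Longer peptides pass
through unchanged.

Isomer classification groups annotations by formula: same named residue
composition with exactly two distinct retention times → diastereomer pair
(reversed-phase C18 resolves the stereoisomers); same formula, different
composition → positional isomers. The Leu/Ile elution-order heuristic
(Ile elutes earlier within a same-formula pair) is opt-in and labelled as a
heuristic in the output, since it is an empirical regularity, not a rule.

## Synthetic data: what it does and does not emulate

`generate_network()` plants known compounds and emits exactly the artifacts
the readers consume (MGF, node/edge tables, ground truth). Peaks are the
predicted fragments minus Bernoulli dropout, plus uniform noise peaks over
[50, precursor + 5] whose intensities sit below the 10th percentile of true
peaks — loud enough to stress the tolerance windows, quiet enough that
presence/absence scoring stays meaningful. Intensities are log-normal
(precursor loudest); observed precursors are perturbed by a 5 ppm Gaussian
truncated at the 10 ppm match tolerance. Edges join nodes sharing ≥ 2
predicted fragment m/z values at 2 d.p., which makes residue-sharing CDPs
cluster the way they do in real networks. Generation is bit-reproducible
for a fixed seed.

What this does **not** emulate: chimeric/co-isolated spectra, isotope
envelopes, adducts other than [M+H]⁺, multiply charged species, intensity
structure informative of fragmentation chemistry, retention-time drift, and
modified-cosine edge scores (synthetic cosine is a shared-fragment
fraction). Passing recovery tests on these fixtures therefore demonstrates
the *logic* of the engine — enumeration, scoring, propagation, revision —
not robustness to every failure mode of real data.

## Numerical and design choices

* Tolerances: 10 ppm precursor, 0.02 Da fragment, 0.01 Da edge deltas,
  0.25 min RT when joining de novo rows to nodes without shared ids — all
  configurable, defaults chosen to match common instrument settings for
  Orbitrap-class data and the upstream tools' own defaults.
* Determinism: nodes are processed in ascending precursor m/z then RT;
  network loads sort canonically; matching tie-breaks are fixed. Identical
  inputs give identical reports.
* Degenerate inputs: empty spectra score weak (not an error); an empty
  prediction list matches nothing; records without a precursor mass are
  skipped with a warning; self-loop edges are dropped; an edge referencing
  an unknown node is a hard error.
* The packaged 53-CDP reference set derives each formula and theoretical m/z
  from the compound name's residues. Three printed formula cells and two
  printed m/z values in the published table are inconsistent with their own
  compound names (e.g. cyclo(MeEGlu-Hyp) printed as C₁₁H₁₆N₂O₃ although the
  isolated compound is C₁₁H₁₆N₂O₅); these rows carry `formula_mismatch` /
  `mz_mismatch` flags and the derived values are used.
* Dataset-dependent totals of the original study (total compounds, node and
  cluster counts, database/de novo layer sizes) depend on raw data this
  package does not process; the pipeline reports its own provenance
  partition instead of attempting to reproduce them.

## Problem sizes used in validation

The shipped tests validate recovery on noise-free planted networks of 32
CDPs (plus 12-compound networks across a dropout × seed grid for the
degradation property, and ≤ 6-node networks for brute-force oracle
equivalence of propagation). These sizes exercise every code path —
multi-candidate formulas, Leu/Ile ties, cross-cluster water deltas — while
keeping the whole suite fast enough to run on every change.

## Known limitations

* Only singly protonated positive-mode species; no adducts, no charge > 1.
* Ring-opening fragmentation of DKPs is modelled by the fixed rule table,
  not combinatorially; unusual residues may need user-supplied diagnostics.
* Stereochemical assignment within a diastereomer pair is out of scope —
  the package counts and pairs isomers, it cannot say which member is which.
* The Leu/Ile heuristic and the de novo→node fallback join (m/z + RT) are
  conventions, clearly labelled, not guarantees.
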