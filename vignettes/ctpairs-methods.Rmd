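---
title: "ctpairs: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctpairs: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpairs)
```

## The problem and the model

ChEMBL stores heterogeneous bioactivity measurements, curated
mechanism-of-action assignments for drugs and clinical candidates, and
compound/target annotations — but not as a single analysis-ready table.
`ctpairs` condenses it into one row per (parent compound, target) pair,
with the pair's provenance made explicit through a drug–target
interaction (DTI) class. The unit of analysis is the *pair*, not the
measurement: a compound measured twenty times on one kinase is one row.

**Record admission.** An activity qualifies if it carries a pChEMBL value
(−log10 of a molar concentration–response endpoint; 1 nM → 9.0) measured
in a binding (`B`) or functional (`F`) assay, is not a flagged potential
duplicate, has no data-validity comment (or the benign "Manually
validated"), is not on the unchecked-target sentinel (TID 22226), and —
by default — comes from a scientific-literature document
(`DOCS.SRC_ID = 1`). The literature default exists because bulk imports
(notably patent data routed through BindingDB for 2013–2016) distort
time- and target-class distributions; switching to all sources changes
pChEMBL-derived columns everywhere, which is why it is a run parameter
(`--all_sources`) and not a filter column.

**Aggregation.** Molecules are first mapped to the root of their
hierarchy — the salt form is deliberately discarded as pharmacologically
irrelevant here; a molecule with two distinct parents is corrupt data and
a fatal error. Per pair, pChEMBL values are summarised as arithmetic
mean, sample median (midpoint convention for even counts) and maximum,
once over B∪F (`_BF`) and once over B only (`_B`). Because the `_B`
record set is a subset of `_BF`, `pchembl_value_max_B ≤
pchembl_value_max_BF` whenever both exist — a property the tests assert
on randomized fixtures. No cross-laboratory outlier handling is
attempted; aggregated values mix assays and labs and should be used with
that in mind.

**First-publication years.** The year fields answer "when was this pair
(or compound) first reported". Records that pass every admission filter
*except* pChEMBL presence still date a pair, which is why the reader has
a `require_pchembl = FALSE` mode feeding the year minima only — this is
what makes `first_publication_cpd_target_pair_BF` and its `_w_pchembl_`
sibling genuinely different columns. Missing years never act as zero:
they simply drop out of the minima. The per-compound year is the minimum
over all of the compound's qualifying records across targets.

**Mechanism merge and DTI.** Curated mechanism rows with
disease-efficacy = 1 assert a therapeutically relevant interaction
without needing a measurement. Their target ids are expanded through a
whitelist of exactly six relation triples (family/complex/complex
group/chimeric/PPI −[superset of]→ single protein; single protein
−[equivalent to]→ single protein), one hop only — transitive chains are
not sanctioned and not followed; both original and mapped ids are kept.
Pairs already present get `in_dm_table = TRUE`; absent ones are appended
with empty pChEMBL columns. DTI assignment then partitions all pairs:
phase 4 → `D_DT`; phases 3/2/1 → `C3_DT`/`C2_DT`/`C1_DT`; below phase 1 →
`C0_DT`; otherwise `DT` if the target occurs in any (expanded) mechanism
row and `NDT` if not. `NDT` rows are discarded. Note a drug can be `DT`
on a target where its mechanism is uncurated — that is the comparator
concept, not an error. "Below phase 1" is release-dependent: phase 0 for
releases ≤ 31; phase 0.5, −1 or NULL from release 32 on (an unknown
release is treated as modern). An out-of-vocabulary phase code is a
fatal data error, not a silent `C0_DT`.

Two open points were decided here: the therapeutic-target set for the
`DT` rule uses the *expanded* mechanism targets (the expansion exists
precisely to propagate mechanism knowledge to members), and subset
membership (below) is evaluated after structure-based removals, so every
reported count refers to rows actually present in the file.

## Annotations

Structures are taken as stored — no standardisation or neutralisation.
Compounds without a SMILES, or with a `.` in the SMILES (mixtures), are
removed and counted per reason. Ligand-efficiency metrics use the
domain-matched **maximum** pChEMBL and the stored property table:

* `LE = 1.37 · pChEMBL / heavy_atoms` (kcal·mol⁻¹ per heavy atom, 300 K)
* `BEI = pChEMBL · 1000 / MW(Da)` (i.e. per kDa)
* `SEI = pChEMBL / (PSA / 100 Å²)`
* `LLE = pChEMBL − logP` (the stored calculated logP, not a recomputed
  one — the stored value is what the property table's other columns are
  consistent with)

A metric is absent — never partially computed — when an operand is
missing or a denominator is non-positive. ATC level-1 codes and protein
class labels (levels 1 and 2) concatenate deduplicated and
alphabetically sorted with `|`; targets with more than one label at
either level go to the multi-class report file for optional manual
reassignment.

The optional RDKit stage shells out to `inst/python/descriptors.py`
(RDKit ships no R binding; the bundled helper plus a `python` with
`rdkit` is the supported route). Aromatic-atom counts iterate atoms under
RDKit's default aromaticity perception, so `n_aromatic_c +
n_aromatic_hetero = n_aromatic_atoms` holds by construction and is
asserted over the whole fixture molecule pool. Stereocenters count
assigned plus unassigned centres. Scaffolds are Bemis–Murcko frameworks
with and without stereo annotations; an acyclic molecule has the empty
scaffold, carried as a missing value (indistinguishable in the output
from a parse failure — a parse failure additionally logs a warning).

## Cleaning, checks, outputs

In memory the canonical missing value is `NA`; in files it is `None`
(empty strings and NaN are folded into it). Floats are rounded to four
decimals — round-half-even, R's IEEE default — except `max_phase`, whose
0.5 code must survive verbatim. Whole-number double columns are written
as integers. Files are UTF-8, `\n`-terminated, `;`-delimited by default.

The basic checks fail loudly rather than repair: uniform missing values,
single-typed columns, *every pChEMBL-less pair is mechanism-backed*, no
surviving `NDT`, and per-column missing counts equal to expectations
derived from joined operand availability (an LE metric is expected
missing exactly where its pChEMBL or property operand is). Every written
file is read back and compared cell-for-cell; the first differing cell is
reported. A failed check makes the CLI exit nonzero.

Subset flags: `BF_100` marks pairs whose target has ≥ 100 distinct
parent compounds with a `_BF` pChEMBL; `_d_dt`, `_c_dt` and `_c_dt_d_dt`
additionally require ≥ 1 drug, ≥ 1 candidate, or ≥ 1 of either on the
target; analogously for `B_`. The threshold is a parameter defaulting
to 100. Each requested subset file equals the full dataset filtered on
its flag (flags retained in the file), and every written dataset has a
`_stats.csv` with pair/compound/target counts — with and without
resolving mutation-variant targets — for the total, drug, candidate and
comparator groups. A mechanism-only pair, which has no measured variant,
counts once under its base target in the "incl. variants" numbers.

## The synthetic world and what green tests mean

`fixture_spec()` defaults describe a deliberately small but fully
featured world: 12 parents with one salt each, 4 single-protein targets
plus a two-member family, B/F/A activity densities 0.45/0.30/0.15,
pChEMBL uniform on [4, 10] with 15% of rows lacking the value, 10%
missing document years over 1995–2020, 4 mechanism rows, the full modern
phase code pool {4, 3, 2, 1, 0.5, −1, NA}, 10% structureless and 10%
mixture parents, 10% missing property rows, 25% unclassified targets and
one multi-class target, plus decoy rows that must be filtered (assay
type A, duplicates, validity comments, a non-literature source, the
unchecked target). These rates are chosen once so that, at desk scale,
every rule in the pipeline actually fires; they are not calibrated to
ChEMBL's real marginals, and no generator parameter was adjusted after
observing test outcomes.

The ground truth is computed by `compute_fixture_truth()` — nested loops
over the raw tables, restating every rule independently of the pipeline
code. A green oracle-equivalence test therefore establishes that two
independent encodings of the rules agree on stores this size; it does
**not** establish fidelity to the published full-scale dataset, which
depends on ChEMBL-scale data the tests cannot reach (see limitations).
The 100-compound subset boundary cannot occur in a 12-compound world, so
it is tested exactly on constructed 99/100/150-compound tables, and
subset-file mechanics are exercised at a threshold of 2.

## Known limitations

* Fetching a store by release number needs network access and is
  unsupported here; a downloaded SQLite file must be supplied. The
  full-scale reproduction criterion is consequently red in this
  environment by design, not silently skipped.
* The literature definition (`SRC_ID = 1` at document level) may need
  adjustment to bit-match published outputs if activity- and
  document-level provenance ever disagree.
* No structure standardisation, no cross-assay weighting or outlier
  rejection, no mechanism action-type modelling, no indication data.
* The xlsx writer is optional; without `writexl` the `--excel` flag
  degrades to a warning while CSV output proceeds.
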