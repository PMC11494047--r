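# ctpairs

Reproducible extraction of an annotated **compound–target interaction
pairs** dataset from a ChEMBL-schema SQLite database.

Retrospective analyses of drug discovery — what separates approved drugs
and clinical candidates from the mass of merely active compounds — need a
dataset that puts all three groups on the same footing, per target.
`ctpairs` builds that dataset from any ChEMBL release ≥ 26:

1. **Activity pairs.** Every activity with a pChEMBL value (−log10 molar
   IC50/EC50/XC50/AC50/Ki/Kd/potency) measured in a binding (`B`) or
   functional (`F`) assay is kept, after record-level hygiene filters
   (no potential duplicates, no validity-flagged rows, no unchecked
   target, literature sources only by default). Compounds are mapped to
   their parent (salt information dropped) and pChEMBL values per
   (parent, target) pair are aggregated into mean / median / max — once
   over B∪F (`_BF` columns) and once over B alone (`_B`), together with
   first-publication years.
2. **Known interactions.** Manually curated mechanism-of-action pairs
   (disease-efficacy = 1) are merged in, with target ids expanded through
   a six-triple whitelist of target relations (e.g. protein family
   −[superset of]→ single protein, one hop). Pairs missing from the
   activity set are appended without pChEMBL values.
3. **DTI classes.** Each pair gets a drug–target interaction class:
   `D_DT` (phase-4 drug on its known target), `C3_DT`…`C0_DT` (clinical
   candidates by max_phase, with release-dependent sub-phase-1 codes),
   `DT` (comparator compound on a therapeutic target), `NDT` (discarded).
4. **Annotations.** Structures (SMILES/InChI; mixtures and structureless
   compounds removed), stored physicochemical properties, ligand
   efficiency metrics (LE = 1.37·pChEMBL/HA, BEI = pChEMBL/MW[kDa],
   SEI = pChEMBL/(PSA/100), LLE = pChEMBL − logP), ATC level-1 codes,
   two-level protein target classes, and optional RDKit descriptors
   (ring systems, stereocenters, aromatic-atom counts, Bemis–Murcko
   scaffolds) via the bundled Python helper.
5. **Cleaning, checks, subsets.** Canonical missing values, 4-dp
   rounding, consistency checks (every pChEMBL-less pair must be
   mechanism-backed, no `NDT` survivor, missing-count bookkeeping),
   write/read round-trip verification, and boolean filter columns such as
   `BF_100_c_dt_d_dt` (targets with ≥ 100 active compounds and ≥ 1 drug
   or candidate) with per-dataset statistics files.

A fixture module (`fixture_spec()`, `build_fixture()`, `edge_case_suite()`)
generates miniature ChEMBL-schema SQLite stores plus an independent
brute-force ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(ctpairs)

fx <- build_fixture(fixture_spec(seed = 1L))   # synthetic mini-ChEMBL
run <- run_pipeline(output_dir = tempfile("out"),
                    store_path = fx$path, chembl_version = 32L)
#> [ctpairs] activity_records: 44
#> [ctpairs] measured_pairs: 34
#> [ctpairs] pairs_with_mechanism: 6
#> [ctpairs] pairs_after_ndt_removal: 36
#> [ctpairs] pairs_final: 21

run$dataset[1:2, .(parent_molregno, tid, pchembl_value_max_BF, DTI)]
#>    parent_molregno   tid pchembl_value_max_BF    DTI
#> 1:               1   102                 9.96     DT
#> 2:               1   103                   NA   D_DT
```

44 pChEMBL-bearing records survive the hygiene filters; they collapse to
34 (parent, target) pairs. Merging the curated mechanisms (with target
expansion) flags or appends 6 mechanism pairs; dropping `NDT` pairs
leaves 36, and removing compounds without a usable structure leaves the
final 21 rows. Row 2 is a mechanism-only pair: no measured pChEMBL, so
its presence is justified by the mechanism table (`in_dm_table = TRUE`)
and its compound is an approved drug on this target (`D_DT`). Outputs land in the run directory as
`ChEMBL32_CTI_literature_only_full_dataset.csv` (+ `_stats.csv`, the
multi-class target report and `run_manifest.json`).

On a real store:

```sh
Rscript inst/exec/ctpairs.R --sqlite chembl_32.db --chembl 32 \
    --output out/ --rdkit --BF --B
```

Flags mirror the reference contract: `--chembl/-v`, `--sqlite/-s`,
`--output/-o` (required), `--delimiter/-d` (default `;`),
`--all_sources`, `--rdkit`, `--excel`, `--BF`, `--B`, `--debug`.

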