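test_that("structure filter removes missing and mixture SMILES", {
  pairs <- data.table::data.table(parent_molregno = c(1L, 2L, 3L, 3L, 4L))
  st <- data.table::data.table(
    molregno = c(1L, 2L, 3L),
    canonical_smiles = c("CCO", "CC(=O)[O-].[Na+]", "c1ccccc1"),
    standard_inchi = paste0("InChI=1S/x", 1:3),
    standard_inchi_key = paste0("K", 1:3))
  out <- attach_structures_and_filter(pairs, st)
  expect_identical(sort(out$pairs$parent_molregno), c(1L, 3L, 3L))
  expect_false(any(grepl(".", out$pairs$canonical_smiles, fixed = TRUE)))
  expect_identical(
    out$removed$n_compounds[out$removed$reason == "missing_smiles"], 1L)
  expect_identical(
    out$removed$n_compounds[out$removed$reason == "smiles_with_full_stop"],
    1L)
})

test_that("ligand efficiency formulas and missingness propagation", {
  le <- compute_ligand_efficiencies(9, 30, 450, 100, 3)
  expect_equal(le$LE, 1.37 * 9 / 30)        # 0.411
  expect_equal(le$BEI, 20)
  expect_equal(le$SEI, 9)
  expect_equal(le$LLE, 6)

  none <- compute_ligand_efficiencies(NA_real_, 30, 450, 100, 3)
  expect_true(all(is.na(none)))
  zero_den <- compute_ligand_efficiencies(9, 0, NA, 0, NA)
  expect_true(all(is.na(zero_den)))
})

test_that("ATC and target class labels concatenate sorted with '|'", {
  expect_identical(concat_atc(c("N", "C")), "C|N")
  expect_identical(concat_atc("L"), "L")
  expect_identical(concat_atc(c("N", "N")), "N")
  expect_true(is.na(concat_atc(character())))

  pairs <- data.table::data.table(tid = c(1L, 2L, 3L))
  classes <- data.table::data.table(
    tid = c(1L, 1L, 2L),
    l1 = c("Enzyme", "Epigenetic regulator", "Enzyme"),
    l2 = c("Kinase", NA, "Kinase"))
  tc <- attach_target_classes(pairs, classes)
  expect_identical(tc$pairs[tid == 2L, target_class_l1], "Enzyme")
  expect_identical(tc$pairs[tid == 2L, target_class_l2], "Kinase")
  expect_identical(tc$pairs[tid == 1L, target_class_l1],
                   "Enzyme|Epigenetic regulator")
  expect_identical(tc$multiclass$tid, 1L)          # report lists tid 1 once
  expect_true(is.na(tc$pairs[tid == 3L, target_class_l1]))  # unclassified
})

test_that("toolkit descriptors match the worked aromatic examples", {
  d <- compute_toolkit_descriptors(c("c1ccccc1", "c1ccncc1", "c1ccoc1"))
  expect_identical(d$n_aromatic_atoms, c(6L, 6L, 5L))
  expect_identical(d$n_aromatic_c, c(6L, 5L, 4L))
  expect_identical(d$n_aromatic_n, c(0L, 1L, 0L))
  expect_identical(d$n_aromatic_hetero, c(0L, 1L, 1L))
  expect_identical(d$n_aromatic_rings, c(1L, 1L, 1L))
})

test_that("aromatic count identity holds across the fixture molecule pool", {
  smiles <- c(ctpairs:::FIXTURE_SMILES, "not-parseable-smiles")
  expect_warning(d <- compute_toolkit_descriptors(smiles), "parsed")
  ok <- !is.na(d$n_aromatic_atoms)
  expect_identical(sum(!ok), 1L)           # only the seeded bad SMILES
  expect_identical(d$n_aromatic_c[ok] + d$n_aromatic_hetero[ok],
                   d$n_aromatic_atoms[ok])
  expect_true(all(d$n_aromatic_n[ok] <= d$n_aromatic_hetero[ok]))
  counts <- d[ok, grep("^n_", names(d), value = TRUE), with = FALSE]
  expect_true(all(as.matrix(counts) >= 0L))
  # acyclic molecules have the empty scaffold
  expect_true(is.na(d$scaffold_wo_stereo[d$canonical_smiles == "CCO"]))
  expect_identical(d$scaffold_wo_stereo[d$canonical_smiles == "c1ccccc1"],
                   "c1ccccc1")
})

test_that("LE metrics appear and vanish consistently with operands", {
  fx <- build_fixture(fixture_spec(seed = 41L))
  res <- run_on_fixture(fx)
  got <- res$dataset
  for (dom in c("BF", "B")) {
    pmax_ <- got[[paste0("pchembl_value_max_", dom)]]
    expect_identical(is.na(got[[paste0("LE_", dom)]]),
                     is.na(pmax_) | is.na(got$heavy_atoms) |
                       got$heavy_atoms <= 0)
    expect_identical(is.na(got[[paste0("LLE_", dom)]]),
                     is.na(pmax_) | is.na(got$alogp))
  }
  # removal filter is global: no surviving SMILES contains '.'
  expect_false(any(grepl(".", got$canonical_smiles, fixed = TRUE)))
})
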