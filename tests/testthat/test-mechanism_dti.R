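rels <- data.table::data.table(
  tid = c(201L, 201L, 101L, 102L, 103L),
  relationship = c("SUPERSET OF", "SUPERSET OF", "SUBSET OF",
                   "SUBSET OF", "EQUIVALENT TO"),
  related_tid = c(101L, 102L, 201L, 201L, 104L),
  target_type = c("PROTEIN FAMILY", "PROTEIN FAMILY", "SINGLE PROTEIN",
                  "SINGLE PROTEIN", "SINGLE PROTEIN"),
  related_target_type = c("SINGLE PROTEIN", "SINGLE PROTEIN",
                          "PROTEIN FAMILY", "PROTEIN FAMILY",
                          "SINGLE PROTEIN"))

test_that("expand_targets follows only whitelisted single-hop relations", {
  # family superset-of members: original and mapped ids kept
  expect_identical(expand_targets(201L, rels), c(101L, 102L, 201L))
  # no relations: identity
  expect_identical(expand_targets(105L, rels), 105L)
  # subset-of is not on the whitelist: not followed
  expect_identical(expand_targets(101L, rels), 101L)
  # equivalent-to between single proteins is followed
  expect_identical(expand_targets(103L, rels), c(103L, 104L))
  # no transitive closure: expansion from a family stops at its members
  rels2 <- rbind(rels, data.table::data.table(
    tid = 104L, relationship = "EQUIVALENT TO", related_tid = 106L,
    target_type = "SINGLE PROTEIN", related_target_type = "SINGLE PROTEIN"))
  expect_identical(expand_targets(103L, rels2), c(103L, 104L))
})

hier0 <- data.table::data.table(molregno = integer(),
                                parent_molregno = integer())

mk_agg <- function(parent, tid, pmax = 7) {
  data.table::data.table(parent_molregno = parent, tid = tid,
                         pchembl_value_mean_BF = pmax,
                         pchembl_value_median_BF = pmax,
                         pchembl_value_max_BF = pmax,
                         pchembl_value_mean_B = NA_real_,
                         pchembl_value_median_B = NA_real_,
                         pchembl_value_max_B = NA_real_)
}

test_that("merge_mechanism_pairs flags existing and appends missing pairs", {
  agg <- mk_agg(1L, 101L)
  mech <- data.table::data.table(molregno = 1L, tid = 101L,
                                 disease_efficacy = 1L)
  m <- merge_mechanism_pairs(agg, mech, rels[0], hier0)
  expect_identical(nrow(m$pairs), 1L)          # idempotent: no new row
  expect_true(m$pairs$in_dm_table)

  mech2 <- data.table::data.table(molregno = 2L, tid = 102L,
                                  disease_efficacy = 1L)
  m2 <- merge_mechanism_pairs(agg, mech2, rels[0], hier0)
  expect_identical(nrow(m2$pairs), 2L)
  new_row <- m2$pairs[parent_molregno == 2L]
  expect_true(new_row$in_dm_table)
  expect_true(is.na(new_row$pchembl_value_max_BF))

  # mechanism on a family expands: measured member flagged, family appended
  mech3 <- data.table::data.table(molregno = 1L, tid = 201L,
                                  disease_efficacy = 1L)
  m3 <- merge_mechanism_pairs(agg, mech3, rels, hier0)
  expect_identical(sort(m3$pairs$tid), c(101L, 102L, 201L))
  expect_true(all(m3$pairs$in_dm_table))
  expect_true(is.na(m3$pairs[tid == 201L, pchembl_value_max_BF]))
  expect_identical(m3$therapeutic_targets, c(101L, 102L, 201L))
})

test_that("assign_dti reproduces the DTI rule table", {
  tt <- c(50L)
  # in mechanism table: class follows max_phase
  expect_identical(as.character(assign_dti(TRUE, 4, 1L, tt)), "D_DT")
  expect_identical(as.character(assign_dti(TRUE, 3, 1L, tt)), "C3_DT")
  expect_identical(as.character(assign_dti(TRUE, 2, 1L, tt)), "C2_DT")
  expect_identical(as.character(assign_dti(TRUE, 1, 1L, tt)), "C1_DT")
  # modern (release >= 32 / unknown) sub-phase-1 codes
  expect_identical(as.character(assign_dti(TRUE, NA, 1L, tt)), "C0_DT")
  expect_identical(as.character(assign_dti(TRUE, 0.5, 1L, tt)), "C0_DT")
  expect_identical(as.character(assign_dti(TRUE, -1, 1L, tt)), "C0_DT")
  # legacy (release <= 31): phase 0 means sub-phase-1
  expect_identical(as.character(assign_dti(TRUE, 0, 1L, tt, release = 31L)),
                   "C0_DT")
  # not in mechanism table: DT on therapeutic targets, NDT otherwise
  expect_identical(as.character(assign_dti(FALSE, 4, 50L, tt)), "DT")
  expect_identical(as.character(assign_dti(FALSE, NA, 1L, tt)), "NDT")
  # a drug elsewhere is only DT on a target without curated mechanism
  expect_identical(as.character(assign_dti(FALSE, 4, 50L, tt)), "DT")
  # unknown phase codes are fatal, naming the code
  expect_error(assign_dti(TRUE, 2.5, 1L, tt), "2.5")
  expect_error(assign_dti(TRUE, 0, 1L, tt), "0")          # 0 invalid >= 32
  expect_error(assign_dti(TRUE, 0.5, 1L, tt, release = 31L), "0.5")
})

test_that("every pair gets exactly one class and NDT never survives", {
  for (seed in c(31L, 32L)) {
    fx <- build_fixture(fixture_spec(seed = seed, n_mechanism_rows = 6L))
    res <- run_on_fixture(fx)
    dti <- as.character(res$dataset$DTI)
    expect_false(any(is.na(dti)))
    expect_false(any(dti == "NDT"))
    # pairs without pChEMBL are mechanism-backed
    no_p <- is.na(res$dataset$pchembl_value_max_BF)
    expect_true(all(res$dataset$in_dm_table[no_p]))
    expect_matches_truth(res, fx$truth)
  }
})
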