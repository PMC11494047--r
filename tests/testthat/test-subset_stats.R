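test_that("the 100-compound threshold is an exact boundary", {
  at_100 <- compute_filter_columns(toy_pairs(n_cpds = 100L))
  expect_true(all(at_100$BF_100))
  at_99 <- compute_filter_columns(toy_pairs(n_cpds = 99L))
  expect_false(any(at_99$BF_100))
  # no binding-assay pChEMBL: B_100 stays false even at 100 compounds
  expect_false(any(at_100$B_100))
})

test_that("drug/candidate sub-flags require the right DTI classes", {
  ds <- toy_pairs(n_cpds = 150L)
  ds$DTI[1] <- "D_DT"                      # one drug pair, no candidates
  ds <- compute_filter_columns(ds)
  expect_true(all(ds$BF_100))
  expect_true(all(ds$BF_100_d_dt))
  expect_false(any(ds$BF_100_c_dt))
  expect_true(all(ds$BF_100_c_dt_d_dt))
  # flag implications: each sub-flag implies its *_100 parent
  for (flag in c("BF_100_c_dt_d_dt", "BF_100_d_dt", "BF_100_c_dt")) {
    expect_true(all(!ds[[flag]] | ds$BF_100))
  }
})

test_that("raising the threshold never adds a target to a subset", {
  fx <- build_fixture(fixture_spec(seed = 61L))
  res <- run_on_fixture(fx, threshold = 2L)
  lo <- res$dataset
  hi <- compute_filter_columns(lo[, !names(lo) %in% ctpairs:::SUBSET_FLAGS,
                                  with = FALSE], threshold = 5L)
  expect_true(all(lo$tid[hi$BF_100] %in% lo$tid[lo$BF_100]))
})

test_that("compute_stats partitions by DTI group", {
  ds <- data.table::data.table(
    parent_molregno = 1:4, tid = c(1L, 1L, 2L, 3L),
    DTI = c("D_DT", "C2_DT", "DT", "DT"))
  st <- compute_stats(ds)
  expect_identical(st[group == "total", n_pairs], 4L)
  expect_identical(st[group == "drugs", n_pairs], 1L)
  expect_identical(st[group == "candidates", n_pairs], 1L)
  expect_identical(st[group == "comparator", n_pairs], 2L)

  empty <- compute_stats(ds[0])
  expect_true(all(unlist(empty[, -1]) == 0L))

  # one pair, two variant annotations: counted twice incl. variants
  vk <- data.table::data.table(parent_molregno = c(1L, 1L),
                               tid = c(1L, 1L), variant_id = c(501L, 502L))
  stv <- compute_stats(ds[1], vk)
  expect_identical(stv[group == "total", n_pairs], 1L)
  expect_identical(stv[group == "total", n_pairs_incl_variants], 2L)
  expect_identical(stv[group == "total", n_targets_incl_variants], 2L)
})

test_that("written subsets equal flag-filtered rows and stats cross-check", {
  fx <- build_fixture(fixture_spec(seed = 62L))
  res <- run_on_fixture(fx, threshold = 2L)
  outdir <- tempfile("out")
  files <- write_outputs(res$dataset, outdir, "ChEMBL32_CTI_literature_only",
                         write_bf = TRUE, write_b = TRUE,
                         variant_keys = res$variant_keys,
                         multiclass = res$multiclass)
  expect_true(all(files$roundtrip_ok))
  expect_true(file.exists(
    file.path(outdir, "ChEMBL32_CTI_literature_only_full_dataset.csv")))
  expect_true(file.exists(
    file.path(outdir, "ChEMBL32_CTI_literature_only_full_dataset_stats.csv")))
  expect_true(file.exists(file.path(
    outdir, "ChEMBL32_CTI_literature_only_targets_w_more_than_one_tclass.csv")))

  for (flag in ctpairs:::SUBSET_FLAGS) {
    f <- file.path(outdir,
                   paste0("ChEMBL32_CTI_literature_only_", flag, ".csv"))
    expect_true(file.exists(f))
    sub <- read_ctp_file(f)
    expect_identical(nrow(sub), sum(res$dataset[[flag]]))
    expect_identical(as.integer(sub$parent_molregno),
                     res$dataset$parent_molregno[res$dataset[[flag]]])
  }

  # stats file of the full dataset equals compute_stats output
  st_file <- read_ctp_file(file.path(
    outdir, "ChEMBL32_CTI_literature_only_full_dataset_stats.csv"))
  st_mem <- compute_stats(res$dataset, res$variant_keys)
  expect_identical(st_file$group, st_mem$group)
  expect_identical(as.integer(st_file$n_pairs), as.integer(st_mem$n_pairs))
  expect_identical(as.integer(st_file$n_targets_incl_variants),
                   as.integer(st_mem$n_targets_incl_variants))
})
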