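hier <- data.table::data.table(
  molregno = c(10L, 11L, 12L, 1L),
  parent_molregno = c(1L, 1L, 2L, 1L))

test_that("map_to_parent strips salts and is identity elsewhere", {
  expect_identical(map_to_parent(c(10L, 11L, 12L), hier), c(1L, 1L, 2L))
  expect_identical(map_to_parent(1L, hier), 1L)        # self-row
  expect_identical(map_to_parent(99L, hier), 99L)      # absent -> itself
  bad <- rbind(hier, data.table::data.table(molregno = 10L,
                                            parent_molregno = 3L))
  expect_error(map_to_parent(10L, bad), "more than one distinct parent")
})

mk_records <- function(mol, tid, type, pchembl, year = NA_integer_) {
  data.table::data.table(molregno = mol, tid = tid,
                         variant_id = NA_integer_, assay_type = type,
                         pchembl_value = pchembl, year = year,
                         src_id = 1L)
}

test_that("aggregate_pairs computes mean/median/max per domain", {
  recs <- mk_records(1L, 5L, c("B", "B", "F"), c(6, 7, 8))
  agg <- aggregate_pairs(recs, hier)
  expect_equal(agg$pchembl_value_mean_BF, 7)
  expect_equal(agg$pchembl_value_median_BF, 7)
  expect_equal(agg$pchembl_value_max_BF, 8)
  expect_equal(agg$pchembl_value_max_B, 7)

  # single value: mean = median = max
  one <- aggregate_pairs(mk_records(1L, 5L, "F", 7.3), hier)
  expect_equal(one$pchembl_value_mean_BF, 7.3)
  expect_equal(one$pchembl_value_median_BF, 7.3)
  expect_equal(one$pchembl_value_max_BF, 7.3)
  expect_true(is.na(one$pchembl_value_max_B))

  # two domains diverge: B max from B records only
  two <- aggregate_pairs(mk_records(1L, 5L, c("B", "F"), c(6, 9)), hier)
  expect_equal(two$pchembl_value_max_B, 6)
  expect_equal(two$pchembl_value_max_BF, 9)

  # even count: midpoint of the two central values
  ev <- aggregate_pairs(mk_records(1L, 5L, rep("B", 4), c(4, 6, 7, 9)), hier)
  expect_equal(ev$pchembl_value_median_BF, 6.5)
})

test_that("two salts of one parent collapse onto one pair", {
  recs <- mk_records(c(10L, 11L), 5L, "B", c(6, 8))
  agg <- aggregate_pairs(recs, hier)
  expect_identical(nrow(agg), 1L)
  expect_identical(agg$parent_molregno, 1L)
  expect_equal(agg$pchembl_value_mean_BF, 7)
})

test_that("first publication years take minima, absent years drop out", {
  recs <- mk_records(1L, 5L, c("B", "F", "B"), c(6, 7, 8),
                     year = c(2004L, 2001L, 2010L))
  yrs <- first_publication_years(recs, hier)
  expect_equal(yrs$pairs$first_publication_cpd_target_pair_BF, 2001L)
  expect_equal(yrs$pairs$first_publication_cpd_target_pair_B, 2004L)

  noyr <- first_publication_years(mk_records(1L, 5L, "B", 7), hier)
  expect_true(is.na(
    noyr$pairs$first_publication_cpd_target_pair_BF) ||
      nrow(noyr$pairs) == 0L)

  # compound on two targets: compound year is the overall minimum
  two <- mk_records(1L, c(5L, 6L), "B", c(7, 7), year = c(2005L, 2003L))
  expect_equal(first_publication_years(two, hier)$compounds$
                 first_publication_cpd, 2003L)

  # records without pChEMBL feed pair years but not the w_pchembl minima
  mixed <- mk_records(1L, 5L, c("B", "B"), c(NA, 7),
                      year = c(1999L, 2010L))
  p <- first_publication_years(mixed, hier)$pairs
  expect_equal(p$first_publication_cpd_target_pair_BF, 1999L)
  expect_equal(p$first_publication_cpd_target_pair_w_pchembl_BF, 2010L)
})

test_that("aggregation equals the oracle and _B <= _BF on random fixtures", {
  for (seed in c(21L, 22L, 23L)) {
    fx <- build_fixture(fixture_spec(seed = seed))
    res <- run_on_fixture(fx)
    got <- res$dataset
    both <- !is.na(got$pchembl_value_max_B) &
      !is.na(got$pchembl_value_max_BF)
    expect_true(all(got$pchembl_value_max_B[both] <=
                      got$pchembl_value_max_BF[both]))
    # _B present implies _BF present
    expect_false(any(!is.na(got$pchembl_value_max_B) &
                       is.na(got$pchembl_value_max_BF)))
    # mean <= max and median <= max whenever present
    for (dom in c("BF", "B")) {
      m <- got[[paste0("pchembl_value_mean_", dom)]]
      md <- got[[paste0("pchembl_value_median_", dom)]]
      mx <- got[[paste0("pchembl_value_max_", dom)]]
      i <- !is.na(mx)
      expect_true(all(m[i] <= mx[i] + 1e-9))
      expect_true(all(md[i] <= mx[i] + 1e-9))
    }
    expect_matches_truth(res, fx$truth)
  }
})

test_that("aggregation is deterministic and order-independent", {
  recs <- mk_records(1L, 5L, c("B", "F", "B"), c(6, 7, 8),
                     year = c(2004L, 2001L, 2010L))
  a <- aggregate_pairs(recs, hier)
  b <- aggregate_pairs(recs[c(3, 1, 2)], hier)
  expect_equal(a, b)
})
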