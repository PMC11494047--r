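# Shared helpers: run the pipeline on a fixture store and compare results
# with the brute-force truth.

run_on_fixture <- function(fx, rdkit = FALSE, threshold = 100L) {
  h <- open_store(path = fx$path, version = fx$spec$release)
  on.exit(close_store(h), add = TRUE)
  assemble_dataset(h, literature_only = TRUE, rdkit = rdkit,
                   threshold = threshold)
}

# NA-aware column equality; numeric truth values are rounded to the
# pipeline's 4-dp output precision before comparing
col_equal <- function(a, b) {
  if (is.factor(a)) a <- as.character(a)
  if (is.factor(b)) b <- as.character(b)
  if (is.numeric(a) && is.numeric(b)) {
    (is.na(a) & is.na(b)) |
      (!is.na(a) & !is.na(b) & abs(a - round(b, 4)) < 1e-9)
  } else {
    a <- as.character(a)
    b <- as.character(b)
    (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  }
}

expect_matches_truth <- function(res, truth) {
  got <- res$dataset
  want <- data.table::as.data.table(truth$pairs)
  if (nrow(want) > 0L) data.table::setkey(want, parent_molregno, tid)
  expect_equal(nrow(got), nrow(want))
  if (nrow(want) == 0L) return(invisible(NULL))
  for (cn in intersect(names(got), names(want))) {
    ok <- col_equal(got[[cn]], want[[cn]])
    expect_true(all(ok),
                label = sprintf("column '%s' matches oracle (rows %s)", cn,
                                paste(utils::head(which(!ok)),
                                      collapse = ",")))
  }
  s_got <- compute_stats(got, res$variant_keys)
  s_want <- data.table::as.data.table(truth$stats)
  expect_equal(s_got$group, s_want$group)
  for (cn in setdiff(names(s_got), "group")) {
    expect_equal(s_got[[cn]], s_want[[cn]],
                 label = paste("stats column", cn))
  }
  expect_equal(res$removed$n_compounds, truth$removed$n_compounds)
  expect_equal(sort(res$multiclass$tid), truth$multiclass_tids)
  invisible(NULL)
}

# a tiny hand-rolled pair table for subset/stats unit tests
toy_pairs <- function(n_targets = 1L, n_cpds = 3L, dti = "DT",
                      pmax_bf = 7, pmax_b = NA_real_) {
  grid <- data.table::CJ(parent_molregno = seq_len(n_cpds),
                         tid = seq_len(n_targets))
  grid[, `:=`(
    pchembl_value_max_BF = rep_len(pmax_bf, .N),
    pchembl_value_max_B = rep_len(pmax_b, .N),
    DTI = factor(rep_len(dti, .N),
                 levels = c("D_DT", "C3_DT", "C2_DT", "C1_DT", "C0_DT",
                            "DT", "NDT")))]
  grid
}
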