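# Filter columns, subset files and per-dataset statistics.

SUBSET_FLAGS <- c(
  "BF_100", "BF_100_c_dt_d_dt", "BF_100_d_dt", "BF_100_c_dt",
  "B_100", "B_100_c_dt_d_dt", "B_100_d_dt", "B_100_c_dt")

CANDIDATE_CLASSES <- c("C3_DT", "C2_DT", "C1_DT", "C0_DT")

#' Compute boolean subset filter columns
#'
#' For each assay domain (`BF`, `B`): `*_100` is true for every pair whose
#' target has at least `threshold` distinct compounds with a pChEMBL value
#' in that domain; `*_d_dt` additionally requires at least one approved
#' drug pair (DTI `D_DT`) on the target, `*_c_dt` at least one clinical
#' candidate pair (`C3_DT`..`C0_DT`), and `*_c_dt_d_dt` at least one of
#' either.
#'
#' @param dataset Pair table with `DTI` and the pChEMBL max columns.
#' @param threshold Minimum number of active compounds per target
#'   (default 100).
#' @return The dataset with the eight logical flag columns appended.
#' @export
compute_filter_columns <- function(dataset, threshold = 100L) {
  out <- data.table::copy(dataset)
  per_target <- out[, .(
    has_drug = any(as.character(DTI) == "D_DT"),
    has_candidate = any(as.character(DTI) %in% CANDIDATE_CLASSES)),
    by = tid]
  for (dom in c("BF", "B")) {
    pmax_ <- out[[paste0("pchembl_value_max_", dom)]]
    n_cpds <- out[!is.na(pmax_),
                  .(n = data.table::uniqueN(parent_molregno)), by = tid]
    ok_targets <- n_cpds[n >= threshold, tid]
    base <- out$tid %in% ok_targets
    drug <- out$tid %in% per_target[has_drug == TRUE, tid]
    cand <- out$tid %in% per_target[has_candidate == TRUE, tid]
    data.table::set(out, j = paste0(dom, "_100"), value = base)
    data.table::set(out, j = paste0(dom, "_100_c_dt_d_dt"),
                    value = base & (drug | cand))
    data.table::set(out, j = paste0(dom, "_100_d_dt"), value = base & drug)
    data.table::set(out, j = paste0(dom, "_100_c_dt"), value = base & cand)
  }
  out[]
}

count_group <- function(pairs, variants) {
  vk <- merge(variants, pairs[, .(parent_molregno, tid)],
              by = c("parent_molregno", "tid"))
  list(
    n_pairs = nrow(unique(pairs[, .(parent_molregno, tid)])),
    n_pairs_incl_variants = nrow(unique(
      vk[, .(parent_molregno, tid, variant_id)])),
    n_compounds = data.table::uniqueN(pairs$parent_molregno),
    n_targets = data.table::uniqueN(pairs$tid),
    n_targets_incl_variants = nrow(unique(vk[, .(tid, variant_id)])))
}

#' Per-dataset statistics
#'
#' Counts of compound-target pairs, compounds and targets -- each with and
#' without resolving mutation-annotated variant targets -- for the whole
#' dataset and for the drug (`D_DT`), clinical-candidate (`C3..C0_DT`) and
#' comparator (`DT`) groups.
#'
#' A pair without any variant-resolved activity (e.g. a mechanism-only
#' pair) counts once, as its base target, in the "incl. variants" numbers.
#'
#' @param dataset Pair table with `DTI`.
#' @param variant_keys Distinct (parent, tid, variant) activity keys from
#'   [variant_pair_keys()]; pairs absent from it are counted with
#'   `variant_id = NA`.
#' @return `data.table` with one row per group (`total`, `comparator`,
#'   `drugs`, `candidates`) and the five count columns.
#' @export
compute_stats <- function(dataset, variant_keys = NULL) {
  pairs <- unique(dataset[, .(parent_molregno, tid, DTI)])
  if (is.null(variant_keys)) {
    variant_keys <- data.table::data.table(
      parent_molregno = integer(), tid = integer(), variant_id = integer())
  }
  # pairs with no measured variant key contribute their base (NA) variant
  base_keys <- pairs[, .(parent_molregno, tid, variant_id = NA_integer_)]
  measured <- unique(variant_keys[, .(parent_molregno, tid)])
  measured[, has_meas := TRUE]
  base_keys <- merge(base_keys, measured, by = c("parent_molregno", "tid"),
                     all.x = TRUE)
  variants <- rbind(
    unique(variant_keys[, .(parent_molregno, tid, variant_id)]),
    base_keys[is.na(has_meas), .(parent_molregno, tid, variant_id)])
  dti <- as.character(pairs$DTI)
  groups <- list(
    total = pairs,
    comparator = pairs[dti == "DT"],
    drugs = pairs[dti == "D_DT"],
    candidates = pairs[dti %in% CANDIDATE_CLASSES])
  rows <- lapply(names(groups), function(g) {
    c(list(group = g), count_group(groups[[g]], variants))
  })
  data.table::rbindlist(rows)
}

subset_file_name <- function(prefix, flag) {
  paste0(prefix, "_", flag, ".csv")
}

#' Write the full dataset, subsets and statistics files
#'
#' The full dataset is always written; each requested subset file contains
#' the rows whose flag column is true (flag columns retained). Every
#' written dataset is accompanied by a `_stats.csv` file and verified by a
#' write/read round-trip. An optional spreadsheet workbook is attempted
#' when requested; failure to write it is a warning, the delimited-text
#' outputs are authoritative.
#'
#' @param dataset Pair table with flag columns (see
#'   [compute_filter_columns()]).
#' @param output_dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"ChEMBL32_CTI_literature_only"`.
#' @param delimiter Field delimiter (default `";"`).
#' @param write_bf,write_b Write the `BF_*` / `B_*` subset files.
#' @param variant_keys Variant keys for the statistics (may be `NULL`).
#' @param multiclass Multi-class target report to write alongside.
#' @param spreadsheet Also write an `.xlsx` workbook (needs `writexl`).
#' @return Invisibly, a `data.table` manifest of written files with their
#'   round-trip status.
#' @export
write_outputs <- function(dataset, output_dir, prefix, delimiter = ";",
                          write_bf = FALSE, write_b = FALSE,
                          variant_keys = NULL, multiclass = NULL,
                          spreadsheet = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  emit <- function(dt, name, with_stats = TRUE) {
    path <- file.path(output_dir, name)
    write_ctp_file(dt, path, delimiter = delimiter)
    ok <- verify_roundtrip(dt, path, delimiter = delimiter)
    written[[length(written) + 1L]] <<- data.table::data.table(
      file = name, n_rows = nrow(dt), roundtrip_ok = isTRUE(ok))
    if (with_stats) {
      stats <- compute_stats(dt, variant_keys)
      spath <- file.path(output_dir, sub("\\.csv$", "_stats.csv", name))
      write_ctp_file(stats, spath, delimiter = delimiter)
      ok2 <- verify_roundtrip(stats, spath, delimiter = delimiter)
      written[[length(written) + 1L]] <<- data.table::data.table(
        file = basename(spath), n_rows = nrow(stats),
        roundtrip_ok = isTRUE(ok2))
    }
    path
  }
  emit(dataset, paste0(prefix, "_full_dataset.csv"))
  wanted <- c(if (write_bf) grep("^BF_", SUBSET_FLAGS, value = TRUE),
              if (write_b) grep("^B_", SUBSET_FLAGS, value = TRUE))
  for (flag in wanted) {
    emit(dataset[dataset[[flag]] == TRUE], subset_file_name(prefix, flag))
  }
  if (!is.null(multiclass)) {
    emit(multiclass, paste0(prefix, "_targets_w_more_than_one_tclass.csv"),
         with_stats = FALSE)
  }
  if (isTRUE(spreadsheet)) {
    if (requireNamespace("writexl", quietly = TRUE)) {
      tryCatch(
        writexl::write_xlsx(dataset,
                            file.path(output_dir,
                                      paste0(prefix, "_full_dataset.xlsx"))),
        error = function(e) warning("spreadsheet write failed: ",
                                    conditionMessage(e), call. = FALSE))
    } else {
      warning("spreadsheet output requested but 'writexl' is not ",
              "installed; CSV outputs were still written", call. = FALSE)
    }
  }
  invisible(data.table::rbindlist(written))
}
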