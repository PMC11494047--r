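# Cleaning, rounding, consistency checks and write/read round-trips.

PCHEMBL_COLS <- c(
  "pchembl_value_mean_BF", "pchembl_value_median_BF", "pchembl_value_max_BF",
  "pchembl_value_mean_B", "pchembl_value_median_B", "pchembl_value_max_B")

# Sentinel used in written files for missing values; in memory missing is NA.
MISSING_SENTINEL <- "None"

#' Normalise missing values and round numeric columns
#'
#' Empty strings and NaN values become the canonical missing value (`NA` in
#' memory, written as `"None"`); whole-number double columns are converted
#' to a nullable integer representation; every floating-point column except
#' `max_phase` is rounded to four decimal places (round-half-even, R's
#' default IEEE rounding).
#'
#' @param dataset A pair `data.table`.
#' @return A normalised copy (idempotent: applying it twice equals once).
#' @export
normalize_and_round <- function(dataset) {
  out <- data.table::copy(dataset)
  for (col in names(out)) {
    v <- out[[col]]
    if (is.character(v)) {
      v[!is.na(v) & (v == "" | v == MISSING_SENTINEL | v == "nan")] <-
        NA_character_
      data.table::set(out, j = col, value = v)
    } else if (is.factor(v)) {
      data.table::set(out, j = col, value = as.character(v))
    } else if (is.double(v) && col != "max_phase") {
      v[is.nan(v)] <- NA_real_
      if (all(is.na(v) | v == floor(v))) {
        data.table::set(out, j = col, value = as.integer(v))
      } else {
        data.table::set(out, j = col, value = round(v, 4))
      }
    }
  }
  out[]
}

#' Run the basic consistency checks
#'
#' Checks performed over the cleaned dataset:
#' \itemize{
#'   \item `uniform_missing`: no empty strings, `"None"`/`"nan"` strings or
#'     NaN values survive in any column;
#'   \item `no_mixed_types`: every column is a single atomic type;
#'   \item `pchembl_less_in_dm`: every pair without any pChEMBL value is in
#'     the mechanism table;
#'   \item `missing_counts`: per-column missing counts equal the
#'     expectations derived from source-table availability;
#'   \item `no_ndt`: no NDT pair survives in the final dataset.
#' }
#'
#' @param dataset Cleaned pair `data.table` with `DTI` and `in_dm_table`.
#' @param expected_missing Named integer vector: expected `NA` count per
#'   column (only the named columns are checked). May be `NULL`.
#' @return A `validation_report`: list with `checks` (`data.table` of
#'   name/expected/observed/pass) and `overall`.
#' @export
run_basic_checks <- function(dataset, expected_missing = NULL) {
  checks <- list()
  add <- function(name, expected, observed) {
    checks[[length(checks) + 1L]] <<- data.table::data.table(
      name = name, expected = as.character(expected),
      observed = as.character(observed),
      pass = identical(as.character(expected), as.character(observed)))
  }

  bad_strings <- sum(vapply(dataset, function(v) {
    if (!is.character(v)) return(0L)
    sum(!is.na(v) & (v == "" | v == MISSING_SENTINEL | v == "nan"))
  }, integer(1)))
  nan_vals <- sum(vapply(dataset, function(v) {
    if (!is.double(v)) return(0L)
    sum(is.nan(v))
  }, integer(1)))
  add("uniform_missing", 0L, bad_strings + nan_vals)

  mixed <- sum(vapply(dataset, function(v) {
    !(is.atomic(v) && length(class(v)) == 1L)
  }, logical(1)))
  add("no_mixed_types", 0L, mixed)

  present <- intersect(PCHEMBL_COLS, names(dataset))
  no_pchembl <- Reduce(`&`, lapply(present, function(cn) is.na(dataset[[cn]])))
  add("pchembl_less_in_dm", 0L,
      sum(no_pchembl & !as.logical(dataset$in_dm_table)))

  if (!is.null(expected_missing)) {
    for (col in names(expected_missing)) {
      add(paste0("missing_count:", col), expected_missing[[col]],
          sum(is.na(dataset[[col]])))
    }
  }

  add("no_ndt", 0L, sum(!is.na(dataset$DTI) & dataset$DTI == "NDT"))

  checks <- data.table::rbindlist(checks)
  report <- list(checks = checks, overall = all(checks$pass))
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation:", if (x$overall) "PASS" else "FAIL", "\n")
  print(x$checks)
  invisible(x)
}

#' Expected missing-value counts for annotation columns
#'
#' Bookkeeping used by the missing-count checks: expectations are derived
#' from the joined availability of source values (e.g. an LE metric is
#' missing exactly when the domain pChEMBL or the property operand is).
#'
#' @param dataset Annotated pair table (before cleaning is fine).
#' @return Named integer vector of expected `NA` counts.
#' @export
expected_missing_counts <- function(dataset) {
  exp <- c(
    structure(sum(is.na(dataset$atc_level1)), names = "atc_level1"),
    structure(sum(is.na(dataset$target_class_l1)),
              names = "target_class_l1"))
  for (dom in c("BF", "B")) {
    pmax_ <- dataset[[paste0("pchembl_value_max_", dom)]]
    ops <- list(LE = dataset$heavy_atoms, BEI = dataset$mw_freebase,
                SEI = dataset$psa, LLE = dataset$alogp)
    for (m in names(ops)) {
      den_bad <- if (m == "LLE") is.na(ops[[m]])
                 else is.na(ops[[m]]) | ops[[m]] <= 0
      exp[paste0(m, "_", dom)] <- sum(is.na(pmax_) | den_bad)
    }
  }
  exp
}

#' Verify a written file round-trips to the in-memory dataset
#'
#' Reads the file back with the same dialect and compares value-for-value
#' after canonical missing/rounding normalisation. On mismatch the first
#' differing cell is reported in the `mismatch` attribute and via a
#' message.
#'
#' @param dataset In-memory `data.table` that was written.
#' @param path File that was written.
#' @param delimiter Field delimiter used when writing.
#' @return `TRUE` on an exact round-trip, else `FALSE`.
#' @export
verify_roundtrip <- function(dataset, path, delimiter = ";") {
  back <- tryCatch(
    read_ctp_file(path, delimiter = delimiter),
    error = function(e) e)
  if (inherits(back, "error")) {
    message("round-trip read failed: ", conditionMessage(back))
    return(structure(FALSE, mismatch = "parse error"))
  }
  ref <- normalize_and_round(dataset)
  if (!identical(dim(ref), dim(back)) ||
      !identical(names(ref), names(back))) {
    message("round-trip shape mismatch: wrote ", nrow(ref), "x", ncol(ref),
            ", read ", nrow(back), "x", ncol(back))
    return(structure(FALSE, mismatch = "shape"))
  }
  for (col in names(ref)) {
    a <- ref[[col]]; b <- back[[col]]
    if (is.factor(a)) a <- as.character(a)
    if (is.logical(b) && !is.logical(a)) b <- as.character(b)
    if (is.numeric(a) && is.numeric(b)) {
      same <- (is.na(a) & is.na(b)) |
        (!is.na(a) & !is.na(b) & abs(a - b) < 1e-9)
    } else {
      a <- as.character(a); b <- as.character(b)
      same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
    }
    if (!all(same)) {
      i <- which(!same)[1L]
      message("round-trip mismatch at row ", i, ", column '", col,
              "': wrote ", a[i], ", read ", b[i])
      return(structure(FALSE, mismatch = sprintf("%s[%d]", col, i)))
    }
  }
  TRUE
}

#' Write a dataset file in the pipeline dialect
#'
#' Delimiter-separated text, UTF-8, `\n` newlines, missing values written
#' as `"None"`.
#'
#' @param dataset `data.table` to write.
#' @param path Output path.
#' @param delimiter Field delimiter (default `";"`).
#' @export
write_ctp_file <- function(dataset, path, delimiter = ";") {
  out <- data.table::copy(dataset)
  for (col in names(out)) {
    if (is.factor(out[[col]])) {
      data.table::set(out, j = col, value = as.character(out[[col]]))
    }
  }
  data.table::fwrite(out, path, sep = delimiter, na = MISSING_SENTINEL,
                     quote = "auto", eol = "\n", bom = FALSE,
                     scipen = 999L)
  invisible(path)
}

#' Read a dataset file written by [write_ctp_file()]
#' @param path File path.
#' @param delimiter Field delimiter.
#' @return `data.table`.
#' @export
read_ctp_file <- function(path, delimiter = ";") {
  data.table::fread(path, sep = delimiter, na.strings = MISSING_SENTINEL,
                    encoding = "UTF-8", logical01 = FALSE)
}
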