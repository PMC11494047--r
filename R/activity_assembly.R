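# Parent mapping and per-pair pChEMBL / first-publication aggregation.

#' Map molecules to their parent compound
#'
#' Every molecule is identified by the root of its molecule hierarchy; salt
#' forms are dropped in favour of the parent. A molecule absent from the
#' hierarchy maps to itself.
#'
#' @param molregno Integer vector of molecule keys.
#' @param hierarchy `data.table` with `molregno`, `parent_molregno`.
#' @return Integer vector of parent keys, same length as `molregno`.
#' @export
map_to_parent <- function(molregno, hierarchy) {
  if (anyDuplicated(hierarchy$molregno)) {
    dup <- hierarchy[duplicated(molregno) |
                       duplicated(molregno, fromLast = TRUE)]
    dup <- dup[, .(n = data.table::uniqueN(parent_molregno)), by = molregno]
    bad <- dup[n > 1L, molregno]
    if (length(bad) > 0L) {
      stop("molecule(s) with more than one distinct parent in ",
           "MOLECULE_HIERARCHY: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  idx <- match(molregno, hierarchy$molregno)
  parent <- hierarchy$parent_molregno[idx]
  parent[is.na(idx)] <- molregno[is.na(idx)]
  # a NULL parent entry also falls back to the molecule itself
  parent[is.na(parent)] <- molregno[is.na(parent)]
  as.integer(parent)
}

agg_one_domain <- function(dt, suffix) {
  gmax <- function(x) if (length(x)) max(x) else NA_real_  # empty-safe
  out <- dt[, .(mean_ = mean(pchembl_value),
                median_ = stats::median(pchembl_value),
                max_ = gmax(pchembl_value)),
            by = .(parent_molregno, tid)]
  data.table::setnames(out, c("mean_", "median_", "max_"),
    paste0(c("pchembl_value_mean_", "pchembl_value_median_",
             "pchembl_value_max_"), suffix))
  out
}

#' Aggregate activity records into per-pair pChEMBL summaries
#'
#' Records are grouped by (parent compound, target) after parent mapping.
#' pChEMBL values are aggregated into the arithmetic mean, the sample
#' median and the maximum -- once over binding and functional assays
#' combined (`_BF` suffix) and once over binding assays only (`_B`).
#'
#' @param records Activity records from [fetch_activity_records()] with a
#'   present pChEMBL value.
#' @param hierarchy Molecule hierarchy table.
#' @return `data.table` keyed by `parent_molregno`, `tid` with the six
#'   aggregate columns; `_B` columns are `NA` for pairs measured only in
#'   functional assays.
#' @export
aggregate_pairs <- function(records, hierarchy) {
  rec <- data.table::copy(records)
  rec[, parent_molregno := map_to_parent(molregno, hierarchy)]
  bf <- agg_one_domain(rec, "BF")
  b <- agg_one_domain(rec[assay_type == "B"], "B")
  out <- merge(bf, b, by = c("parent_molregno", "tid"), all.x = TRUE)
  data.table::setkey(out, parent_molregno, tid)
  out[]
}

year_minima <- function(dt, col) {
  gmin <- function(x) if (length(x)) min(x) else NA_integer_
  dt[!is.na(year), stats::setNames(.(gmin(year)), col),
     by = .(parent_molregno, tid)]
}

#' First-publication years per pair and per compound
#'
#' The publication year of each record's document is aggregated into the
#' year of the first publication of the compound-target pair and the year
#' of the first publication associated with a pChEMBL value, per assay
#' domain. The per-compound first publication year is the minimum over all
#' of the compound's qualifying records.
#'
#' @param records_all Activity records with the pChEMBL presence
#'   requirement lifted (`require_pchembl = FALSE`).
#' @param hierarchy Molecule hierarchy table.
#' @return List with `pairs` (per-pair year columns for both domains) and
#'   `compounds` (`parent_molregno`, `first_publication_cpd`).
#' @export
first_publication_years <- function(records_all, hierarchy) {
  rec <- data.table::copy(records_all)
  rec[, parent_molregno := map_to_parent(molregno, hierarchy)]
  recp <- rec[!is.na(pchembl_value) & pchembl_value > 0]
  parts <- list(
    year_minima(rec, "first_publication_cpd_target_pair_BF"),
    year_minima(recp, "first_publication_cpd_target_pair_w_pchembl_BF"),
    year_minima(rec[assay_type == "B"], "first_publication_cpd_target_pair_B"),
    year_minima(recp[assay_type == "B"],
                "first_publication_cpd_target_pair_w_pchembl_B")
  )
  pairs <- Reduce(function(a, b)
    merge(a, b, by = c("parent_molregno", "tid"), all = TRUE), parts)
  gmin <- function(x) if (length(x)) min(x) else NA_integer_
  compounds <- rec[!is.na(year),
                   .(first_publication_cpd = gmin(year)),
                   by = parent_molregno]
  list(pairs = pairs, compounds = compounds)
}

#' Variant-resolved pair keys
#'
#' Distinct (parent, target, variant) combinations among the qualifying
#' records; used only for the "incl. variant targets" statistics.
#'
#' @param records Activity records (pChEMBL-bearing).
#' @param hierarchy Molecule hierarchy table.
#' @return `data.table` with `parent_molregno`, `tid`, `variant_id`
#'   (`NA` = base target).
#' @export
variant_pair_keys <- function(records, hierarchy) {
  rec <- data.table::copy(records)
  rec[, parent_molregno := map_to_parent(molregno, hierarchy)]
  unique(rec[, .(parent_molregno, tid, variant_id)])
}
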