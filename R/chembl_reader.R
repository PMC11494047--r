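#' @import data.table
#' @importFrom stats median
#' @importFrom utils packageVersion
NULL

# Tables every store must contain (ChEMBL schema subset read by the pipeline).
REQUIRED_TABLES <- c(
  "ACTIVITIES", "ASSAYS", "DOCS", "MOLECULE_HIERARCHY", "MOLECULE_DICTIONARY",
  "DRUG_MECHANISM", "TARGET_RELATIONS", "TARGET_DICTIONARY",
  "COMPOUND_PROPERTIES", "COMPOUND_STRUCTURES", "MOLECULE_ATC_CLASSIFICATION",
  "PROTEIN_CLASSIFICATION", "TARGET_COMPONENTS", "COMPONENT_CLASS"
)

# ChEMBL sentinel for the "Unchecked" target; activities on it are dropped.
UNCHECKED_TARGET_TID <- 22226L

# src_id of the scientific-literature source channel in the ChEMBL SRC table.
LITERATURE_SRC_ID <- 1L

#' Open a ChEMBL-schema SQLite store
#'
#' Opens a single-file relational database in the ChEMBL schema and verifies
#' that every table the pipeline reads is present. The store can be given as
#' a file path or requested by release number; fetching by release number
#' uses the standard ChEMBL distribution mechanism and therefore requires
#' network access, which this build does not provide -- supplying a path is
#' the supported route.
#'
#' @param path Path to an existing SQLite database file, or `NULL`.
#' @param version Integer ChEMBL release number (>= 26), or `NULL`. Used to
#'   record the release for release-dependent `max_phase` semantics; when a
#'   `path` is also given the file at `path` is opened and `version` is only
#'   recorded. Without a `path`, fetching by version is unsupported offline
#'   and raises an error.
#' @return A `chembl_store` handle (list with the DBI connection, `path` and
#'   `release`; `release` is `NA` when unknown).
#' @export
open_store <- function(path = NULL, version = NULL) {
  if (!is.null(version)) {
    version <- as.integer(version)
    if (is.na(version) || version < 26L) {
      stop("ChEMBL 26 is the earliest release supported; got release ",
           version, call. = FALSE)
    }
  }
  if (is.null(path)) {
    if (is.null(version)) {
      stop("no store given: supply 'path' (offline builds cannot determine ",
           "the latest release)", call. = FALSE)
    }
    stop("fetching ChEMBL release ", version, " requires network access; ",
         "supply a downloaded SQLite file via 'path'", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("store file not found: ", path, call. = FALSE)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  tabs <- toupper(DBI::dbListTables(con))
  missing <- setdiff(REQUIRED_TABLES, tabs)
  if (length(missing) > 0L) {
    DBI::dbDisconnect(con)
    stop("store schema is missing required table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  handle <- list(con = con, path = path,
                 release = if (is.null(version)) NA_integer_ else version)
  class(handle) <- "chembl_store"
  handle
}

#' Close a store handle
#' @param handle A `chembl_store` handle.
#' @export
close_store <- function(handle) {
  stopifnot(inherits(handle, "chembl_store"))
  DBI::dbDisconnect(handle$con)
  invisible(NULL)
}

#' @export
print.chembl_store <- function(x, ...) {
  cat("<chembl_store> ", x$path, " (release ",
      if (is.na(x$release)) "unknown" else x$release, ")\n", sep = "")
  invisible(x)
}

store_query <- function(handle, sql) {
  stopifnot(inherits(handle, "chembl_store"))
  data.table::setDT(DBI::dbGetQuery(handle$con, sql))
}

#' Fetch qualifying activity records
#'
#' Streams one row per activity measurement that passes the record-level
#' filters: assay type B (binding) or F (functional), `POTENTIAL_DUPLICATE`
#' equal to 0, `DATA_VALIDITY_COMMENT` absent or "Manually validated", and
#' the unchecked-target sentinel (TID 22226) excluded. With
#' `literature_only` (the default) only activities whose document comes from
#' the scientific-literature source channel (`DOCS.SRC_ID = 1`) are kept.
#'
#' @param handle A `chembl_store` handle.
#' @param literature_only Keep only literature-sourced records (default
#'   `TRUE`).
#' @param require_pchembl When `TRUE` (default) only records with a present,
#'   positive pChEMBL value are emitted -- these feed the pChEMBL
#'   aggregation. With `FALSE` the pChEMBL presence requirement is lifted
#'   (all other filters stay), which is the record set used for
#'   first-publication years.
#' @return A `data.table` with columns `molregno`, `tid`, `variant_id`,
#'   `assay_type`, `pchembl_value`, `year`, `src_id`. May be empty.
#' @export
fetch_activity_records <- function(handle, literature_only = TRUE,
                                   require_pchembl = TRUE) {
  sql <- paste(
    "SELECT act.molregno AS molregno, ass.tid AS tid,",
    "       ass.variant_id AS variant_id, ass.assay_type AS assay_type,",
    "       act.pchembl_value AS pchembl_value, d.year AS year,",
    "       d.src_id AS src_id",
    "FROM ACTIVITIES act",
    "JOIN ASSAYS ass ON ass.assay_id = act.assay_id",
    "JOIN DOCS d ON d.doc_id = act.doc_id",
    "WHERE ass.assay_type IN ('B','F')",
    "  AND act.potential_duplicate = 0",
    "  AND (act.data_validity_comment IS NULL",
    "       OR act.data_validity_comment = 'Manually validated')",
    sprintf("  AND ass.tid <> %d", UNCHECKED_TARGET_TID)
  )
  if (require_pchembl) {
    sql <- paste(sql, "AND act.pchembl_value IS NOT NULL",
                 "AND act.pchembl_value > 0")
  }
  if (literature_only) {
    sql <- paste(sql, sprintf("AND d.src_id = %d", LITERATURE_SRC_ID))
  }
  out <- store_query(handle, sql)
  out[, `:=`(molregno = as.integer(molregno), tid = as.integer(tid),
             variant_id = as.integer(variant_id),
             pchembl_value = as.numeric(pchembl_value),
             year = as.integer(year))]
  out[]
}

#' Fetch curated mechanism-of-action rows
#'
#' Returns the `DRUG_MECHANISM` rows restricted to entries whose
#' disease-efficacy flag is 1, i.e. interactions believed to drive the
#' compound's efficacy in its approved indication.
#'
#' @param handle A `chembl_store` handle.
#' @return `data.table` with `molregno`, `tid`, `disease_efficacy`.
#' @export
fetch_mechanisms <- function(handle) {
  out <- store_query(handle, paste(
    "SELECT molregno, tid, disease_efficacy FROM DRUG_MECHANISM",
    "WHERE disease_efficacy = 1 AND tid IS NOT NULL AND molregno IS NOT NULL"
  ))
  out[, `:=`(molregno = as.integer(molregno), tid = as.integer(tid))]
  out[]
}

#' Fetch target relations
#' @param handle A `chembl_store` handle.
#' @return `data.table` with `tid`, `relationship`, `related_tid` plus the
#'   target types of both sides (joined from `TARGET_DICTIONARY`).
#' @export
fetch_target_relations <- function(handle) {
  out <- store_query(handle, paste(
    "SELECT tr.tid AS tid, tr.relationship AS relationship,",
    "       tr.related_tid AS related_tid,",
    "       td1.target_type AS target_type,",
    "       td2.target_type AS related_target_type",
    "FROM TARGET_RELATIONS tr",
    "LEFT JOIN TARGET_DICTIONARY td1 ON td1.tid = tr.tid",
    "LEFT JOIN TARGET_DICTIONARY td2 ON td2.tid = tr.related_tid"
  ))
  out[, `:=`(tid = as.integer(tid), related_tid = as.integer(related_tid))]
  out[]
}

#' Fetch compound-side tables
#'
#' Verbatim reads of the hierarchy, dictionary, property, structure and ATC
#' tables, restricted to the columns downstream stages use.
#'
#' @param handle A `chembl_store` handle.
#' @return Named list of `data.table`s: `hierarchy` (molregno,
#'   parent_molregno), `dictionary` (molregno, chembl_id, max_phase),
#'   `properties`, `structures`, `atc`.
#' @export
fetch_compound_tables <- function(handle) {
  hierarchy <- store_query(handle,
    "SELECT molregno, parent_molregno FROM MOLECULE_HIERARCHY")
  dictionary <- store_query(handle,
    "SELECT molregno, chembl_id, max_phase FROM MOLECULE_DICTIONARY")
  properties <- store_query(handle, paste(
    "SELECT molregno, mw_freebase, alogp, psa, hba, hbd, rtb,",
    "       num_ro5_violations, aromatic_rings, heavy_atoms, qed_weighted",
    "FROM COMPOUND_PROPERTIES"))
  structures <- store_query(handle, paste(
    "SELECT molregno, canonical_smiles, standard_inchi, standard_inchi_key",
    "FROM COMPOUND_STRUCTURES"))
  atc <- store_query(handle,
    "SELECT molregno, level1 FROM MOLECULE_ATC_CLASSIFICATION")
  for (dt in list(hierarchy, dictionary, properties, structures, atc)) {
    dt[, molregno := as.integer(molregno)]
  }
  hierarchy[, parent_molregno := as.integer(parent_molregno)]
  list(hierarchy = hierarchy[], dictionary = dictionary[],
       properties = properties[], structures = structures[], atc = atc[])
}

#' Fetch per-target protein classes
#'
#' Joins `TARGET_COMPONENTS` -> `COMPONENT_CLASS` -> `PROTEIN_CLASSIFICATION`
#' and resolves each assigned class to its level-1 and level-2 ancestors by
#' walking the classification hierarchy.
#'
#' @param handle A `chembl_store` handle.
#' @return `data.table` with `tid`, `l1`, `l2` (one row per distinct
#'   assignment; `l2` is `NA` for classes at level 1).
#' @export
fetch_target_classes <- function(handle) {
  assign <- store_query(handle, paste(
    "SELECT tc.tid AS tid, cc.protein_class_id AS protein_class_id",
    "FROM TARGET_COMPONENTS tc",
    "JOIN COMPONENT_CLASS cc ON cc.component_id = tc.component_id"))
  classes <- store_query(handle, paste(
    "SELECT protein_class_id, parent_id, pref_name, class_level",
    "FROM PROTEIN_CLASSIFICATION"))
  if (nrow(assign) == 0L) {
    return(data.table(tid = integer(), l1 = character(), l2 = character()))
  }
  classes[, `:=`(protein_class_id = as.integer(protein_class_id),
                 parent_id = as.integer(parent_id),
                 class_level = as.integer(class_level))]
  by_id <- split(classes, by = "protein_class_id", keep.by = TRUE)
  resolve_levels <- function(pcid) {
    l1 <- NA_character_; l2 <- NA_character_
    seen <- 0L
    while (!is.na(pcid) && seen < 32L) {
      row <- by_id[[as.character(pcid)]]
      if (is.null(row)) break
      if (row$class_level == 1L) l1 <- row$pref_name
      if (row$class_level == 2L) l2 <- row$pref_name
      pcid <- row$parent_id
      seen <- seen + 1L
    }
    list(l1 = l1, l2 = l2)
  }
  assign[, `:=`(tid = as.integer(tid),
                protein_class_id = as.integer(protein_class_id))]
  lv <- lapply(assign$protein_class_id, resolve_levels)
  assign[, `:=`(l1 = vapply(lv, `[[`, character(1), "l1"),
                l2 = vapply(lv, `[[`, character(1), "l2"))]
  unique(assign[!is.na(l1), .(tid, l1, l2)])
}
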