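# Compound/target annotations: structures, properties, ligand-efficiency
# metrics, ATC codes, target classes and optional RDKit descriptors.

#' Attach compound structures and drop undefined or mixture compounds
#'
#' Joins canonical SMILES, InChI and InChI key onto each pair by parent
#' compound. Compounds without a SMILES and compounds whose SMILES contains
#' a full stop (mixtures, salts that survived parent mapping) are removed
#' from the dataset; a per-reason removal report is returned.
#'
#' @param pairs Pair table with `parent_molregno`.
#' @param structures Structure rows (`molregno`, `canonical_smiles`,
#'   `standard_inchi`, `standard_inchi_key`).
#' @return List with `pairs` (structure columns attached, offending
#'   compounds removed) and `removed` (`data.table` of
#'   `reason`/`n_compounds`).
#' @export
attach_structures_and_filter <- function(pairs, structures) {
  out <- merge(pairs, structures, by.x = "parent_molregno",
               by.y = "molregno", all.x = TRUE)
  no_smiles <- is.na(out$canonical_smiles) | out$canonical_smiles == ""
  mixture <- !no_smiles & grepl(".", out$canonical_smiles, fixed = TRUE)
  removed <- data.table::data.table(
    reason = c("missing_smiles", "smiles_with_full_stop"),
    n_compounds = c(data.table::uniqueN(out$parent_molregno[no_smiles]),
                    data.table::uniqueN(out$parent_molregno[mixture])))
  list(pairs = out[!no_smiles & !mixture], removed = removed)
}

#' Ligand-efficiency metrics
#'
#' Standard efficiency metrics computed from a pChEMBL value and stored
#' compound properties:
#' \itemize{
#'   \item LE  = 1.37 * pChEMBL / heavy atoms (kcal/mol per heavy atom,
#'     approximating the binding free energy at 300 K),
#'   \item BEI = pChEMBL * 1000 / MW (Da), i.e. pChEMBL per kDa,
#'   \item SEI = pChEMBL / (PSA / 100 A^2),
#'   \item LLE = pChEMBL - calculated logP.
#' }
#' Each metric is `NA` whenever an operand is missing or its denominator
#' is not positive.
#'
#' @param pchembl Numeric vector (the domain-matched maximum pChEMBL).
#' @param heavy_atoms,mw,psa,logp Numeric property vectors.
#' @return `data.table` with columns `LE`, `BEI`, `SEI`, `LLE`.
#' @export
compute_ligand_efficiencies <- function(pchembl, heavy_atoms, mw, psa, logp) {
  safe_div <- function(num, den) {
    ifelse(is.na(num) | is.na(den) | den <= 0, NA_real_, num / den)
  }
  data.table::data.table(
    LE = safe_div(1.37 * pchembl, heavy_atoms),
    BEI = safe_div(pchembl * 1000, mw),
    SEI = safe_div(pchembl, psa / 100),
    LLE = ifelse(is.na(pchembl) | is.na(logp), NA_real_, pchembl - logp))
}

#' Concatenate level-1 ATC codes per compound
#'
#' Distinct codes are sorted alphabetically and joined with `|`.
#'
#' @param codes Character vector of level-1 ATC codes for one compound.
#' @return Single string, or `NA` if there are no codes.
#' @export
concat_atc <- function(codes) {
  codes <- unique(codes[!is.na(codes) & codes != ""])
  if (length(codes) == 0L) return(NA_character_)
  paste(sort(codes), collapse = "|")
}

concat_labels <- concat_atc  # same rule for target class labels

#' Attach target class annotations
#'
#' Per-target level-1 and level-2 protein class labels; multiple
#' assignments at a level are concatenated alphabetically with `|`. Targets
#' with more than one label at either level are listed once in the
#' multi-class report (these could be reassigned by hand downstream).
#'
#' @param pairs Pair table with `tid`.
#' @param target_classes Rows from [fetch_target_classes()].
#' @return List with `pairs` (columns `target_class_l1`, `target_class_l2`
#'   added) and `multiclass` (report `data.table`: `tid`, `target_class_l1`,
#'   `target_class_l2`).
#' @export
attach_target_classes <- function(pairs, target_classes) {
  if (nrow(target_classes) > 0L) {
    per_target <- target_classes[, .(
      target_class_l1 = concat_labels(l1),
      target_class_l2 = concat_labels(l2),
      n_l1 = data.table::uniqueN(l1[!is.na(l1)]),
      n_l2 = data.table::uniqueN(l2[!is.na(l2)])), by = tid]
  } else {
    per_target <- data.table::data.table(
      tid = integer(), target_class_l1 = character(),
      target_class_l2 = character(), n_l1 = integer(), n_l2 = integer())
  }
  multiclass <- per_target[n_l1 > 1L | n_l2 > 1L,
                           .(tid, target_class_l1, target_class_l2)]
  data.table::setkey(multiclass, tid)
  out <- merge(pairs,
               per_target[, .(tid, target_class_l1, target_class_l2)],
               by = "tid", all.x = TRUE)
  list(pairs = out, multiclass = multiclass[])
}

toolkit_descriptor_columns <- function() {
  c("fraction_csp3", "n_heteroatoms", "n_stereocenters",
    "n_aliphatic_rings", "n_aliphatic_carbocycles",
    "n_aliphatic_heterocycles", "n_aromatic_rings",
    "n_aromatic_carbocycles", "n_aromatic_heterocycles",
    "n_saturated_rings", "n_saturated_carbocycles",
    "n_saturated_heterocycles", "n_aromatic_atoms", "n_aromatic_c",
    "n_aromatic_n", "n_aromatic_hetero", "scaffold_w_stereo",
    "scaffold_wo_stereo")
}

#' RDKit-based compound descriptors
#'
#' Computes, for each SMILES, the fraction of sp3 carbons, heteroatom and
#' stereocenter counts (assigned plus unassigned), nine ring counts
#' ([aliphatic/aromatic/saturated] x [rings/carbocycles/heterocycles]),
#' aromatic-atom counts (total, carbon, nitrogen, hetero) obtained by
#' iterating atoms under RDKit's default aromaticity model, and
#' Bemis-Murcko scaffold SMILES with and without stereochemistry. The
#' scaffold of an acyclic molecule is the empty string.
#'
#' The computation is delegated to a bundled Python helper (RDKit has no R
#' distribution); `python` with the `rdkit` module must be on the PATH.
#' Unparseable SMILES yield all-`NA` rows with a warning.
#'
#' @param smiles Character vector of SMILES strings.
#' @param python Python interpreter to use (default `"python"`).
#' @return `data.table` with one row per input SMILES and the columns
#'   listed above (prefixed counts are integers).
#' @export
compute_toolkit_descriptors <- function(smiles, python = "python") {
  script <- system.file("python", "descriptors.py", package = "ctpairs")
  if (script == "" || Sys.which(python) == "") {
    stop("RDKit descriptor stage needs the bundled python helper and a ",
         "python interpreter with rdkit on the PATH", call. = FALSE)
  }
  uniq <- unique(smiles[!is.na(smiles)])
  empty <- data.table::data.table(canonical_smiles = character())
  for (col in toolkit_descriptor_columns()) {
    empty[, (col) := if (grepl("^scaffold|^fraction", col)) character()
          else integer()]
  }
  if (length(uniq) == 0L) {
    return(empty[data.table::data.table(canonical_smiles = smiles),
                 on = "canonical_smiles"])
  }
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(uniq, infile)
  status <- system2(python, c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile)) {
    stop("python RDKit helper failed (exit status ", status, ")",
         call. = FALSE)
  }
  desc <- data.table::fread(outfile, sep = ",", na.strings = "",
                            colClasses = list(character = "canonical_smiles"))
  if (any(desc$parse_error == 1L)) {
    warning(sum(desc$parse_error), " SMILES could not be parsed by RDKit; ",
            "descriptors set to NA", call. = FALSE)
  }
  desc[, parse_error := NULL]
  desc[, fraction_csp3 := as.numeric(fraction_csp3)]
  int_cols <- grep("^n_", toolkit_descriptor_columns(), value = TRUE)
  desc[, (int_cols) := lapply(.SD, as.integer), .SDcols = int_cols]
  out <- desc[data.table::data.table(canonical_smiles = smiles),
              on = "canonical_smiles"]
  out[]
}

#' Attach all compound and target annotations to a pair table
#'
#' Convenience wrapper running structure filtering, property join,
#' ligand-efficiency computation, ATC and target class annotation and the
#' optional RDKit descriptor stage in order.
#'
#' @param pairs Pair table (aggregates + DTI + `max_phase`).
#' @param compound_tables List from [fetch_compound_tables()].
#' @param target_classes Rows from [fetch_target_classes()].
#' @param first_pub_compounds Per-compound first publication years.
#' @param rdkit Compute toolkit descriptors (default `FALSE`).
#' @param python Python interpreter for the descriptor stage.
#' @return List with `pairs`, `removed`, `multiclass`.
#' @export
annotate_pairs <- function(pairs, compound_tables, target_classes,
                           first_pub_compounds, rdkit = FALSE,
                           python = "python") {
  st <- attach_structures_and_filter(pairs, compound_tables$structures)
  out <- st$pairs
  out <- merge(out, compound_tables$properties, by.x = "parent_molregno",
               by.y = "molregno", all.x = TRUE)
  out <- merge(out, first_pub_compounds, by = "parent_molregno", all.x = TRUE)
  atc <- compound_tables$atc[, .(atc_level1 = concat_atc(level1)),
                             by = molregno]
  out <- merge(out, atc, by.x = "parent_molregno", by.y = "molregno",
               all.x = TRUE)
  for (dom in c("BF", "B")) {
    le <- compute_ligand_efficiencies(
      out[[paste0("pchembl_value_max_", dom)]],
      out$heavy_atoms, out$mw_freebase, out$psa, out$alogp)
    data.table::setnames(le, paste0(names(le), "_", dom))
    out <- cbind(out, le)
  }
  tc <- attach_target_classes(out, target_classes)
  out <- tc$pairs
  if (isTRUE(rdkit)) {
    desc <- compute_toolkit_descriptors(out$canonical_smiles, python = python)
    desc[, canonical_smiles := NULL]
    out <- cbind(out, desc)
  }
  list(pairs = out, removed = st$removed, multiclass = tc$multiclass)
}
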