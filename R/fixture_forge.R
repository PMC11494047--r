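# Miniature ChEMBL-schema stores with controllable composition, for testing
# the pipeline without downloads. Not a statistically faithful ChEMBL
# simulator; chemistry realism stops at parseable SMILES.

# valid, parseable SMILES pool (assigned to parent compounds round-robin)
FIXTURE_SMILES <- c(
  "CCO", "c1ccccc1", "c1ccncc1", "c1ccoc1", "CC(=O)Oc1ccccc1C(=O)O",
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "C[C@H](N)C(=O)O", "O=C(O)c1ccccc1O", "CCN(CC)CC", "C1CCCCC1",
  "c1ccc2ccccc2c1", "CC(=O)Nc1ccc(O)cc1", "Clc1ccccc1", "OCC1OC(O)C(O)C(O)C1O")
MIXTURE_SMILES <- "CC(=O)[O-].[Na+]"

#' Describe a synthetic mini-ChEMBL store
#'
#' Collects every knob of the fixture generator with defaults sized for a
#' desk-scale store: a few dozen compounds and a handful of targets, dense
#' enough that pairs with multiple measurements, salts, variants, families
#' and mechanism-only pairs all occur.
#'
#' @param n_parents Number of parent compounds.
#' @param n_salts_per_parent Extra salt forms per parent (mapped to the
#'   parent through the hierarchy).
#' @param n_targets Number of single-protein targets.
#' @param n_variant_targets How many targets carry mutation-variant assays.
#' @param density Named probabilities that a (molecule, target, assay type)
#'   combination has an activity row, per assay type.
#' @param pchembl_range Range pChEMBL values are drawn from.
#' @param frac_missing_pchembl Fraction of activity rows lacking a pChEMBL
#'   value (they still count for first-publication years).
#' @param frac_missing_year Fraction of documents without a year.
#' @param n_mechanism_rows Number of curated mechanism rows.
#' @param max_phase_pool Pool the per-parent maximum clinical phase is
#'   drawn from (`NA` = preclinical).
#' @param include_family Add a protein family target plus its whitelisted
#'   (and one non-whitelisted) relations.
#' @param include_decoys Emit rows that must be filtered out: assay type A,
#'   potential duplicates, validity-flagged rows, a non-literature source
#'   and activities on the unchecked-target sentinel.
#' @param frac_missing_structure,frac_mixture_smiles Fractions of parents
#'   without a structure row / with a mixture (full-stop) SMILES.
#' @param frac_missing_properties Fraction of parents without a property
#'   row.
#' @param frac_unclassified_targets Fraction of targets without any protein
#'   class.
#' @param n_multiclass_targets Targets given two classes at level 1.
#' @param year_range Publication-year range of the documents.
#' @param release ChEMBL release number the store claims (drives
#'   `max_phase` semantics).
#' @param seed Integer seed; fixes the store byte-for-byte.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_parents = 12L, n_salts_per_parent = 1L,
                         n_targets = 4L, n_variant_targets = 1L,
                         density = c(B = 0.45, F = 0.30, A = 0.15),
                         pchembl_range = c(4, 10),
                         frac_missing_pchembl = 0.15,
                         frac_missing_year = 0.10,
                         n_mechanism_rows = 4L,
                         max_phase_pool = c(4, 3, 2, 1, 0.5, -1, NA),
                         include_family = TRUE,
                         include_decoys = TRUE,
                         frac_missing_structure = 0.10,
                         frac_mixture_smiles = 0.10,
                         frac_missing_properties = 0.10,
                         frac_unclassified_targets = 0.25,
                         n_multiclass_targets = 1L,
                         year_range = c(1995L, 2020L),
                         release = 32L,
                         seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_parents >= 0, n_salts_per_parent >= 0, n_targets >= 0,
            n_variant_targets <= n_targets, n_mechanism_rows >= 0)
  n_slots <- (n_parents * (1L + n_salts_per_parent)) *
    (n_targets + include_family)
  if (n_mechanism_rows > max(n_slots, 0L)) {
    stop("impossible spec: ", n_mechanism_rows, " mechanism rows but only ",
         n_slots, " compound-target slots", call. = FALSE)
  }
  class(spec) <- "fixture_spec"
  spec
}

# generate the raw in-memory tables for a spec (deterministic given seed)
fixture_tables <- function(spec) {
  set.seed(spec$seed)
  P <- spec$n_parents
  S <- spec$n_salts_per_parent
  parents <- seq_len(P)
  salts <- if (S > 0L && P > 0L) (P + 1L):(P + P * S) else integer()
  salt_parent <- if (length(salts)) rep(parents, each = S) else integer()
  molecules <- c(parents, salts)
  mol_parent <- c(parents, salt_parent)

  hierarchy <- data.frame(molregno = molecules, parent_molregno = mol_parent)

  pool <- spec$max_phase_pool
  phases <- pool[sample.int(length(pool), P, replace = TRUE)]
  dictionary <- data.frame(
    molregno = molecules,
    chembl_id = paste0("CHEMBL", molecules),
    max_phase = c(phases, rep(NA_real_, length(salts))))

  tids <- if (spec$n_targets > 0L) 100L + seq_len(spec$n_targets) else integer()
  family_tid <- if (spec$include_family) 201L else integer()
  target_dictionary <- data.frame(
    tid = c(tids, family_tid,
            if (spec$include_decoys) 22226L else integer()),
    chembl_id = paste0("CHEMBL", 100000L +
                         c(tids, family_tid,
                           if (spec$include_decoys) 22226L else integer())),
    pref_name = c(paste0("Target ", tids),
                  if (spec$include_family) "Target family" else character(),
                  if (spec$include_decoys) "Unchecked" else character()),
    target_type = c(rep("SINGLE PROTEIN", length(tids)),
                    if (spec$include_family) "PROTEIN FAMILY" else character(),
                    if (spec$include_decoys) "UNCHECKED" else character()),
    stringsAsFactors = FALSE)

  relations <- data.frame(tid = integer(), relationship = character(),
                          related_tid = integer(), stringsAsFactors = FALSE)
  if (spec$include_family && length(tids) >= 2L) {
    relations <- rbind(
      relations,
      data.frame(tid = family_tid, relationship = "SUPERSET OF",
                 related_tid = tids[1:2]),
      # reverse direction: not on the whitelist, must never be followed
      data.frame(tid = tids[1:2], relationship = "SUBSET OF",
                 related_tid = family_tid))
    if (length(tids) >= 4L) {
      relations <- rbind(relations, data.frame(
        tid = tids[3L], relationship = "EQUIVALENT TO",
        related_tid = tids[4L]))
    }
  }

  n_docs <- 8L
  doc_years <- sample(seq(spec$year_range[1], spec$year_range[2]), n_docs,
                      replace = TRUE)
  doc_years[stats::runif(n_docs) < spec$frac_missing_year] <- NA_integer_
  doc_src <- rep(1L, n_docs)
  if (spec$include_decoys && n_docs >= 2L) doc_src[n_docs] <- 37L
  docs <- data.frame(doc_id = seq_len(n_docs), year = doc_years,
                     src_id = doc_src)

  variant_tids <- if (spec$n_variant_targets > 0L)
    tids[seq_len(spec$n_variant_targets)] else integer()

  assay_rows <- list(); act_rows <- list()
  assay_id <- 0L; act_id <- 0L
  types <- c("B", "F", if (spec$include_decoys) "A")
  act_tids <- c(tids, if (spec$include_decoys) 22226L else integer())
  for (m in molecules) {
    for (t in act_tids) {
      for (ty in types) {
        dens <- spec$density[[ty]]
        if (is.null(dens) || is.na(dens)) dens <- 0
        if (stats::runif(1) >= dens) next
        assay_id <- assay_id + 1L; act_id <- act_id + 1L
        variant <- if (t %in% variant_tids && stats::runif(1) < 0.4)
          500L + sample.int(2L, 1L) else NA_integer_
        doc <- sample.int(n_docs, 1L)
        pchembl <- round(stats::runif(1, spec$pchembl_range[1],
                                      spec$pchembl_range[2]), 2)
        if (stats::runif(1) < spec$frac_missing_pchembl) pchembl <- NA_real_
        dup <- 0L; validity <- NA_character_
        if (spec$include_decoys) {
          r <- stats::runif(1)
          if (r < 0.05) dup <- 1L
          else if (r < 0.10) validity <- "Outside typical range"
          else if (r < 0.15) validity <- "Manually validated"
        }
        assay_rows[[assay_id]] <- data.frame(
          assay_id = assay_id, assay_type = ty, tid = t,
          variant_id = variant, doc_id = doc, stringsAsFactors = FALSE)
        act_rows[[act_id]] <- data.frame(
          activity_id = act_id, assay_id = assay_id, doc_id = doc,
          molregno = m, pchembl_value = pchembl, potential_duplicate = dup,
          data_validity_comment = validity, stringsAsFactors = FALSE)
      }
    }
  }
  assays <- if (length(assay_rows)) do.call(rbind, assay_rows) else
    data.frame(assay_id = integer(), assay_type = character(),
               tid = integer(), variant_id = integer(), doc_id = integer())
  activities <- if (length(act_rows)) do.call(rbind, act_rows) else
    data.frame(activity_id = integer(), assay_id = integer(),
               doc_id = integer(), molregno = integer(),
               pchembl_value = numeric(), potential_duplicate = integer(),
               data_validity_comment = character())

  mech_tids <- c(tids, family_tid)
  mech <- data.frame(mec_id = integer(), molregno = integer(),
                     tid = integer(), disease_efficacy = integer())
  if (spec$n_mechanism_rows > 0L && length(molecules) > 0L &&
      length(mech_tids) > 0L) {
    slots <- expand.grid(molregno = molecules, tid = mech_tids)
    pick <- slots[sample.int(nrow(slots),
                             min(spec$n_mechanism_rows, nrow(slots))), ]
    mech <- data.frame(mec_id = seq_len(nrow(pick)),
                       molregno = pick$molregno, tid = pick$tid,
                       disease_efficacy = 1L)
    if (spec$include_decoys && nrow(mech) > 1L) {
      mech$disease_efficacy[nrow(mech)] <- 0L
    }
  }

  has_prop <- stats::runif(P) >= spec$frac_missing_properties
  properties <- data.frame(
    molregno = parents[has_prop],
    mw_freebase = round(stats::runif(sum(has_prop), 150, 600), 2),
    alogp = round(stats::runif(sum(has_prop), -2, 7), 2),
    psa = round(stats::runif(sum(has_prop), 20, 200), 2),
    hba = sample(0:10, sum(has_prop), replace = TRUE),
    hbd = sample(0:5, sum(has_prop), replace = TRUE),
    rtb = sample(0:12, sum(has_prop), replace = TRUE),
    num_ro5_violations = sample(0:2, sum(has_prop), replace = TRUE),
    aromatic_rings = sample(0:4, sum(has_prop), replace = TRUE),
    heavy_atoms = sample(10:50, sum(has_prop), replace = TRUE),
    qed_weighted = round(stats::runif(sum(has_prop)), 3))

  u <- stats::runif(P)
  has_struct <- u >= spec$frac_missing_structure
  is_mixture <- has_struct &
    (u < spec$frac_missing_structure + spec$frac_mixture_smiles)
  smi <- FIXTURE_SMILES[((parents - 1L) %% length(FIXTURE_SMILES)) + 1L]
  smi[is_mixture] <- MIXTURE_SMILES
  structures <- data.frame(
    molregno = parents[has_struct],
    canonical_smiles = smi[has_struct],
    standard_inchi = paste0("InChI=1S/FIX", parents[has_struct]),
    standard_inchi_key = sprintf("FIXKEY%08d", parents[has_struct]),
    stringsAsFactors = FALSE)

  atc_pool <- c("A", "C", "J", "L", "N")
  atc_rows <- list()
  for (p in parents) {
    k <- sample(0:2, 1L, prob = c(0.6, 0.3, 0.1))
    if (k > 0L) {
      atc_rows[[length(atc_rows) + 1L]] <- data.frame(
        molregno = p, level1 = sample(atc_pool, k), stringsAsFactors = FALSE)
    }
  }
  atc <- if (length(atc_rows)) do.call(rbind, atc_rows) else
    data.frame(molregno = integer(), level1 = character())

  protein_classification <- data.frame(
    protein_class_id = c(10L, 11L, 20L, 21L, 30L),
    parent_id = c(NA, 10L, NA, 20L, NA),
    pref_name = c("Enzyme", "Kinase", "Membrane receptor", "Family A GPCR",
                  "Ion channel"),
    class_level = c(1L, 2L, 1L, 2L, 1L), stringsAsFactors = FALSE)
  leaf_pool <- c(11L, 21L, 30L)
  tc_rows <- list(); cc_rows <- list(); comp_id <- 0L
  classified <- stats::runif(length(tids)) >= spec$frac_unclassified_targets
  multi <- tids[classified][seq_len(min(spec$n_multiclass_targets,
                                        sum(classified)))]
  for (i in seq_along(tids)) {
    if (!classified[i]) next
    comp_id <- comp_id + 1L
    cls <- leaf_pool[((i - 1L) %% length(leaf_pool)) + 1L]
    tc_rows[[length(tc_rows) + 1L]] <-
      data.frame(tid = tids[i], component_id = comp_id)
    cc_rows[[length(cc_rows) + 1L]] <-
      data.frame(component_id = comp_id, protein_class_id = cls)
    if (tids[i] %in% multi) {
      comp_id <- comp_id + 1L
      other <- leaf_pool[(i %% length(leaf_pool)) + 1L]
      tc_rows[[length(tc_rows) + 1L]] <-
        data.frame(tid = tids[i], component_id = comp_id)
      cc_rows[[length(cc_rows) + 1L]] <-
        data.frame(component_id = comp_id, protein_class_id = other)
    }
  }
  target_components <- if (length(tc_rows)) do.call(rbind, tc_rows) else
    data.frame(tid = integer(), component_id = integer())
  component_class <- if (length(cc_rows)) do.call(rbind, cc_rows) else
    data.frame(component_id = integer(), protein_class_id = integer())

  list(ACTIVITIES = activities, ASSAYS = assays, DOCS = docs,
       MOLECULE_HIERARCHY = hierarchy, MOLECULE_DICTIONARY = dictionary,
       DRUG_MECHANISM = mech, TARGET_RELATIONS = relations,
       TARGET_DICTIONARY = target_dictionary,
       COMPOUND_PROPERTIES = properties, COMPOUND_STRUCTURES = structures,
       MOLECULE_ATC_CLASSIFICATION = atc,
       PROTEIN_CLASSIFICATION = protein_classification,
       TARGET_COMPONENTS = target_components,
       COMPONENT_CLASS = component_class)
}

write_fixture_store <- function(tables, path) {
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (name in names(tables)) {
    DBI::dbWriteTable(con, name, tables[[name]])
  }
  invisible(path)
}

#' Build a synthetic mini-ChEMBL store with its ground truth
#'
#' Generates the raw tables for a [fixture_spec()], writes them to a
#' single-file SQLite store and computes the expected pipeline outputs with
#' the independent brute-force oracle ([compute_fixture_truth()]).
#'
#' @param spec A `fixture_spec`.
#' @param path Where to write the store (default: a temp file).
#' @return List with `path`, `tables` (the raw in-memory tables), `truth`
#'   (oracle expectations) and `spec`.
#' @export
build_fixture <- function(spec, path = tempfile(fileext = ".db")) {
  tables <- fixture_tables(spec)
  write_fixture_store(tables, path)
  truth <- compute_fixture_truth(tables, release = spec$release)
  list(path = path, tables = tables, truth = truth, spec = spec)
}

#' Edge-case fixture suite
#'
#' Hand-tuned specs covering: mechanism-only pairs, mixture SMILES,
#' unclassified and multi-class targets, relation expansion, the full
#' modern `max_phase` code set, empty activity tables, and a store with no
#' salts or decoys at all.
#'
#' @return Named list of `fixture_spec`s.
#' @export
edge_case_suite <- function() {
  list(
    mechanism_only = fixture_spec(
      n_parents = 6L, n_targets = 3L,
      density = c(B = 0, F = 0, A = 0), n_mechanism_rows = 5L,
      include_decoys = FALSE, seed = 101L),
    mixtures_and_missing = fixture_spec(
      n_parents = 10L, frac_missing_structure = 0.3,
      frac_mixture_smiles = 0.3, seed = 102L),
    multiclass_targets = fixture_spec(
      n_targets = 6L, n_multiclass_targets = 3L,
      frac_unclassified_targets = 0.4, seed = 103L),
    relation_expansion = fixture_spec(
      n_parents = 8L, n_targets = 5L, include_family = TRUE,
      n_mechanism_rows = 6L, seed = 104L),
    modern_phases = fixture_spec(
      max_phase_pool = c(0.5, -1, NA), n_mechanism_rows = 6L, seed = 105L),
    legacy_phases = fixture_spec(
      max_phase_pool = c(4, 3, 2, 1, 0), release = 31L,
      n_mechanism_rows = 6L, seed = 106L),
    no_activities_no_mech = fixture_spec(
      n_parents = 4L, n_targets = 2L,
      density = c(B = 0, F = 0, A = 0), n_mechanism_rows = 0L,
      include_decoys = FALSE, seed = 107L),
    plain_dense = fixture_spec(
      n_parents = 15L, n_salts_per_parent = 2L, n_targets = 5L,
      density = c(B = 0.7, F = 0.5, A = 0), include_decoys = FALSE,
      frac_missing_structure = 0, frac_mixture_smiles = 0, seed = 108L))
}
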