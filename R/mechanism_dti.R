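# Mechanism-of-action integration and drug-target interaction (DTI) classes.

# Whitelisted (original type, relationship, related type) triples; target
# expansion follows these relations only, single hop.
RELATION_WHITELIST <- data.table::data.table(
  target_type = c("PROTEIN FAMILY", "PROTEIN COMPLEX", "PROTEIN COMPLEX GROUP",
                  "SINGLE PROTEIN", "CHIMERIC PROTEIN",
                  "PROTEIN-PROTEIN INTERACTION"),
  relationship = c("SUPERSET OF", "SUPERSET OF", "SUPERSET OF",
                   "EQUIVALENT TO", "SUPERSET OF", "SUPERSET OF"),
  related_target_type = rep("SINGLE PROTEIN", 6L)
)

DTI_LEVELS <- c("D_DT", "C3_DT", "C2_DT", "C1_DT", "C0_DT", "DT", "NDT")

admissible_relations <- function(relations) {
  rel <- data.table::copy(relations)
  rel[, `:=`(target_type = toupper(target_type),
             relationship = toupper(relationship),
             related_target_type = toupper(related_target_type))]
  merge(rel, RELATION_WHITELIST,
        by = c("target_type", "relationship", "related_target_type"))
}

#' Expand target keys through whitelisted relations
#'
#' Maps a target to the union of itself and all targets reachable by one
#' admissible relation. Only six relation triples are followed (protein
#' family/complex/complex group/chimeric protein/protein-protein
#' interaction superset-of single protein, and single protein
#' equivalent-to single protein); expansion is single hop, no transitive
#' closure.
#'
#' @param tid Integer target key.
#' @param relations Relations table from [fetch_target_relations()].
#' @return Integer vector of target keys including `tid` itself.
#' @export
expand_targets <- function(tid, relations) {
  adm <- admissible_relations(relations)
  related <- adm$related_tid[adm$tid == tid]
  sort(unique(c(tid, related[!is.na(related)])))
}

# vectorised internal: mechanism rows -> expanded (molregno, tid) pairs
expand_mechanism_targets <- function(mechanisms, relations) {
  adm <- admissible_relations(relations)
  orig <- mechanisms[, .(molregno, tid)]
  mapped <- merge(mechanisms[, .(molregno, tid)], adm[, .(tid, related_tid)],
                  by = "tid", allow.cartesian = TRUE)
  mapped <- mapped[, .(molregno, tid = related_tid)]
  unique(rbind(orig, mapped))
}

#' Merge mechanism pairs into the aggregated pair collection
#'
#' Curated disease-efficacy mechanism pairs (compound keys parent-mapped,
#' target keys expanded through the relation whitelist) are merged with the
#' measured-activity pairs: existing pairs get `in_dm_table = TRUE`; pairs
#' not yet present are appended with all pChEMBL fields absent.
#'
#' @param aggregates Pair aggregates from [aggregate_pairs()].
#' @param mechanisms Mechanism rows (`disease_efficacy = 1`).
#' @param relations Relations table.
#' @param hierarchy Molecule hierarchy table.
#' @return List with `pairs` (aggregates plus `in_dm_table` and appended
#'   mechanism-only rows) and `therapeutic_targets` (integer vector: all
#'   targets occurring in any mechanism row after expansion).
#' @export
merge_mechanism_pairs <- function(aggregates, mechanisms, relations,
                                  hierarchy) {
  mech <- expand_mechanism_targets(mechanisms, relations)
  mech[, molregno := map_to_parent(molregno, hierarchy)]
  mech <- unique(mech)
  data.table::setnames(mech, "molregno", "parent_molregno")
  pairs <- data.table::copy(aggregates)
  pairs[, in_dm_table := FALSE]
  mech[, in_dm_table_mech := TRUE]
  pairs <- merge(pairs, mech, by = c("parent_molregno", "tid"), all = TRUE)
  pairs[, in_dm_table := !is.na(in_dm_table_mech)]
  pairs[, in_dm_table_mech := NULL]
  list(pairs = pairs[],
       therapeutic_targets = sort(unique(mech$tid)))
}

#' Assign a drug-target interaction class to each pair
#'
#' Pairs in the mechanism table are classed by the compound's maximum
#' clinical phase: phase 4 is `D_DT` (approved drug on its known target),
#' phases 3/2/1 are `C3_DT`/`C2_DT`/`C1_DT`, and anything below phase 1 is
#' `C0_DT`. Pairs not in the mechanism table are `DT` when the target is
#' therapeutic (occurs in some mechanism row) and `NDT` otherwise; `NDT`
#' rows are discarded from the final dataset by the caller.
#'
#' `max_phase` semantics are release-dependent: up to release 31 "below
#' phase 1" means phase 0; from release 32 (and for unknown releases) it
#' means 0.5 (early phase 1), -1 (clinical phase unknown) or `NA`
#' (preclinical).
#'
#' @param in_dm_table Logical vector: pair is in the mechanism table.
#' @param max_phase Numeric vector of maximum clinical phases (may be `NA`).
#' @param tid Integer vector of target keys.
#' @param therapeutic_targets Integer vector of therapeutic target keys.
#' @param release Integer ChEMBL release or `NA` (treated as >= 32).
#' @return Factor with levels `r paste(DTI_LEVELS, collapse = ", ")`.
#' @export
assign_dti <- function(in_dm_table, max_phase, tid, therapeutic_targets,
                       release = NA_integer_) {
  legacy <- !is.na(release) && release <= 31L
  sub1 <- if (legacy) {
    function(p) !is.na(p) & p == 0
  } else {
    function(p) is.na(p) | p == 0.5 | p == -1
  }
  known <- c(4, 3, 2, 1, if (legacy) 0 else c(0.5, -1))
  bad <- in_dm_table & !is.na(max_phase) & !(max_phase %in% known)
  if (any(bad)) {
    stop("unknown max_phase code(s) for release ",
         if (is.na(release)) ">=32" else release, ": ",
         paste(unique(max_phase[bad]), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(in_dm_table))
  out[in_dm_table & !is.na(max_phase) & max_phase == 4] <- "D_DT"
  out[in_dm_table & !is.na(max_phase) & max_phase == 3] <- "C3_DT"
  out[in_dm_table & !is.na(max_phase) & max_phase == 2] <- "C2_DT"
  out[in_dm_table & !is.na(max_phase) & max_phase == 1] <- "C1_DT"
  out[in_dm_table & sub1(max_phase)] <- "C0_DT"
  therap <- tid %in% therapeutic_targets
  out[!in_dm_table & therap] <- "DT"
  out[!in_dm_table & !therap] <- "NDT"
  factor(out, levels = DTI_LEVELS)
}
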