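# Brute-force ground truth for fixture stores. Deliberately written as
# straight-line loops over the raw tables, sharing no logic with the
# pipeline modules: independence is the point, speed is not.

oracle_parent <- function(m, hierarchy) {
  for (i in seq_len(nrow(hierarchy))) {
    if (hierarchy$molregno[i] == m && !is.na(hierarchy$parent_molregno[i])) {
      return(hierarchy$parent_molregno[i])
    }
  }
  m
}

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# whitelisted relation triples, re-stated independently
oracle_relation_ok <- function(orig_type, rel, related_type) {
  key <- paste(toupper(orig_type), toupper(rel), toupper(related_type))
  key %in% c(
    "PROTEIN FAMILY SUPERSET OF SINGLE PROTEIN",
    "PROTEIN COMPLEX SUPERSET OF SINGLE PROTEIN",
    "PROTEIN COMPLEX GROUP SUPERSET OF SINGLE PROTEIN",
    "SINGLE PROTEIN EQUIVALENT TO SINGLE PROTEIN",
    "CHIMERIC PROTEIN SUPERSET OF SINGLE PROTEIN",
    "PROTEIN-PROTEIN INTERACTION SUPERSET OF SINGLE PROTEIN")
}

#' Brute-force expected outputs for a fixture store
#'
#' Recomputes the whole pipeline result by naive enumeration over the raw
#' fixture tables: record filters, parent mapping, per-pair aggregation,
#' mechanism merge with single-hop target expansion, DTI assignment,
#' structure-based removal, filter flags and group statistics.
#'
#' @param tables Raw tables as produced by the fixture generator.
#' @param release ChEMBL release number (drives `max_phase` semantics).
#' @param literature_only Restrict to literature-sourced documents.
#' @param threshold Active-compound threshold for the `*_100` flags.
#' @return List: `pairs` (expected dataset rows with aggregates, years,
#'   `in_dm_table`, `DTI` and flag columns), `stats`, `removed`,
#'   `multiclass_tids`, `therapeutic_targets`, `variant_keys`.
#' @export
compute_fixture_truth <- function(tables, release = 32L,
                                  literature_only = TRUE, threshold = 100L) {
  act <- tables$ACTIVITIES; ass <- tables$ASSAYS; docs <- tables$DOCS
  hier <- tables$MOLECULE_HIERARCHY; dict <- tables$MOLECULE_DICTIONARY
  mech <- tables$DRUG_MECHANISM; rels <- tables$TARGET_RELATIONS
  tdict <- tables$TARGET_DICTIONARY

  # -- qualifying records (with and without the pChEMBL requirement) -----
  recs <- list()
  for (i in seq_len(nrow(act))) {
    ai <- which(ass$assay_id == act$assay_id[i])
    if (length(ai) != 1) next
    di <- which(docs$doc_id == act$doc_id[i])
    if (length(di) != 1) next
    if (!(ass$assay_type[ai] %in% c("B", "F"))) next
    if (act$potential_duplicate[i] != 0) next
    dv <- act$data_validity_comment[i]
    if (!is.na(dv) && dv != "Manually validated") next
    if (ass$tid[ai] == 22226) next
    if (literature_only && docs$src_id[di] != 1) next
    recs[[length(recs) + 1]] <- list(
      parent = oracle_parent(act$molregno[i], hier),
      tid = ass$tid[ai], variant = ass$variant_id[ai],
      type = ass$assay_type[ai], pchembl = act$pchembl_value[i],
      year = docs$year[di])
  }
  has_p <- vapply(recs, function(r) !is.na(r$pchembl) && r$pchembl > 0,
                  logical(1))

  # -- per-pair aggregates over pChEMBL-bearing records ------------------
  pkeys <- unique(lapply(recs[has_p], function(r) c(r$parent, r$tid)))
  pair_rows <- list()
  for (k in pkeys) {
    vals_bf <- c(); vals_b <- c()
    yr_all_bf <- c(); yr_all_b <- c(); yr_p_bf <- c(); yr_p_b <- c()
    for (j in seq_along(recs)) {
      r <- recs[[j]]
      if (r$parent != k[1] || r$tid != k[2]) next
      if (has_p[j]) {
        vals_bf <- c(vals_bf, r$pchembl)
        if (r$type == "B") vals_b <- c(vals_b, r$pchembl)
        if (!is.na(r$year)) {
          yr_p_bf <- c(yr_p_bf, r$year)
          if (r$type == "B") yr_p_b <- c(yr_p_b, r$year)
        }
      }
      if (!is.na(r$year)) {
        yr_all_bf <- c(yr_all_bf, r$year)
        if (r$type == "B") yr_all_b <- c(yr_all_b, r$year)
      }
    }
    mn <- function(x) if (length(x)) min(x) else NA_integer_
    pair_rows[[length(pair_rows) + 1]] <- data.frame(
      parent_molregno = k[1], tid = k[2],
      pchembl_value_mean_BF = mean(vals_bf),
      pchembl_value_median_BF = oracle_median(vals_bf),
      pchembl_value_max_BF = max(vals_bf),
      pchembl_value_mean_B = if (length(vals_b)) mean(vals_b) else NA_real_,
      pchembl_value_median_B =
        if (length(vals_b)) oracle_median(vals_b) else NA_real_,
      pchembl_value_max_B = if (length(vals_b)) max(vals_b) else NA_real_,
      first_publication_cpd_target_pair_BF = mn(yr_all_bf),
      first_publication_cpd_target_pair_w_pchembl_BF = mn(yr_p_bf),
      first_publication_cpd_target_pair_B = mn(yr_all_b),
      first_publication_cpd_target_pair_w_pchembl_B = mn(yr_p_b))
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(parent_molregno = integer(), tid = integer(),
               pchembl_value_mean_BF = numeric(),
               pchembl_value_median_BF = numeric(),
               pchembl_value_max_BF = numeric(),
               pchembl_value_mean_B = numeric(),
               pchembl_value_median_B = numeric(),
               pchembl_value_max_B = numeric(),
               first_publication_cpd_target_pair_BF = integer(),
               first_publication_cpd_target_pair_w_pchembl_BF = integer(),
               first_publication_cpd_target_pair_B = integer(),
               first_publication_cpd_target_pair_w_pchembl_B = integer())

  # per-compound first publication year
  cpd_year <- list()
  for (j in seq_along(recs)) {
    r <- recs[[j]]
    if (is.na(r$year)) next
    key <- as.character(r$parent)
    cpd_year[[key]] <- min(c(cpd_year[[key]], r$year))
  }

  # -- mechanism pairs with single-hop expansion -------------------------
  ttype <- function(t) {
    i <- which(tdict$tid == t)
    if (length(i) == 1) tdict$target_type[i] else NA_character_
  }
  mech_pairs <- list()
  for (i in seq_len(nrow(mech))) {
    if (mech$disease_efficacy[i] != 1) next
    p <- oracle_parent(mech$molregno[i], hier)
    t0 <- mech$tid[i]
    targets <- t0
    for (j in seq_len(nrow(rels))) {
      if (rels$tid[j] != t0) next
      if (oracle_relation_ok(ttype(rels$tid[j]), rels$relationship[j],
                             ttype(rels$related_tid[j]))) {
        targets <- c(targets, rels$related_tid[j])
      }
    }
    for (t in unique(targets)) {
      mech_pairs[[length(mech_pairs) + 1]] <- c(p, t)
    }
  }
  mech_pairs <- unique(mech_pairs)
  therapeutic <- sort(unique(vapply(mech_pairs,
                                    function(x) as.numeric(x[2]),
                                    numeric(1))))

  # merge: flag existing, append new
  pairs$in_dm_table <- logical(nrow(pairs))
  for (mp in mech_pairs) {
    hit <- which(pairs$parent_molregno == mp[1] & pairs$tid == mp[2])
    if (length(hit) == 1) {
      pairs$in_dm_table[hit] <- TRUE
    } else {
      new <- pairs[0, ][1, ]
      new$parent_molregno <- mp[1]; new$tid <- mp[2]
      new$in_dm_table <- TRUE
      pairs <- rbind(pairs, new)
    }
  }

  # -- DTI ---------------------------------------------------------------
  phase_of <- function(p) {
    i <- which(dict$molregno == p)
    if (length(i) == 1) dict$max_phase[i] else NA_real_
  }
  dti <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ph <- phase_of(pairs$parent_molregno[i])
    if (pairs$in_dm_table[i]) {
      if (!is.na(ph) && ph == 4) dti[i] <- "D_DT"
      else if (!is.na(ph) && ph == 3) dti[i] <- "C3_DT"
      else if (!is.na(ph) && ph == 2) dti[i] <- "C2_DT"
      else if (!is.na(ph) && ph == 1) dti[i] <- "C1_DT"
      else if (release <= 31) {
        if (!is.na(ph) && ph == 0) dti[i] <- "C0_DT"
      } else if (is.na(ph) || ph %in% c(0.5, -1)) dti[i] <- "C0_DT"
    } else {
      dti[i] <- if (pairs$tid[i] %in% therapeutic) "DT" else "NDT"
    }
  }
  pairs$DTI <- dti
  pairs <- pairs[pairs$DTI != "NDT", , drop = FALSE]

  # -- structure removal -------------------------------------------------
  st <- tables$COMPOUND_STRUCTURES
  keep <- logical(nrow(pairs)); reason <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    si <- which(st$molregno == pairs$parent_molregno[i])
    if (length(si) != 1 || is.na(st$canonical_smiles[si]) ||
        st$canonical_smiles[si] == "") {
      reason[i] <- "missing_smiles"
    } else if (grepl(".", st$canonical_smiles[si], fixed = TRUE)) {
      reason[i] <- "smiles_with_full_stop"
    } else {
      keep[i] <- TRUE
    }
  }
  removed <- data.frame(
    reason = c("missing_smiles", "smiles_with_full_stop"),
    n_compounds = c(
      length(unique(pairs$parent_molregno[reason == "missing_smiles"])),
      length(unique(
        pairs$parent_molregno[reason == "smiles_with_full_stop"]))))
  pairs <- pairs[keep, , drop = FALSE]

  pairs$first_publication_cpd <- rep(NA_integer_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    y <- cpd_year[[as.character(pairs$parent_molregno[i])]]
    if (!is.null(y)) pairs$first_publication_cpd[i] <- y
  }

  # -- filter flags ------------------------------------------------------
  for (dom in c("BF", "B")) {
    col <- paste0("pchembl_value_max_", dom)
    base <- logical(nrow(pairs)); drug <- logical(nrow(pairs))
    cand <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      t <- pairs$tid[i]
      on_t <- pairs$tid == t
      n_cpd <- length(unique(pairs$parent_molregno[on_t &
                                                     !is.na(pairs[[col]])]))
      base[i] <- n_cpd >= threshold
      drug[i] <- any(pairs$DTI[on_t] == "D_DT")
      cand[i] <- any(pairs$DTI[on_t] %in%
                       c("C3_DT", "C2_DT", "C1_DT", "C0_DT"))
    }
    pairs[[paste0(dom, "_100")]] <- base
    pairs[[paste0(dom, "_100_c_dt_d_dt")]] <- base & (drug | cand)
    pairs[[paste0(dom, "_100_d_dt")]] <- base & drug
    pairs[[paste0(dom, "_100_c_dt")]] <- base & cand
  }

  # -- variant keys and group statistics ---------------------------------
  vkeys <- unique(do.call(rbind, c(list(
    data.frame(parent_molregno = integer(), tid = integer(),
               variant_id = integer())),
    lapply(recs[has_p], function(r) data.frame(
      parent_molregno = r$parent, tid = r$tid,
      variant_id = if (is.na(r$variant)) NA_integer_ else r$variant)))))

  grp_stats <- function(sel) {
    sub <- pairs[sel, , drop = FALSE]
    vk <- merge(vkeys, sub[, c("parent_molregno", "tid")],
                by = c("parent_molregno", "tid"))
    extra <- 0L; extra_t <- character()
    for (i in seq_len(nrow(sub))) {
      m <- vk$parent_molregno == sub$parent_molregno[i] &
        vk$tid == sub$tid[i]
      if (!any(m)) {
        extra <- extra + 1L
        extra_t <- c(extra_t, paste(sub$tid[i], NA))
      }
    }
    vt <- unique(c(paste(vk$tid, vk$variant_id), extra_t))
    data.frame(
      n_pairs = nrow(unique(sub[, c("parent_molregno", "tid")])),
      n_pairs_incl_variants = nrow(unique(vk)) + extra,
      n_compounds = length(unique(sub$parent_molregno)),
      n_targets = length(unique(sub$tid)),
      n_targets_incl_variants = length(vt))
  }
  dtiv <- pairs$DTI
  stats <- cbind(
    data.frame(group = c("total", "comparator", "drugs", "candidates")),
    rbind(grp_stats(rep(TRUE, nrow(pairs))),
          grp_stats(dtiv == "DT"),
          grp_stats(dtiv == "D_DT"),
          grp_stats(dtiv %in% c("C3_DT", "C2_DT", "C1_DT", "C0_DT"))))

  # multi-class targets
  tcl <- merge(merge(tables$TARGET_COMPONENTS, tables$COMPONENT_CLASS,
                     by = "component_id"),
               tables$PROTEIN_CLASSIFICATION, by = "protein_class_id")
  multiclass <- integer()
  for (t in unique(tcl$tid)) {
    rows <- tcl[tcl$tid == t, ]
    l1 <- character(); l2 <- character()
    for (i in seq_len(nrow(rows))) {
      pc <- rows$protein_class_id[i]
      while (!is.na(pc)) {
        j <- which(tables$PROTEIN_CLASSIFICATION$protein_class_id == pc)
        if (length(j) != 1) break
        lvl <- tables$PROTEIN_CLASSIFICATION$class_level[j]
        nm <- tables$PROTEIN_CLASSIFICATION$pref_name[j]
        if (lvl == 1) l1 <- c(l1, nm)
        if (lvl == 2) l2 <- c(l2, nm)
        pc <- tables$PROTEIN_CLASSIFICATION$parent_id[j]
      }
    }
    if (length(unique(l1)) > 1 || length(unique(l2)) > 1) {
      multiclass <- c(multiclass, t)
    }
  }

  list(pairs = pairs, stats = stats, removed = removed,
       multiclass_tids = sort(multiclass),
       therapeutic_targets = therapeutic,
       variant_keys = vkeys)
}
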