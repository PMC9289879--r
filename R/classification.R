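# Molecule novelty classification against a reference drug ring set.
#
# A "new" ring system is one whose canonical key is not in the reference
# drug set (exact match). Classes:
#   class1  only drug ring systems
#   class2  drug ring systems plus exactly one new ring system
#   class3  drug ring systems plus two or more new ring systems
#   class4a a single ring system, and it is new
#   class4b two or more ring systems, all new
#   class5  no ring systems

CLASS_LEVELS <- c("class1", "class2", "class3", "class4a", "class4b", "class5")

#' Classify one molecule by ring-system novelty
#'
#' @param rings Character vector of canonical ring keys present in the
#'   molecule (deduplicated; may be empty).
#' @param drug_rings Character vector of reference drug ring keys.
#' @return A list of class `molecule_class` with `label`, `n_ring_systems`,
#'   `n_novel`.
#' @export
classify_molecule <- function(rings, drug_rings) {
  rings <- unique(rings[!is.na(rings) & nzchar(rings)])
  n <- length(rings)
  novel <- setdiff(rings, drug_rings)
  k <- length(novel)
  label <- if (n == 0L) "class5"
  else if (k == 0L) "class1"
  else if (k == n) { if (n == 1L) "class4a" else "class4b" }
  else if (k == 1L) "class2"
  else "class3"
  structure(list(label = label, n_ring_systems = n, n_novel = k),
            class = "molecule_class")
}

#' Classify every molecule of a fragmented library
#'
#' @param ids Character vector of molecule ids to classify; ids with no
#'   ring row become `class5`.
#' @param rings_df The `rings` data.frame from [fragment_library()].
#' @param drug_rings Character vector of reference drug ring keys.
#' @return Named character vector of class labels, one per id.
#' @export
classify_ids <- function(ids, rings_df, drug_rings) {
  ring_by_mol <- split(rings_df$ring_key, rings_df$molecule_id)
  vapply(ids, function(i) {
    classify_molecule(ring_by_mol[[i]], drug_rings)$label
  }, character(1))
}

#' Per-phase classification table
#'
#' Counts molecules of each novelty class in every phase. Percentages are
#' reported twice: over all molecules of the phase, and over the molecules
#' that contain at least one ring system (class 5 excluded), the
#' denominator used for headline class-1 comparisons. Percentages are
#' rounded to integers.
#'
#' @param records A phase-exclusive standardized library data.frame with
#'   `id`, `smiles_std`, `phase`. Duplicated structures are collapsed
#'   before classification.
#' @param rings The `rings` data.frame from [fragment_library()].
#' @param drug_rings Character vector of reference drug ring keys.
#' @return A data.frame with one row per phase and class:
#'   `phase`, `class`, `n`, `pct_all`, `pct_ringed`.
#' @export
classify_phase <- function(records, rings, drug_rings) {
  records <- records[!duplicated(records$smiles_std), , drop = FALSE]
  out <- list()
  for (ph in intersect(PHASE_LEVELS, unique(records$phase))) {
    ids <- records$id[records$phase == ph]
    labels <- classify_ids(ids, rings, drug_rings)
    tab <- table(factor(labels, levels = CLASS_LEVELS))
    n_all <- sum(tab)
    n_ringed <- n_all - tab[["class5"]]
    out[[ph]] <- data.frame(
      phase = ph, class = CLASS_LEVELS, n = as.integer(tab),
      pct_all = if (n_all > 0) as.integer(round(100 * as.integer(tab) / n_all))
        else 0L,
      pct_ringed = if (n_ringed > 0)
        as.integer(round(100 * as.integer(tab) / n_ringed)) else 0L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ring-system novelty table by phase
#'
#' For each phase, partitions its unique ring systems into those that are
#' new (present neither in drugs nor in any higher phase), those present in
#' drugs, and those present in a higher phase (but not drugs). An
#' `all_phases` row uses union semantics: new = rings in any clinical phase
#' minus the drug rings.
#'
#' @param phase_rings Named list mapping phase (`phase1`, `phase2`,
#'   `phase3`) to a character vector of canonical ring keys.
#' @param drug_rings Character vector of drug ring keys.
#' @return A data.frame with columns `phase`, `n_unique`, `n_new`,
#'   `n_from_drugs`, `n_from_higher`.
#' @export
ring_novelty_table <- function(phase_rings, drug_rings) {
  phases <- intersect(c("phase1", "phase2", "phase3"), names(phase_rings))
  rows <- lapply(phases, function(ph) {
    rs <- unique(phase_rings[[ph]])
    higher <- setdiff(phases, ph)
    higher <- higher[match(higher, PHASE_LEVELS) > match(ph, PHASE_LEVELS)]
    higher_rings <- unique(unlist(phase_rings[higher], use.names = FALSE))
    from_drugs <- intersect(rs, drug_rings)
    from_higher <- setdiff(intersect(rs, higher_rings), drug_rings)
    new <- setdiff(rs, union(drug_rings, higher_rings))
    data.frame(phase = ph, n_unique = length(rs), n_new = length(new),
               n_from_drugs = length(from_drugs),
               n_from_higher = length(from_higher), stringsAsFactors = FALSE)
  })
  all_rings <- unique(unlist(phase_rings[phases], use.names = FALSE))
  rows[[length(rows) + 1L]] <- data.frame(
    phase = "all_phases", n_unique = length(all_rings),
    n_new = length(setdiff(all_rings, drug_rings)),
    n_from_drugs = length(intersect(all_rings, drug_rings)),
    n_from_higher = 0L, stringsAsFactors = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
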