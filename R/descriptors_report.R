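# Ring-system property distributions and the summary / fraction-of-space
# arithmetic built on top of the catalogs and classification tables.

#' Ring-system properties
#'
#' Computes, for each canonical ring key, the number of smallest-set rings
#' and the fractions of nitrogen, oxygen, sulfur, combined heteroatoms and
#' sp3 carbon centers. All fractions use the heavy atoms of the ring system
#' (including retained exocyclic atoms) as denominator; sp3 centers are
#' carbon atoms carrying only single bonds.
#'
#' @param keys Character vector of canonical ring SMILES.
#' @return A data.frame with columns `ring_key`, `n_rings`, `n_heavy`,
#'   `pct_N`, `pct_O`, `pct_S`, `pct_hetero`, `pct_sp3` (fractions in
#'   `[0, 1]`).
#' @export
ring_properties <- function(keys) {
  mols <- parse_smiles(keys)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stop("unparseable ring key(s): ", paste(keys[bad], collapse = ", "))
  }
  rows <- lapply(seq_along(keys), function(i) {
    m <- mols[[i]]
    n <- n_atoms(m)
    bos_multi <- rep(FALSE, n)
    b <- m$bonds
    for (k in seq_len(nrow(b))) {
      if (b$order[k] > 1L) {
        bos_multi[b$a1[k]] <- TRUE
        bos_multi[b$a2[k]] <- TRUE
      }
    }
    sp3 <- sum(m$elem == "C" & !bos_multi)
    data.frame(
      ring_key = keys[i],
      n_rings = count_rings(m, ring_atom_idx(m)),
      n_heavy = n,
      pct_N = sum(m$elem == "N") / n,
      pct_O = sum(m$elem == "O") / n,
      pct_S = sum(m$elem == "S") / n,
      pct_hetero = sum(m$elem != "C") / n,
      pct_sp3 = sp3 / n,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare ring-property histograms across ring sets
#'
#' Computes per-label normalized histograms of one ring property on shared
#' bins, for side-by-side comparison of e.g. drug rings vs clinical-trial
#' rings.
#'
#' @param sets Named list mapping a label to a character vector of ring
#'   keys.
#' @param property One of `"n_rings"`, `"pct_N"`, `"pct_O"`, `"pct_S"`,
#'   `"pct_hetero"`, `"pct_sp3"`.
#' @param breaks Bin edges; defaults to 10% steps for fractions and unit
#'   steps for ring counts.
#' @return A data.frame with columns `label`, `bin_low`, `bin_high`,
#'   `share`; shares sum to 1 within each label.
#' @export
histogram_compare <- function(sets,
                              property = c("n_rings", "pct_N", "pct_O",
                                           "pct_S", "pct_hetero", "pct_sp3"),
                              breaks = NULL) {
  property <- match.arg(property)
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  props <- lapply(sets, function(k) ring_properties(unique(k))[[property]])
  if (is.null(breaks)) {
    breaks <- if (property == "n_rings") {
      seq(0.5, max(unlist(props)) + 0.5, by = 1)
    } else {
      seq(0, 1, by = 0.1)
    }
  }
  rows <- lapply(names(sets), function(lb) {
    x <- props[[lb]]
    h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    data.frame(label = lb,
               bin_low = utils::head(breaks, -1),
               bin_high = breaks[-1],
               share = if (length(x)) h$counts / length(x) else
                 rep(0, length(breaks) - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth-vector overlap table
#'
#' For each phase: the number of unique ring systems, how many of them are
#' drug rings, the number of unique (ring, growth-vector-combination)
#' pairs, and how many of those pairs also occur among the drug pairs. The
#' pair overlap can never exceed the ring-level overlap.
#'
#' @param phase_data Named list mapping phase to a data.frame with columns
#'   `ring_key`, `vectors`, `stereo_tags` (e.g. the per-phase slices of the
#'   `rings` table from [fragment_library()]).
#' @param drug_data The drug data.frame in the same format.
#' @return A data.frame with one row per phase plus `all_phases` and
#'   `drugs`: `status`, `n_unique_rings`, `n_from_drugs`, `n_ring_vector`,
#'   `n_pair_overlap`.
#' @export
vector_overlap_table <- function(phase_data, drug_data) {
  pair_key <- function(df) {
    unique(paste(df$ring_key, df$vectors, df$stereo_tags, sep = "|"))
  }
  drug_rings <- unique(drug_data$ring_key)
  drug_pairs <- pair_key(drug_data)
  one_row <- function(status, df) {
    rings <- unique(df$ring_key)
    pairs <- pair_key(df)
    data.frame(status = status,
               n_unique_rings = length(rings),
               n_from_drugs = length(intersect(rings, drug_rings)),
               n_ring_vector = length(pairs),
               n_pair_overlap = length(intersect(pairs, drug_pairs)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(phase_data), function(ph) one_row(ph, phase_data[[ph]]))
  all_df <- do.call(rbind, phase_data)
  rows[[length(rows) + 1L]] <- one_row("all_phases", all_df)
  rows[[length(rows) + 1L]] <- one_row("drugs", drug_data)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fractions of scaffold space
#'
#' Expresses counts of ring sets as percentages of a total scaffold space,
#' rounded to two significant figures (e.g. 378 of 458,748 rings is
#' 0.082%).
#'
#' @param counts Named numeric vector of ring-set sizes.
#' @param total Total number of ring systems in the reference space.
#' @return A data.frame with columns `label`, `count`, `pct` (percent, two
#'   significant figures).
#' @export
space_fractions <- function(counts, total) {
  if (length(total) != 1 || is.na(total) || total <= 0) {
    stop("total must be a positive count")
  }
  data.frame(label = names(counts),
             count = as.numeric(counts),
             pct = signif(100 * as.numeric(counts) / total, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Coverage estimate from a class-1 fraction
#'
#' Composite estimate of the share of future drugs covered by known plus
#' near-known ring systems: the class-1 fraction (molecules built only from
#' known drug rings) plus half of the remainder (the share of novel-ring
#' molecules whose new ring lies within two atom changes of a known ring).
#' A class-1 fraction of 0.70 gives 85%.
#'
#' @param class1_fraction Fraction in `[0, 1]` of molecules containing only
#'   known drug ring systems.
#' @return Coverage percentage.
#' @export
coverage_estimate <- function(class1_fraction) {
  stopifnot(class1_fraction >= 0, class1_fraction <= 1)
  100 * (class1_fraction + (1 - class1_fraction) / 2)
}
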