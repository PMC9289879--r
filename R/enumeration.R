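# Systematic N+1 / N+2 ring mutations: enumerate every ring system within
# one or two elementary edits of a seed ring, where an edit is a ring-atom
# element substitution or the addition/removal of an exocyclic double bond.
# Candidates must pass valence checks (which also rejects unkekulizable
# aromatic edits, since editing happens on the kekulized graph) and a
# configurable SMARTS stability blacklist.

# Substructures considered unstable in generated rings. The list is
# configurable; these defaults forbid ring O-O / S-S / O-S bonds, three
# contiguous non-aromatic ring nitrogens, and geminal ring diols.
DEFAULT_STABILITY_SMARTS <- c(
  ring_OO = "[#8;R]~[#8;R]",
  ring_SS = "[#16;R]~[#16;R]",
  ring_OS = "[#8;R]~[#16;R]",
  triple_ring_N = "[#7;A;R][#7;A;R][#7;A;R]",
  geminal_ring_diol = "[C;R]([OX2H1])[OX2H1]"
)

#' Mutation specification
#'
#' @param max_changes Maximum number of elementary edits (1 or 2).
#' @param substitution_elements Elements allowed as ring-atom substitution
#'   partners (edits swap among this set).
#' @param exo_edit Allow addition/removal of exocyclic double bonds.
#' @param exo_elements Elements addable/removable as exocyclic double-bond
#'   atoms (default `"O"`; `"S"` may be added).
#' @param stability_smarts Named character vector of forbidden SMARTS.
#' @param max_rings Seeds with more smallest-set rings than this are
#'   skipped (default 5).
#' @return A list of class `mutation_spec`.
#' @export
mutation_spec <- function(max_changes = 2,
                          substitution_elements = c("C", "N", "O", "S"),
                          exo_edit = TRUE,
                          exo_elements = "O",
                          stability_smarts = DEFAULT_STABILITY_SMARTS,
                          max_rings = 5) {
  stopifnot(max_changes %in% c(1, 2), max_rings >= 1)
  structure(list(max_changes = as.integer(max_changes),
                 substitution_elements = substitution_elements,
                 exo_edit = isTRUE(exo_edit),
                 exo_elements = exo_elements,
                 stability_smarts = stability_smarts,
                 max_rings = as.integer(max_rings)),
            class = "mutation_spec")
}

# All graphs one elementary edit away from `mol` (validity not enforced
# here; two-edit enumeration composes these and only the final candidate is
# checked).
one_change_graphs <- function(mol, spec) {
  out <- list()
  ratoms <- ring_atom_idx(mol)
  bos <- bond_order_sum(mol)
  deg <- heavy_degree(mol)
  # ring-atom element substitution: any organic ring atom may be replaced
  # by an element of the substitution set
  for (a in ratoms) {
    if (!(mol$elem[a] %in% c("C", "N", "O", "S"))) next
    for (el in setdiff(spec$substitution_elements, mol$elem[a])) {
      m2 <- mol
      m2$elem[a] <- el
      out[[length(out) + 1L]] <- m2
    }
  }
  if (spec$exo_edit) {
    # addition of an exocyclic double bond on a ring atom with free valence
    for (a in ratoms) {
      av <- allowed_valence(mol$elem[a], mol$charge[a])
      if (all(is.na(av)) || !any(av >= bos[a] + 2)) next
      for (el in spec$exo_elements) {
        m2 <- mol
        m2$elem <- c(m2$elem, el)
        m2$charge <- c(m2$charge, 0L)
        m2$bonds <- rbind(m2$bonds,
                          data.frame(a1 = a, a2 = n_atoms(mol) + 1L,
                                     order = 2L))
        out[[length(out) + 1L]] <- m2
      }
    }
    # removal of a terminal exocyclic double-bond atom
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] != 2L) next
      for (pair in list(c(mol$bonds$a1[k], mol$bonds$a2[k]),
                        c(mol$bonds$a2[k], mol$bonds$a1[k]))) {
        term <- pair[1]; anchor <- pair[2]
        if (deg[term] == 1L && !(term %in% ratoms) && anchor %in% ratoms &&
            mol$elem[term] %in% spec$exo_elements) {
          keep <- setdiff(seq_len(n_atoms(mol)), term)
          out[[length(out) + 1L]] <- submol(mol, keep)$mol
        }
      }
    }
  }
  out
}

# Canonicalize, valence-check, stability-filter a list of candidate graphs;
# returns unique canonical SMILES.
finalize_candidates <- function(graphs, spec) {
  if (!length(graphs)) return(character())
  ok <- vapply(graphs, valence_ok, logical(1))
  graphs <- graphs[ok]
  if (!length(graphs)) return(character())
  smi <- mols_to_smiles(graphs)
  smi <- unique(smi[!is.na(smi)])
  if (!length(smi)) return(character())
  # structures whose canonical form fails to re-parse are rejected
  reparsed <- parse_smiles(smi)
  smi <- smi[!vapply(reparsed, is.null, logical(1))]
  if (length(spec$stability_smarts) && length(smi)) {
    smi <- smi[!stability_hit(smi, spec$stability_smarts)]
  }
  smi
}

# TRUE for each SMILES matching any of the forbidden SMARTS patterns.
stability_hit <- function(smiles, patterns) {
  ids <- paste0("rsq", seq_along(smiles))
  sdf_txt <- ob_convert("SMI", "SDF",
                        paste0(smiles, " ", ids, "\n", collapse = ""))
  hit <- rep(FALSE, length(smiles))
  if (!nzchar(sdf_txt)) return(hit)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(
    ChemmineR::read.SDFstr(strsplit(sdf_txt, "\n", fixed = TRUE)[[1]])))
  nm <- vapply(seq_along(sdfset), function(i)
    ChemmineR::header(sdfset[[i]])[["Molecule_Name"]], character(1))
  for (p in patterns) {
    counts <- suppressWarnings(ChemmineR::smartsSearchOB(sdfset, p,
                                                         uniqueMatches = TRUE))
    matched <- nm[counts > 0]
    hit[ids %in% matched] <- TRUE
  }
  hit
}

#' Enumerate ring systems within N atom changes of a seed
#'
#' Generates every canonical, valence-valid, stability-filtered ring system
#' reachable from the seed by at most `spec$max_changes` elementary edits.
#' The seed itself is excluded. Edits never change ring count or ring
#' sizes. Two-edit enumeration composes single edits without requiring the
#' intermediate to be valid (distance is defined by atom differences, not
#' by valid paths).
#'
#' @param ring Canonical SMILES of the seed ring system.
#' @param spec A [mutation_spec()].
#' @return Character vector of canonical SMILES.
#' @export
mutate_ring <- function(ring, spec = mutation_spec()) {
  by_n <- mutate_ring_by_changes(ring, spec)
  unique(unlist(by_n, use.names = FALSE))
}

# As mutate_ring but keeps the 1-change and 2-change shells separate
# (list with elements "1" and, when requested, "2"; shells are cumulative
# only through the union taken by mutate_ring).
mutate_ring_by_changes <- function(ring, spec = mutation_spec()) {
  mol <- parse_smiles(ring)[[1]]
  if (is.null(mol)) stop("unparseable ring SMILES: ", ring)
  nr <- count_rings(mol, ring_atom_idx(mol))
  if (nr > spec$max_rings) {
    warning("seed exceeds max_rings (", nr, " > ", spec$max_rings,
            "); skipped: ", ring)
    return(list(`1` = character(), `2` = character()))
  }
  seed_can <- canonical_smiles(ring)
  g1 <- one_change_graphs(mol, spec)
  s1 <- setdiff(finalize_candidates(g1, spec), seed_can)
  res <- list(`1` = s1)
  if (spec$max_changes >= 2) {
    g2 <- list()
    for (g in g1) {
      g2 <- c(g2, one_change_graphs(g, spec))
    }
    s2 <- setdiff(finalize_candidates(g2, spec), c(seed_can, s1))
    res$`2` <- s2
  }
  res
}

#' Overlap of a novel ring set with the mutation neighborhood of a seed set
#'
#' Counts how many of the novel ring systems are reachable from any seed
#' within one change, and within at most two changes. Ring systems with
#' more than `spec$max_rings` rings are excluded from the denominator.
#'
#' @param novel_rings Character vector of canonical ring keys (disjoint
#'   from the seeds).
#' @param seed_rings Character vector of canonical seed ring keys.
#' @param spec A [mutation_spec()].
#' @return A data.frame with rows for 1 and 2 changes: `n_changes`,
#'   `n_novel`, `n_overlap`, `pct` (integer percent of the restricted novel
#'   set).
#' @export
overlap_within_n <- function(novel_rings, seed_rings, spec = mutation_spec()) {
  novel_rings <- unique(novel_rings)
  # restrict both sets by ring count
  keep_small <- function(keys) {
    mols <- parse_smiles(keys)
    keys[vapply(seq_along(keys), function(i) {
      m <- mols[[i]]
      !is.null(m) && count_rings(m, ring_atom_idx(m)) <= spec$max_rings
    }, logical(1))]
  }
  novel_rings <- keep_small(novel_rings)
  seed_rings <- keep_small(unique(seed_rings))
  u1 <- character(); u2 <- character()
  for (s in seed_rings) {
    shells <- mutate_ring_by_changes(s, spec)
    u1 <- union(u1, shells$`1`)
    u2 <- union(u2, unlist(shells, use.names = FALSE))
  }
  n <- length(novel_rings)
  o1 <- length(intersect(novel_rings, u1))
  o2 <- length(intersect(novel_rings, u2))
  data.frame(
    n_changes = c(1L, 2L),
    n_novel = n,
    n_overlap = c(o1, o2),
    pct = overlap_pct(c(o1, o2), n))
}

#' Integer overlap percentage
#'
#' The rounding convention used for all overlap tables:
#' `round(100 * n_overlap / n_total)` as integer, 0 when the total is 0.
#' Vectorized over `n_overlap`.
#'
#' @param n_overlap Overlap counts.
#' @param n_total Set size.
#' @return Integer vector of percentages.
#' @export
overlap_pct <- function(n_overlap, n_total) {
  if (length(n_total) != 1 || is.na(n_total) || n_total < 0) {
    stop("n_total must be a single non-negative count")
  }
  if (n_total == 0) return(rep(0L, length(n_overlap)))
  as.integer(round(100 * n_overlap / n_total))
}

#' Filters applied when deriving a future ring set
#'
#' @param min_catalog_frequency Rings must be reported in the catalog
#'   strictly more than this many times (default 100).
#' @param max_heteroatom_counts Named integer vector (`N`, `O`, `S`) of
#'   maximum allowed heteroatom counts; when `NULL` and `derive_from` is
#'   given, the maxima observed in that reference ring set are used.
#' @param derive_from Optional character vector of reference ring SMILES
#'   (typically the drug ring set) from which heteroatom cutoffs are
#'   derived.
#' @return A list of class `future_set_filters`.
#' @export
future_set_filters <- function(min_catalog_frequency = 100,
                               max_heteroatom_counts = NULL,
                               derive_from = NULL) {
  if (is.null(max_heteroatom_counts) && !is.null(derive_from)) {
    counts <- ring_heteroatom_counts(derive_from)
    max_heteroatom_counts <- c(N = max(counts$N), O = max(counts$O),
                               S = max(counts$S))
  }
  structure(list(min_catalog_frequency = min_catalog_frequency,
                 max_heteroatom_counts = max_heteroatom_counts),
            class = "future_set_filters")
}

ring_heteroatom_counts <- function(keys) {
  mols <- parse_smiles(keys)
  cnt <- function(m, el) if (is.null(m)) NA_integer_ else sum(m$elem == el)
  data.frame(ring_key = keys,
             N = vapply(mols, cnt, integer(1), "N"),
             O = vapply(mols, cnt, integer(1), "O"),
             S = vapply(mols, cnt, integer(1), "S"),
             stringsAsFactors = FALSE)
}

#' Derive a future ring-system set
#'
#' Mutates every seed ring by up to two atom changes, then keeps only the
#' candidates that are recorded in the reference catalog strictly more than
#' `filters$min_catalog_frequency` times, pass the heteroatom cutoffs, and
#' are not themselves seeds.
#'
#' @param seed_rings Character vector of canonical seed ring keys.
#' @param catalog A [ring_catalog()] of observed chemical ring space.
#' @param spec A [mutation_spec()].
#' @param filters A [future_set_filters()].
#' @return Character vector of canonical ring keys, sorted.
#' @export
build_future_set <- function(seed_rings, catalog, spec = mutation_spec(),
                             filters = future_set_filters()) {
  if (!length(catalog$entries)) {
    warning("empty reference catalog; future set is empty")
    return(character())
  }
  seed_rings <- unique(seed_rings)
  cand <- character()
  for (s in seed_rings) {
    mol <- parse_smiles(s)[[1]]
    if (is.null(mol)) next
    if (count_rings(mol, ring_atom_idx(mol)) > spec$max_rings) next
    cand <- union(cand, mutate_ring(s, spec))
  }
  cand <- setdiff(cand, seed_rings)
  freq <- catalog_frequencies(catalog)
  cand <- cand[cand %in% names(freq)]
  cand <- cand[freq[cand] > filters$min_catalog_frequency]
  if (!is.null(filters$max_heteroatom_counts) && length(cand)) {
    het <- ring_heteroatom_counts(cand)
    lim <- filters$max_heteroatom_counts
    ok <- rep(TRUE, nrow(het))
    for (el in intersect(names(lim), c("N", "O", "S"))) {
      ok <- ok & het[[el]] <= lim[[el]]
    }
    cand <- cand[ok]
  }
  sort(cand)
}
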