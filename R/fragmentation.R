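# Ring-system / framework decomposition with growth-vector recording.
#
# A ring system is a connected set of rings (fused, bridged or spiro —
# anything sharing an atom or bond) plus any terminal atoms double-bonded to
# it (retained exocyclic double bonds). The framework is the molecule
# reduced to its ring systems and the linkers connecting them, again with
# exocyclic double bonds retained. Every bond cut while isolating a ring
# system is recorded as a growth vector at the canonical symmetry rank of
# the ring-system atom it was attached to, so the same ring coming from
# different molecules exposes comparable attachment positions.

# Default set of elements retained when double-bonded exocyclically.
EXO_RETAIN <- c("O", "S", "N", "C")

# Per-atom chirality flags ("", "@", "@@") scanned from a SMILES string.
# Open Babel preserves input atom order into the SDF connection table, so
# flag i belongs to atom i of the parsed molecule.
smiles_atom_flags <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  flags <- character(0)
  i <- 1L
  n <- length(chars)
  two_letter <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I",
               "b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      tok <- paste(chars[i:j], collapse = "")
      flags <- c(flags,
                 if (grepl("@@", tok, fixed = TRUE)) "@@"
                 else if (grepl("@", tok, fixed = TRUE)) "@" else "")
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1]) %in% two_letter) {
      flags <- c(flags, "")
      i <- i + 2L
    } else if (ch %in% organic) {
      flags <- c(flags, "")
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  flags
}

# Core decomposition on a parsed molecule. Returns a list with one entry per
# ring system: atom indices (incl. exo), cut-bond attachment atoms, counts.
decompose_mol <- function(mol, exo_retain = EXO_RETAIN) {
  comps <- ring_system_components(mol)
  if (!length(comps)) return(list())
  rb <- ring_bond_idx(mol)
  ratoms <- ring_atom_idx(mol, rb)
  b <- mol$bonds
  lapply(comps, function(core) {
    # retained exocyclic double-bond atoms: terminal w.r.t. the system
    exo <- integer()
    for (k in seq_len(nrow(b))) {
      if (b$order[k] != 2L) next
      for (pair in list(c(b$a1[k], b$a2[k]), c(b$a2[k], b$a1[k]))) {
        ring_end <- pair[1]; other <- pair[2]
        if (ring_end %in% core && !(other %in% ratoms) &&
            mol$elem[other] %in% exo_retain) {
          exo <- c(exo, other)
        }
      }
    }
    atoms <- sort(unique(c(core, exo)))
    # growth vectors: bonds with exactly one endpoint inside the system
    cut_at <- integer()
    for (k in seq_len(nrow(b))) {
      in1 <- b$a1[k] %in% atoms; in2 <- b$a2[k] %in% atoms
      if (in1 && !in2) cut_at <- c(cut_at, b$a1[k])
      if (in2 && !in1) cut_at <- c(cut_at, b$a2[k])
    }
    list(atoms = atoms, core = core, exo = unique(exo), cut_at = cut_at)
  })
}

# Atom indices of the framework: ring systems, linkers between them, and
# exocyclic double-bond atoms attached to those. Computed by iterated
# removal of terminal atoms (leaving rings plus inter-ring paths), then
# adding back retained exocyclic atoms.
framework_atoms <- function(mol, exo_retain = EXO_RETAIN) {
  n <- n_atoms(mol)
  if (n == 0L || nrow(mol$bonds) == 0L) return(integer())
  alive <- rep(TRUE, n)
  b <- mol$bonds
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(b))) {
      if (alive[b$a1[k]] && alive[b$a2[k]]) {
        deg[b$a1[k]] <- deg[b$a1[k]] + 1L
        deg[b$a2[k]] <- deg[b$a2[k]] + 1L
      }
    }
    leaves <- which(alive & deg <= 1L)
    if (!length(leaves)) break
    alive[leaves] <- FALSE
  }
  core <- which(alive)
  if (!length(core)) return(integer())
  exo <- integer()
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2L) next
    for (pair in list(c(b$a1[k], b$a2[k]), c(b$a2[k], b$a1[k]))) {
      kept <- pair[1]; other <- pair[2]
      if (kept %in% core && !(other %in% core) &&
          mol$elem[other] %in% exo_retain) {
        exo <- c(exo, other)
      }
    }
  }
  sort(unique(c(core, exo)))
}

# Build the per-ring-system record (key left NA; filled in batch later).
ring_system_record <- function(mol, dec, flags = NULL) {
  sm <- submol(mol, dec$atoms)
  ranks <- canonical_ranks(sm$mol)
  pos <- sort(ranks[sm$map[dec$cut_at]])
  stereo <- if (is.null(flags)) rep("none", length(dec$cut_at)) else {
    vapply(dec$cut_at, function(a) {
      f <- flags[a]
      if (is.na(f) || f == "") "none" else if (f == "@@") "R" else "S"
    }, character(1))
  }
  # order stereo tags along with positions
  ord <- order(ranks[sm$map[dec$cut_at]])
  comp <- table(sm$mol$elem)
  list(
    mol = sm$mol,
    n_rings = count_rings(mol, dec$core),
    n_heavy = length(dec$atoms),
    exo_double_bonds = length(dec$exo),
    formula = paste0(names(comp), as.integer(comp), collapse = ";"),
    vectors = paste(pos, collapse = ";"),
    stereo_tags = paste(stereo[ord], collapse = ";"),
    n_vectors = length(pos)
  )
}

#' Fragment a molecule library into ring systems and frameworks
#'
#' Decomposes every molecule into its ring systems (rings sharing an atom or
#' bond merged, exocyclic double bonds retained, substituents replaced by
#' hydrogen) and its framework, recording for each ring system the growth
#' vectors: the canonical symmetry ranks of the atoms where substituents or
#' linkers were attached in the parent molecule, with an enantiomer tag when
#' the attachment atom carried a tetrahedral specification.
#'
#' @param records A data.frame with at least `id` and `smiles_std` columns
#'   (see [standardize_library()]), or a character vector of SMILES.
#' @param exo_retain Elements retained when terminal and double-bonded to a
#'   ring or framework atom.
#' @return A list with two data.frames: `rings` (one row per ring-system
#'   occurrence: `molecule_id`, `ring_key`, `n_rings`, `n_heavy`,
#'   `exo_double_bonds`, `formula`, `vectors`, `stereo_tags`, `n_vectors`)
#'   and `frameworks` (`molecule_id`, `framework`; empty string for acyclic
#'   molecules).
#' @export
fragment_library <- function(records, exo_retain = EXO_RETAIN) {
  if (is.character(records)) {
    records <- data.frame(id = paste0("m", seq_along(records)),
                          smiles_std = records, stringsAsFactors = FALSE)
  }
  n <- nrow(records)
  mols <- parse_smiles(records$smiles_std)
  ring_rows <- list()
  ring_mols <- list()
  fw_mols <- vector("list", n)
  fw_has <- logical(n)
  for (i in seq_len(n)) {
    mol <- mols[[i]]
    if (is.null(mol)) next
    flags <- smiles_atom_flags(records$smiles_std[i])
    if (length(flags) != n_atoms(mol)) flags <- NULL
    decs <- decompose_mol(mol, exo_retain)
    for (d in decs) {
      rec <- ring_system_record(mol, d, flags)
      ring_rows[[length(ring_rows) + 1L]] <- data.frame(
        molecule_id = records$id[i], ring_key = NA_character_,
        n_rings = rec$n_rings, n_heavy = rec$n_heavy,
        exo_double_bonds = rec$exo_double_bonds, formula = rec$formula,
        vectors = rec$vectors, stereo_tags = rec$stereo_tags,
        n_vectors = rec$n_vectors, stringsAsFactors = FALSE)
      ring_mols[[length(ring_mols) + 1L]] <- rec$mol
    }
    if (length(decs)) {
      fa <- framework_atoms(mol, exo_retain)
      fw_mols[[i]] <- submol(mol, fa)$mol
      fw_has[i] <- TRUE
    }
  }
  rings <- if (length(ring_rows)) do.call(rbind, ring_rows) else
    data.frame(molecule_id = character(), ring_key = character(),
               n_rings = integer(), n_heavy = integer(),
               exo_double_bonds = integer(), formula = character(),
               vectors = character(), stereo_tags = character(),
               n_vectors = integer(), stringsAsFactors = FALSE)
  if (length(ring_mols)) rings$ring_key <- mols_to_smiles(ring_mols)
  fw <- data.frame(molecule_id = records$id,
                   framework = "", stringsAsFactors = FALSE)
  if (any(fw_has)) fw$framework[fw_has] <- mols_to_smiles(fw_mols[fw_has])
  list(rings = rings, frameworks = fw)
}

#' Fragment a single molecule
#'
#' @param smiles A single SMILES string (standardized form recommended).
#' @param exo_retain Elements retained when terminal and double-bonded to a
#'   ring or framework atom.
#' @return A list of class `fragmentation_result` with `ring_systems`
#'   (data.frame as in [fragment_library()]) and `framework` (canonical
#'   SMILES, `""` when acyclic).
#' @export
fragment_molecule <- function(smiles, exo_retain = EXO_RETAIN) {
  res <- fragment_library(smiles, exo_retain)
  structure(list(ring_systems = res$rings,
                 framework = res$frameworks$framework[1]),
            class = "fragmentation_result")
}

#' Build the Bemis-Murcko-style framework of a molecule
#'
#' Removes all terminal acyclic groups, keeping ring systems, the linkers
#' connecting them, and exocyclic double-bonded atoms on those.
#'
#' @inheritParams fragment_molecule
#' @return Canonical SMILES of the framework; `""` for acyclic input.
#' @export
build_framework <- function(smiles, exo_retain = EXO_RETAIN) {
  fragment_molecule(smiles, exo_retain)$framework
}

#' Extract the ring systems of a molecule
#'
#' @inheritParams fragment_molecule
#' @return The `ring_systems` data.frame of [fragment_molecule()].
#' @export
extract_ring_systems <- function(smiles, exo_retain = EXO_RETAIN) {
  fragment_molecule(smiles, exo_retain)$ring_systems
}

#' Enumerate sub-frameworks
#'
#' Emits the canonical SMILES of every connected subset (up to `max_units`
#' ring systems) of the ring-system adjacency graph of a molecule, with the
#' connecting linkers retained and cut bonds hydrogen-capped.
#'
#' @inheritParams fragment_molecule
#' @param max_units Maximum number of ring systems per sub-framework.
#' @return Character vector of deduplicated canonical SMILES.
#' @export
enumerate_sub_frameworks <- function(smiles, max_units = 3,
                                     exo_retain = EXO_RETAIN) {
  stopifnot(max_units >= 1)
  mol <- parse_smiles(smiles)[[1]]
  if (is.null(mol)) stop("unparseable SMILES: ", smiles)
  decs <- decompose_mol(mol, exo_retain)
  if (!length(decs)) return(character())
  ns <- length(decs)
  fa <- framework_atoms(mol, exo_retain)
  rb <- ring_bond_idx(mol)
  ratoms <- ring_atom_idx(mol, rb)
  sys_of <- rep(NA_integer_, n_atoms(mol))
  for (s in seq_len(ns)) sys_of[decs[[s]]$atoms] <- s
  # linker atoms: framework atoms in no ring system
  linker <- setdiff(fa, which(!is.na(sys_of)))
  b <- mol$bonds
  # adjacency edges between systems with the linker path atoms
  edges <- list()
  add_edge <- function(p, q, path_atoms) {
    key <- paste(min(p, q), max(p, q))
    prev <- edges[[key]]
    edges[[key]] <<- list(p = min(p, q), q = max(p, q),
                          atoms = sort(unique(c(prev$atoms, path_atoms))))
  }
  # direct bonds between two systems
  for (k in seq_len(nrow(b))) {
    s1 <- sys_of[b$a1[k]]; s2 <- sys_of[b$a2[k]]
    if (!is.na(s1) && !is.na(s2) && s1 != s2) add_edge(s1, s2, integer())
  }
  # paths through linker components (acyclic, so paths are unique)
  if (length(linker)) {
    lsub <- submol(mol, linker)
    lg <- mol_igraph(lsub$mol)
    lcomp <- igraph::components(lg)$membership
    # attachments: (linker atom, system)
    att <- list()
    for (k in seq_len(nrow(b))) {
      for (pair in list(c(b$a1[k], b$a2[k]), c(b$a2[k], b$a1[k]))) {
        la <- pair[1]; sa <- pair[2]
        if (la %in% linker && !is.na(sys_of[sa])) {
          att[[length(att) + 1L]] <- c(la, sys_of[sa])
        }
      }
    }
    if (length(att)) {
      att <- do.call(rbind, att)
      for (ci in unique(lcomp)) {
        rows <- which(lcomp[lsub$map[att[, 1]]] == ci)
        if (length(rows) < 2L) next
        for (u in rows) for (v in rows) {
          if (att[u, 2] >= att[v, 2]) next
          sp <- igraph::shortest_paths(
            lg, from = lsub$map[att[u, 1]], to = lsub$map[att[v, 1]])$vpath[[1]]
          path <- linker[match(as.integer(sp), lsub$map[linker])]
          add_edge(att[u, 2], att[v, 2], path)
        }
      }
    }
  }
  # connected-subset enumeration over the adjacency graph
  adj_mat <- matrix(FALSE, ns, ns)
  for (e in edges) { adj_mat[e$p, e$q] <- TRUE; adj_mat[e$q, e$p] <- TRUE }
  # standard connected-subgraph enumeration with exclusion to avoid dupes
  subsets <- list()
  enum <- function(set, excluded) {
    subsets[[length(subsets) + 1L]] <<- set
    if (length(set) >= max_units) return()
    cand <- setdiff(which(apply(adj_mat[, set, drop = FALSE], 1, any)),
                    c(set, excluded))
    ex <- excluded
    for (x in cand) {
      enum(sort(c(set, x)), ex)
      ex <- c(ex, x)
    }
  }
  for (s in seq_len(ns)) enum(s, if (s > 1) seq_len(s - 1) else integer())
  frames <- lapply(subsets, function(set) {
    atoms <- unlist(lapply(set, function(s) decs[[s]]$atoms))
    for (e in edges) {
      if (e$p %in% set && e$q %in% set) atoms <- c(atoms, e$atoms)
    }
    submol(mol, sort(unique(atoms)))$mol
  })
  unique(mols_to_smiles(frames))
}

#' Average growth vectors per ring, by ring-system size
#'
#' For each ring-system size class (number of smallest-set rings), computes
#' the mean and population standard deviation of the number of growth
#' vectors used per ring across all ring-system occurrences.
#'
#' @param rings The `rings` data.frame from [fragment_library()].
#' @return A data.frame with columns `n_rings`, `n_observations`,
#'   `mean_vectors_per_ring`, `sd_vectors_per_ring`.
#' @export
vectors_per_ring <- function(rings) {
  if (nrow(rings) == 0L) {
    return(data.frame(n_rings = integer(), n_observations = integer(),
                      mean_vectors_per_ring = numeric(),
                      sd_vectors_per_ring = numeric()))
  }
  vpr <- rings$n_vectors / rings$n_rings
  grp <- split(vpr, rings$n_rings)
  data.frame(
    n_rings = as.integer(names(grp)),
    n_observations = lengths(grp),
    mean_vectors_per_ring = vapply(grp, mean, numeric(1)),
    sd_vectors_per_ring = vapply(grp, function(x)
      sqrt(mean((x - mean(x))^2)), numeric(1)),
    row.names = NULL)
}
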