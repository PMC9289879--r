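# Internal molecular-graph layer.
#
# Molecules are held as plain graphs: an atom table (element, formal charge)
# plus a bond table (endpoints, kekulized bond order). Parsing, aromaticity
# perception and canonical SMILES generation are delegated to Open Babel via
# ChemmineOB/ChemmineR; everything structural (ring perception, pruning,
# editing) operates on the graph directly.

# Average atomic masses (IUPAC 2021 standard atomic weights, conventional
# values where an interval is published). Covers the elements that occur in
# small-molecule libraries, including metals so that metal-containing inputs
# still get a molecular weight before being filtered out.
ATOMIC_MASS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971,
  Br = 79.904, Kr = 83.798, Rb = 85.468, Sr = 87.62, Y = 88.906,
  Zr = 91.224, Nb = 92.906, Mo = 95.95, Tc = 97, Ru = 101.07, Rh = 102.91,
  Pd = 106.42, Ag = 107.87, Cd = 112.41, In = 114.82, Sn = 118.71,
  Sb = 121.76, Te = 127.60, I = 126.90, Xe = 131.29, Cs = 132.91,
  Ba = 137.33, La = 138.91, Ce = 140.12, Gd = 157.25, Pt = 195.08,
  Au = 196.97, Hg = 200.59, Tl = 204.38, Pb = 207.2, Bi = 208.98, U = 238.03
)

# Elements regarded as "organic" for the metal filter; everything else is a
# metal (or metalloid treated as disallowed). Configurable from
# filter_library().
ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "Si", "P", "S", "Se",
                      "F", "Cl", "Br", "I")

# Allowed total valences (sum of bond orders incl. implicit H) per neutral
# element. Multiple entries mean hypervalent states are accepted.
ALLOWED_VALENCE <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Se = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

V2000_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

new_mol <- function(elem, charge = integer(length(elem)),
                    a1 = integer(), a2 = integer(), order = integer()) {
  structure(list(
    elem = as.character(elem),
    charge = as.integer(charge),
    bonds = data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
                       order = as.integer(order))
  ), class = "ringmol")
}

n_atoms <- function(mol) length(mol$elem)

#' @noRd
ob_convert <- function(from, to, text) {
  if (!nzchar(text)) return("")
  suppressWarnings(ChemmineOB::convertFormat(from, to, text))
}

#' Canonical SMILES via Open Babel
#'
#' Batch-converts SMILES to canonical SMILES.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector aligned with `smiles`; `NA` where Open Babel
#'   could not parse the input.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character())
  ids <- paste0("rsq", seq_len(n))
  out <- ob_convert("SMI", "CAN", paste0(smiles, " ", ids, "\n", collapse = ""))
  res <- rep(NA_character_, n)
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) == 2L) {
        idx <- match(trimws(p[2]), ids)
        if (!is.na(idx)) res[idx] <- p[1]
      }
    }
  }
  res
}

# Parse a batch of SMILES into ringmol objects via an Open Babel SDF round
# trip (kekulized bond orders). Returns a list aligned with `smiles`; NULL
# entries mark unparseable inputs.
parse_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(list())
  ids <- paste0("rsq", seq_len(n))
  sdf_txt <- ob_convert("SMI", "SDF", paste0(smiles, " ", ids, "\n", collapse = ""))
  res <- vector("list", n)
  if (!nzchar(sdf_txt)) return(res)
  recs <- strsplit(sdf_txt, "$$$$", fixed = TRUE)[[1]]
  for (rec in recs) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    while (length(lines) && !nzchar(trimws(lines[1]))) lines <- lines[-1]
    if (length(lines) < 4L) next
    idx <- match(trimws(lines[1]), ids)
    if (is.na(idx)) next
    res[[idx]] <- mol_from_molblock(lines)
  }
  res
}

# Read the V2000 connection table of one molblock (vector of lines with the
# title on line 1). Fixed-width fields per the CTfile spec; charges come
# from M CHG lines when present, else from the atom-block charge column.
mol_from_molblock <- function(lines) {
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4L + na + nb) return(NULL)
  atom_lines <- lines[4L + seq_len(na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  chg_code <- trimws(substr(atom_lines, 37, 39))
  charge <- V2000_CHARGE[chg_code]
  charge[is.na(charge)] <- 0L
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(na)
    for (cl in chg_lines) {
      k <- as.integer(substr(cl, 7, 9))
      for (j in seq_len(k)) {
        at <- as.integer(substr(cl, 10 + (j - 1) * 8, 13 + (j - 1) * 8))
        q <- as.integer(substr(cl, 14 + (j - 1) * 8, 17 + (j - 1) * 8))
        if (!is.na(at) && at >= 1 && at <= na) charge[at] <- q
      }
    }
  }
  if (nb == 0L) return(new_mol(elem, charge))
  bond_lines <- lines[4L + na + seq_len(nb)]
  a1 <- as.integer(substr(bond_lines, 1, 3))
  a2 <- as.integer(substr(bond_lines, 4, 6))
  ord <- as.integer(substr(bond_lines, 7, 9))
  keep <- !is.na(a1) & !is.na(a2) & a1 >= 1 & a2 >= 1 & a1 <= na & a2 <= na
  new_mol(elem, charge, a1 = a1[keep], a2 = a2[keep], order = ord[keep])
}

# Write a ringmol as a V2000 molblock (coordinates zeroed; Open Babel only
# needs the connection table to re-perceive aromaticity and canonicalize).
mol_to_molblock <- function(mol, title = "mol") {
  na <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$elem)
  bonds <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  } else character()
  chg_idx <- which(mol$charge != 0L)
  chg <- character()
  if (length(chg_idx)) {
    # M CHG lines hold at most 8 pairs each
    grp <- split(chg_idx, ceiling(seq_along(chg_idx) / 8))
    chg <- vapply(grp, function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, mol$charge[ix]), collapse = ""))
    }, character(1))
  }
  paste(c(title, " ringscape", "", counts, atoms, bonds, chg, "M  END", "$$$$"),
        collapse = "\n")
}

# Batch canonical SMILES for a list of ringmol objects (NAs for failures).
mols_to_smiles <- function(mols) {
  n <- length(mols)
  if (n == 0L) return(character())
  ids <- paste0("rsq", seq_len(n))
  blocks <- vapply(seq_len(n), function(i) mol_to_molblock(mols[[i]], ids[i]),
                   character(1))
  out <- ob_convert("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"))
  res <- rep(NA_character_, n)
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) == 2L) {
        idx <- match(trimws(p[2]), ids)
        if (!is.na(idx)) res[idx] <- p[1]
      }
    }
  }
  res
}

mol_to_smiles <- function(mol) mols_to_smiles(list(mol))[1]

# Adjacency list: for each atom, data.frame-free list of (neighbor, order).
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]; o <- b$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o, k))
    adj[[j]] <- rbind(adj[[j]], c(i, o, k))
  }
  adj
}

heavy_degree <- function(mol) {
  deg <- integer(n_atoms(mol))
  tab <- table(factor(c(mol$bonds$a1, mol$bonds$a2), levels = seq_len(n_atoms(mol))))
  as.integer(tab)
}

bond_order_sum <- function(mol) {
  s <- numeric(n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
    s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
  }
  s
}

# Effective allowed valences after formal-charge adjustment, following the
# usual organic-chemistry conventions (N+ 4, O- 1, O+ 3, C- 3, S+ 3, ...).
allowed_valence <- function(elem, charge) {
  base <- ALLOWED_VALENCE[[elem]]
  if (is.null(base)) return(NA_real_)
  if (charge == 0L) return(base)
  if (elem %in% c("N", "P")) return(base[1] + charge)
  if (elem %in% c("O", "S", "Se")) return(base[1] + charge)
  if (elem == "C") return(base - abs(charge))
  if (elem == "B") return(base + charge)
  base
}

# Implicit hydrogen count per atom (0 when no allowed valence fits).
implicit_h <- function(mol) {
  bos <- bond_order_sum(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    av <- allowed_valence(mol$elem[i], mol$charge[i])
    if (all(is.na(av))) return(0L)
    fit <- av[av >= bos[i]]
    if (!length(fit)) return(0L)
    as.integer(min(fit) - bos[i])
  }, integer(1))
}

# TRUE when every atom's bond-order sum fits an allowed valence state.
valence_ok <- function(mol) {
  bos <- bond_order_sum(mol)
  for (i in seq_len(n_atoms(mol))) {
    av <- allowed_valence(mol$elem[i], mol$charge[i])
    if (all(is.na(av))) next   # elements outside the table are not judged
    if (!any(av >= bos[i])) return(FALSE)
  }
  TRUE
}

mol_weight <- function(mol) {
  m <- ATOMIC_MASS[mol$elem]
  if (anyNA(m)) return(NA_real_)
  sum(m) + sum(implicit_h(mol)) * ATOMIC_MASS[["H"]]
}

contains_metal <- function(mol, organic = ORGANIC_ELEMENTS) {
  any(!(mol$elem %in% organic))
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# Indices of bonds that sit in a ring (non-bridge edges of the bond graph).
ring_bond_idx <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(integer())
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
}

ring_atom_idx <- function(mol, rb = ring_bond_idx(mol)) {
  sort(unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb])))
}

# Connected components of the ring-bond subgraph: each component is one ring
# system's atom set (fused, bridged and spiro rings all merge because they
# share at least an atom).
ring_system_components <- function(mol) {
  rb <- ring_bond_idx(mol)
  if (!length(rb)) return(list())
  ratoms <- ring_atom_idx(mol, rb)
  sub <- igraph::graph_from_data_frame(
    d = mol$bonds[rb, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = ratoms))
  comp <- igraph::components(sub)
  split(as.integer(igraph::V(sub)$name), comp$membership)
}

# Size of the smallest ring through every ring bond; the largest of these is
# the size of the biggest smallest-set ring, which drives the macrocycle
# filter. Returns integer(0) for acyclic molecules.
smallest_ring_sizes <- function(mol) {
  rb <- ring_bond_idx(mol)
  if (!length(rb)) return(integer())
  g <- mol_igraph(mol)
  vapply(rb, function(k) {
    u <- as.character(mol$bonds$a1[k]); v <- as.character(mol$bonds$a2[k])
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    d <- igraph::distances(g2, v = u, to = v)[1, 1]
    as.integer(d + 1)
  }, integer(1))
}

# Number of smallest-set rings in an atom subset (cyclomatic number of the
# induced ring-bond subgraph).
count_rings <- function(mol, atom_idx) {
  b <- mol$bonds
  keep <- b$a1 %in% atom_idx & b$a2 %in% atom_idx
  sum(keep) - length(atom_idx) + 1L
}

# Induced sub-molecule; returns list(mol=, map=) where map[i] gives the new
# index of original atom i (NA when dropped).
submol <- function(mol, atom_idx) {
  atom_idx <- sort(atom_idx)
  map <- rep(NA_integer_, n_atoms(mol))
  map[atom_idx] <- seq_along(atom_idx)
  b <- mol$bonds
  keep <- b$a1 %in% atom_idx & b$a2 %in% atom_idx
  m <- new_mol(mol$elem[atom_idx], mol$charge[atom_idx],
               a1 = map[b$a1[keep]], a2 = map[b$a2[keep]],
               order = b$order[keep])
  list(mol = m, map = map)
}

mol_components <- function(mol) {
  g <- mol_igraph(mol)
  comp <- igraph::components(g)
  split(seq_len(n_atoms(mol)), comp$membership)
}

# Canonical symmetry ranks via iterative neighbourhood refinement (Morgan
# style). Atoms in the same orbit of the refinement share a rank; ranks are
# dense integers assigned in a representation-independent order, so the same
# ring system parsed from differently-ordered inputs yields identical ranks.
# Ring-bond orders are deliberately excluded from the invariants: aromatic
# rings are kekulized arbitrarily by the SMILES writer, and ranks must not
# depend on which kekule structure a parse happens to produce. Ring bonds
# therefore contribute topology only, while acyclic bonds (including
# exocyclic double bonds) contribute their order.
canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer())
  rb <- ring_bond_idx(mol)
  in_ring_bond <- seq_len(nrow(mol$bonds)) %in% rb
  ring_deg <- integer(n)
  nonring_bos <- numeric(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (in_ring_bond[k]) {
      ring_deg[b$a1[k]] <- ring_deg[b$a1[k]] + 1L
      ring_deg[b$a2[k]] <- ring_deg[b$a2[k]] + 1L
    } else {
      nonring_bos[b$a1[k]] <- nonring_bos[b$a1[k]] + b$order[k]
      nonring_bos[b$a2[k]] <- nonring_bos[b$a2[k]] + b$order[k]
    }
  }
  code <- paste(mol$elem, mol$charge, heavy_degree(mol), ring_deg,
                nonring_bos, sep = "|")
  adj <- adjacency(mol)
  rank <- match(code, sort(unique(code)))
  repeat {
    nxt <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(as.character(rank[i]))
      lab <- ifelse(in_ring_bond[nb[, 3]], "R", as.character(nb[, 2]))
      sig <- sort(paste(lab, rank[nb[, 1]], sep = ":"))
      paste(mol$elem[i], rank[i], paste(sig, collapse = ","), sep = "#")
    }, character(1))
    new_rank <- match(nxt, sort(unique(nxt)))
    if (length(unique(new_rank)) == length(unique(rank))) {
      return(rank)
    }
    rank <- new_rank
  }
}
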