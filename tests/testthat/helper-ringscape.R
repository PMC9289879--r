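# Shared helpers for the test suite.

# Canonicalize a character vector and sort, for set comparisons.
canon_set <- function(smiles) {
  sort(unique(canonical_smiles(smiles)))
}

# Rewrite a SMILES with its atoms in the order given by `ord` (a permutation
# of the atom indices), producing a non-canonical SMILES of the same
# molecule. Used to probe representation independence.
permute_atoms_smiles <- function(smiles, ord) {
  m <- ringscape:::parse_smiles(smiles)[[1]]
  stopifnot(!is.null(m), length(ord) == length(m$elem))
  inv <- match(seq_along(ord), ord)
  m2 <- ringscape:::new_mol(m$elem[ord], m$charge[ord],
                            inv[m$bonds$a1], inv[m$bonds$a2], m$bonds$order)
  mb <- ringscape:::mol_to_molblock(m2)
  out <- ringscape:::ob_convert("SDF", "SMI", mb)
  strsplit(trimws(out), "[ \t]")[[1]][1]
}

# Batched variant: list of (smiles, ord) pairs -> character vector of
# reordered SMILES, one Open Babel call for the whole batch.
permute_atoms_smiles_batch <- function(smiles, orders) {
  mols <- ringscape:::parse_smiles(smiles)
  blocks <- vapply(seq_along(smiles), function(i) {
    m <- mols[[i]]
    ord <- orders[[i]]
    inv <- match(seq_along(ord), ord)
    m2 <- ringscape:::new_mol(m$elem[ord], m$charge[ord],
                              inv[m$bonds$a1], inv[m$bonds$a2],
                              m$bonds$order)
    ringscape:::mol_to_molblock(m2, title = paste0("p", i))
  }, character(1))
  out <- ringscape:::ob_convert("SDF", "SMI",
                                paste0(paste(blocks, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) == 2L) {
      i <- match(trimws(p[2]), paste0("p", seq_along(smiles)))
      if (!is.na(i)) res[i] <- p[1]
    }
  }
  res
}

# Independent brute-force oracle for substitution-only mutation: enumerate
# every assignment of set elements to every subset of up to `max_changes`
# editable ring positions, then apply the same validity pipeline (valence,
# canonicalization, re-parse, stability) and drop the seed.
oracle_substitutions <- function(ring, elements, max_changes = 2,
                                 stability = ringscape:::DEFAULT_STABILITY_SMARTS) {
  seed_can <- canonical_smiles(ring)
  mol <- ringscape:::parse_smiles(seed_can)[[1]]
  editable <- ringscape:::ring_atom_idx(mol)
  editable <- editable[mol$elem[editable] %in% c("C", "N", "O", "S")]
  variants <- list()
  for (npos in seq_len(max_changes)) {
    if (length(editable) < npos) next
    possets <- combn(editable, npos)
    assigns <- as.matrix(expand.grid(rep(list(elements), npos),
                                     stringsAsFactors = FALSE))
    for (ci in seq_len(ncol(possets))) {
      for (ai in seq_len(nrow(assigns))) {
        m2 <- mol
        m2$elem[possets[, ci]] <- assigns[ai, ]
        variants[[length(variants) + 1L]] <- m2
      }
    }
  }
  variants <- variants[vapply(variants, ringscape:::valence_ok, logical(1))]
  smi <- unique(ringscape:::mols_to_smiles(variants))
  smi <- smi[!is.na(smi)]
  smi <- smi[!vapply(ringscape:::parse_smiles(smi), is.null, logical(1))]
  if (length(smi)) smi <- smi[!ringscape:::stability_hit(smi, stability)]
  sort(setdiff(smi, seed_can))
}

# Fifty single-ring-system fixture molecules used for stability properties.
stability_fixtures <- function() {
  c(default_drug_rings(), default_novel_rings())[1:50]
}
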