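test_that("chlorthalidone yields two ring systems with the exo C=O kept", {
  fx <- fixture_molecules()
  smi <- standardize_smiles(fx$smiles[fx$name == "chlorthalidone"])
  rs <- extract_ring_systems(smi)
  expect_equal(nrow(rs), 2L)
  expect_true(canonical_smiles("c1ccccc1") %in% rs$ring_key)
  bi <- rs[rs$ring_key != canonical_smiles("c1ccccc1"), ]
  expect_equal(bi$ring_key, canonical_smiles("O=C1NCc2ccccc12"))
  expect_equal(bi$n_rings, 2L)
  expect_equal(bi$exo_double_bonds, 1L)
})

test_that("simple azines are single ring systems", {
  fx <- fixture_molecules()
  az <- fx[fx$expectation == "n_ring_systems" & fx$name != "chlorthalidone", ]
  for (i in seq_len(nrow(az))) {
    rs <- extract_ring_systems(az$smiles[i])
    expect_equal(nrow(rs), as.integer(az$expected_value[i]), info = az$name[i])
    expect_equal(rs$ring_key, canonical_smiles(az$smiles[i]))
  }
})

test_that("acyclic molecules give no rings and an empty framework", {
  res <- fragment_molecule("CCOCC")
  expect_equal(nrow(res$ring_systems), 0L)
  expect_equal(res$framework, "")
})

test_that("fused, spiro and bridged rings merge into one system", {
  cases <- c(naphthalene = "c1ccc2ccccc2c1",
             spiro = "C1CC2(C1)CCC2",
             bridged = "C1CC2CCC1CC2")
  for (nm in names(cases)) {
    rs <- extract_ring_systems(cases[[nm]])
    expect_equal(nrow(rs), 1L, info = nm)
    expect_equal(rs$n_rings, 2L, info = nm)
  }
})

test_that("growth vectors collapse symmetry-equivalent positions", {
  # any single substituent on benzene attaches at the unique symmetry rank
  tol <- extract_ring_systems("Cc1ccccc1")
  expect_equal(tol$n_vectors, 1L)
  xyl <- extract_ring_systems("Cc1ccc(C)cc1")
  expect_equal(xyl$n_vectors, 2L)
  expect_equal(length(unique(strsplit(xyl$vectors, ";")[[1]])), 1L)
  # on pyridine, 2- and 3-substitution give different ranks
  v2 <- extract_ring_systems("Cc1ccccn1")$vectors
  v3 <- extract_ring_systems("Cc1cccnc1")$vectors
  expect_false(identical(v2, v3))
})

test_that("growth-vector ranks do not depend on the kekule structure", {
  # the same ring embedded in different molecules, substituted at the
  # homologous position, must report the same vector rank
  a <- extract_ring_systems("Cc1ccc2occc2c1")
  b <- extract_ring_systems("CCCNCc1ccc2occc2c1")
  expect_equal(a$ring_key, b$ring_key)
  expect_equal(a$vectors, b$vectors)
})

test_that("stereo tags record the enantiomeric form of attachment atoms", {
  rs1 <- extract_ring_systems("C[C@@H]1CCCCO1")
  rs2 <- extract_ring_systems("C[C@H]1CCCCO1")
  expect_equal(rs1$stereo_tags, "R")
  expect_equal(rs2$stereo_tags, "S")
  expect_equal(extract_ring_systems("CC1CCCCO1")$stereo_tags, "none")
})

test_that("frameworks prune terminal chains but keep linkers and exo atoms", {
  expect_equal(build_framework("CCc1ccccc1CC"), canonical_smiles("c1ccccc1"))
  expect_equal(build_framework("c1ccccc1CCc1ccccc1"),
               canonical_smiles("c1ccccc1CCc1ccccc1"))
  # exocyclic carbonyl on a kept linker atom is retained
  expect_equal(build_framework("c1ccccc1C(=O)Nc1ccccc1"),
               canonical_smiles("c1ccccc1C(=O)Nc1ccccc1"))
  # terminal acyl group is pruned entirely
  expect_equal(build_framework("O=CCc1ccccc1"), canonical_smiles("c1ccccc1"))
})

test_that("decomposition conserves atoms", {
  smis <- c("OC1(c2cc(ccc2Cl)S(N)(=O)=O)c2ccccc2C(=O)N1",
            "c1ccccc1CCc1ccncc1", "O=C1CCC(=O)N1C1CC1",
            "C1CC2(C1)CCC2OCc1ccco1")
  for (smi in smis) {
    mol <- ringscape:::parse_smiles(smi)[[1]]
    decs <- ringscape:::decompose_mol(mol)
    cores <- unlist(lapply(decs, `[[`, "core"))
    expect_false(any(duplicated(cores)), info = smi)
    expect_setequal(cores, ringscape:::ring_atom_idx(mol))
    atoms <- unlist(lapply(decs, `[[`, "atoms"))
    expect_true(all(atoms %in% seq_along(mol$elem)), info = smi)
    expect_equal(sum(vapply(decs, function(d) length(d$atoms), integer(1))),
                 length(unique(atoms)))
  }
})

test_that("ring keys are stable under atom reordering", {
  set.seed(7)
  smis <- c("OC1(c2cc(ccc2Cl)S(N)(=O)=O)c2ccccc2C(=O)N1",
            "c1ccc2[nH]ccc2c1", "O=C1CCCCN1")
  for (smi in smis) {
    base <- sort(extract_ring_systems(canonical_smiles(smi))$ring_key)
    m <- ringscape:::parse_smiles(smi)[[1]]
    for (r in 1:5) {
      v <- permute_atoms_smiles(smi, sample(length(m$elem)))
      expect_equal(sort(extract_ring_systems(v)$ring_key), base, info = smi)
    }
  }
})

test_that("fragment_library returns aligned rings and frameworks tables", {
  lib <- c(a = "c1ccccc1CCc1ccncc1", b = "CCO")
  res <- fragment_library(data.frame(id = names(lib), smiles_std = unname(lib),
                                     stringsAsFactors = FALSE))
  expect_equal(sum(res$rings$molecule_id == "a"), 2L)
  expect_equal(sum(res$rings$molecule_id == "b"), 0L)
  expect_equal(res$frameworks$framework[res$frameworks$molecule_id == "b"], "")
  expect_equal(res$frameworks$framework[res$frameworks$molecule_id == "a"],
               canonical_smiles("c1ccccc1CCc1ccncc1"))
})

test_that("sub-framework enumeration emits connected ring-system subsets", {
  # three distinct rings in a chain: 3 singles + 2 adjacent pairs + 1 triple
  smi <- "c1ccccc1CC1CCNCC1COc1ccco1"
  subs <- enumerate_sub_frameworks(smi, max_units = 3)
  expect_equal(length(subs), 6L)
  expect_true(canonical_smiles("c1ccccc1") %in% subs)
  expect_true(canonical_smiles(smi) %in% subs)
  subs2 <- enumerate_sub_frameworks(smi, max_units = 1)
  expect_equal(length(subs2), 3L)
})

test_that("vectors_per_ring aggregates by ring count", {
  rings <- data.frame(n_rings = c(1L, 1L, 2L), n_vectors = c(2L, 4L, 2L))
  vp <- vectors_per_ring(rings)
  expect_equal(vp$mean_vectors_per_ring[vp$n_rings == 1], 3)
  expect_equal(vp$sd_vectors_per_ring[vp$n_rings == 1], 1)
  expect_equal(vp$mean_vectors_per_ring[vp$n_rings == 2], 1)
})
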