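test_that("benzene N-substitution matches the textbook azine sets", {
  spec1 <- mutation_spec(max_changes = 1, substitution_elements = c("C", "N"),
                         exo_edit = FALSE)
  expect_equal(canon_set(mutate_ring("c1ccccc1", spec1)),
               canon_set("c1ccncc1"))
  spec2 <- mutation_spec(max_changes = 2, substitution_elements = c("C", "N"),
                         exo_edit = FALSE)
  out <- mutate_ring("c1ccccc1", spec2)
  expect_equal(canon_set(out),
               canon_set(c("c1ccncc1",            # pyridine
                           "c1ccnnc1",            # pyridazine
                           "c1cncnc1",            # pyrimidine
                           "c1cnccn1")))          # pyrazine
  expect_equal(length(out), 4L)
})

test_that("mutate_ring equals the brute-force oracle on small rings", {
  cases <- list(
    list(ring = "c1ccccc1", elements = c("C", "N", "O", "S")),
    list(ring = "c1ccncc1", elements = c("C", "N")),
    list(ring = "C1CCCC1", elements = c("C", "N", "O")),
    list(ring = "c1ccoc1", elements = c("C", "N", "O")),
    list(ring = "C1COC1", elements = c("C", "N", "O", "S")),
    list(ring = "c1ccc2ccccc2c1", elements = c("C", "N"))
  )
  for (cs in cases) {
    spec <- mutation_spec(max_changes = 2,
                          substitution_elements = cs$elements,
                          exo_edit = FALSE)
    got <- canon_set(mutate_ring(cs$ring, spec))
    want <- canon_set(oracle_substitutions(cs$ring, cs$elements))
    expect_equal(got, want, info = cs$ring)
  }
})

test_that("exocyclic double-bond edits add and remove =O", {
  spec <- mutation_spec(max_changes = 1, substitution_elements = character(),
                        exo_edit = TRUE)
  expect_equal(canon_set(mutate_ring("C1CCCCC1", spec)),
               canon_set("O=C1CCCCC1"))
  back <- mutate_ring("O=C1CCCCC1", spec)
  expect_true(canonical_smiles("C1CCCCC1") %in% back)
})

test_that("one-change substitutions are invertible", {
  spec <- mutation_spec(max_changes = 1, exo_edit = FALSE)
  a <- canonical_smiles("C1CCOC1")
  for (b in mutate_ring(a, spec)) {
    expect_true(a %in% mutate_ring(b, spec), info = b)
  }
})

test_that("stability filters reject forbidden ring motifs", {
  spec <- mutation_spec(max_changes = 2, substitution_elements = c("C", "O"),
                        exo_edit = FALSE)
  out <- canon_set(mutate_ring("C1CCCCC1", spec))
  expect_false(canonical_smiles("O1OCCCC1") %in% out)  # ring O-O
  expect_true(canonical_smiles("O1CCOCC1") %in% out)   # 1,4-dioxane
  # with an empty blacklist the 1,2-dioxane appears
  spec_open <- mutation_spec(max_changes = 2,
                             substitution_elements = c("C", "O"),
                             exo_edit = FALSE, stability_smarts = character())
  expect_true(canonical_smiles("O1OCCCC1") %in%
                canon_set(mutate_ring("C1CCCCC1", spec_open)))
})

test_that("edits never change ring count or ring sizes", {
  spec <- mutation_spec(max_changes = 2, exo_edit = TRUE)
  for (seed in c("c1ccccc1", "C1CC2(C1)CCC2")) {
    seed_mol <- ringscape:::parse_smiles(canonical_smiles(seed))[[1]]
    seed_sizes <- sort(ringscape:::smallest_ring_sizes(seed_mol))
    muts <- mutate_ring(seed, spec)
    mols <- ringscape:::parse_smiles(muts)
    for (m in mols) {
      expect_equal(sort(ringscape:::smallest_ring_sizes(m)), seed_sizes)
    }
  }
})

test_that("seeds exceeding max_rings are skipped with a warning", {
  spec <- mutation_spec(max_rings = 1)
  expect_warning(out <- mutate_ring("c1ccc2ccccc2c1", spec), "max_rings")
  expect_equal(out, character())
})

test_that("unparseable seeds error", {
  expect_error(mutate_ring("xxx"), "unparseable")
})

test_that("overlap_within_n counts shell membership of a novel set", {
  spec <- mutation_spec(max_changes = 2, substitution_elements = c("C", "N"),
                        exo_edit = FALSE)
  novel <- canonical_smiles(c("c1ccncc1",   # 1 change from benzene
                              "c1cncnc1",   # 2 changes
                              "C1CCCCCC1")) # unreachable (7-ring)
  tab <- overlap_within_n(novel, "c1ccccc1", spec)
  expect_equal(tab$n_overlap, c(1L, 2L))
  expect_equal(tab$n_novel, c(3L, 3L))
  expect_equal(tab$pct, c(33L, 67L))
  expect_true(tab$n_overlap[2] >= tab$n_overlap[1])
})

test_that("overlap_pct applies the integer rounding convention", {
  expect_identical(overlap_pct(c(98L, 130L), 276L), c(36L, 47L))
  expect_identical(overlap_pct(1L, 0L), 0L)
  expect_error(overlap_pct(1L, -1L), "non-negative")
})

test_that("future_set_filters derives heteroatom cutoffs from a reference", {
  f <- future_set_filters(derive_from = c("c1ccncc1", "C1COCCN1", "C1CCSC1"))
  expect_equal(f$max_heteroatom_counts[["N"]], 1L)
  expect_equal(f$max_heteroatom_counts[["O"]], 1L)
  expect_equal(f$max_heteroatom_counts[["S"]], 1L)
})

test_that("build_future_set applies frequency and heteroatom filters", {
  pyridine <- canonical_smiles("c1ccncc1")
  pyridazine <- canonical_smiles("c1ccnnc1")
  pyrimidine <- canonical_smiles("c1cncnc1")
  rings <- data.frame(
    molecule_id = c(sprintf("a%03d", 1:150), sprintf("b%03d", 1:100),
                    sprintf("c%03d", 1:120)),
    ring_key = c(rep(pyridine, 150), rep(pyridazine, 100),
                 rep(pyrimidine, 120)),
    n_rings = 1L, vectors = "", stereo_tags = "",
    stringsAsFactors = FALSE)
  catalog <- build_catalog(rings)
  spec <- mutation_spec(max_changes = 2, substitution_elements = c("C", "N"),
                        exo_edit = FALSE)
  # frequency filter only: pyridazine at 100 is excluded (strictly > 100)
  fs <- build_future_set("c1ccccc1", catalog, spec,
                         future_set_filters(min_catalog_frequency = 100))
  expect_setequal(fs, c(pyridine, pyrimidine))
  # heteroatom cutoff N <= 1 removes the diazine
  fs2 <- build_future_set("c1ccccc1", catalog, spec,
                          future_set_filters(min_catalog_frequency = 100,
                                             max_heteroatom_counts = c(N = 1)))
  expect_equal(fs2, pyridine)
  # seeds are never returned
  fs3 <- build_future_set(pyridine, catalog, spec,
                          future_set_filters(min_catalog_frequency = 0))
  expect_false(pyridine %in% fs3)
  expect_warning(out <- build_future_set("c1ccccc1", ring_catalog(), spec),
                 "empty")
  expect_equal(out, character())
})
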