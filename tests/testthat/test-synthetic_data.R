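small_spec <- function(seed = 11L) {
  library_spec(seed = seed,
               n_molecules = c(drug = 40L, phase2 = 20L, phase1 = 20L),
               class_mix = c(class1 = 0.5, class2 = 0.2, class3 = 0.05,
                             class4a = 0.1, class4b = 0.05, class5 = 0.1))
}

test_that("pool rings are single ring systems equal to their own key", {
  for (pool in list(default_drug_rings(), default_novel_rings())) {
    rs <- fragment_library(pool)$rings
    expect_equal(nrow(rs), length(pool))
    expect_setequal(rs$ring_key, pool)
  }
})

test_that("library_spec validates its inputs", {
  expect_error(library_spec(class_mix = c(class1 = 0.5, class2 = 0.4)),
               "sum to 1")
  expect_error(library_spec(n_molecules = c(approved = 10L)), "phases")
  expect_error(library_spec(novel_ring_pool = "C1COC1",
                            class_mix = c(class1 = 0, class4b = 1)),
               "novel_ring_pool")
})

test_that("generation is deterministic and leaves the session RNG alone", {
  set.seed(999)
  before <- .Random.seed
  a <- generate_library(small_spec())
  expect_identical(.Random.seed, before)
  b <- generate_library(small_spec())
  expect_identical(a$records, b$records)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth_rings, b$truth_rings)
  c <- generate_library(small_spec(seed = 12L))
  expect_false(identical(a$records$smiles_input, c$records$smiles_input))
})

test_that("generated molecules standardize cleanly and are unique", {
  lib <- generate_library(small_spec())
  expect_equal(nrow(lib$records), 80L)
  expect_true(all(lib$records$std_ok))
  expect_false(any(duplicated(lib$records$smiles_std)))
  expect_equal(lib$manifest$id, lib$records$id)
  expect_true(all(lib$manifest$class %in%
                    c("class1", "class2", "class3", "class4a", "class4b",
                      "class5")))
})

test_that("fragmentation recovers exactly the planted rings and vectors", {
  lib <- generate_library(small_spec())
  frag <- fragment_library(lib$records)
  got <- with(frag$rings, sort(paste(molecule_id, ring_key, vectors)))
  want <- with(lib$truth_rings, sort(paste(molecule_id, ring_key, vectors)))
  expect_identical(got, want)
  # manifest ring-system counts agree too
  per_mol <- table(frag$rings$molecule_id)
  counts <- as.integer(per_mol[lib$manifest$id])
  counts[is.na(counts)] <- 0L
  expect_equal(unname(lib$manifest$n_ring_systems), counts)
})

test_that("classification against the pool reproduces the manifest", {
  lib <- generate_library(small_spec())
  frag <- fragment_library(lib$records)
  cls <- classify_ids(lib$records$id, frag$rings,
                      canonical_smiles(default_drug_rings()))
  expect_identical(unname(cls),
                   lib$manifest$class[match(names(cls), lib$manifest$id)])
})

test_that("co-occurrence blocks confine drug-ring pairs to one block", {
  pool <- default_drug_rings()[1:9]
  blocks <- list(pool[1:3], pool[4:6], pool[7:9])
  spec <- library_spec(seed = 5L,
                       n_molecules = c(drug = 60L),
                       drug_ring_pool = pool,
                       class_mix = c(class1 = 1),
                       cooccurrence_blocks = blocks)
  lib <- generate_library(spec)
  block_of <- rep(1:3, each = 3)
  names(block_of) <- canonical_smiles(pool)
  by_mol <- split(lib$truth_rings$ring_key, lib$truth_rings$molecule_id)
  for (rs in by_mol) {
    expect_equal(length(unique(block_of[unique(rs)])), 1L)
  }
  expect_error(
    generate_library(library_spec(cooccurrence_blocks = list("C1CC2CC12"))),
    "subsets")
})

test_that("target labels only appear on molecules containing rule rings", {
  pool <- default_drug_rings()
  spec <- library_spec(seed = 8L, n_molecules = c(drug = 60L),
                       class_mix = c(class1 = 1),
                       target_label_rules = list(
                         kinase = list(rings = pool[1:5], prob = 1)))
  lib <- generate_library(spec)
  has_lab <- grepl("kinase", lib$manifest$targets)
  rule_keys <- canonical_smiles(pool[1:5])
  by_mol <- split(lib$truth_rings$ring_key, lib$truth_rings$molecule_id)
  has_ring <- vapply(lib$manifest$id, function(i)
    length(intersect(by_mol[[i]], rule_keys)) > 0, logical(1))
  expect_identical(unname(has_lab), unname(has_ring))  # prob = 1
})

test_that("fixture molecules carry their documented expectations", {
  fx <- fixture_molecules()
  expect_true(all(c("chlorthalidone", "cyclodecane", "metal_complex",
                    "heavy_alkane") %in% fx$name))
  expect_false(anyNA(canonical_smiles(fx$smiles)))
})
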