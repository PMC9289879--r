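# Synthetic phase-labeled molecule libraries with known ground truth.
#
# Molecules are assembled bottom-up from a ring vocabulary and acyclic
# linkers, so the true ring systems, growth vectors, novelty class, phase
# and target labels of every molecule are known by construction. This
# makes every pipeline stage testable end to end: fragmentation must
# recover the planted rings and vectors, classification must recover the
# planted class mix, and network clustering must recover planted
# co-occurrence blocks.

#' Built-in drug ring vocabulary
#'
#' Around forty ring systems common in marketed small-molecule drugs
#' (benzene, pyridine, piperidine, piperazine, indole, morpholine, ...),
#' used as the default drug ring pool of the generator.
#'
#' @return Character vector of canonical ring SMILES.
#' @export
default_drug_rings <- function() {
  smi <- c(
    "c1ccccc1",            # benzene
    "c1ccncc1",            # pyridine
    "c1cncnc1",            # pyrimidine
    "c1ccnnc1",            # pyridazine
    "c1cnccn1",            # pyrazine
    "C1CCNCC1",            # piperidine
    "C1CNCCN1",            # piperazine
    "C1COCCN1",            # morpholine
    "C1CCNC1",             # pyrrolidine
    "C1CCOC1",             # tetrahydrofuran
    "C1CCOCC1",            # tetrahydropyran
    "C1CC1",               # cyclopropane
    "C1CCC1",              # cyclobutane
    "C1CCCC1",             # cyclopentane
    "C1CCCCC1",            # cyclohexane
    "C1CNC1",              # azetidine
    "c1cc[nH]c1",          # pyrrole
    "c1ccoc1",             # furan
    "c1ccsc1",             # thiophene
    "c1cnc[nH]1",          # imidazole
    "c1cn[nH]c1",          # pyrazole
    "c1cnco1",             # oxazole
    "c1cnoc1",             # isoxazole
    "c1cncs1",             # thiazole
    "c1cn[nH]n1",          # 1,2,3-triazole
    "c1ccc2ccccc2c1",      # naphthalene
    "c1ccc2[nH]ccc2c1",    # indole
    "c1ccc2ncccc2c1",      # quinoline
    "c1ccc2cnccc2c1",      # isoquinoline
    "c1ccc2ncncc2c1",      # quinazoline
    "c1ccc2[nH]cnc2c1",    # benzimidazole
    "c1ccc2[nH]ncc2c1",    # indazole
    "c1ccc2occc2c1",       # benzofuran
    "c1ccc2sccc2c1",       # benzothiophene
    "c1ncc2[nH]cnc2n1",    # purine
    "O=C1CCCCN1",          # piperidinone (lactam)
    "O=c1cccc[nH]1",       # 2-pyridone
    "O=C1CCCN1",           # pyrrolidinone
    "C1CC2CCC1CC2",        # bicyclo[2.2.2]octane
    "C1CSCCN1"             # thiomorpholine
  )
  unique(canonical_smiles(smi))
}

#' Built-in novel ring vocabulary
#'
#' Ring systems absent from [default_drug_rings()], standing in for the
#' newer scaffolds seen only in clinical-trial compounds.
#'
#' @return Character vector of canonical ring SMILES.
#' @export
default_novel_rings <- function() {
  smi <- c(
    "C1COC1",                # oxetane
    "C1CSC1",                # thietane
    "C1CC2(C1)CCC2",         # spiro[3.3]heptane
    "C1CC2(C1)COC2",         # 2-oxaspiro[3.3]heptane
    "C1CC2(C1)CNC2",         # 2-azaspiro[3.3]heptane
    "C1CC2CC1CN2",           # azabicyclohexane-like bridge
    "C1CN2CCC1CC2",          # quinuclidine
    "c1cnc2[nH]ccc2c1",      # azaindole
    "c1cc2cccnc2[nH]1",      # pyrrolopyridine
    "c1cnn2cccc2c1",         # pyrazolopyridine (fused)
    "c1cnc2sccc2c1",         # thienopyridine
    "c1cnc2occc2c1",         # furopyridine
    "C1CCC2(CC1)CCNCC2",     # spiro piperidine
    "C1CC2CCC(C1)N2",        # tropane-like bridge
    "c1cc2ccnn2cc1",         # fused diazine variant (bridgehead N)
    "C1COCCNC1",             # oxazepane (7-ring)
    "C1CCNCCC1",             # azepane
    "C1CCSCC1",              # thiane
    "O=C1CCC(=O)N1",         # succinimide
    "O=C1CCOC1"              # gamma-butyrolactone
  )
  out <- unique(canonical_smiles(smi))
  out[!is.na(out)]
}

#' Built-in linker vocabulary
#'
#' Small acyclic fragments used to join ring systems; attachment happens at
#' the first and last atom of each fragment.
#'
#' @return Character vector of SMILES.
#' @export
default_linkers <- function() {
  c(NA_character_,  # direct ring-ring bond
    "C", "CC", "CCC", "CO", "CN", "COC", "CNC", "CCO", "OCC", "CCN")
}

#' Specification of a synthetic library
#'
#' @param seed Random seed; the same spec always generates the same
#'   library.
#' @param n_molecules Named integer vector of molecules per phase, e.g.
#'   `c(drug = 200, phase3 = 100, phase2 = 100, phase1 = 100)`.
#' @param drug_ring_pool,novel_ring_pool Ring vocabularies (SMILES).
#' @param class_mix Named probabilities over
#'   `class1, class2, class3, class4a, class4b, class5`; must sum to 1.
#' @param linker_pool Acyclic linker SMILES (`NA` entries mean a direct
#'   bond).
#' @param cooccurrence_blocks Optional list of character vectors of drug
#'   ring SMILES; each molecule then draws all of its drug rings from a
#'   single block, planting block structure in the drug-ring co-occurrence
#'   graph.
#' @param target_label_rules Optional named list: label ->
#'   `list(rings = <SMILES>, prob = <assignment probability>)`. A molecule
#'   containing any listed ring receives the label with that probability.
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(seed = 1L,
                         n_molecules = c(drug = 100L, phase3 = 50L,
                                         phase2 = 50L, phase1 = 50L),
                         drug_ring_pool = default_drug_rings(),
                         novel_ring_pool = default_novel_rings(),
                         class_mix = c(class1 = 0.67, class2 = 0.24,
                                       class3 = 0.02, class4a = 0.06,
                                       class4b = 0.01, class5 = 0),
                         linker_pool = default_linkers(),
                         cooccurrence_blocks = NULL,
                         target_label_rules = NULL) {
  class_mix <- class_mix[CLASS_LEVELS[CLASS_LEVELS %in% names(class_mix)]]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!all(names(n_molecules) %in% PHASE_LEVELS)) {
    stop("n_molecules names must be phases: ",
         paste(PHASE_LEVELS, collapse = ", "))
  }
  need_novel <- sum(class_mix[c("class2", "class3", "class4a", "class4b")],
                    na.rm = TRUE) > 0
  if (need_novel && length(novel_ring_pool) < 2) {
    stop("novel_ring_pool needs at least 2 rings for the requested classes")
  }
  if (sum(class_mix[c("class1", "class2", "class3")], na.rm = TRUE) > 0 &&
      length(drug_ring_pool) < 3) {
    stop("drug_ring_pool needs at least 3 rings for the requested classes")
  }
  structure(list(seed = as.integer(seed), n_molecules = n_molecules,
                 drug_ring_pool = drug_ring_pool,
                 novel_ring_pool = novel_ring_pool,
                 class_mix = class_mix, linker_pool = linker_pool,
                 cooccurrence_blocks = cooccurrence_blocks,
                 target_label_rules = target_label_rules),
            class = "library_spec")
}

# Join ring molecules with linkers into one molecule graph, chaining
# ring1 - linker - ring2 - linker - ring3. Attachment atoms are sampled
# among ring-core atoms with a free valence. Returns list(mol=, attach=)
# where attach is a list (per ring) of attachment atom indices local to
# that ring.
assemble_molecule <- function(ring_mols, linker_mols) {
  stopifnot(length(ring_mols) >= 1)
  nr <- length(ring_mols)
  offsets <- integer(nr)
  elem <- character(); charge <- integer()
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  attach <- vector("list", nr)
  core_sets <- vector("list", nr)
  for (i in seq_len(nr)) {
    offsets[i] <- length(elem)
    m <- ring_mols[[i]]
    elem <- c(elem, m$elem); charge <- c(charge, m$charge)
    if (nrow(m$bonds)) {
      bonds <- rbind(bonds, data.frame(a1 = m$bonds$a1 + offsets[i],
                                       a2 = m$bonds$a2 + offsets[i],
                                       order = m$bonds$order))
    }
    core_sets[[i]] <- ring_atom_idx(m)
    attach[[i]] <- integer()
  }
  mol <- new_mol(elem, charge, bonds$a1, bonds$a2, bonds$order)
  pick_site <- function(ri) {
    ih <- implicit_h(mol)
    cand <- core_sets[[ri]][ih[core_sets[[ri]] + offsets[ri]] >= 1L]
    if (!length(cand)) stop("no free attachment position on ring ", ri)
    cand[sample.int(length(cand), 1L)]
  }
  for (i in seq_len(nr - 1L)) {
    a_local <- pick_site(i)
    b_local <- pick_site(i + 1L)
    a <- a_local + offsets[i]
    b <- b_local + offsets[i + 1L]
    lk <- linker_mols[[i]]
    if (is.null(lk)) {
      mol$bonds <- rbind(mol$bonds, data.frame(a1 = a, a2 = b, order = 1L))
    } else {
      off <- n_atoms(mol)
      mol$elem <- c(mol$elem, lk$elem)
      mol$charge <- c(mol$charge, lk$charge)
      if (nrow(lk$bonds)) {
        mol$bonds <- rbind(mol$bonds,
                           data.frame(a1 = lk$bonds$a1 + off,
                                      a2 = lk$bonds$a2 + off,
                                      order = lk$bonds$order))
      }
      mol$bonds <- rbind(mol$bonds,
                         data.frame(a1 = c(a, off + n_atoms(lk)),
                                    a2 = c(off + 1L, b),
                                    order = c(1L, 1L)))
    }
    attach[[i]] <- c(attach[[i]], a_local)
    attach[[i + 1L]] <- c(attach[[i + 1L]], b_local)
  }
  list(mol = mol, attach = attach)
}

# Acyclic molecules used for class 5 (no ring systems).
ACYCLIC_POOL <- c("CCO", "CCN(CC)CC", "CC(C)CO", "CCOC(C)C", "NCCO",
                  "CCCCC", "CC(C)(C)CO", "CCSCC", "OCCOCCO", "CC(C)NCC")

#' Generate a synthetic phase-labeled library
#'
#' Assembles molecules ring-by-ring according to the class mix and returns
#' both the standardized library and a ground-truth manifest. Generation is
#' deterministic for a fixed spec (the RNG state of the session is left
#' untouched).
#'
#' @param spec A [library_spec()].
#' @return A list with `records` (standardized library data.frame as from
#'   [standardize_library()]), `manifest` (data.frame `id`, `phase`,
#'   `class`, `n_ring_systems`, `targets`) and `truth_rings` (data.frame
#'   `molecule_id`, `ring_key`, `vectors` with planted attachment ranks).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  drug_keys <- canonical_smiles(spec$drug_ring_pool)
  novel_keys <- canonical_smiles(spec$novel_ring_pool)
  if (anyNA(drug_keys) || anyNA(novel_keys)) stop("unparseable pool ring")
  drug_mols <- parse_smiles(drug_keys)
  novel_mols <- parse_smiles(novel_keys)
  ranks_drug <- lapply(drug_mols, canonical_ranks)
  ranks_novel <- lapply(novel_mols, canonical_ranks)
  linker_mols <- lapply(spec$linker_pool, function(s)
    if (is.na(s)) NULL else parse_smiles(s)[[1]])
  blocks <- NULL
  if (!is.null(spec$cooccurrence_blocks)) {
    blocks <- lapply(spec$cooccurrence_blocks, function(b)
      match(canonical_smiles(b), drug_keys))
    if (anyNA(unlist(blocks))) {
      stop("cooccurrence_blocks must be subsets of drug_ring_pool")
    }
  }
  rules <- spec$target_label_rules
  rule_keys <- lapply(rules, function(r) canonical_smiles(r$rings))

  draw_rings <- function(cls) {
    # returns list(idx_drug=, idx_novel=)
    nd <- 0L; nn <- 0L
    if (cls == "class1") {
      nd <- sample(1:3, 1L, prob = c(0.4, 0.4, 0.2))
    } else if (cls == "class2") {
      nd <- sample(1:2, 1L); nn <- 1L
    } else if (cls == "class3") {
      nd <- 1L; nn <- 2L
    } else if (cls == "class4a") {
      nn <- 1L
    } else if (cls == "class4b") {
      nn <- 2L
    }
    idx_d <- integer()
    if (nd > 0L) {
      if (!is.null(blocks)) {
        blk <- blocks[[sample.int(length(blocks), 1L)]]
        idx_d <- blk[sample.int(length(blk), min(nd, length(blk)))]
      } else {
        idx_d <- sample.int(length(drug_keys), nd)
      }
    }
    idx_n <- if (nn > 0L) sample.int(length(novel_keys), nn) else integer()
    list(drug = idx_d, novel = idx_n)
  }

  total <- sum(spec$n_molecules)
  ids <- character(total); phases <- character(total)
  classes <- character(total); targets <- character(total)
  mols_out <- vector("list", total)
  truth <- list()
  seen <- new.env(parent = emptyenv())
  k <- 0L
  cls_levels <- names(spec$class_mix)
  for (ph in names(spec$n_molecules)) {
    for (j in seq_len(spec$n_molecules[[ph]])) {
      k <- k + 1L
      id <- sprintf("%s_%04d", ph, j)
      for (try in 1:100) {
        cls <- sample(cls_levels, 1L, prob = spec$class_mix)
        if (cls == "class5") {
          smi <- ACYCLIC_POOL[sample.int(length(ACYCLIC_POOL), 1L)]
          mol <- parse_smiles(smi)[[1]]
          occ <- NULL
        } else {
          sel <- draw_rings(cls)
          rmols <- c(drug_mols[sel$drug], novel_mols[sel$novel])
          rkeys <- c(drug_keys[sel$drug], novel_keys[sel$novel])
          rranks <- c(ranks_drug[sel$drug], ranks_novel[sel$novel])
          ord <- sample.int(length(rmols))
          rmols <- rmols[ord]; rkeys <- rkeys[ord]; rranks <- rranks[ord]
          lks <- lapply(seq_len(max(length(rmols) - 1L, 0L)), function(x)
            linker_mols[[sample.int(length(linker_mols), 1L)]])
          asm <- assemble_molecule(rmols, lks)
          mol <- asm$mol
          occ <- data.frame(
            molecule_id = id, ring_key = rkeys,
            vectors = vapply(seq_along(rkeys), function(ri)
              paste(sort(rranks[[ri]][asm$attach[[ri]]]), collapse = ";"),
              character(1)),
            stringsAsFactors = FALSE)
        }
        smi_can <- mol_to_smiles(mol)
        if (is.na(smi_can)) next
        if (!is.null(seen[[smi_can]])) next
        seen[[smi_can]] <- TRUE
        break
      }
      ids[k] <- id; phases[k] <- ph; classes[k] <- cls
      mols_out[[k]] <- mol
      if (!is.null(occ)) truth[[length(truth) + 1L]] <- occ
      lab <- character()
      if (!is.null(rules) && cls != "class5") {
        for (nm in names(rules)) {
          if (length(intersect(occ$ring_key, rule_keys[[nm]])) &&
              stats::runif(1) < rules[[nm]]$prob) {
            lab <- c(lab, nm)
          }
        }
      }
      targets[k] <- paste(lab, collapse = ";")
    }
  }
  smiles <- mols_to_smiles(mols_out)
  records <- data.frame(id = ids, smiles_input = smiles, phase = phases,
                        target_classes = targets, stringsAsFactors = FALSE)
  records <- standardize_library(records)
  manifest <- data.frame(id = ids, phase = phases, class = classes,
                         targets = targets, stringsAsFactors = FALSE)
  truth_rings <- if (length(truth)) do.call(rbind, truth) else
    data.frame(molecule_id = character(), ring_key = character(),
               vectors = character(), stringsAsFactors = FALSE)
  manifest$n_ring_systems <- vapply(manifest$id, function(i)
    sum(truth_rings$molecule_id == i), integer(1))
  list(records = records, manifest = manifest, truth_rings = truth_rings)
}

#' Curated fixture molecules
#'
#' Small named set of molecules with known expected outcomes, used
#' throughout the test suite: the Chlorthalidone two-ring-system example,
#' simple azines, a macrocycle, a metal complex, a salt, a keto/enol pair
#' and an overweight alkane.
#'
#' @return A data.frame with columns `name`, `smiles`, `expectation`,
#'   `expected_value`.
#' @export
fixture_molecules <- function() {
  data.frame(
    name = c("chlorthalidone", "benzene", "pyridine", "pyridazine",
             "pyrimidine", "pyrazine", "cyclodecane", "metal_complex",
             "salt", "enol", "keto", "heavy_alkane"),
    smiles = c("OC1(c2cc(ccc2Cl)S(N)(=O)=O)c2ccccc2C(=O)N1",
               "c1ccccc1", "c1ccncc1", "c1ccnnc1", "c1cncnc1", "c1cnccn1",
               "C1CCCCCCCCC1", "Cl[Zn]c1ccccc1", "CC.Cl",
               "CC(O)=C", "CC(=O)C",
               paste(rep("C", 75), collapse = "")),
    expectation = c("n_ring_systems", "n_ring_systems", "n_ring_systems",
                    "n_ring_systems", "n_ring_systems", "n_ring_systems",
                    "filter_rule", "filter_rule", "standardized_smiles",
                    "same_std_as_keto", "same_std_as_enol", "filter_rule"),
    expected_value = c("2", "1", "1", "1", "1", "1",
                       "ring_size", "metal", "CC", "", "", "mw"),
    stringsAsFactors = FALSE)
}
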