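#' Read a molecule library
#'
#' Reads a compound library from a SMILES file (whitespace-separated
#' `smiles id`, one molecule per line), a CSV file (header required, columns
#' `id`, `smiles`, `phase`, optional `target_class` with `;`-separated
#' labels) or an SDF (V2000). Entries whose structure cannot be parsed are
#' dropped and counted, not fatal.
#'
#' @param path Path to the input file.
#' @param format One of `"smiles"`, `"csv"`, `"sdf"`.
#' @return A data.frame with columns `id`, `smiles_input`, `phase`
#'   (one of `other`, `phase1`, `phase2`, `phase3`, `drug`) and
#'   `target_classes` (`;`-separated, possibly empty). The number of
#'   unparseable entries is attached as attribute `n_parse_failed`.
#' @export
read_library <- function(path, format = c("smiles", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) return(empty_library())
    parts <- strsplit(lines, "[ \t]+")
    smiles <- vapply(parts, `[`, character(1), 1)
    id <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("m", i),
      character(1))
    rec <- data.frame(id = id, smiles_input = smiles,
                      phase = "other", target_classes = "",
                      stringsAsFactors = FALSE)
  } else if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "smiles", "phase")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols)) {
      stop("csv is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    rec <- data.frame(id = as.character(tab$id),
                      smiles_input = as.character(tab$smiles),
                      phase = as.character(tab$phase),
                      target_classes = if ("target_class" %in% names(tab))
                        as.character(tab$target_class) else "",
                      stringsAsFactors = FALSE)
    if (nrow(rec) == 0L) return(empty_library())
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    smi <- ob_convert("SDF", "CAN", paste0(txt, "\n"))
    if (!nzchar(smi)) return(empty_library())
    lines <- strsplit(smi, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smiles <- vapply(parts, `[`, character(1), 1)
    id <- vapply(seq_along(parts), function(i) {
      nm <- if (length(parts[[i]]) >= 2) trimws(parts[[i]][2]) else ""
      if (nzchar(nm)) nm else paste0("m", i)
    }, character(1))
    rec <- data.frame(id = id, smiles_input = smiles,
                      phase = "other", target_classes = "",
                      stringsAsFactors = FALSE)
  }
  rec$phase <- normalize_phase(rec$phase)
  rec$target_classes[is.na(rec$target_classes)] <- ""
  # drop unparseable structures, keep count
  can <- canonical_smiles(rec$smiles_input)
  bad <- is.na(can)
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_parse_failed") <- sum(bad)
  out
}

empty_library <- function() {
  out <- data.frame(id = character(), smiles_input = character(),
                    phase = character(), target_classes = character(),
                    stringsAsFactors = FALSE)
  attr(out, "n_parse_failed") <- 0L
  out
}

PHASE_LEVELS <- c("other", "phase1", "phase2", "phase3", "drug")

normalize_phase <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!(x %in% PHASE_LEVELS)] <- "other"
  x
}

phase_rank <- function(x) match(normalize_phase(x), PHASE_LEVELS)

#' Standardization rule set
#'
#' The fixed, documented transform list applied by [standardize_library()]:
#' keep the largest organic fragment (salt stripping), neutralize charges
#' where a proton gain/loss achieves neutrality (charge-separated groups
#' such as nitro or N-oxides are left intact), and rewrite non-ring enol
#' tautomers to the keto form. The contract is determinism and idempotence.
#'
#' @param strip_salts,neutralize,keto_enol Logical switches for the three
#'   transforms.
#' @return A list of class `standardization_rules`.
#' @export
standardization_rules <- function(strip_salts = TRUE, neutralize = TRUE,
                                  keto_enol = TRUE) {
  structure(list(strip_salts = strip_salts, neutralize = neutralize,
                 keto_enol = keto_enol),
            class = "standardization_rules")
}

# Keep the largest fragment, preferring carbon-containing (organic) ones.
strip_salts_mol <- function(mol) {
  comps <- mol_components(mol)
  if (length(comps) <= 1L) return(mol)
  has_c <- vapply(comps, function(ix) any(mol$elem[ix] == "C"), logical(1))
  size <- lengths(comps)
  key <- vapply(comps, function(ix) paste(sort(mol$elem[ix]), collapse = ""),
                character(1))
  ord <- order(-as.integer(has_c), -size, key)
  submol(mol, comps[[ord[1]]])$mol
}

neutralize_mol <- function(mol) {
  charged <- which(mol$charge != 0L)
  if (!length(charged)) return(mol)
  adj <- adjacency(mol)
  ih <- implicit_h(mol)
  for (i in charged) {
    nb <- adj[[i]]
    if (!is.null(nb) && any(mol$charge[nb[, 1]] * mol$charge[i] < 0)) {
      next  # charge-separated group (nitro, N-oxide, azide): leave as is
    }
    q <- mol$charge[i]
    bos <- sum(if (is.null(nb)) 0 else nb[, 2])
    av <- ALLOWED_VALENCE[[mol$elem[i]]]
    if (is.null(av)) next
    if (q < 0L) {
      # anion: protonation always possible if neutral valence accommodates it
      if (any(av >= bos)) mol$charge[i] <- 0L
    } else if (q > 0L && ih[i] >= q) {
      # cation carrying protons: deprotonate
      if (any(av >= bos)) mol$charge[i] <- 0L
    }
  }
  mol
}

# Rewrite non-ring enols O(H)-C=C to the keto form O=C-C(H).
keto_enol_mol <- function(mol) {
  repeat {
    deg <- heavy_degree(mol)
    rb <- ring_bond_idx(mol)
    hit <- FALSE
    b <- mol$bonds
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]
      if (b$order[k] != 1L) next
      # orient: o = hydroxyl oxygen, c1 = enol carbon
      for (pair in list(c(i, j), c(j, i))) {
        o <- pair[1]; c1 <- pair[2]
        if (mol$elem[o] != "O" || mol$charge[o] != 0L || deg[o] != 1L) next
        if (mol$elem[c1] != "C") next
        # find a non-ring C=C double bond from c1
        cand <- which((b$a1 == c1 | b$a2 == c1) & b$order == 2L)
        cand <- setdiff(cand, rb)
        cand <- cand[vapply(cand, function(kk) {
          other <- if (b$a1[kk] == c1) b$a2[kk] else b$a1[kk]
          mol$elem[other] == "C"
        }, logical(1))]
        if (!length(cand)) next
        kk <- cand[1]
        mol$bonds$order[k] <- 2L    # O=C
        mol$bonds$order[kk] <- 1L   # C-C
        hit <- TRUE
        break
      }
      if (hit) break
    }
    if (!hit) return(mol)
  }
}

standardize_mol <- function(mol, rules = standardization_rules()) {
  if (isTRUE(rules$strip_salts)) mol <- strip_salts_mol(mol)
  if (isTRUE(rules$neutralize)) mol <- neutralize_mol(mol)
  if (isTRUE(rules$keto_enol)) mol <- keto_enol_mol(mol)
  mol
}

#' Standardize a molecule library
#'
#' Applies the [standardization_rules()] transforms to every record and adds
#' `smiles_std` (canonical standardized SMILES) and `mw` (molecular weight,
#' average atomic masses, in Da). Standardization is idempotent and
#' deterministic for a fixed rule set. Records whose structure cannot be
#' parsed or standardized get `std_ok = FALSE` and are excluded by
#' [filter_library()].
#'
#' @param records A library data.frame as returned by [read_library()].
#' @param rules A [standardization_rules()] object.
#' @return The input data.frame with columns `smiles_std`, `mw`, `std_ok`
#'   added.
#' @export
standardize_library <- function(records, rules = standardization_rules()) {
  n <- nrow(records)
  records$smiles_std <- rep(NA_character_, n)
  records$mw <- rep(NA_real_, n)
  records$std_ok <- rep(FALSE, n)
  if (n == 0L) return(records)
  mols <- parse_smiles(records$smiles_input)
  ok <- !vapply(mols, is.null, logical(1))
  std <- vector("list", n)
  for (i in which(ok)) {
    std[[i]] <- standardize_mol(mols[[i]], rules)
  }
  smi <- rep(NA_character_, n)
  smi[ok] <- mols_to_smiles(std[ok])
  records$smiles_std <- smi
  records$std_ok <- ok & !is.na(smi)
  records$mw[records$std_ok] <- vapply(std[records$std_ok], mol_weight,
                                       numeric(1))
  records
}

#' Standardize a vector of SMILES
#'
#' Convenience wrapper over [standardize_library()] for bare structures.
#'
#' @param smiles Character vector of SMILES.
#' @param rules A [standardization_rules()] object.
#' @return Character vector of standardized canonical SMILES (`NA` on
#'   failure), aligned with the input.
#' @export
standardize_smiles <- function(smiles, rules = standardization_rules()) {
  lib <- data.frame(id = paste0("s", seq_along(smiles)),
                    smiles_input = smiles, phase = "other",
                    target_classes = "", stringsAsFactors = FALSE)
  standardize_library(lib, rules)$smiles_std
}

#' Apply the library inclusion filters
#'
#' Keeps molecules whose smallest-set rings all have at most `ring_size_max`
#' bonds (macrocycles are excluded), that contain no metal atoms, and whose
#' molecular weight is strictly below `mw_max` Da. Removals are attributed
#' to the first failing rule in the order `standardization`, `metal`,
#' `ring_size`, `mw`.
#'
#' @param records A standardized library data.frame
#'   (see [standardize_library()]).
#' @param ring_size_max Maximum allowed bonds per smallest-set ring
#'   (default 9).
#' @param mw_max Molecular weight cutoff in Da, strict (default 1000).
#' @param allowed_elements Elements not counted as metals.
#' @return A list with `records` (the kept rows) and `report`, a
#'   `filter_report` list with fields `n_input`, `n_kept`,
#'   `n_removed_by_rule`.
#' @export
filter_library <- function(records, ring_size_max = 9, mw_max = 1000,
                           allowed_elements = ORGANIC_ELEMENTS) {
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  if (n > 0L) {
    std_ok <- if ("std_ok" %in% names(records)) records$std_ok else
      !is.na(records$smiles_std)
    rule[!std_ok] <- "standardization"
    todo <- which(is.na(rule))
    if (length(todo)) {
      mols <- parse_smiles(records$smiles_std[todo])
      for (j in seq_along(todo)) {
        i <- todo[j]; m <- mols[[j]]
        if (is.null(m)) { rule[i] <- "standardization"; next }
        if (contains_metal(m, allowed_elements)) { rule[i] <- "metal"; next }
        sz <- smallest_ring_sizes(m)
        if (length(sz) && max(sz) > ring_size_max) { rule[i] <- "ring_size"; next }
        mw <- records$mw[i]
        if (is.na(mw)) mw <- mol_weight(m)
        if (!is.na(mw) && mw >= mw_max) { rule[i] <- "mw"; next }
      }
    }
  }
  kept <- records[is.na(rule), , drop = FALSE]
  rownames(kept) <- NULL
  removed <- rule[!is.na(rule)]
  report <- structure(list(
    n_input = n,
    n_kept = nrow(kept),
    n_removed_by_rule = as.list(table(removed))
  ), class = "filter_report")
  list(records = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter report: ", x$n_kept, "/", x$n_input, " kept\n", sep = "")
  for (r in names(x$n_removed_by_rule)) {
    cat("  removed by ", r, ": ", x$n_removed_by_rule[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Enforce phase exclusivity
#'
#' A structure (identified by `smiles_std`) present in drugs is removed from
#' all clinical phases; one present in phase 3 is removed from phases 1-2,
#' and so on (ordering `other < phase1 < phase2 < phase3 < drug`). Duplicate
#' records of the same structure within the surviving phase are collapsed to
#' the first.
#'
#' @param records A standardized library data.frame.
#' @return The records whose phase is the highest phase observed for their
#'   structure, one row per structure.
#' @export
enforce_phase_exclusivity <- function(records) {
  if (nrow(records) == 0L) return(records)
  pr <- phase_rank(records$phase)
  best <- tapply(pr, records$smiles_std, max)
  keep <- pr == best[records$smiles_std]
  out <- records[keep, , drop = FALSE]
  out <- out[!duplicated(out$smiles_std), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a configuration file
#'
#' Reads a YAML configuration for the standardization and filtering
#' thresholds; keys `ring_size_max`, `mw_max`, `allowed_elements`,
#' `strip_salts`, `neutralize`, `keto_enol` override the defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of settings merged over the defaults.
#' @export
read_config <- function(path) {
  defaults <- list(ring_size_max = 9, mw_max = 1000,
                   allowed_elements = ORGANIC_ELEMENTS,
                   strip_salts = TRUE, neutralize = TRUE, keto_enol = TRUE)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaults, cfg[names(cfg) %in% names(defaults)])
}
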