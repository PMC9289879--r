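# Ring-system catalog: canonical ring key -> frequency (number of distinct
# molecules containing the ring), per-molecule occurrence count, source
# tags, phases, and the observed growth-vector combinations. This is the
# in-package analog of a large-scale ring database built from synthesized
# chemical space; it is built incrementally and merges associatively so
# large libraries can be processed in shards.

#' Create an empty ring catalog
#'
#' @param settings Optional named list describing the fragmentation settings
#'   used to produce the keys (stored as metadata; [membership_partition()]
#'   refuses to compare catalogs built with different settings).
#' @return An object of class `ring_catalog`.
#' @export
ring_catalog <- function(settings = list(exo_retain = EXO_RETAIN)) {
  structure(list(entries = list(), settings = settings),
            class = "ring_catalog")
}

#' Build a ring catalog from fragmentation results
#'
#' Frequency counts distinct molecules: a ring appearing twice in one
#' molecule adds one to `frequency` and two to `occurrences`.
#' Growth-vector combinations are stored deduplicated as
#' `"ranks|stereo"` strings.
#'
#' @param rings The `rings` data.frame from [fragment_library()].
#' @param tag Source tag recorded on every entry (e.g. a dataset name).
#' @param phases Optional named character vector mapping `molecule_id` to a
#'   phase label.
#' @param settings Fragmentation settings metadata (see [ring_catalog()]).
#' @return A `ring_catalog`.
#' @export
build_catalog <- function(rings, tag = "default", phases = NULL,
                          settings = list(exo_retain = EXO_RETAIN)) {
  cat_ <- ring_catalog(settings)
  if (nrow(rings) == 0L) return(cat_)
  combo <- paste(rings$vectors, rings$stereo_tags, sep = "|")
  for (key in unique(rings$ring_key)) {
    sel <- rings$ring_key == key
    mols <- rings$molecule_id[sel]
    ph <- if (is.null(phases)) character() else
      sort(unique(unname(phases[unique(mols)])))
    cat_$entries[[key]] <- list(
      frequency = length(unique(mols)),
      occurrences = sum(sel),
      n_rings = rings$n_rings[sel][1],
      sources = tag,
      phases = ph,
      vector_combos = sort(unique(combo[sel])))
  }
  cat_
}

#' Merge two ring catalogs
#'
#' Frequencies and occurrence counts add; sources, phases and vector
#' combinations union. Commutative and associative, with the empty catalog
#' as identity.
#'
#' @param a,b `ring_catalog` objects built with the same settings.
#' @return A merged `ring_catalog`.
#' @export
catalog_merge <- function(a, b) {
  stopifnot(inherits(a, "ring_catalog"), inherits(b, "ring_catalog"))
  if (length(a$entries) && length(b$entries) &&
      !identical(a$settings, b$settings)) {
    stop("cannot merge catalogs built with different fragmentation settings")
  }
  out <- ring_catalog(if (length(a$entries)) a$settings else b$settings)
  out$entries <- a$entries
  for (key in names(b$entries)) {
    eb <- b$entries[[key]]
    ea <- out$entries[[key]]
    if (is.null(ea)) {
      out$entries[[key]] <- eb
    } else {
      out$entries[[key]] <- list(
        frequency = ea$frequency + eb$frequency,
        occurrences = ea$occurrences + eb$occurrences,
        n_rings = ea$n_rings,
        sources = sort(unique(c(ea$sources, eb$sources))),
        phases = sort(unique(c(ea$phases, eb$phases))),
        vector_combos = sort(unique(c(ea$vector_combos, eb$vector_combos))))
    }
  }
  out
}

#' @export
print.ring_catalog <- function(x, ...) {
  freq <- catalog_frequencies(x)
  cat("ring catalog:", length(x$entries), "ring systems,",
      sum(freq == 1), "singletons\n")
  invisible(x)
}

#' Frequencies of all catalog entries
#'
#' @param catalog A `ring_catalog`.
#' @return Named integer vector of molecule frequencies.
#' @export
catalog_frequencies <- function(catalog) {
  vapply(catalog$entries, function(e) as.integer(e$frequency), integer(1))
}

#' Partition a query ring set against a reference catalog
#'
#' @param query Character vector of canonical ring keys.
#' @param reference A `ring_catalog`, or a character vector of reference
#'   keys.
#' @param settings Fragmentation settings of the query keys; compared with
#'   the catalog metadata when `reference` is a catalog.
#' @return A list with disjoint character vectors `in_reference` and
#'   `novel`; their sizes sum to `length(unique(query))`.
#' @export
membership_partition <- function(query, reference,
                                 settings = list(exo_retain = EXO_RETAIN)) {
  query <- unique(query)
  if (inherits(reference, "ring_catalog")) {
    if (length(reference$entries) && !identical(reference$settings, settings)) {
      stop("query and reference use different fragmentation settings")
    }
    ref_keys <- names(reference$entries)
  } else {
    ref_keys <- reference
  }
  list(in_reference = intersect(query, ref_keys),
       novel = setdiff(query, ref_keys))
}

#' Export a catalog as a data.frame / CSV
#'
#' @param catalog A `ring_catalog`.
#' @param path Optional path; when given the table is also written as CSV.
#' @return A data.frame with columns `ring_key`, `frequency`, `occurrences`,
#'   `n_rings`, `sources`, `phases`, `n_vector_combos`.
#' @export
catalog_as_data_frame <- function(catalog, path = NULL) {
  e <- catalog$entries
  df <- data.frame(
    ring_key = names(e),
    frequency = vapply(e, function(x) as.integer(x$frequency), integer(1)),
    occurrences = vapply(e, function(x) as.integer(x$occurrences), integer(1)),
    n_rings = vapply(e, function(x) as.integer(x$n_rings), integer(1)),
    sources = vapply(e, function(x) paste(x$sources, collapse = ";"),
                     character(1)),
    phases = vapply(e, function(x) paste(x$phases, collapse = ";"),
                    character(1)),
    n_vector_combos = vapply(e, function(x) length(x$vector_combos),
                             integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$frequency, df$ring_key), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
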