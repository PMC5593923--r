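# Substructure dictionary (SSD) and the binary descriptor matrix: each
# compound becomes the indicator vector of which dictionary fragments it
# contains, with presence-frequency filters for descriptor selection.

#' Build a substructure dictionary
#'
#' Orders mined fragments by descending background frequency (popularity)
#' and then canonical key.  Duplicate canonical keys are an error.
#'
#' @param mined A `mined_set` from [mine()], or a list of records with
#'   `fragment` and `popularity` fields.
#' @param source_id Free-text provenance tag for the source library.
#' @return An object of class `ssd`: `fragments` (list), `keys`, `freq`,
#'   `provenance`.
#' @export
build_ssd <- function(mined, source_id = "library") {
  recs <- if (inherits(mined, "mined_set")) mined$fragments else mined
  if (length(recs) == 0L) stop("no fragments to build an SSD from")
  keys <- vapply(recs, function(r) r$fragment$canonical_key, "")
  if (anyDuplicated(keys)) stop("duplicate canonical keys in SSD input")
  freq <- vapply(recs, function(r) as.integer(r$popularity), 0L)
  o <- order(-freq, keys)
  structure(list(fragments = lapply(recs[o], `[[`, "fragment"),
                 keys = keys[o], freq = freq[o],
                 provenance = list(
                   source = source_id,
                   t = if (inherits(mined, "mined_set")) mined$t else NA)),
            class = "ssd")
}

#' Build an SSD directly from a fragment catalog
#'
#' Convenience for planted-fragment studies where the dictionary is known a
#' priori rather than mined.
#'
#' @param fragments Named list of `fragment`s.
#' @param freq Optional frequency counts (defaults to 0).
#' @param source_id Provenance tag.
#' @return An `ssd`.
#' @export
ssd_from_fragments <- function(fragments, freq = NULL, source_id = "catalog") {
  recs <- lapply(seq_along(fragments), function(i)
    list(fragment = fragments[[i]],
         popularity = if (is.null(freq)) 0L else freq[i]))
  s <- build_ssd(recs, source_id)
  s
}

#' @export
print.ssd <- function(x, ...) {
  cat("<ssd> ", length(x$keys), " fragments (source: ", x$provenance$source,
      ")\n", sep = "")
  invisible(x)
}

#' @export
length.ssd <- function(x) length(x$keys)

.ssd_subset <- function(ssd, idx) {
  ssd$fragments <- ssd$fragments[idx]
  ssd$keys <- ssd$keys[idx]
  ssd$freq <- ssd$freq[idx]
  ssd
}

#' Vectorize a library against an SSD
#'
#' The descriptor matrix L has one row per dictionary fragment and one
#' column per compound; L[i, j] is 1 exactly when fragment i occurs as a
#' subgraph of compound j (binary mode), or the number of distinct
#' embeddings (count mode).
#'
#' @param library List of `molgraph`s.
#' @param ssd An `ssd`.
#' @param mode `"binary"` (canonical) or `"count"`.
#' @return Integer matrix with fragment keys as row names and mol ids as
#'   column names; class `descriptor_matrix`.
#' @export
vectorize <- function(library, ssd, mode = c("binary", "count")) {
  mode <- match.arg(mode)
  if (length(library) == 0L || length(ssd$keys) == 0L)
    stop("library and ssd must be nonempty")
  lib <- library_index(library)
  L <- matrix(0L, nrow = length(ssd$keys), ncol = length(lib),
              dimnames = list(ssd$keys, names(lib)))
  for (i in seq_along(ssd$fragments)) for (j in seq_along(lib)) {
    if (mode == "binary") {
      L[i, j] <- as.integer(has_fragment(ssd$fragments[[i]], lib[[j]]))
    } else {
      L[i, j] <- length(subgraph_match(ssd$fragments[[i]], lib[[j]]))
    }
  }
  class(L) <- c("descriptor_matrix", class(L))
  L
}

#' @export
`[.descriptor_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out) && !inherits(out, "descriptor_matrix"))
    class(out) <- c("descriptor_matrix", class(out))
  out
}

#' Presence counts of SSD fragments in a library
#'
#' @param ssd An `ssd`.
#' @param library List of `molgraph`s.
#' @return Integer vector named by fragment key: number of distinct
#'   molecules containing each fragment.
#' @export
presence_counts <- function(ssd, library) {
  lib <- library_index(library)
  vapply(ssd$fragments, function(f)
    sum(vapply(lib, function(m) has_fragment(f, m), logical(1))),
    0L) -> n
  names(n) <- ssd$keys
  n
}

#' Select descriptors by minimum presence fraction
#'
#' Keeps fragments present in at least `min_fraction` of the library
#' molecules; a fragment at exactly the boundary is kept (the rule removes
#' only those below it).  Idempotent.
#'
#' @param ssd An `ssd`.
#' @param library List of `molgraph`s.
#' @param min_fraction Minimum presence fraction (default 0.05).
#' @return The filtered `ssd`.
#' @export
select_descriptors <- function(ssd, library, min_fraction = 0.05) {
  if (length(library) == 0L) stop("empty library")
  n <- presence_counts(ssd, library)
  keep <- n / length(library) >= min_fraction - 1e-12
  .ssd_subset(ssd, keep)
}

#' Subset an SSD at a frequency tuning point
#'
#' Keeps fragments whose presence count in the library reaches `min_count`
#' and attaches the descending frequency curve (attribute
#' `frequency_curve`) so the flattening point can be read off when choosing
#' the cut.
#'
#' @param ssd An `ssd`.
#' @param library List of `molgraph`s.
#' @param min_count Minimum presence count (>= 1).
#' @return The filtered `ssd` with attribute `frequency_curve`.
#' @export
frequency_tuning_subset <- function(ssd, library, min_count) {
  if (min_count < 1L) stop("min_count must be >= 1")
  n <- presence_counts(ssd, library)
  keep <- n >= min_count
  if (!any(keep)) warning("no fragment reaches min_count = ", min_count)
  out <- .ssd_subset(ssd, keep)
  attr(out, "frequency_curve") <- sort(n, decreasing = TRUE)
  out
}

#' Write a descriptor matrix
#'
#' Writes TSV (`<path>.tsv`) and MatrixMarket (`<path>.mtx`) renditions
#' with separate row/column label files for the sparse form.
#'
#' @param L A `descriptor_matrix`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(L, path) {
  M <- unclass(L)
  utils::write.table(M, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     col.names = NA)
  Matrix::writeMM(Matrix::Matrix(M, sparse = TRUE), paste0(path, ".mtx"))
  writeLines(rownames(M), paste0(path, ".rows"))
  writeLines(colnames(M), paste0(path, ".cols"))
  invisible(path)
}
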