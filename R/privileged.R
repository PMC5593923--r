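# Privileged-fragment election: the privileged fragment index (PFI),
# one-tailed Fisher exact enrichment of each fragment in actives versus a
# background library, Benjamini-Hochberg FDR control, and the ranked report.

#' Privileged fragment index
#'
#' PFI(i) = f_i * a_i / T, where f_i is the number of library molecules
#' containing fragment i, a_i the number of active molecules containing it,
#' and T the library size.  Monotone in both f_i and a_i; maximal (= T)
#' when every molecule is active and contains the fragment.
#'
#' @param f_i Molecules containing the fragment.
#' @param a_i Active molecules containing the fragment (a_i <= f_i).
#' @param T_total Library size (f_i <= T_total).
#' @return Numeric score in [0, f_i].
#' @export
pfi <- function(f_i, a_i, T_total) {
  if (T_total <= 0) stop("T must be > 0")
  if (a_i < 0 || a_i > f_i || f_i > T_total)
    stop("need 0 <= a_i <= f_i <= T")
  f_i * a_i / T_total
}

#' One-tailed Fisher exact test for fragment enrichment
#'
#' For the 2x2 table [[A, B], [C, D]] (matched/unmatched in actives over
#' matched/unmatched in background), sums the hypergeometric probabilities
#' of all tables with the observed margins at least as enriched (a >= A).
#' Equals the standard one-sided "greater" Fisher exact p-value.
#'
#' @param A,B Matched / unmatched counts in the active set.
#' @param C,D Matched / unmatched counts in the background set.
#' @return p-value in (0, 1].
#' @export
fisher_one_tailed <- function(A, B, C, D) {
  counts <- c(A, B, C, D)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("all-zero table")
  m <- A + B           # active set size
  n <- C + D           # background size
  kk <- A + C          # total matched
  hi <- min(m, kk)
  p <- sum(stats::dhyper(A:hi, m, n, kk))
  # the exact tail is positive; guard against floating-point underflow
  min(max(p, 1e-300), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, clipped to 1 and monotone in the p-value
#' ranks (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Count fragment matches in a background library
#'
#' @param fragments Named list of `fragment`s or an `ssd`.
#' @param background List of `molgraph`s playing the background role.
#' @return `data.frame` with `key`, `matched`, `unmatched`.
#' @export
background_counts <- function(fragments, background) {
  fr <- if (inherits(fragments, "ssd")) fragments$fragments else fragments
  keys <- vapply(fr, function(f) f$canonical_key, "")
  matched <- vapply(fr, function(f)
    sum(vapply(background, function(m) has_fragment(f, m), logical(1))), 0L)
  data.frame(key = keys, matched = matched,
             unmatched = length(background) - matched,
             stringsAsFactors = FALSE)
}

#' Elect privileged fragments
#'
#' Per fragment the 2x2 enrichment table is A = active molecules containing
#' it, B = active molecules lacking it, against C/D = matched/unmatched
#' counts in the background library; p comes from [fisher_one_tailed()],
#' q from [fdr_adjust()].  Fragments passing the significance gate are
#' ranked by descending PFI (ties by canonical key) with their active hit
#' lists attached.
#'
#' @param fragments Named list of `fragment`s or an `ssd`.
#' @param focused_library List of `molgraph`s (the focused library).
#' @param activity_labels Binary labels (0/1) aligned to the library.
#' @param background_counts `data.frame` from [background_counts()] (or
#'   with the same columns), aligned by fragment key.
#' @param alpha Significance level (default 0.05).
#' @param gate `"q"` (default: adjusted values) or `"p"` (raw p-values).
#' @return Object of class `privileged_report`: a `data.frame` with one row
#'   per significant fragment (`key`, `f_i`, `a_i`, `T`, `pfi`, `p_value`,
#'   `q_value`) ordered by descending PFI, with `hits` (active hit ids) and
#'   `fragment` list-columns; attribute `all` holds the unfiltered table.
#' @export
elect_privileged <- function(fragments, focused_library, activity_labels,
                             background_counts, alpha = 0.05,
                             gate = c("q", "p")) {
  gate <- match.arg(gate)
  fr <- if (inherits(fragments, "ssd")) fragments$fragments else fragments
  lib <- library_index(focused_library)
  if (length(activity_labels) != length(lib))
    stop("labels must align with the library")
  if (sum(activity_labels == 1L) == 0L) stop("no active molecules")
  keys <- vapply(fr, function(f) f$canonical_key, "")
  T_total <- length(lib)
  act <- activity_labels == 1L

  present <- vapply(fr, function(f)
    vapply(lib, function(m) has_fragment(f, m), logical(1)),
    logical(length(lib)))
  if (is.null(dim(present))) present <- matrix(present, nrow = length(lib))

  f_i <- colSums(present)
  a_i <- colSums(present & act)
  bg <- background_counts[match(keys, background_counts$key), , drop = FALSE]
  if (anyNA(bg$matched)) stop("background counts missing for some fragments")
  n_act <- sum(act)
  p <- vapply(seq_along(fr), function(i)
    fisher_one_tailed(a_i[i], n_act - a_i[i], bg$matched[i], bg$unmatched[i]),
    0)
  q <- fdr_adjust(p)
  score <- vapply(seq_along(fr), function(i) pfi(f_i[i], a_i[i], T_total), 0)
  hits <- lapply(seq_along(fr), function(i)
    names(lib)[present[, i] & act])

  tab <- data.frame(key = keys, f_i = as.integer(f_i), a_i = as.integer(a_i),
                    T = T_total, pfi = score, p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  tab$hits <- hits
  tab$fragment <- fr
  o <- order(-tab$pfi, tab$key)
  tab <- tab[o, ]
  keep <- if (gate == "q") tab$q_value < alpha else tab$p_value < alpha
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, all = tab, alpha = alpha, gate = gate,
            class = c("privileged_report", "data.frame"))
}

#' @export
print.privileged_report <- function(x, ...) {
  cat("<privileged_report> ", nrow(x), " significant fragment(s) (gate ",
      attr(x, "gate"), " < ", attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x[, c("key", "f_i", "a_i", "T", "pfi", "p_value",
                         "q_value")], digits = 4)
  invisible(x)
}

#' Write a privileged-fragment report
#'
#' @param report A `privileged_report`.
#' @param path Output path stem (writes `<path>.tsv` and `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_privileged_report <- function(report, path) {
  flat <- report[, c("key", "f_i", "a_i", "T", "pfi", "p_value", "q_value")]
  flat$rendering <- vapply(report$fragment, fragment_rendering, "")
  flat$hits <- vapply(report$hits, paste, "", collapse = ",")
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(report)), function(i) list(
      key = report$key[i], f_i = report$f_i[i], a_i = report$a_i[i],
      T = report$T[i], pfi = report$pfi[i], p_value = report$p_value[i],
      q_value = report$q_value[i], hits = report$hits[[i]])),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
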