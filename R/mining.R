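# Frequent maximal substructure mining: a depth-first tree per root (single
# bond) fragment, nodes annotated with subIDs (linear embedding notation),
# potential-reporting-node (PRN) detection, and pruning through a registry
# of already-reported subID strings.

#' Construct a subID
#'
#' A subID is the linear notation recording every embedding of a growing
#' substructure: an ordered list of components, each a molecule id plus the
#' set of bond ids the embedding covers.  Its canonical string (mol ids and
#' bond ids sorted) makes isomorphism bookkeeping a string comparison.
#'
#' @param components Named list: names are molecule ids, each element a
#'   vector of bond ids (one list element per embedding; a molecule may
#'   contribute several components).
#' @return An object of class `subid`.
#' @export
subid <- function(components) {
  if (length(components) == 0L) stop("a subID needs at least one component")
  mol_ids <- names(components)
  if (is.null(mol_ids) || any(!nzchar(mol_ids)))
    stop("every subID component needs a molecule id as its name")
  sizes <- lengths(components)
  if (length(unique(sizes)) != 1L)
    stop("all subID components must have the same number of bond ids")
  comp <- lapply(components, function(x) .rsort(as.character(x)))
  str <- paste0(mol_ids, ":", vapply(comp, paste, "", collapse = ","))
  o <- order(str, method = "radix")
  structure(list(components = comp[o], mol_ids = mol_ids[o],
                 canonical_string = paste(str[o], collapse = "|")),
            class = "subid")
}

#' @export
print.subid <- function(x, ...) {
  cat("<subid> ", x$canonical_string, " (popularity ", popularity(x), ")\n",
      sep = "")
  invisible(x)
}

#' Popularity (support) of a subID
#'
#' The number of distinct library molecules among the components; a molecule
#' carrying several embeddings of the fragment counts once.
#'
#' @param subid A `subid`.
#' @return Integer count.
#' @export
popularity <- function(subid) {
  stopifnot(inherits(subid, "subid"))
  length(unique(subid$mol_ids))
}

.tree_node <- function(fragment, subid, parent_key = NA_character_) {
  structure(list(fragment = fragment, subid = subid, parent_key = parent_key,
                 is_prn = NA), class = "tree_node")
}

#' Root nodes of the substructure generation trees
#'
#' One root per distinct single-bond fragment type occurring in the library;
#' a root's subID has one component per occurrence of that bond type in
#' every molecule.  Roots are ordered by canonical key.
#'
#' @param library List of `molgraph`s.
#' @return Named list of `tree_node`s keyed by canonical key.
#' @export
init_roots <- function(library) {
  if (length(library) == 0L) stop("empty library")
  acc <- list()  # key -> list(fragment, comps = list(named bond vectors))
  for (mol in library) {
    if (nrow(mol$bonds) == 0L) next
    for (i in seq_len(nrow(mol$bonds))) {
      f <- fragment_from_bonds(mol, mol$bonds$bond_id[i])
      key <- f$canonical_key
      comp <- list(mol$bonds$bond_id[i]); names(comp) <- mol$mol_id
      if (is.null(acc[[key]])) acc[[key]] <- list(fragment = f, comps = comp)
      else acc[[key]]$comps <- c(acc[[key]]$comps, comp)
    }
  }
  if (length(acc) == 0L) {
    warning("library has no bonds; no root fragments")
    return(list())
  }
  acc <- acc[order(names(acc))]
  lapply(acc, function(x) .tree_node(x$fragment, subid(x$comps)))
}

#' Grow a tree node by one adjacent bond
#'
#' Every embedding in the node's subID is extended by every adjacent bond
#' not already covered; the resulting occurrences are grouped by the
#' canonical form of the induced fragment, one child node per distinct
#' fragment with all supporting components, children ordered by canonical
#' key.  Because root subIDs are complete and extension preserves
#' completeness, each node's subID lists every embedding of its fragment in
#' the library.
#'
#' @param node A `tree_node`.
#' @param library Named list of `molgraph`s keyed by mol_id (see
#'   [library_index()]).
#' @param keycache Optional environment memoizing canonical keys per
#'   (molecule, bond set); [mine()] shares one across the traversal.
#' @return Named list of child `tree_node`s (empty if nothing is adjacent).
#' @export
grow_node <- function(node, library, keycache = NULL) {
  lib <- library_index(library)
  comps <- node$subid$components
  mids <- node$subid$mol_ids
  # distinct extension occurrences (mol, bond set), deduplicated before any
  # canonicalization: the same extended embedding is reachable from several
  # parent embeddings
  occ_mid <- character(); occ_set <- list()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(comps)) {
    mol <- lib[[mids[i]]]
    if (is.null(mol)) stop("subID references molecule absent from library: ", mids[i])
    bset <- as.integer(comps[[i]])
    rows <- match(bset, mol$bonds$bond_id)
    atoms <- unique(c(mol$bonds$a1[rows], mol$bonds$a2[rows]))
    adjacent <- mol$bonds$bond_id[mol$bonds$a1 %in% atoms | mol$bonds$a2 %in% atoms]
    for (b in setdiff(adjacent, bset)) {
      newset <- sort.int(c(bset, b))
      ck <- paste0(mids[i], ":", paste(newset, collapse = ","))
      if (!exists(ck, envir = seen, inherits = FALSE)) {
        assign(ck, TRUE, envir = seen)
        occ_mid <- c(occ_mid, mids[i])
        occ_set[[length(occ_set) + 1L]] <- newset
      }
    }
  }
  if (length(occ_set) == 0L) return(list())
  acc <- list()
  for (k in seq_along(occ_set)) {
    mid <- occ_mid[k]; newset <- occ_set[[k]]
    ck <- paste0(mid, ":", paste(newset, collapse = ","))
    f <- NULL
    if (!is.null(keycache) && exists(ck, envir = keycache, inherits = FALSE)) {
      key <- get(ck, envir = keycache)
    } else {
      f <- fragment_from_bonds(lib[[mid]], newset)
      key <- f$canonical_key
      if (!is.null(keycache)) assign(ck, key, envir = keycache)
    }
    if (is.null(acc[[key]])) {
      if (is.null(f)) f <- fragment_from_bonds(lib[[mid]], newset)
      acc[[key]] <- list(fragment = f, comps = list())
    }
    comp <- list(newset); names(comp) <- mid
    acc[[key]]$comps <- c(acc[[key]]$comps, comp)
  }
  acc <- acc[order(names(acc))]
  lapply(acc, function(x)
    .tree_node(x$fragment, subid(x$comps), node$fragment$canonical_key))
}

#' Is a node a potential reporting node (PRN)?
#'
#' A node is a PRN when no child preserves its full molecule support: the
#' node's fragment cannot be extended without losing some supporting
#' molecule, i.e. it is maximal for its support set.  Leaves are PRNs.
#'
#' @param node A `tree_node`.
#' @param children The node's children, exactly as returned by [grow_node()].
#' @return Logical scalar.
#' @export
is_prn <- function(node, children) {
  if (length(children) == 0L) return(TRUE)
  parent_support <- sort(unique(node$subid$mol_ids))
  !any(vapply(children, function(ch)
    identical(sort(unique(ch$subid$mol_ids)), parent_support), logical(1)))
}

#' Index a library by molecule id
#'
#' @param library List of `molgraph`s (possibly already named).
#' @return The same list named by `mol_id`; errors on duplicate ids.
#' @export
library_index <- function(library) {
  ids <- vapply(library, function(m) m$mol_id, "")
  if (!is.null(names(library)) && identical(names(library), ids)) return(library)
  if (anyDuplicated(ids)) stop("duplicate mol_ids in library")
  names(library) <- ids
  library
}

#' Mine frequent maximal substructures
#'
#' Depth-first traversal over all root trees.  A node already present (by
#' subID canonical string) in the reported-substructure registry is pruned:
#' an identical subID means an identical fragment with an identical subtree,
#' already fully explored.  PRNs with popularity at or above the threshold
#' `t` are reported; children are expanded only while their popularity can
#' still reach `t`.  With `prune = FALSE` the registry is ignored, which
#' must (and, in the test suite, does) leave the reported set unchanged.
#'
#' @param library List of `molgraph`s.
#' @param t Minimum popularity (support) of a reported fragment, >= 2.
#' @param max_edges Safety cap on fragment size in bonds.
#' @param prune Use the subID registry to prune revisited branches?
#' @param integrity Apply [integrity_filter()] (drop fragments with broken
#'   aromatic rings) before returning?
#' @return An object of class `mined_set`: list with `fragments` (list of
#'   records: `fragment`, `subid`, `popularity`, `mol_ids`), `visited`
#'   (nodes expanded), `pruned` (registry hits), `t`, `n_molecules`.
#' @export
mine <- function(library, t = 2, max_edges = 20L, prune = TRUE,
                 integrity = TRUE) {
  if (length(library) == 0L) stop("empty library")
  if (t < 2) stop("popularity threshold t must be >= 2")
  lib <- library_index(library)
  registry <- new.env(parent = emptyenv())   # subID string -> TRUE
  keycache <- new.env(parent = emptyenv())   # (mol, bond set) -> canonical key
  reported <- list()                         # canonical key -> record
  visited <- 0L; pruned <- 0L

  visit <- function(node) {
    skey <- node$subid$canonical_string
    if (prune && exists(skey, envir = registry, inherits = FALSE)) {
      pruned <<- pruned + 1L
      return(invisible(NULL))
    }
    visited <<- visited + 1L
    children <- if (node$fragment$n_edges < max_edges)
      grow_node(node, lib, keycache) else list()
    if (is_prn(node, children) && popularity(node$subid) >= t) {
      assign(skey, TRUE, envir = registry)
      fkey <- node$fragment$canonical_key
      if (is.null(reported[[fkey]]))
        reported[[fkey]] <<- list(fragment = node$fragment, subid = node$subid,
                                  popularity = popularity(node$subid),
                                  mol_ids = sort(unique(node$subid$mol_ids)))
    }
    for (ch in children) if (popularity(ch$subid) >= t) visit(ch)
    invisible(NULL)
  }

  for (root in init_roots(lib)) visit(root)
  if (length(reported)) reported <- reported[order(names(reported))]
  out <- structure(list(fragments = reported, visited = visited,
                        pruned = pruned, t = t,
                        n_molecules = length(lib)),
                   class = "mined_set")
  if (integrity) out$fragments <- integrity_filter(out$fragments, lib)
  out
}

#' @export
print.mined_set <- function(x, ...) {
  cat("<mined_set> ", length(x$fragments), " maximal fragments (t = ", x$t,
      ", ", x$n_molecules, " molecules; ", x$visited, " nodes expanded, ",
      x$pruned, " pruned)\n", sep = "")
  invisible(x)
}

#' Collapse reported fragments into frequent fragment ids (FFIDs)
#'
#' An FFID is a subID with bond ids removed: the multiset of supporting
#' molecule ids.  Fragments sharing an FFID are grouped; within a group a
#' fragment that is a substructure of another is dropped (the larger is
#' kept), while mutually non-nested fragments stay together.
#'
#' @param reported List of records as in `mined_set$fragments`.
#' @return Named list keyed by FFID string; each element has `mol_ids`
#'   (multiset) and `fragments` (surviving records).
#' @export
collapse_ffid <- function(reported) {
  if (length(reported) == 0L) stop("nothing to collapse")
  ffid_of <- vapply(reported, function(r)
    paste(sort(r$subid$mol_ids), collapse = "|"), "")
  groups <- split(reported, ffid_of)
  out <- lapply(groups, function(grp) {
    keep <- rep(TRUE, length(grp))
    if (length(grp) > 1L) {
      for (i in seq_along(grp)) for (j in seq_along(grp)) {
        if (i == j || !keep[i]) next
        fi <- grp[[i]]$fragment; fj <- grp[[j]]$fragment
        if (fi$n_edges < fj$n_edges &&
            has_fragment(fi, fragment_as_molgraph(fj)))
          keep[i] <- FALSE
      }
    }
    list(mol_ids = sort(grp[[1L]]$subid$mol_ids), fragments = grp[keep])
  })
  out[order(names(out))]
}

#' Drop fragments that break aromatic rings
#'
#' A chemically intact fragment may not contain an aromatic bond whose
#' smallest aromatic ring in the source molecule is not fully inside the
#' fragment (e.g. three contiguous bonds cut out of a benzene ring).  A
#' fragment is removed if any of its supporting embeddings leaves such a
#' ring incomplete.
#'
#' @param reported List of records as in `mined_set$fragments`.
#' @param library The library the fragments were mined from.
#' @return The filtered list.
#' @export
integrity_filter <- function(reported, library) {
  lib <- library_index(library)
  ok <- vapply(reported, function(r) {
    if (!any(r$fragment$bonds$order == "aromatic")) return(TRUE)
    comps <- r$subid$components; mids <- r$subid$mol_ids
    for (i in seq_along(comps)) {
      mol <- lib[[mids[i]]]
      bset <- as.integer(comps[[i]])
      rows <- match(bset, mol$bonds$bond_id)
      arom <- bset[mol$bonds$order[rows] == "aromatic"]
      for (b in arom)
        if (!.aromatic_ring_complete(mol, bset, b)) return(FALSE)
    }
    TRUE
  }, logical(1))
  reported[ok]
}

# TRUE when some minimum-length aromatic ring of `mol` through bond `b`
# lies entirely inside the bond set `bset`.
.aromatic_ring_complete <- function(mol, bset, b) {
  mb <- mol$bonds
  arom_rows <- which(mb$order == "aromatic" & mb$bond_id != b)
  row_b <- which(mb$bond_id == b)
  src <- mb$a1[row_b]; dst <- mb$a2[row_b]
  d_all <- .bfs_dist(mb[arom_rows, , drop = FALSE], src)[as.character(dst)]
  if (is.na(d_all) || !is.finite(d_all)) return(TRUE)  # not in any aromatic ring
  in_frag <- arom_rows[mb$bond_id[arom_rows] %in% bset]
  d_frag <- .bfs_dist(mb[in_frag, , drop = FALSE], src)[as.character(dst)]
  isTRUE(is.finite(d_frag) && d_frag == d_all)
}

# shortest-path distances from `src` over a bond table; named by atom id
.bfs_dist <- function(bonds, src) {
  dist <- c(structure(0, names = as.character(src)))
  if (nrow(bonds) == 0L) return(dist)
  frontier <- as.character(src); d <- 0
  repeat {
    d <- d + 1
    nxt <- character()
    for (v in frontier) {
      vi <- as.integer(v)
      nb <- c(bonds$a2[bonds$a1 == vi], bonds$a1[bonds$a2 == vi])
      for (w in as.character(nb)) if (is.na(dist[w])) {
        dist[w] <- d; nxt <- c(nxt, w)
      }
    }
    if (length(nxt) == 0L) break
    frontier <- nxt
  }
  dist
}

#' Tabulate a mined set
#'
#' @param mined A `mined_set`.
#' @return `data.frame` with canonical key, edge count, popularity and the
#'   supporting molecule ids (comma-separated).
#' @export
mined_table <- function(mined) {
  fr <- mined$fragments
  data.frame(
    canonical_key = vapply(fr, function(r) r$fragment$canonical_key, ""),
    rendering = vapply(fr, function(r) fragment_rendering(r$fragment), ""),
    n_edges = vapply(fr, function(r) r$fragment$n_edges, 0L),
    popularity = vapply(fr, function(r) r$popularity, 0L),
    mol_ids = vapply(fr, function(r) paste(r$mol_ids, collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
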