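# Core molecular-graph model: hydrogen-suppressed labeled graphs, canonical
# fragment keys, subgraph matching, and exhaustive connected-subgraph
# enumeration (the brute-force oracle used throughout the test suite).

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Construct a molecular graph
#'
#' A molecular graph is a hydrogen-suppressed labeled graph: an ordered atom
#' list (element, formal charge, aromatic flag), an ordered bond list with
#' orders in `single`, `double`, `triple`, `aromatic`, and a free-form
#' property table (name, activity fields).  Atom and bond ids must be unique
#' within the graph; hydrogens are not represented.
#'
#' @param mol_id Identifier, coerced to character.
#' @param atoms `data.frame` with columns `atom_id`, `element`, and
#'   optionally `charge` (default 0) and `aromatic` (default `FALSE`).
#' @param bonds `data.frame` with columns `bond_id`, `a1`, `a2`, `order`.
#'   May have zero rows for a single-atom graph.
#' @param properties Named list of molecule-level properties.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(mol_id, atoms, bonds = NULL, properties = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms <- atoms[, c("atom_id", "element", "charge", "aromatic")]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$charge <- as.integer(atoms$charge)
  atoms$aromatic <- as.logical(atoms$aromatic)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(bond_id = integer(), a1 = integer(), a2 = integer(),
                        order = character(), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds <- bonds[, c("bond_id", "a1", "a2", "order")]
    bonds$bond_id <- as.integer(bonds$bond_id)
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.character(bonds$order)
  }
  g <- structure(list(mol_id = as.character(mol_id), atoms = atoms,
                      bonds = bonds, properties = properties),
                 class = "molgraph")
  validate_molgraph(g)
  g
}

#' Validate a molecular graph
#'
#' Checks structural invariants: unique atom and bond ids, bonds referencing
#' two distinct existing atoms, no duplicate atom pairs, known bond orders,
#' and no explicit hydrogens.  With `valence = TRUE` also checks a simple
#' valence table (C<=4, N<=3, O<=2, S<=6, Cl<=1, aromatic bonds counted 1.5).
#'
#' @param g A `molgraph`.
#' @param valence Also check the valence table?
#' @return `g`, invisibly; errors on violation.
#' @export
validate_molgraph <- function(g, valence = FALSE) {
  stopifnot(inherits(g, "molgraph"))
  a <- g$atoms; b <- g$bonds
  if (nrow(a) == 0L) stop("molgraph '", g$mol_id, "': no atoms")
  if (anyDuplicated(a$atom_id)) stop("molgraph '", g$mol_id, "': duplicate atom_id")
  if (any(a$element == "H")) stop("molgraph '", g$mol_id, "': explicit hydrogens are not allowed")
  if (nrow(b)) {
    if (anyDuplicated(b$bond_id)) stop("molgraph '", g$mol_id, "': duplicate bond_id")
    if (!all(b$order %in% BOND_ORDERS))
      stop("molgraph '", g$mol_id, "': unknown bond order")
    if (any(b$a1 == b$a2)) stop("molgraph '", g$mol_id, "': self-bond")
    if (!all(c(b$a1, b$a2) %in% a$atom_id))
      stop("molgraph '", g$mol_id, "': bond references missing atom")
    pair <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(pair)) stop("molgraph '", g$mol_id, "': duplicate bond between same atoms")
  }
  if (valence) {
    # aromatic bonds count 1.5 except at lone-pair donors (O, S), where the
    # two ring bonds are formally single (furan, thiophene)
    vmax <- c(C = 4, N = 3, O = 2, S = 6, P = 5, Cl = 1, Br = 1, F = 1, I = 1)
    ov <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
    elem_of <- structure(a$element, names = as.character(a$atom_id))
    deg <- numeric(nrow(a)); names(deg) <- as.character(a$atom_id)
    if (nrow(b)) for (i in seq_len(nrow(b))) {
      for (end in c(as.character(b$a1[i]), as.character(b$a2[i]))) {
        w <- ov[[b$order[i]]]
        if (b$order[i] == "aromatic" && elem_of[[end]] %in% c("O", "S")) w <- 1
        deg[end] <- deg[end] + w
      }
    }
    lim <- vmax[a$element]
    bad <- !is.na(lim) & deg > lim + 1e-9
    if (any(bad))
      stop("molgraph '", g$mol_id, "': valence exceeded at atom(s) ",
           paste(a$atom_id[bad], collapse = ", "))
  }
  invisible(g)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$mol_id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# atom label used for matching and canonicalization
.atom_label <- function(atoms) {
  paste0(atoms$element, ifelse(atoms$charge == 0L, "",
                               sprintf("%+d", atoms$charge)),
         ifelse(atoms$aromatic, ":ar", ""))
}

#' Extract a fragment from a molecule by bond ids
#'
#' The bond-induced subgraph must be connected; fragments are the unit of
#' mining and matching and carry a canonical key such that two fragments are
#' isomorphic (matching element, charge, aromatic flag and bond order) if
#' and only if their keys are equal.
#'
#' @param mol A `molgraph`.
#' @param bond_ids Bond ids of `mol` inducing the fragment.
#' @return An object of class `fragment` with fields `atoms`, `bonds`,
#'   `canonical_key`, `n_edges`.
#' @export
fragment_from_bonds <- function(mol, bond_ids) {
  b <- mol$bonds[match(bond_ids, mol$bonds$bond_id), , drop = FALSE]
  if (anyNA(b$bond_id)) stop("unknown bond id(s) for molecule ", mol$mol_id)
  aid <- unique(c(b$a1, b$a2))
  a <- mol$atoms[match(aid, mol$atoms$atom_id), , drop = FALSE]
  new_fragment(a, b)
}

#' Construct a fragment from raw atom and bond tables
#'
#' @param atoms,bonds Tables as in [molgraph()].
#' @return A `fragment`; errors if the bond-induced graph is disconnected.
#' @export
new_fragment <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) == 0L) stop("a fragment needs at least one bond")
  if (!.is_connected(atoms$atom_id, bonds))
    stop("fragment is disconnected: ", nrow(atoms), " atoms, ",
         nrow(bonds), " bonds")
  f <- structure(list(atoms = atoms, bonds = bonds,
                      canonical_key = NULL, n_edges = nrow(bonds)),
                 class = "fragment")
  f$canonical_key <- canonical_form(f)
  f
}

#' @export
print.fragment <- function(x, ...) {
  cat("<fragment> ", x$n_edges, " bonds: ", x$canonical_key, "\n", sep = "")
  invisible(x)
}

#' View a fragment as a standalone molecular graph
#'
#' @param fragment A `fragment`.
#' @param mol_id Identifier for the resulting graph.
#' @return A `molgraph` with the fragment's atoms and bonds.
#' @export
fragment_as_molgraph <- function(fragment, mol_id = "fragment") {
  molgraph(mol_id, fragment$atoms, fragment$bonds)
}

.is_connected <- function(atom_ids, bonds) {
  n <- length(atom_ids)
  if (n == 1L) return(TRUE)
  idx <- seq_len(n); names(idx) <- as.character(atom_ids)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    u <- idx[[as.character(bonds$a1[i])]]; v <- idx[[as.character(bonds$a2[i])]]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# ---- canonicalization -------------------------------------------------------
# Iterative neighborhood-label refinement (Morgan-style) followed by
# exhaustive individualization of residual symmetric classes.  The canonical
# string is the lexicographic minimum over all refinement-consistent discrete
# orderings, so equal strings <=> isomorphic labeled graphs.

#' Canonical string form of a fragment
#'
#' Deterministic serialization invariant under atom/bond reordering; two
#' fragments have equal strings exactly when they are isomorphic as labeled
#' graphs (element, formal charge, aromatic flag, bond order).  This is the
#' identity used by the mining registry and the descriptor dictionary.
#'
#' @param fragment A `fragment`, or anything with `$atoms`/`$bonds`
#'   describing a connected graph.
#' @return A character scalar.
#' @export
canonical_form <- function(fragment) {
  a <- fragment$atoms; b <- fragment$bonds
  n <- nrow(a)
  idx <- seq_len(n); names(idx) <- as.character(a$atom_id)
  lab <- .atom_label(a)
  m <- nrow(b)
  eu <- idx[as.character(b$a1)]; ev <- idx[as.character(b$a2)]
  eo <- b$order
  adj <- vector("list", n)   # list of c(neighbor, edge index)
  for (i in seq_len(m)) {
    adj[[eu[i]]] <- rbind(adj[[eu[i]]], c(ev[i], i))
    adj[[ev[i]]] <- rbind(adj[[ev[i]]], c(eu[i], i))
  }

  refine <- function(col) {
    repeat {
      sig <- vapply(seq_len(n), function(v) {
        nb <- adj[[v]]
        if (is.null(nb)) return(col[v])
        s <- .rsort(paste0(eo[nb[, 2L]], "~", col[nb[, 1L]]))
        paste0(col[v], "|", paste(s, collapse = ","))
      }, character(1))
      newcol <- as.character(match(sig, .rsort(unique(sig))))
      if (length(unique(newcol)) == length(unique(col))) return(newcol)
      col <- newcol
    }
  }

  serialize <- function(ord) {
    # ord[v] = position of vertex v in the canonical ordering
    el <- paste0(pmin(ord[eu], ord[ev]), "-", pmax(ord[eu], ord[ev]), ":", eo)
    paste0(paste(lab[order(ord)], collapse = ","), ";",
           paste(.rsort(el), collapse = "|"))
  }

  best <- NULL
  search <- function(col) {
    col <- refine(col)
    tab <- split(seq_len(n), col)
    sizes <- vapply(tab, length, 1L)
    if (all(sizes == 1L)) {
      key <- rank(paste0(formatC(nchar(col), width = 6, flag = "0"), col),
                  ties.method = "first")
      s <- serialize(key)
      if (is.null(best) || s < best) best <<- s
      return(invisible(NULL))
    }
    # individualize each member of the first smallest non-singleton class
    cand <- tab[sizes > 1L]
    ords <- order(vapply(cand, length, 1L), names(cand))
    cls <- cand[[ords[1L]]]
    for (v in cls) {
      col2 <- col
      col2[v] <- paste0(col2[v], "*")
      search(col2)
    }
  }
  search(lab)
  best
}

#' SMILES-like linear rendering of a fragment
#'
#' Human-readable depth-first serialization: lowercase symbols for aromatic
#' atoms, `=`/`#` for double/triple bonds, parentheses for branches and
#' digits for ring closures.  For display only — not canonical and not
#' guaranteed to re-parse; fragment identity is the canonical key.
#'
#' @param fragment A `fragment` (or anything with `$atoms`/`$bonds`).
#' @return A character scalar.
#' @export
fragment_rendering <- function(fragment) {
  a <- fragment$atoms; b <- fragment$bonds
  sym <- ifelse(a$aromatic, tolower(a$element), a$element)
  sym <- ifelse(nchar(sym) > 1L | a$charge != 0L,
                paste0("[", sym, ifelse(a$charge == 0L, "",
                                        sprintf("%+d", a$charge)), "]"),
                sym)
  names(sym) <- as.character(a$atom_id)
  bsym <- c(single = "", double = "=", triple = "#", aromatic = "")
  inc <- lapply(a$atom_id, function(x) which(b$a1 == x | b$a2 == x))
  names(inc) <- as.character(a$atom_id)

  # spanning DFS: classify bonds into tree bonds and ring closures
  start <- a$atom_id[1L]
  seen <- as.character(start)
  tree <- logical(nrow(b)); ring <- integer(0)
  order_visit <- function(atom) {
    for (r in inc[[as.character(atom)]]) {
      if (tree[r] || r %in% ring) next
      other <- if (b$a1[r] == atom) b$a2[r] else b$a1[r]
      if (as.character(other) %in% seen) {
        ring <<- c(ring, r)
      } else {
        tree[r] <<- TRUE
        seen <<- c(seen, as.character(other))
        order_visit(other)
      }
    }
  }
  order_visit(start)
  digit <- integer(nrow(b))
  digit[ring] <- seq_along(ring)

  emit <- function(atom, in_row) {
    out <- sym[[as.character(atom)]]
    for (r in inc[[as.character(atom)]])
      if (digit[r] > 0L) out <- paste0(out, bsym[[b$order[r]]], digit[r])
    branches <- character()
    for (r in inc[[as.character(atom)]]) {
      if (!tree[r] || identical(r, in_row)) next
      other <- if (b$a1[r] == atom) b$a2[r] else b$a1[r]
      branches <- c(branches, paste0(bsym[[b$order[r]]], emit(other, r)))
    }
    if (length(branches) > 1L)
      out <- paste0(out, paste0("(", branches[-length(branches)], ")",
                                collapse = ""), branches[length(branches)])
    else if (length(branches) == 1L) out <- paste0(out, branches)
    out
  }
  emit(start, NA_integer_)
}

# ---- subgraph matching ------------------------------------------------------

#' Find all embeddings of a fragment in a molecule
#'
#' Backtracking subgraph monomorphism over bonds: atom labels (element,
#' charge, aromatic flag) and bond orders must match exactly.  Embeddings
#' are identified by the set of molecule bond ids they cover; automorphic
#' re-mappings onto the same bond set count once.
#'
#' @param fragment A `fragment`.
#' @param mol A `molgraph`.
#' @param first_only Stop after the first embedding (presence testing).
#' @return List of integer vectors (sorted bond ids of `mol`); empty list if
#'   the fragment is absent.
#' @export
subgraph_match <- function(fragment, mol, first_only = FALSE) {
  fa <- fragment$atoms; fb <- fragment$bonds
  ma <- mol$atoms; mb <- mol$bonds
  if (nrow(mb) < nrow(fb)) return(list())
  flab <- .atom_label(fa); names(flab) <- as.character(fa$atom_id)
  mlab <- .atom_label(ma); names(mlab) <- as.character(ma$atom_id)

  # order fragment bonds so each shares an atom with an earlier one
  ord <- .connected_bond_order(fb)
  fb <- fb[ord, , drop = FALSE]

  # molecule adjacency: incident bond rows per atom
  minc <- lapply(as.character(ma$atom_id), function(id)
    which(mb$a1 == as.integer(id) | mb$a2 == as.integer(id)))
  names(minc) <- as.character(ma$atom_id)

  results <- new.env(parent = emptyenv())
  found_any <- FALSE

  recurse <- function(i, amap, used) {
    # amap: named chr->chr fragment atom id -> mol atom id; used: bond rows
    if (found_any && first_only) return(invisible(NULL))
    if (i > nrow(fb)) {
      key <- paste(sort.int(mb$bond_id[used]), collapse = ",")
      assign(key, sort(mb$bond_id[used]), envir = results)
      found_any <<- TRUE
      return(invisible(NULL))
    }
    u <- as.character(fb$a1[i]); v <- as.character(fb$a2[i]); oo <- fb$order[i]
    mu <- amap[[u]]; mv <- amap[[v]]
    if (!is.null(mu)) {
      cand <- minc[[mu]]
    } else if (!is.null(mv)) {
      tmp <- u; u <- v; v <- tmp; mu <- mv; mv <- amap[[v]]
      cand <- minc[[mu]]
    } else {
      cand <- seq_len(nrow(mb))  # first bond only
    }
    for (j in cand) {
      if (j %in% used || mb$order[j] != oo) next
      ends <- c(as.character(mb$a1[j]), as.character(mb$a2[j]))
      for (k in 1:2) {
        x <- ends[k]; y <- ends[3L - k]
        if (!is.null(mu) && x != mu) next
        if (mlab[[x]] != flab[[u]] || mlab[[y]] != flab[[v]]) next
        if (!is.null(mv)) {
          if (y != mv) next
          recurse(i + 1L, amap, c(used, j))
        } else {
          if (y %in% unlist(amap, use.names = FALSE)) next
          amap2 <- amap; amap2[[v]] <- y
          if (is.null(mu)) {
            if (x %in% unlist(amap, use.names = FALSE)) next
            amap2[[u]] <- x
          }
          recurse(i + 1L, amap2, c(used, j))
        }
        if (found_any && first_only) return(invisible(NULL))
      }
    }
    invisible(NULL)
  }
  recurse(1L, structure(list(), names = character()), integer())
  out <- as.list(results)
  if (length(out) == 0L) return(list())
  out <- out[order(names(out))]
  names(out) <- NULL
  out
}

.connected_bond_order <- function(bonds) {
  m <- nrow(bonds)
  if (m == 1L) return(1L)
  placed <- logical(m); ord <- integer(m)
  ord[1L] <- 1L; placed[1L] <- TRUE
  atoms <- c(bonds$a1[1L], bonds$a2[1L])
  for (i in 2:m) {
    nxt <- which(!placed & (bonds$a1 %in% atoms | bonds$a2 %in% atoms))[1L]
    if (is.na(nxt)) stop("fragment bonds are disconnected")
    ord[i] <- nxt; placed[nxt] <- TRUE
    atoms <- unique(c(atoms, bonds$a1[nxt], bonds$a2[nxt]))
  }
  ord
}

#' Molecule contains a fragment?
#'
#' @param fragment A `fragment`.
#' @param mol A `molgraph`.
#' @return Logical scalar.
#' @export
has_fragment <- function(fragment, mol) {
  length(subgraph_match(fragment, mol, first_only = TRUE)) > 0L
}

# ---- exhaustive enumeration -------------------------------------------------

#' Enumerate all connected bond-induced subgraphs of a molecule
#'
#' Exhaustive oracle: returns every distinct (by canonical key) connected
#' subgraph with at most `max_edges` bonds.  A molecule with n bonds has at
#' most 2^n - 1 such subgraphs, so keep this to small molecules; the mining
#' test-suite uses it as the ground-truth reference.
#'
#' @param mol A `molgraph` with at least one bond.
#' @param max_edges Maximum number of bonds per subgraph (>= 1).
#' @return Named list of `fragment`s keyed by canonical key; each carries an
#'   attribute `embeddings` listing its supporting bond-id sets in `mol`.
#' @export
enumerate_connected_subgraphs <- function(mol, max_edges) {
  if (max_edges < 1L) stop("max_edges must be >= 1")
  if (nrow(mol$bonds) == 0L) stop("molecule has no bonds")
  mb <- mol$bonds
  bond_atoms <- lapply(seq_len(nrow(mb)), function(i) c(mb$a1[i], mb$a2[i]))
  level <- lapply(seq_len(nrow(mb)), function(i) i)   # sets of bond rows
  seen <- new.env(parent = emptyenv())
  all_sets <- list()
  for (s in level) assign(paste(s, collapse = ","), TRUE, envir = seen)
  all_sets <- level
  k <- 1L
  while (k < max_edges && length(level)) {
    nxt <- list()
    for (s in level) {
      atoms <- unique(unlist(bond_atoms[s]))
      adjacent <- which(mb$a1 %in% atoms | mb$a2 %in% atoms)
      for (j in setdiff(adjacent, s)) {
        s2 <- sort(c(s, j))
        key <- paste(s2, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    all_sets <- c(all_sets, nxt)
    level <- nxt
    k <- k + 1L
  }
  out <- list()
  for (s in all_sets) {
    f <- fragment_from_bonds(mol, mb$bond_id[s])
    key <- f$canonical_key
    if (is.null(out[[key]])) {
      attr(f, "embeddings") <- list(sort(mb$bond_id[s]))
      out[[key]] <- f
    } else {
      attr(out[[key]], "embeddings") <-
        c(attr(out[[key]], "embeddings"), list(sort(mb$bond_id[s])))
    }
  }
  out[order(names(out))]
}
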