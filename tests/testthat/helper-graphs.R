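# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (permutation search, exhaustive
# enumeration) and never reuse the code paths they check.

chain_mol <- function(id, elems, orders = rep("single", length(elems) - 1L)) {
  n <- length(elems)
  molgraph(id, data.frame(atom_id = seq_len(n), element = elems),
           data.frame(bond_id = seq_len(n - 1L), a1 = seq_len(n - 1L),
                      a2 = 2:n, order = orders))
}

ring_mol <- function(id, elems, order = "single", aromatic = FALSE) {
  n <- length(elems)
  molgraph(id, data.frame(atom_id = seq_len(n), element = elems,
                          aromatic = aromatic),
           data.frame(bond_id = seq_len(n), a1 = seq_len(n),
                      a2 = c(2:n, 1L), order = order))
}

benzene_mol <- function(id = "benzene", perm = 1:6) {
  molgraph(id, data.frame(atom_id = perm, element = "C", aromatic = TRUE),
           data.frame(bond_id = 1:6, a1 = perm, a2 = perm[c(2:6, 1L)],
                      order = "aromatic"))
}

toluene_mol <- function(id = "toluene") {
  molgraph(id,
           data.frame(atom_id = 1:7, element = "C",
                      aromatic = c(rep(TRUE, 6), FALSE)),
           data.frame(bond_id = 1:7, a1 = c(1:6, 1L), a2 = c(2:6, 1L, 7L),
                      order = c(rep("aromatic", 6), "single")))
}

frag_of <- function(mol, bond_ids = mol$bonds$bond_id)
  fragment_from_bonds(mol, bond_ids)

# ---- oracle: labeled-graph isomorphism by permutation search ---------------

oracle_isomorphic <- function(f1, f2) {
  a1 <- f1$atoms; a2 <- f2$atoms; b1 <- f1$bonds; b2 <- f2$bonds
  if (nrow(a1) != nrow(a2) || nrow(b1) != nrow(b2)) return(FALSE)
  lab <- function(a) paste0(a$element, "/", a$charge, "/", a$aromatic)
  l1 <- lab(a1); l2 <- lab(a2)
  if (!identical(sort(l1), sort(l2))) return(FALSE)
  edge_key <- function(bonds, ids, map = seq_along(ids)) {
    pos <- matrix(map[match(c(bonds$a1, bonds$a2), ids)], ncol = 2L)
    sort(paste0(pmin(pos[, 1L], pos[, 2L]), "-",
                pmax(pos[, 1L], pos[, 2L]), ":", bonds$order))
  }
  e2 <- edge_key(b2, a2$atom_id)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(nrow(a1)))) {
    # atom i of f1 (position) -> position p[i] of f2
    if (!identical(l1, l2[p])) next
    if (identical(edge_key(b1, a1$atom_id, p), e2)) return(TRUE)
  }
  FALSE
}

# ---- oracle: maximal frequent fragments by exhaustive enumeration ----------
# enumerate per molecule, count supports, keep >= t, drop any fragment that
# is a subfragment of a kept fragment with the identical support set

oracle_maximal_frequent <- function(library, t, max_edges = 10L) {
  per_mol <- lapply(library, function(m)
    names(enumerate_connected_subgraphs(m, max_edges)))
  all_keys <- sort(unique(unlist(per_mol)))
  support <- lapply(all_keys, function(k)
    sort(names(library)[vapply(per_mol, function(x) k %in% x, logical(1))]))
  names(support) <- all_keys
  keep <- all_keys[vapply(support, length, 0L) >= t]
  # fragment objects for subgraph testing
  frag_by_key <- new.env(parent = emptyenv())
  for (m in library) {
    fr <- enumerate_connected_subgraphs(m, max_edges)
    for (k in names(fr))
      if (!exists(k, envir = frag_by_key, inherits = FALSE))
        assign(k, fr[[k]], envir = frag_by_key)
  }
  is_sub <- function(k1, k2) {
    f1 <- get(k1, envir = frag_by_key); f2 <- get(k2, envir = frag_by_key)
    if (f1$n_edges >= f2$n_edges) return(FALSE)
    k1 %in% names(enumerate_connected_subgraphs(
      fragment_as_molgraph(f2), f1$n_edges))
  }
  maximal <- keep[vapply(keep, function(k) {
    !any(vapply(keep, function(k2)
      k2 != k && identical(support[[k]], support[[k2]]) && is_sub(k, k2),
      logical(1)))
  }, logical(1))]
  sort(maximal)
}
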