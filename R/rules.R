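# Fragment-combination rules: how pairs of privileged fragments co-occur
# inside active molecules — sharing atoms (merge), joined by a covalent
# bond (direct), or connected through a linker path — plus standalone
# scaffolds for molecules matched by a single fragment.

.emb_atoms <- function(mol, bond_ids) {
  rows <- match(bond_ids, mol$bonds$bond_id)
  unique(c(mol$bonds$a1[rows], mol$bonds$a2[rows]))
}

#' Relation between two embeddings in a molecule
#'
#' Shared atom(s) give `merge`; otherwise a molecule bond joining an atom of
#' each gives `direct`; otherwise `linker`, with the linker equal to the
#' bonds of a shortest path between the two atom sets (ties broken by the
#' smallest canonical key of the induced linker fragment).
#'
#' @param mol A `molgraph`.
#' @param emb1,emb2 Bond-id sets of two embeddings in `mol`.
#' @return List with `relation` (`"merge"`, `"direct"`, `"linker"`) and
#'   `linker_bonds` (bond ids, only for linker) plus `linker_key`.
#' @export
embedding_relation <- function(mol, emb1, emb2) {
  if (!all(emb1 %in% mol$bonds$bond_id) || !all(emb2 %in% mol$bonds$bond_id))
    stop("embedding references bonds absent from the molecule")
  at1 <- .emb_atoms(mol, emb1); at2 <- .emb_atoms(mol, emb2)
  if (length(intersect(at1, at2)))
    return(list(relation = "merge", linker_bonds = NULL, linker_key = NA))
  b <- mol$bonds
  joins <- (b$a1 %in% at1 & b$a2 %in% at2) | (b$a1 %in% at2 & b$a2 %in% at1)
  if (any(joins))
    return(list(relation = "direct", linker_bonds = NULL, linker_key = NA))
  paths <- .shortest_paths_between(mol, at1, at2)
  if (length(paths) == 0L) stop("embeddings lie in different components")
  keys <- vapply(paths, function(p)
    fragment_from_bonds(mol, p)$canonical_key, "")
  best <- order(keys)[1L]
  list(relation = "linker", linker_bonds = paths[[best]],
       linker_key = keys[best])
}

# all shortest bond paths from atom set S to atom set T (excluding bonds
# incident only within the sets), as lists of bond ids
.shortest_paths_between <- function(mol, S, T_set) {
  b <- mol$bonds
  dist <- rep(Inf, nrow(mol$atoms)); names(dist) <- as.character(mol$atoms$atom_id)
  dist[as.character(S)] <- 0
  frontier <- as.character(S); d <- 0
  while (length(frontier)) {
    d <- d + 1; nxt <- character()
    for (v in frontier) {
      vi <- as.integer(v)
      rows <- which(b$a1 == vi | b$a2 == vi)
      for (r in rows) {
        w <- as.character(if (b$a1[r] == vi) b$a2[r] else b$a1[r])
        if (dist[w] > d) { dist[w] <- d; nxt <- c(nxt, w) }
      }
    }
    frontier <- unique(nxt)
    if (any(is.finite(dist[as.character(T_set)]))) break
  }
  dT <- min(dist[as.character(T_set)])
  if (!is.finite(dT)) return(list())
  targets <- T_set[dist[as.character(T_set)] == dT]
  paths <- list()
  backtrack <- function(atom, acc) {
    dd <- dist[as.character(atom)]
    if (dd == 0) { paths[[length(paths) + 1L]] <<- sort(acc); return(invisible(NULL)) }
    rows <- which(b$a1 == atom | b$a2 == atom)
    for (r in rows) {
      prev <- if (b$a1[r] == atom) b$a2[r] else b$a1[r]
      if (dist[as.character(prev)] == dd - 1)
        backtrack(prev, c(acc, b$bond_id[r]))
    }
  }
  for (tt in targets) backtrack(tt, integer())
  unique(paths)
}

#' Derive fragment-combination rules from active molecules
#'
#' For every active molecule and every unordered pair of privileged
#' fragments both embedded in it, the pair's relation is classified using
#' the most intimate embedding pair (merge > direct > linker; among linker
#' candidates the shortest, then smallest-key linker).  Each molecule votes
#' once per pair.  Molecules matched by exactly one privileged fragment
#' contribute standalone records.  Records are aggregated by (pair,
#' relation, linker key), filtered at `min_support` and sorted by
#' descending support.
#'
#' @param privileged_fragments Named list of `fragment`s, a
#'   `privileged_report`, or an `ssd`.
#' @param active_library List of `molgraph`s (actives only).
#' @param min_support Minimum number of supporting molecules.
#' @return Object of class `rule_set`: `data.frame` with `fragment_a`,
#'   `fragment_b` (NA for standalone), `relation`, `linker_key`, `support`,
#'   and a list-column `mol_ids`.
#' @export
derive_rules <- function(privileged_fragments, active_library,
                         min_support = 1L) {
  fr <- if (inherits(privileged_fragments, "privileged_report"))
    privileged_fragments$fragment
  else if (inherits(privileged_fragments, "ssd")) privileged_fragments$fragments
  else privileged_fragments
  if (length(fr) == 0L) stop("no privileged fragments")
  if (length(active_library) == 0L) stop("empty active library")
  keys <- vapply(fr, function(f) f$canonical_key, "")
  nm <- names(fr)
  if (is.null(nm) || any(!nzchar(nm))) nm <- keys
  lib <- library_index(active_library)

  votes <- list()
  add_vote <- function(id, mol_id) {
    v <- votes[[id]]
    if (is.null(v)) votes[[id]] <<- list(mol_ids = mol_id)
    else votes[[id]]$mol_ids <<- c(v$mol_ids, mol_id)
  }
  rank_rel <- c(merge = 1, direct = 2, linker = 3)

  for (mol in lib) {
    embs <- lapply(fr, function(f) subgraph_match(f, mol))
    hit <- which(lengths(embs) > 0L)
    if (length(hit) == 1L) {
      add_vote(paste0("standalone\r", nm[hit], "\r\r"), mol$mol_id)
      next
    }
    if (length(hit) < 2L) next
    for (ii in seq_along(hit)) for (jj in seq_along(hit)) {
      if (ii >= jj) next
      i <- hit[ii]; j <- hit[jj]
      best <- NULL
      for (e1 in embs[[i]]) for (e2 in embs[[j]]) {
        if (length(intersect(e1, e2))) next  # overlapping bonds: same region
        rel <- embedding_relation(mol, e1, e2)
        cand <- list(rel = rel,
                     rank = rank_rel[[rel$relation]],
                     len = if (is.null(rel$linker_bonds)) 0L
                     else length(rel$linker_bonds),
                     key = if (is.na(rel$linker_key)) "" else rel$linker_key)
        if (is.null(best) || cand$rank < best$rank ||
            (cand$rank == best$rank &&
             (cand$len < best$len ||
              (cand$len == best$len && cand$key < best$key))))
          best <- cand
      }
      if (is.null(best)) next
      pair <- sort(c(nm[i], nm[j]))
      add_vote(paste0(best$rel$relation, "\r", pair[1L], "\r", pair[2L],
                      "\r", best$key), mol$mol_id)
    }
  }

  if (length(votes) == 0L) {
    out <- data.frame(fragment_a = character(), fragment_b = character(),
                      relation = character(), linker_key = character(),
                      support = integer(), stringsAsFactors = FALSE)
    out$mol_ids <- list()
    return(structure(out, class = c("rule_set", "data.frame")))
  }
  parts <- strsplit(names(votes), "\r", fixed = TRUE)
  out <- data.frame(
    relation = vapply(parts, `[`, "", 1L),
    fragment_a = vapply(parts, `[`, "", 2L),
    fragment_b = vapply(parts, function(p)
      if (length(p) >= 3L && nzchar(p[3L])) p[3L] else NA_character_, ""),
    linker_key = vapply(parts, function(p) if (length(p) >= 4L &&
                                               nzchar(p[4L])) p[4L] else
                                                 NA_character_, ""),
    stringsAsFactors = FALSE)
  out$support <- vapply(votes, function(v) length(unique(v$mol_ids)), 0L)
  out$mol_ids <- lapply(votes, function(v) unique(v$mol_ids))
  out <- out[out$support >= min_support, , drop = FALSE]
  o <- order(-out$support, out$fragment_a, out$fragment_b, out$relation)
  out <- out[o, c("fragment_a", "fragment_b", "relation", "linker_key",
                  "support", "mol_ids")]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> ", nrow(x), " rule(s)\n", sep = "")
  print.data.frame(x[, setdiff(names(x), "mol_ids")])
  invisible(x)
}

#' Write a rule set
#'
#' @param rules A `rule_set`.
#' @param path Output path stem (writes `<path>.tsv` and `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  flat <- rules[, c("fragment_a", "fragment_b", "relation", "linker_key",
                    "support")]
  flat$mol_ids <- vapply(rules$mol_ids, paste, "", collapse = ",")
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(rules)), function(i) list(
      fragment_a = rules$fragment_a[i], fragment_b = rules$fragment_b[i],
      relation = rules$relation[i], linker_key = rules$linker_key[i],
      support = rules$support[i], mol_ids = rules$mol_ids[[i]])),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
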