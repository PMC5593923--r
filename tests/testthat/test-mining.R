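# subIDs, tree growth, PRN detection, registry pruning, FFID collapse and
# the aromatic-ring integrity filter.

test_that("subID construction canonicalizes and counts popularity", {
  s <- subid(list(A = "n", B = "m", C = "h", D = "e", D = "k"))
  expect_identical(popularity(s), 4L)
  # order of components does not matter
  s2 <- subid(list(D = "k", C = "h", A = "n", D = "e", B = "m"))
  expect_identical(s$canonical_string, s2$canonical_string)
  expect_identical(popularity(subid(list(m1 = 1))), 1L)
  expect_identical(popularity(subid(list(m1 = 1, m1 = 2, m1 = 3))), 1L)
  expect_error(subid(list()), "at least one")
  expect_error(subid(list(A = 1, B = c(1, 2))), "same number")
})

test_that("roots carry one component per bond occurrence", {
  lib <- fig_tree_library()
  roots <- init_roots(lib)
  cc_key <- frag_of(chain_mol("x", c("C", "C")))$canonical_key
  cc <- roots[[cc_key]]
  expect_false(is.null(cc))
  expect_length(cc$subid$components, 5L)      # A, B, C and two in D
  expect_identical(popularity(cc$subid), 4L)
  expect_identical(sort(unique(cc$subid$mol_ids)), c("A", "B", "C", "D"))
  # one ethanol: two root types, each popularity 1
  r2 <- init_roots(list(chain_mol("m", c("C", "C", "O"))))
  expect_length(r2, 2L)
  expect_true(all(vapply(r2, function(n) popularity(n$subid), 0L) == 1L))
  # two identical ethanes: one root, two components
  r3 <- init_roots(list(chain_mol("e1", c("C", "C")),
                        chain_mol("e2", c("C", "C"))))
  expect_length(r3, 1L)
  expect_identical(popularity(r3[[1L]]$subid), 2L)
})

test_that("growing the demonstration-library root yields two children", {
  lib <- fig_tree_library()
  cc_key <- frag_of(chain_mol("x", c("C", "C")))$canonical_key
  children <- grow_node(init_roots(lib)[[cc_key]], lib)
  expect_length(children, 2L)
  pops <- sort(unname(vapply(children, function(n) popularity(n$subid), 0L)))
  expect_identical(pops, c(1L, 3L))           # C-C-N in A; C-C-O in B, C, D
})

test_that("grow_node counts each extended embedding once", {
  # C-C root in propane: both single-bond embeddings extend to the same
  # 2-bond embedding, which must appear as one component
  lib <- list(chain_mol("p", c("C", "C", "C")))
  ch <- grow_node(init_roots(lib)[[1L]], lib)
  expect_length(ch, 1L)
  expect_length(ch[[1L]]$subid$components, 1L)
  # whole-molecule embedding has nothing adjacent
  expect_length(grow_node(ch[[1L]], lib), 0L)
})

test_that("PRN detection compares molecule-support sets", {
  lib <- fig_tree_library()
  cc <- init_roots(lib)[[frag_of(chain_mol("x", c("C", "C")))$canonical_key]]
  ch <- grow_node(cc, lib)
  expect_true(is_prn(cc, ch))                 # no child keeps {A,B,C,D}
  # a node whose only child keeps full support is not a PRN
  lib2 <- library_index(list(chain_mol("m1", c("C", "C", "O")),
                             chain_mol("m2", c("C", "C", "O"))))
  cc2 <- init_roots(lib2)[[frag_of(chain_mol("x", c("C", "C")))$canonical_key]]
  expect_false(is_prn(cc2, grow_node(cc2, lib2)))
  expect_true(is_prn(cc2, list()))            # leaves are PRNs
})

test_that("mine reports maximal frequent fragments on worked examples", {
  # three ethanols: only the whole molecule is maximal
  lib <- list(chain_mol("m1", c("C", "C", "O")),
              chain_mol("m2", c("C", "C", "O")),
              chain_mol("m3", c("C", "C", "O")))
  m <- mine(lib, t = 2)
  expect_length(m$fragments, 1L)
  expect_identical(m$fragments[[1L]]$popularity, 3L)
  expect_identical(names(m$fragments),
                   frag_of(chain_mol("x", c("C", "C", "O")))$canonical_key)
  # ethane + propane: C-C-C has support 1 < t, so C-C is reported
  m2 <- mine(list(chain_mol("e", c("C", "C")),
                  chain_mol("p", c("C", "C", "C"))), t = 2)
  expect_identical(names(m2$fragments),
                   frag_of(chain_mol("x", c("C", "C")))$canonical_key)
  # popularity ceiling 1 in a single-molecule library
  expect_length(mine(list(chain_mol("solo", c("C", "C", "O"))),
                     t = 2)$fragments, 0L)
  expect_error(mine(list(), t = 2), "empty")
  expect_error(mine(lib, t = 1), "t must be >= 2")
})

test_that("mining equals the exhaustive oracle on random libraries", {
  ts <- c(2, 3, 5)
  for (i in 1:3) {
    lib <- random_small_library(520 + i, n_molecules = 10L, max_bonds = 8L)
    m <- mine(lib, t = ts[i], integrity = FALSE)
    expect_identical(sort(as.character(names(m$fragments))),
                     oracle_maximal_frequent(lib, ts[i]),
                     info = paste("library", i))
  }
})

test_that("pruning changes cost but never the result", {
  lib <- random_small_library(77, n_molecules = 12L, max_bonds = 8L)
  on_ <- mine(lib, t = 2, integrity = FALSE)
  off <- mine(lib, t = 2, prune = FALSE, integrity = FALSE)
  expect_identical(names(on_$fragments), names(off$fragments))
  expect_lte(on_$visited, off$visited)
  expect_gt(on_$pruned, 0L)
  expect_lt(on_$visited, off$visited)
  expect_identical(off$pruned, 0L)
})

test_that("reported popularity equals the number of matching molecules", {
  lib <- random_small_library(88, n_molecules = 10L, max_bonds = 7L)
  m <- mine(lib, t = 2, integrity = FALSE)
  for (r in m$fragments) {
    n_match <- sum(vapply(lib, function(mol)
      has_fragment(r$fragment, mol), logical(1)))
    expect_identical(r$popularity, n_match)
  }
})

test_that("FFID collapse keeps the larger of nested fragments", {
  f_small <- frag_of(chain_mol("x", c("C", "C")))
  f_large <- frag_of(chain_mol("y", c("C", "C", "O")))
  f_other <- frag_of(chain_mol("z", c("N", "C", "O")))
  rec <- function(f, mols) list(
    fragment = f, popularity = length(unique(mols)),
    mol_ids = sort(unique(mols)),
    subid = subid(stats::setNames(as.list(seq_along(mols)), mols)))
  # Case 1: nested pair sharing an FFID -> larger kept
  out <- collapse_ffid(list(rec(f_small, c("a", "b")),
                            rec(f_large, c("a", "b"))))
  expect_length(out, 1L)
  expect_length(out[[1L]]$fragments, 1L)
  expect_identical(out[[1L]]$fragments[[1L]]$fragment$canonical_key,
                   f_large$canonical_key)
  # Case 2: non-nested pair -> both kept under the same FFID
  out2 <- collapse_ffid(list(rec(f_large, c("a", "b")),
                             rec(f_other, c("a", "b"))))
  expect_length(out2, 1L)
  expect_length(out2[[1L]]$fragments, 2L)
  # singleton group unchanged
  out3 <- collapse_ffid(list(rec(f_small, c("a", "b"))))
  expect_length(out3[[1L]]$fragments, 1L)
  expect_error(collapse_ffid(list()), "nothing")
})

test_that("integrity filter removes fragments with broken aromatic rings", {
  benz <- benzene_mol("bz")
  tolu <- toluene_mol("tl")
  lib <- library_index(list(benz, tolu))
  rec <- function(mol, bond_ids) {
    f <- fragment_from_bonds(mol, bond_ids)
    list(fragment = f, popularity = 1L, mol_ids = mol$mol_id,
         subid = subid(stats::setNames(list(bond_ids), mol$mol_id)))
  }
  # three contiguous aromatic bonds cut from benzene: removed
  broken <- rec(benz, 1:3)
  # the full ring with the methyl attachment: kept
  whole <- rec(tolu, 1:7)
  # purely aliphatic fragment: kept
  aliph <- rec(tolu, 7L)
  kept <- integrity_filter(list(broken, whole, aliph), lib)
  keys <- vapply(kept, function(r) r$fragment$canonical_key, "")
  expect_length(kept, 2L)
  expect_false(broken$fragment$canonical_key %in% keys)
  expect_true(all(c(whole$fragment$canonical_key,
                    aliph$fragment$canonical_key) %in% keys))
})

test_that("mining with integrity filtering drops partial rings", {
  lib <- list(toluene_mol("t1"), toluene_mol("t2"))
  with_int <- mine(lib, t = 2, integrity = TRUE)
  # every reported aromatic fragment carries its complete ring
  for (r in with_int$fragments) {
    if (any(r$fragment$bonds$order == "aromatic"))
      expect_gte(sum(r$fragment$bonds$order == "aromatic"), 6L)
  }
  without <- mine(lib, t = 2, integrity = FALSE)
  expect_gte(length(without$fragments), length(with_int$fragments))
})
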