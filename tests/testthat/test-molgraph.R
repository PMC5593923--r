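# Graph model, canonical keys, matching and exhaustive enumeration.

test_that("molgraph validation rejects malformed graphs", {
  expect_error(molgraph("h", data.frame(atom_id = 1, element = "H")),
               "hydrogens")
  expect_error(molgraph("d", data.frame(atom_id = c(1, 1), element = "C")),
               "duplicate atom_id")
  expect_error(molgraph("s", data.frame(atom_id = 1:2, element = "C"),
                        data.frame(bond_id = 1, a1 = 1, a2 = 1,
                                   order = "single")), "self-bond")
  expect_error(molgraph("m", data.frame(atom_id = 1:2, element = "C"),
                        data.frame(bond_id = 1, a1 = 1, a2 = 3,
                                   order = "single")), "missing atom")
  expect_error(molgraph("o", data.frame(atom_id = 1:2, element = "C"),
                        data.frame(bond_id = 1, a1 = 1, a2 = 2,
                                   order = "quadruple")), "bond order")
  pentavalent <- molgraph("v", data.frame(atom_id = 1:6, element = "C"),
                          data.frame(bond_id = 1:5, a1 = 1, a2 = 2:6,
                                     order = "single"))
  expect_error(validate_molgraph(pentavalent, valence = TRUE), "valence")
})

test_that("canonical keys are invariant under atom relabeling", {
  expect_identical(frag_of(benzene_mol())$canonical_key,
                   frag_of(benzene_mol(perm = c(3, 5, 1, 6, 2, 4)))$canonical_key)
  # a single C-C bond canonicalizes to one fixed string across constructions
  e1 <- frag_of(chain_mol("a", c("C", "C")))
  e2 <- frag_of(chain_mol("b", c("C", "C")))
  expect_identical(e1$canonical_key, e2$canonical_key)
  # label differences break equality
  expect_false(frag_of(chain_mol("c", c("C", "N")))$canonical_key ==
                 e1$canonical_key)
  expect_false(frag_of(chain_mol("d", c("C", "C"), "double"))$canonical_key ==
                 e1$canonical_key)
})

test_that("disconnected fragments are rejected with a diagnostic", {
  expect_error(new_fragment(
    data.frame(atom_id = 1:4, element = "C"),
    data.frame(bond_id = 1:2, a1 = c(1, 3), a2 = c(2, 4),
               order = "single")), "disconnected")
})

test_that("canonical key equality agrees with brute-force isomorphism", {
  # all pairs among random fragments drawn from random small molecules:
  # string equality must coincide exactly with permutation-search isomorphism
  lib <- random_small_library(301, n_molecules = 12L, max_bonds = 6L)
  frags <- list()
  set.seed(302)
  for (m in lib) {
    subs <- enumerate_connected_subgraphs(m, 5L)
    frags <- c(frags, subs[sample.int(length(subs),
                                      min(6L, length(subs)))])
  }
  frags <- frags[seq_len(min(40L, length(frags)))]
  for (i in seq_along(frags)) for (j in seq_len(i - 1L)) {
    same_key <- frags[[i]]$canonical_key == frags[[j]]$canonical_key
    expect_identical(same_key, oracle_isomorphic(frags[[i]], frags[[j]]),
                     info = paste("pair", i, j))
  }
})

test_that("subgraph_match finds exactly the distinct bond-set embeddings", {
  cc <- frag_of(chain_mol("e", c("C", "C")))
  expect_length(subgraph_match(cc, chain_mol("ethane", c("C", "C"))), 1L)
  expect_length(subgraph_match(cc, chain_mol("propane", c("C", "C", "C"))), 2L)
  # benzene in toluene: one embedding despite 12 automorphic atom maps
  expect_length(subgraph_match(frag_of(benzene_mol()), toluene_mol()), 1L)
  expect_length(subgraph_match(frag_of(benzene_mol()), benzene_mol()), 1L)
  # absent fragment
  expect_length(subgraph_match(frag_of(chain_mol("x", c("C", "O"))),
                               chain_mol("ethane", c("C", "C"))), 0L)
})

test_that("match presence coincides with enumeration membership", {
  lib <- random_small_library(77, n_molecules = 8L, max_bonds = 7L)
  pool <- enumerate_connected_subgraphs(lib[[1L]], 4L)
  for (f in pool[seq_len(min(5L, length(pool)))]) {
    for (m in lib) {
      enum_keys <- names(enumerate_connected_subgraphs(m, f$n_edges))
      expect_identical(length(subgraph_match(f, m)) > 0L,
                       f$canonical_key %in% enum_keys)
    }
  }
})

test_that("connected-subgraph enumeration matches hand counts", {
  # triangle: every nonempty edge subset is connected, 2^3 - 1 = 7
  tri <- ring_mol("cyclopropane", rep("C", 3))
  expect_identical(sum(lengths(lapply(
    enumerate_connected_subgraphs(tri, 3L), attr, "embeddings"))), 7L)
  # 3-edge path: 6 connected subsets ({e1,e3} is disconnected)
  but <- chain_mol("butane", rep("C", 4))
  sets <- enumerate_connected_subgraphs(but, 3L)
  expect_identical(sum(lengths(lapply(sets, attr, "embeddings"))), 6L)
  expect_length(enumerate_connected_subgraphs(
    chain_mol("ethane", c("C", "C")), 1L), 1L)
  expect_error(enumerate_connected_subgraphs(but, 0L), "max_edges")
})

test_that("enumeration respects the 2^n - 1 bound", {
  for (seed in 1:3) {
    lib <- random_small_library(400 + seed, n_molecules = 4L, max_bonds = 8L)
    for (m in lib) {
      n <- nrow(m$bonds)
      total <- sum(lengths(lapply(enumerate_connected_subgraphs(m, n),
                                  attr, "embeddings")))
      expect_lte(total, 2^n - 1)
    }
  }
})
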