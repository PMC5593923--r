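# File formats and activity preprocessing.

test_that("SDF round trip preserves structure, charges and properties", {
  lib <- list(benzene_mol("b1"), toluene_mol("t1"),
              molgraph("chg", data.frame(atom_id = 1:3,
                                         element = c("C", "C", "O"),
                                         charge = c(0L, 0L, -1L)),
                       data.frame(bond_id = 1:2, a1 = 1:2, a2 = 2:3,
                                  order = c("single", "single")),
                       properties = list(IC50_nM = 500)))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(lib, path)
  back <- read_library(path, "sdf", perceive_aromatic = FALSE)
  expect_length(back, 3L)
  for (i in seq_along(lib)) {
    expect_identical(
      frag_of(back[[i]], back[[i]]$bonds$bond_id)$canonical_key,
      frag_of(lib[[i]], lib[[i]]$bonds$bond_id)$canonical_key)
  }
  expect_identical(back$chg$properties$ic50_nM, 500)
  expect_identical(back$chg$atoms$charge[3L], -1L)
})

test_that("malformed SDF records are skipped with a warning", {
  lib <- list(chain_mol("ok1", c("C", "C", "O")),
              chain_mol("ok2", c("C", "N")))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(lib, path)
  txt <- readLines(path)
  corrupt <- c("broken", "", "", "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C  ", "M  END", "$$$$")
  writeLines(c(txt, corrupt), path)
  expect_warning(back <- read_library(path, "sdf"), "skipped")
  expect_length(back, 2L)
  # a file with no valid record is a hard error
  bad <- withr::local_tempfile(fileext = ".sdf")
  writeLines(corrupt, bad)
  expect_error(suppressWarnings(read_library(bad, "sdf")))
})

test_that("SMILES tables parse into graphs with activities", {
  skip_if(Sys.which("obabel") == "", "obabel not on PATH")
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("m1\tCCO\t500", "m2\tc1ccccc1\t20000"), path)
  lib <- read_library(path, "smiles")
  expect_length(lib, 2L)
  expect_identical(nrow(lib$m1$atoms), 3L)
  expect_identical(nrow(lib$m1$bonds), 2L)
  expect_identical(lib$m1$properties$ic50_nM, 500)
  # benzene comes back as an aromatic ring after perception
  expect_identical(frag_of(lib$m2, lib$m2$bonds$bond_id)$canonical_key,
                   frag_of(benzene_mol())$canonical_key)
})

test_that("salt stripping keeps the largest component deterministically", {
  two_comp <- molgraph("salt",
    data.frame(atom_id = 1:5, element = c("C", "C", "O", "O", "N")),
    data.frame(bond_id = 1:3, a1 = c(1, 2, 2), a2 = c(2, 3, 4),
               order = c("single", "double", "single")))
  # atoms 1-4 form the acid; atom 5 is the counter-ion
  kept <- strip_salt(two_comp)
  expect_identical(nrow(kept$atoms), 4L)
  expect_false("N" %in% kept$atoms$element)
  # single component: unchanged
  single <- chain_mol("one", c("C", "C"))
  expect_identical(strip_salt(single)$atoms, single$atoms)
  # equal-size components: smaller canonical key wins
  tie <- molgraph("tie",
    data.frame(atom_id = 1:4, element = c("C", "C", "C", "O")),
    data.frame(bond_id = 1:2, a1 = c(1, 3), a2 = c(2, 4), order = "single"))
  kept2 <- strip_salt(tie)
  k_cc <- frag_of(chain_mol("x", c("C", "C")))$canonical_key
  k_co <- frag_of(chain_mol("y", c("C", "O")))$canonical_key
  expect_identical(frag_of(kept2, kept2$bonds$bond_id)$canonical_key,
                   min(k_cc, k_co))
})

test_that("deduplication keeps first occurrences and is idempotent", {
  etoh_a <- chain_mol("a", c("C", "C", "O"))
  etoh_b <- chain_mol("b", c("O", "C", "C"))   # same molecule, reordered
  prop <- chain_mol("c", c("C", "C", "C"))
  out <- deduplicate(list(etoh_a, etoh_b, prop))
  expect_identical(vapply(out, function(m) m$mol_id, ""), c("a", "c"))
  expect_identical(deduplicate(out), out)
  all_unique <- list(etoh_a, prop)
  expect_length(deduplicate(all_unique), 2L)
  expect_error(deduplicate(list()), "empty")
})

test_that("activity preparation applies the 10 micromolar threshold", {
  rec <- data.frame(mol_id = c("a", "b", "c", "d"),
                    ic50_nM = c(20000, 10000, 1000, 15))
  cls <- prepare_activity(rec, "classification")
  expect_identical(cls$label, c(0L, 1L, 1L, 1L))   # strict "greater than"
  expect_identical(nrow(cls), 4L)                  # all rows kept
  reg <- prepare_activity(rec, "regression")
  expect_identical(reg$mol_id, c("b", "c", "d"))   # 20,000 nM removed
  expect_equal(reg$pIC50[reg$mol_id == "c"], 6.0)  # 1 uM -> 6.0
  expect_equal(reg$pIC50[reg$mol_id == "b"], 5.0)
  # non-positive IC50 rejected with diagnostic
  expect_warning(bad <- prepare_activity(
    data.frame(mol_id = c("x", "y"), ic50_nM = c(-5, 100)),
    "classification"), "non-positive")
  expect_identical(bad$mol_id, "y")
})

test_that("library graphs flow from molgraphs into activity tables", {
  lib <- list(structure(chain_mol("m", c("C", "C")), class = "molgraph"))
  lib[[1L]]$properties$ic50_nM <- 2000
  tab <- prepare_activity(lib, "classification")
  expect_identical(tab$label, 1L)
  expect_identical(tab$mol_id, "m")
})
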