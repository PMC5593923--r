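# Seeded generator of benchmark libraries: a catalog of ring fragments,
# molecules assembled by joining planted fragments through linkers, direct
# bonds or shared atoms, fragment-driven IC50 values, and a ground-truth
# manifest.  Everything is reproducible from the seed and passes the
# package's own structural validation (valence table, connectivity, no
# explicit hydrogens).

.ring_fragment <- function(elements, aromatic = FALSE) {
  k <- length(elements)
  new_fragment(
    data.frame(atom_id = seq_len(k), element = elements, charge = 0L,
               aromatic = aromatic),
    data.frame(bond_id = seq_len(k), a1 = seq_len(k), a2 = c(2:k, 1L),
               order = if (aromatic) "aromatic" else "single"))
}

#' Catalog of named ring fragments
#'
#' Thirty-one mutually non-nested ring fragments: aromatic six-membered
#' rings over C/N substitution patterns, aliphatic six- and five-membered
#' rings with O/N/S heteroatoms, and aromatic five-membered rings.  Rings
#' of equal size with different atom patterns cannot contain one another
#' and rings of different sizes cannot either, so presence indicators of
#' distinct catalog entries are independent of each other by construction.
#'
#' @return Named list of `fragment`s.
#' @export
fragment_catalog <- function() {
  six <- function(pos, elem) { e <- rep("C", 6L); e[pos] <- elem; e }
  five <- function(pos, elem) { e <- rep("C", 5L); e[pos] <- elem; e }
  cat6ar <- list(
    benzene = six(integer(), "N"),
    pyridine = six(1L, "N"),
    pyridazine = six(c(1L, 2L), "N"),
    pyrimidine = six(c(1L, 3L), "N"),
    pyrazine = six(c(1L, 4L), "N"),
    triazine_123 = six(1:3, "N"),
    triazine_124 = six(c(1L, 2L, 4L), "N"),
    triazine_135 = six(c(1L, 3L, 5L), "N"))
  cat6al <- list(
    cyclohexane = six(integer(), "O"),
    oxane = six(1L, "O"),
    dioxane_14 = six(c(1L, 4L), "O"),
    dioxane_13 = six(c(1L, 3L), "O"),
    piperidine = six(1L, "N"),
    piperazine = six(c(1L, 4L), "N"),
    thiane = six(1L, "S"),
    dithiane_14 = six(c(1L, 4L), "S"),
    morpholine = { e <- rep("C", 6L); e[1L] <- "O"; e[4L] <- "N"; e })
  cat5al <- list(
    cyclopentane = five(integer(), "O"),
    oxolane = five(1L, "O"),
    pyrrolidine = five(1L, "N"),
    thiolane = five(1L, "S"),
    dioxolane = five(c(1L, 3L), "O"),
    imidazolidine = five(c(1L, 3L), "N"),
    oxazolidine = { e <- rep("C", 5L); e[1L] <- "O"; e[3L] <- "N"; e },
    dithiolane = five(c(1L, 3L), "S"))
  cat5ar <- list(
    furan = five(1L, "O"),
    pyrrole = five(1L, "N"),
    thiophene = five(1L, "S"),
    oxazole = { e <- rep("C", 5L); e[1L] <- "O"; e[3L] <- "N"; e },
    thiazole = { e <- rep("C", 5L); e[1L] <- "S"; e[3L] <- "N"; e },
    imidazole = five(c(1L, 3L), "N"))
  c(lapply(cat6ar, .ring_fragment, aromatic = TRUE),
    lapply(cat6al, .ring_fragment, aromatic = FALSE),
    lapply(cat5al, .ring_fragment, aromatic = FALSE),
    lapply(cat5ar, .ring_fragment, aromatic = TRUE))
}

#' Generator configuration
#'
#' Defines the study conditions for a synthetic focused library: which
#' catalog fragments are causal, how strongly fragment content drives
#' pIC50, how often fragments appear in actives versus inactives, and any
#' planted fragment-combination rules.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param n_molecules Library size (>= 10).
#' @param catalog Named list of `fragment`s (default [fragment_catalog()]).
#' @param causal Names of causal fragments (subset of the catalog).
#' @param effects Named pIC50 increments per causal fragment.
#' @param baseline_pIC50 Intercept of the activity model.
#' @param noise_sd Gaussian noise on pIC50 (>= 0).
#' @param prevalence Active fraction, in (0, 1]; 1 gives a potency-graded
#'   library with no inactives (regression benchmarks).
#' @param p_frag_active,p_frag_inactive Probability that each causal
#'   fragment is planted in an active / inactive molecule.
#' @param decoy_range Number of non-causal fragments per molecule, drawn
#'   uniformly from this range (class-independent).
#' @param p_decoy_chain Probability of appending a short random aliphatic
#'   chain as extra decoy complexity.
#' @param rules Planted combination rules: list of lists with fields `a`,
#'   `b` (catalog names), `relation` (`"linker"` or `"direct"`),
#'   `linker_n` (carbon count, linker only) and `prevalence` (fraction of
#'   actives built through the rule).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_molecules = 200L,
                             catalog = fragment_catalog(),
                             causal = character(),
                             effects = NULL,
                             baseline_pIC50 = 6,
                             noise_sd = 0.2,
                             prevalence = 0.5,
                             p_frag_active = 0.65,
                             p_frag_inactive = 0.10,
                             decoy_range = c(1L, 2L),
                             p_decoy_chain = 0.3,
                             rules = list()) {
  if (n_molecules < 10L) stop("n_molecules must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  if (!all(causal %in% names(catalog)))
    stop("causal fragments missing from the catalog")
  if (is.null(effects)) {
    effects <- rep_len(c(1.5, 1.2, 1.0, 0.8, 0.6), length(causal))
    names(effects) <- causal
  }
  if (!all(causal %in% names(effects))) stop("effects must cover causal fragments")
  for (r in rules) {
    if (!all(c(r$a, r$b) %in% names(catalog)))
      stop("rule references fragment absent from the catalog: ",
           paste(setdiff(c(r$a, r$b), names(catalog)), collapse = ", "))
    if (!r$relation %in% c("linker", "direct"))
      stop("plantable rule relations are 'linker' and 'direct'")
  }
  structure(list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
                 catalog = catalog, causal = causal, effects = effects,
                 baseline_pIC50 = baseline_pIC50, noise_sd = noise_sd,
                 prevalence = prevalence, p_frag_active = p_frag_active,
                 p_frag_inactive = p_frag_inactive,
                 decoy_range = as.integer(decoy_range),
                 p_decoy_chain = p_decoy_chain, rules = rules),
            class = "generator_config")
}

.VALENCE <- c(C = 4, N = 3, O = 2, S = 6)
.ORDER_VAL <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# mutable molecule-under-construction helpers ------------------------------

.mol_builder <- function() {
  list(atoms = data.frame(atom_id = integer(), element = character(),
                          charge = integer(), aromatic = logical()),
       bonds = data.frame(bond_id = integer(), a1 = integer(), a2 = integer(),
                          order = character()))
}

.used_valence <- function(mb, atom) {
  rows <- mb$bonds$a1 == atom | mb$bonds$a2 == atom
  w <- .ORDER_VAL[mb$bonds$order[rows]]
  elem <- mb$atoms$element[mb$atoms$atom_id == atom]
  if (length(elem) && elem %in% c("O", "S"))
    w[mb$bonds$order[rows] == "aromatic"] <- 1
  sum(w)
}

.spare_carbons <- function(mb, need = 1) {
  cand <- mb$atoms$atom_id[mb$atoms$element == "C"]
  cand[vapply(cand, function(a)
    .VALENCE[["C"]] - .used_valence(mb, a) >= need, logical(1))]
}

# add a fragment's atoms/bonds with fresh ids; returns list(mb, atom_map)
.add_fragment <- function(mb, frag) {
  shift_a <- if (nrow(mb$atoms)) max(mb$atoms$atom_id) else 0L
  shift_b <- if (nrow(mb$bonds)) max(mb$bonds$bond_id) else 0L
  a <- frag$atoms; b <- frag$bonds
  amap <- stats::setNames(a$atom_id + shift_a, as.character(a$atom_id))
  mb$atoms <- rbind(mb$atoms,
                    data.frame(atom_id = a$atom_id + shift_a,
                               element = a$element, charge = a$charge,
                               aromatic = a$aromatic))
  if (nrow(b))
    mb$bonds <- rbind(mb$bonds,
                      data.frame(bond_id = b$bond_id + shift_b,
                                 a1 = amap[as.character(b$a1)],
                                 a2 = amap[as.character(b$a2)],
                                 order = b$order))
  list(mb = mb, atoms = unname(amap))
}

.add_bond <- function(mb, a1, a2, order = "single") {
  mb$bonds <- rbind(mb$bonds,
                    data.frame(bond_id = if (nrow(mb$bonds))
                      max(mb$bonds$bond_id) + 1L else 1L,
                      a1 = a1, a2 = a2, order = order))
  mb
}

.add_chain_atom <- function(mb, attach_to, element = "C") {
  new_id <- max(mb$atoms$atom_id) + 1L
  mb$atoms <- rbind(mb$atoms,
                    data.frame(atom_id = new_id, element = element,
                               charge = 0L, aromatic = FALSE))
  .add_bond(mb, attach_to, new_id)
}

# join a new fragment to the molecule under construction
# relation: "linker" (n_linker carbons), "direct" (0-carbon bond),
# "merge" (share one carbon atom)
.join_fragment <- function(mb, frag, relation = "linker", n_linker = 1L) {
  if (nrow(mb$atoms) == 0L) return(.add_fragment(mb, frag)$mb)
  site <- .spare_carbons(mb)
  if (length(site) == 0L) return(.add_fragment(mb, frag)$mb)  # disconnected guard
  site <- site[sample.int(length(site), 1L)]
  added <- .add_fragment(mb, frag)
  mb <- added$mb
  new_c <- intersect(added$atoms,
                     mb$atoms$atom_id[mb$atoms$element == "C"])
  new_c <- new_c[vapply(new_c, function(a)
    .VALENCE[["C"]] - .used_valence(mb, a) >= 1, logical(1))]
  target <- new_c[sample.int(length(new_c), 1L)]
  if (relation == "merge") {
    # splice: rewire the chosen new carbon's bonds onto the site atom
    keep <- mb$atoms$atom_id != target
    mb$bonds$a1[mb$bonds$a1 == target] <- site
    mb$bonds$a2[mb$bonds$a2 == target] <- site
    mb$atoms <- mb$atoms[keep, , drop = FALSE]
    return(mb)
  }
  if (relation == "direct" || n_linker == 0L) return(.add_bond(mb, site, target))
  prev <- site
  for (i in seq_len(n_linker)) {
    mb <- .add_chain_atom(mb, prev)
    prev <- max(mb$atoms$atom_id)
  }
  .add_bond(mb, prev, target)
}

#' Generate a synthetic compound library
#'
#' Molecules are assembled from catalog fragments: actives carry each
#' causal fragment with probability `p_frag_active` (inactives
#' `p_frag_inactive`), both classes carry class-independent decoy
#' fragments, and planted combination rules override the assembly of the
#' designated fraction of actives.  Active pIC50 values follow
#' `baseline + sum(effects * presence) + N(0, noise_sd)`, truncated so
#' IC50 stays at or below 10,000 nM; inactive IC50 values are drawn
#' log-uniformly from (10^4, 10^6] nM.
#'
#' @param config A `generator_config`.
#' @return List with `library` (list of `molgraph`s, IC50 in
#'   `properties$ic50_nM`), `activity` (`data.frame` mol_id, ic50_nM,
#'   active), and `manifest` (per-molecule ground truth: planted fragment
#'   names, rule applied, pIC50).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  decoys <- setdiff(names(cfg$catalog), cfg$causal)
  lib <- vector("list", cfg$n_molecules)
  man <- vector("list", cfg$n_molecules)
  with_preserved_seed(cfg$seed, {
    for (i in seq_len(cfg$n_molecules)) {
      mol_id <- sprintf("syn%04d", i)
      active <- stats::runif(1) < cfg$prevalence
      rule_applied <- NA_character_
      planted <- character()
      mb <- .mol_builder()

      rule <- NULL
      if (active && length(cfg$rules)) {
        for (ri in seq_along(cfg$rules)) {
          r <- cfg$rules[[ri]]
          if (stats::runif(1) < r$prevalence) { rule <- r; rule_applied <-
            paste0("rule", ri); break }
        }
      }
      if (!is.null(rule)) {
        mb <- .join_fragment(mb, cfg$catalog[[rule$a]])
        mb <- .join_fragment(mb, cfg$catalog[[rule$b]],
                             relation = rule$relation,
                             n_linker = if (is.null(rule$linker_n)) 1L
                             else rule$linker_n)
        planted <- c(planted, rule$a, rule$b)
      }
      p_causal <- if (active) cfg$p_frag_active else cfg$p_frag_inactive
      for (f in setdiff(cfg$causal, planted)) {
        if (stats::runif(1) < p_causal) {
          mb <- .join_fragment(mb, cfg$catalog[[f]],
                               n_linker = sample(0:2, 1L))
          planted <- c(planted, f)
        }
      }
      n_dec <- sample(seq(cfg$decoy_range[1L], cfg$decoy_range[2L]), 1L)
      dec <- sample(decoys, n_dec)
      for (f in dec) {
        mb <- .join_fragment(mb, cfg$catalog[[f]],
                             n_linker = sample(0:2, 1L))
        planted <- c(planted, f)
      }
      if (stats::runif(1) < cfg$p_decoy_chain) {
        site <- .spare_carbons(mb)
        if (length(site)) {
          prev <- site[sample.int(length(site), 1L)]
          for (k in seq_len(sample(1:3, 1L))) {
            mb <- .add_chain_atom(mb, prev)
            prev <- max(mb$atoms$atom_id)
          }
        }
      }

      presence <- as.numeric(cfg$causal %in% planted)
      pic50 <- NA_real_
      if (active) {
        pic50 <- cfg$baseline_pIC50 +
          sum(cfg$effects[cfg$causal] * presence) +
          stats::rnorm(1, 0, cfg$noise_sd)
        pic50 <- max(pic50, 5)          # IC50 capped at 10,000 nM
        ic50 <- 10^(9 - pic50)
      } else {
        ic50 <- 10^stats::runif(1, 4.02, 6)
      }
      g <- molgraph(mol_id, mb$atoms, mb$bonds,
                    properties = list(ic50_nM = ic50))
      validate_molgraph(g, valence = TRUE)
      lib[[i]] <- g
      man[[i]] <- data.frame(mol_id = mol_id, active = active,
                             fragments = paste(sort(planted), collapse = ","),
                             rule = rule_applied, pIC50 = pic50,
                             ic50_nM = ic50, stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, man)
  list(library = library_index(lib),
       activity = data.frame(mol_id = manifest$mol_id,
                             ic50_nM = manifest$ic50_nM,
                             active = manifest$active,
                             stringsAsFactors = FALSE),
       manifest = manifest)
}

#' Random small molecule library for mining benchmarks
#'
#' Molecules are random trees over a C/C/C/N/O element alphabet with
#' occasional double bonds and ring closures, capped at `max_bonds` bonds,
#' so exhaustive subgraph enumeration stays tractable and frequent
#' fragments recur across molecules.
#'
#' @param seed Integer seed.
#' @param n_molecules Library size.
#' @param max_bonds Per-molecule bond cap (<= 10 keeps brute force cheap).
#' @return List of `molgraph`s.
#' @export
random_small_library <- function(seed, n_molecules = 10L, max_bonds = 10L) {
  with_preserved_seed(seed, {
    lib <- lapply(seq_len(n_molecules), function(i) {
      n_atoms <- sample(3:min(8L, max_bonds + 1L), 1L)
      elems <- sample(c("C", "C", "C", "N", "O"), n_atoms, replace = TRUE)
      mb <- .mol_builder()
      mb$atoms <- data.frame(atom_id = seq_len(n_atoms), element = elems,
                             charge = 0L, aromatic = FALSE)
      for (a in 2:n_atoms) {
        cand <- Filter(function(x) {
          .VALENCE[[elems[x]]] - .used_valence(mb, x) >= 1 &&
            .VALENCE[[elems[a]]] - .used_valence(mb, a) >= 1
        }, seq_len(a - 1L))
        if (length(cand) == 0L) cand <- seq_len(a - 1L)
        to <- cand[sample.int(length(cand), 1L)]
        ord <- if (stats::runif(1) < 0.15 &&
                   .VALENCE[[elems[to]]] - .used_valence(mb, to) >= 2 &&
                   .VALENCE[[elems[a]]] >= 2) "double" else "single"
        mb <- .add_bond(mb, to, a, ord)
      }
      if (stats::runif(1) < 0.3 && nrow(mb$bonds) < max_bonds) {
        pairs <- which(outer(seq_len(n_atoms), seq_len(n_atoms), "<"),
                       arr.ind = TRUE)
        ok <- apply(pairs, 1L, function(p) {
          u <- p[1L]; v <- p[2L]
          if (any((mb$bonds$a1 == u & mb$bonds$a2 == v) |
                  (mb$bonds$a1 == v & mb$bonds$a2 == u))) return(FALSE)
          .VALENCE[[elems[u]]] - .used_valence(mb, u) >= 1 &&
            .VALENCE[[elems[v]]] - .used_valence(mb, v) >= 1
        })
        if (any(ok)) {
          p <- pairs[which(ok)[sample.int(sum(ok), 1L)], ]
          mb <- .add_bond(mb, p[1L], p[2L])
        }
      }
      molgraph(sprintf("rnd%03d", i), mb$atoms, mb$bonds)
    })
    library_index(lib)
  })
}

#' Assemble the named benchmark suite
#'
#' Fixed fixtures exercising every pipeline stage: `fig_tree`, a
#' four-molecule library whose C-C root fragment has five embeddings in
#' four molecules (popularity 4) and exactly two one-bond extensions;
#' `mining`, twenty random libraries small enough for the brute-force
#' oracle; `classification` and `regression`, planted-signal QSAR
#' libraries; `rules`, a library with a planted one-carbon linker rule;
#' `background`, a neutral library for enrichment testing.
#'
#' @param seed Integer seed for the random components.
#' @param which Character vector choosing components (default all).
#' @return Named list of fixtures.
#' @export
make_benchmark_suite <- function(seed = 1L,
                                 which = c("fig_tree", "mining",
                                           "classification", "regression",
                                           "rules", "background")) {
  out <- list()
  if ("fig_tree" %in% which) out$fig_tree <- fig_tree_library()
  if ("mining" %in% which) {
    sizes <- with_preserved_seed(seed, sample(5:25, 20L, replace = TRUE))
    out$mining <- lapply(seq_len(20L), function(i)
      random_small_library(seed * 1000L + i, n_molecules = sizes[i],
                           max_bonds = 10L))
  }
  if ("classification" %in% which)
    out$classification <- generate_library(benchmark_config("classification",
                                                            seed))
  if ("regression" %in% which)
    out$regression <- generate_library(benchmark_config("regression", seed))
  if ("rules" %in% which)
    out$rules <- generate_library(benchmark_config("rules", seed))
  if ("background" %in% which)
    out$background <- generate_library(benchmark_config("background", seed))
  out
}

#' Benchmark generator configurations
#'
#' The canonical study conditions used by the package's recovery
#' benchmarks: `classification` (600 molecules, 30-fragment dictionary, 5
#' causal fragments), `regression` (300 potency-graded molecules, two
#' causal fragments with +1.5 and +1.0 pIC50 effects, noise sd 0.2,
#' baseline 5), `rules` (a planted one-carbon linker rule joining two
#' rings in 70 percent of actives), and `background` (no causal signal;
#' plays the role of a large neutral compound collection).
#'
#' The additional `pipeline` configuration is a compact library (40
#' molecules, one decoy ring each) sized so that the full mine -> SSD ->
#' models -> privileged -> rules chain runs in seconds.
#'
#' @param name One of `"classification"`, `"regression"`, `"rules"`,
#'   `"background"`, `"pipeline"`.
#' @param seed Integer seed.
#' @return A `generator_config`.
#' @export
benchmark_config <- function(name = c("classification", "regression",
                                      "rules", "background", "pipeline"),
                             seed = 1L) {
  name <- match.arg(name)
  causal5 <- c("pyridine", "furan", "piperazine", "thiophene", "morpholine")
  switch(name,
    classification = generator_config(
      seed = seed, n_molecules = 600L, causal = causal5,
      effects = stats::setNames(c(1.5, 1.2, 1.0, 0.8, 0.6), causal5),
      baseline_pIC50 = 6, noise_sd = 0.2, prevalence = 0.5,
      p_frag_active = 0.65, p_frag_inactive = 0.10),
    regression = generator_config(
      seed = seed, n_molecules = 300L, causal = c("pyridine", "furan"),
      effects = c(pyridine = 1.5, furan = 1.0), baseline_pIC50 = 5,
      noise_sd = 0.2, prevalence = 1, p_frag_active = 0.5),
    rules = generator_config(
      seed = seed, n_molecules = 200L, causal = c("pyridine", "furan"),
      effects = c(pyridine = 1.5, furan = 1.0), prevalence = 0.5,
      p_frag_active = 0.3, p_frag_inactive = 0.05,
      rules = list(list(a = "pyridine", b = "furan", relation = "linker",
                        linker_n = 1L, prevalence = 0.7))),
    background = generator_config(
      seed = seed, n_molecules = 300L, causal = character(),
      prevalence = 0.5, decoy_range = c(1L, 2L)),
    pipeline = generator_config(
      seed = seed, n_molecules = 40L, causal = c("pyridine", "furan"),
      effects = c(pyridine = 1.5, furan = 1.0), prevalence = 0.5,
      p_frag_active = 0.6, p_frag_inactive = 0.1,
      decoy_range = c(1L, 1L), p_decoy_chain = 0.1,
      rules = list(list(a = "pyridine", b = "furan", relation = "linker",
                        linker_n = 1L, prevalence = 0.7))))
}

#' The four-molecule substructure-tree demonstration library
#'
#' Molecules A, B, C each contain one C-C single bond and molecule D two,
#' so the C-C root fragment's subID has five components over four
#' molecules (popularity 4) and growing the root yields exactly two child
#' fragments.
#'
#' @return Named list of four `molgraph`s.
#' @export
fig_tree_library <- function() {
  chain <- function(id, elems) {
    n <- length(elems)
    molgraph(id, data.frame(atom_id = seq_len(n), element = elems),
             data.frame(bond_id = seq_len(n - 1L), a1 = seq_len(n - 1L),
                        a2 = 2:n, order = "single"))
  }
  library_index(list(chain("A", c("C", "C", "N")),
                     chain("B", c("C", "C", "O")),
                     chain("C", c("C", "C", "O")),
                     chain("D", c("C", "C", "O", "C", "C"))))
}
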