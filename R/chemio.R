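# Reading and writing compound libraries (SDF V2000, SMILES tables) and the
# activity preprocessing applied before modeling: salt stripping,
# deduplication, IC50 -> binary label at 10,000 nM, IC50 -> pIC50.

#' Read a compound library
#'
#' SDF files (V2000 MOL blocks) are parsed with ChemmineR; formal charges
#' are recovered from the `M  CHG` property lines, which ChemmineR does not
#' surface, and bond order 4 is interpreted as aromatic.  SMILES tables
#' (one record per line: id, SMILES, optional activity columns, tab- or
#' comma-separated) are converted to SDF with the OpenBabel `obabel` tool
#' and then read the same way; Kekule rings written by OpenBabel are
#' re-perceived as aromatic for six-membered alternating rings.
#'
#' Malformed records are skipped with a warning and counted in the
#' `n_skipped` attribute; a file with no valid record is an error.
#'
#' @param path File path.
#' @param format `"sdf"` or `"smiles"`.
#' @param activity_field Name of the SDF data field / table column holding
#'   IC50 values in nM.
#' @param perceive_aromatic Re-perceive aromaticity on alternating
#'   single/double six-membered rings (applied to SMILES input).
#' @return List of `molgraph`s with `properties$ic50_nM` populated where
#'   available; attribute `n_skipped` counts rejected records.
#' @export
read_library <- function(path, format = c("sdf", "smiles"),
                         activity_field = "IC50_nM",
                         perceive_aromatic = (format[1] == "smiles")) {
  format <- match.arg(format)
  if (format == "smiles") {
    tab <- utils::read.table(path, sep = "", header = FALSE,
                             stringsAsFactors = FALSE, fill = TRUE,
                             col.names = paste0("V", 1:3))[, 1:3]
    # columns: id, smiles, optional ic50; accept "id<TAB>smiles<TAB>ic50"
    # or "smiles id" obabel-style by sniffing which column parses as SMILES
    smi <- tempfile(fileext = ".smi"); on.exit(unlink(smi), add = TRUE)
    writeLines(paste(tab$V2, tab$V1), smi)
    out <- tempfile(fileext = ".sdf"); on.exit(unlink(out), add = TRUE)
    status <- system2("obabel", c("-ismi", smi, "-osdf", "-O", out),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(out)) stop("obabel SMILES conversion failed")
    lib <- read_library(out, "sdf", activity_field = activity_field,
                        perceive_aromatic = FALSE)
    if (perceive_aromatic) lib <- lapply(lib, perceive_aromatic_rings)
    ic50 <- suppressWarnings(as.numeric(tab$V3))
    names(ic50) <- as.character(tab$V1)
    lib <- lapply(lib, function(m) {
      v <- ic50[[m$mol_id]]
      if (!is.null(v) && length(v) && !is.na(v)) m$properties$ic50_nM <- v
      m
    })
    return(library_index(lib))
  }

  parsed <- .read_sdf_records(path)
  sdfrecs <- parsed$records
  n_skipped <- parsed$n_skipped
  charges <- .sdf_charge_blocks(path)[parsed$kept]
  lib <- list(); used <- character()
  for (i in seq_along(sdfrecs)) {
    g <- tryCatch(
      .sdf_to_molgraph(sdfrecs[[i]], charges[[i]], activity_field),
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(g)) { n_skipped <- n_skipped + 1L; next }
    if (g$mol_id %in% used) g$mol_id <- paste0(g$mol_id, "_", i)
    used <- c(used, g$mol_id)
    if (perceive_aromatic) g <- perceive_aromatic_rings(g)
    lib[[length(lib) + 1L]] <- g
  }
  if (n_skipped > 0L)
    warning(n_skipped, " malformed record(s) skipped in ", path)
  if (length(lib) == 0L) stop("no valid records in ", path)
  structure(library_index(lib), n_skipped = n_skipped)
}

# parse an SDF into per-record SDF objects; a record ChemmineR cannot parse
# (or flags as invalid) is dropped and counted.  The whole file is read in
# one pass when clean; the per-record fallback isolates corrupt blocks.
.read_sdf_records <- function(path) {
  whole <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                    error = function(e) NULL)
  if (!is.null(whole)) {
    valid <- ChemmineR::validSDF(whole)
    return(list(records = lapply(which(valid), function(i) whole[[i]]),
                kept = which(valid), n_skipped = sum(!valid)))
  }
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- list(); kept <- integer(); n_skipped <- 0L
  tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(tmp))
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:ends[i]]
    if (all(!nzchar(trimws(blk)))) next
    if (!any(grepl("^\\$\\$\\$\\$", blk))) blk <- c(blk, "$$$$")
    writeLines(blk, tmp)
    s <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tmp)),
                  error = function(e) NULL)
    if (is.null(s) || length(s) == 0L || !ChemmineR::validSDF(s)[1L]) {
      n_skipped <- n_skipped + 1L
    } else {
      records[[length(records) + 1L]] <- s[[1L]]
      kept <- c(kept, i)
    }
  }
  list(records = records, kept = kept, n_skipped = n_skipped)
}

# formal charges per record from the raw M  CHG lines, in record order
.sdf_charge_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_end <- grep("^\\$\\$\\$\\$", lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  if (length(rec_end) == 0L) { rec_start <- 1L; rec_end <- length(lines) }
  lapply(seq_along(rec_start), function(i) {
    blk <- lines[rec_start[i]:rec_end[i]]
    chg <- grep("^M  CHG", blk, value = TRUE)
    out <- integer()
    for (ln in chg) {
      v <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)),
                               "\\s+")[[1]])
      if (length(v) >= 2L)
        for (k in seq(1L, length(v) - 1L, by = 2L))
          out[as.character(v[k])] <- v[k + 1L]
    }
    out
  })
}

.sdf_to_molgraph <- function(sdf, charges, activity_field) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  keep <- elem != "H"
  atom_ids <- seq_len(nrow(ab))
  chg <- integer(nrow(ab))
  if (length(charges)) chg[as.integer(names(charges))] <- unname(charges)
  b <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                  raw = as.integer(bb[, 3]))
  b <- b[keep[b$a1] & keep[b$a2], , drop = FALSE]
  order_map <- c(`1` = "single", `2` = "double", `3` = "triple",
                 `4` = "aromatic")
  if (!all(as.character(b$raw) %in% names(order_map)))
    stop("unsupported bond order in record")
  bonds <- data.frame(bond_id = seq_len(nrow(b)), a1 = b$a1, a2 = b$a2,
                      order = order_map[as.character(b$raw)])
  arom_atoms <- unique(c(bonds$a1[bonds$order == "aromatic"],
                         bonds$a2[bonds$order == "aromatic"]))
  atoms <- data.frame(atom_id = atom_ids, element = elem, charge = chg,
                      aromatic = atom_ids %in% arom_atoms)[keep, , drop = FALSE]
  hdr <- ChemmineR::header(sdf)
  mol_id <- trimws(hdr[["Molecule_Name"]])
  if (!nzchar(mol_id)) mol_id <- "unnamed"
  props <- as.list(ChemmineR::datablock(sdf))
  if (!is.null(props[[activity_field]])) {
    v <- suppressWarnings(as.numeric(props[[activity_field]]))
    if (!is.na(v)) props$ic50_nM <- v
  }
  molgraph(mol_id, atoms, bonds, props)
}

#' Perceive aromaticity on alternating six-membered rings
#'
#' Marks as aromatic the bonds and atoms of any six-membered ring of C/N
#' atoms whose bond orders alternate single/double (the Kekule form written
#' by most SMILES tool chains).  Deliberately minimal: fused and
#' five-membered aromatic systems are left as drawn.
#'
#' @param mol A `molgraph`.
#' @return The updated `molgraph`.
#' @export
perceive_aromatic_rings <- function(mol) {
  b <- mol$bonds
  if (nrow(b) < 6L) return(mol)
  rings <- .find_rings(mol, size = 6L)
  for (ring in rings) {
    rows <- match(ring, b$bond_id)
    ords <- b$order[rows]
    aid <- unique(c(b$a1[rows], b$a2[rows]))
    el <- mol$atoms$element[match(aid, mol$atoms$atom_id)]
    if (!all(el %in% c("C", "N"))) next
    if (sum(ords == "double") == 3L && sum(ords == "single") == 3L) {
      # alternating check: no two doubles share an atom
      dr <- rows[ords == "double"]
      at <- c(b$a1[dr], b$a2[dr])
      if (anyDuplicated(at)) next
      mol$bonds$order[rows] <- "aromatic"
      mol$atoms$aromatic[match(aid, mol$atoms$atom_id)] <- TRUE
    } else if (all(ords == "aromatic")) {
      mol$atoms$aromatic[match(aid, mol$atoms$atom_id)] <- TRUE
    }
  }
  mol
}

# simple cycles of a given size, as bond-id vectors
.find_rings <- function(mol, size) {
  b <- mol$bonds
  adj <- lapply(mol$atoms$atom_id, function(a)
    which(b$a1 == a | b$a2 == a))
  names(adj) <- as.character(mol$atoms$atom_id)
  rings <- list(); seen <- character()
  walk <- function(start, current, path_bonds, path_atoms) {
    if (length(path_bonds) == size) {
      if (current == start) {
        key <- paste(sort(path_bonds), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- sort(path_bonds)
        }
      }
      return(invisible(NULL))
    }
    for (r in adj[[as.character(current)]]) {
      bid <- b$bond_id[r]
      if (bid %in% path_bonds) next
      nxt <- if (b$a1[r] == current) b$a2[r] else b$a1[r]
      if (nxt %in% path_atoms && nxt != start) next
      if (nxt == start && length(path_bonds) + 1L < size) next
      walk(start, nxt, c(path_bonds, bid), c(path_atoms, nxt))
    }
  }
  for (a in mol$atoms$atom_id) walk(a, a, integer(), a)
  rings
}

#' Write a library as SDF (V2000)
#'
#' Aromatic bonds are written with bond order 4 and formal charges as
#' `M  CHG` lines, matching what [read_library()] expects back; molecule
#' properties become SDF data fields.  Output is deterministic.
#'
#' @param library List of `molgraph`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(library, path) {
  order_map <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  con <- file(path, "w"); on.exit(close(con))
  for (mol in library) {
    a <- mol$atoms; b <- mol$bonds
    ridx <- seq_len(nrow(a)); names(ridx) <- as.character(a$atom_id)
    lines <- c(mol$mol_id, "  fragmine", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, a$element),
               if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0",
                                    ridx[as.character(b$a1)],
                                    ridx[as.character(b$a2)],
                                    order_map[b$order]))
    chg <- which(a$charge != 0L)
    if (length(chg))
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                               paste0(sprintf("%4d", ridx[chg]),
                                      sprintf("%4d", a$charge[chg]),
                                      collapse = "")))
    lines <- c(lines, "M  END")
    for (nm in names(mol$properties)) {
      val <- mol$properties[[nm]]
      if (is.null(val) || length(val) != 1L) next
      lines <- c(lines, paste0("> <", nm, ">"), format(val, trim = TRUE), "")
    }
    writeLines(c(lines, "$$$$"), con)
  }
  invisible(path)
}

#' Write a library as a SMILES-free id table
#'
#' Libraries whose graphs originated outside SMILES have no stored SMILES;
#' this writes a TSV of id, canonical key and IC50 for bookkeeping.
#'
#' @param library List of `molgraph`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_table <- function(library, path) {
  df <- data.frame(
    mol_id = vapply(library, function(m) m$mol_id, ""),
    canonical_key = vapply(library, function(m)
      fragment_from_bonds(m, m$bonds$bond_id)$canonical_key, ""),
    ic50_nM = vapply(library, function(m)
      if (is.null(m$properties$ic50_nM)) NA_real_ else
        as.numeric(m$properties$ic50_nM), 0),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strip salt components
#'
#' Keeps the connected component with the most heavy atoms; ties broken by
#' bond count, then by lexicographically smallest canonical key, so the
#' result is deterministic.
#'
#' @param mol A `molgraph` (possibly multi-component).
#' @return A single-component `molgraph`.
#' @export
strip_salt <- function(mol) {
  comp <- .components(mol)
  if (length(comp) == 1L) return(mol)
  score <- lapply(comp, function(aids) {
    rows <- mol$bonds$a1 %in% aids & mol$bonds$a2 %in% aids
    key <- if (any(rows))
      fragment_from_bonds(mol, mol$bonds$bond_id[rows])$canonical_key
    else paste0("atom:", .atom_label(mol$atoms[match(aids, mol$atoms$atom_id), ]))
    list(n_atoms = length(aids), n_bonds = sum(rows), key = key)
  })
  o <- order(-vapply(score, `[[`, 0L, "n_atoms"),
             -vapply(score, `[[`, 0L, "n_bonds"),
             vapply(score, `[[`, "", "key"))
  aids <- comp[[o[1L]]]
  rows <- mol$bonds$a1 %in% aids & mol$bonds$a2 %in% aids
  molgraph(mol$mol_id,
           mol$atoms[match(aids, mol$atoms$atom_id), , drop = FALSE],
           mol$bonds[rows, , drop = FALSE], mol$properties)
}

.components <- function(mol) {
  aid <- mol$atoms$atom_id
  parent <- seq_along(aid); names(parent) <- as.character(aid)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(mol$bonds))) {
    i <- find(match(mol$bonds$a1[k], aid)); j <- find(match(mol$bonds$a2[k], aid))
    if (i != j) parent[j] <- i
  }
  roots <- vapply(seq_along(aid), find, 0L)
  split(aid, roots)
}

#' Remove duplicate structures
#'
#' Keeps the first occurrence per whole-molecule canonical form (computed
#' after salt stripping); order otherwise preserved.  Idempotent.
#'
#' @param library List of `molgraph`s.
#' @param strip Apply [strip_salt()] before comparing?
#' @return The deduplicated library.
#' @export
deduplicate <- function(library, strip = TRUE) {
  if (length(library) == 0L) stop("empty library")
  keys <- vapply(library, function(m) {
    if (strip) m <- strip_salt(m)
    if (nrow(m$bonds) == 0L)
      paste0("atom:", .atom_label(m$atoms))
    else fragment_from_bonds(m, m$bonds$bond_id)$canonical_key
  }, "")
  library[!duplicated(keys)]
}

#' Prepare activity records for modeling
#'
#' Classification: label 0 when IC50 exceeds 10,000 nM, else 1 (a value of
#' exactly 10,000 nM is active); all rows kept.  Regression: rows above
#' 10,000 nM removed, pIC50 = -log10(IC50 in molar) on the rest.
#' Non-positive IC50 rows are rejected with a warning.
#'
#' @param records `data.frame` with columns `mol_id`, `ic50_nM`, or a
#'   library of `molgraph`s carrying `properties$ic50_nM`.
#' @param mode `"classification"` or `"regression"`.
#' @param threshold_nM Activity threshold (default 10,000 nM).
#' @return `data.frame` with columns `mol_id`, `ic50_nM` and `label` or
#'   `pIC50`.
#' @export
prepare_activity <- function(records, mode = c("classification", "regression"),
                             threshold_nM = 10000) {
  mode <- match.arg(mode)
  if (!is.data.frame(records)) {
    records <- data.frame(
      mol_id = vapply(records, function(m) m$mol_id, ""),
      ic50_nM = vapply(records, function(m) {
        v <- m$properties$ic50_nM
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, 0), stringsAsFactors = FALSE)
  }
  if (anyNA(records$ic50_nM)) stop("every record needs an ic50_nM value")
  bad <- records$ic50_nM <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive IC50 rejected")
    records <- records[!bad, , drop = FALSE]
  }
  if (mode == "classification") {
    records$label <- ifelse(records$ic50_nM > threshold_nM, 0L, 1L)
  } else {
    records <- records[records$ic50_nM <= threshold_nM, , drop = FALSE]
    records$pIC50 <- -log10(records$ic50_nM * 1e-9)
  }
  rownames(records) <- NULL
  records
}
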