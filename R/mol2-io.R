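#' Read a multi-entry Sybyl TRIPOS MOL2 file
#'
#' Parses every `@<TRIPOS>MOLECULE` record into a [Mol2Molecule-class],
#' preserving atom order, Sybyl types and partial charges exactly. Both
#' status-bit and no-status-bit ATOM lines are accepted; when the charge
#' column is absent charges default to 0 with a warning. Entry names that
#' collide (pose files repeat the ligand name per pose) are deduplicated by
#' appending an ordinal suffix.
#'
#' @param path path to a MOL2 file.
#' @return list of [Mol2Molecule-class] entries, in file order.
#' @export
readMol2 <- function(path) {
  if (!file.exists(path)) stop("MOL2 file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  mol_starts <- which(trimws(lines) == "@<TRIPOS>MOLECULE")
  if (length(mol_starts) == 0)
    stop("no @<TRIPOS>MOLECULE record in ", path)
  bounds <- c(mol_starts, length(lines) + 1L)
  entries <- vector("list", length(mol_starts))
  charge_warned <- FALSE
  for (k in seq_along(mol_starts)) {
    block <- mol_starts[k]:(bounds[k + 1L] - 1L)
    res <- .parseMol2Block(lines, block)
    if (res$missing_charge) charge_warned <- TRUE
    entries[[k]] <- res$entry
  }
  if (charge_warned)
    warning("missing charge column in one or more ATOM lines; charges set to 0")
  nm <- vapply(entries, function(e) e@name, character(1))
  dup <- duplicated(nm)
  if (any(dup)) {
    nm2 <- make.unique(nm, sep = "_")
    for (k in which(nm2 != nm)) entries[[k]]@name <- nm2[k]
  }
  entries
}

.parseMol2Block <- function(lines, block) {
  txt <- lines[block]
  hdr_name <- if (length(txt) >= 2) trimws(txt[2]) else ""
  counts <- if (length(txt) >= 3) suppressWarnings(
    as.integer(strsplit(trimws(txt[3]), "\\s+")[[1]])) else integer(0)
  n_atoms_decl <- if (length(counts) >= 1) counts[1] else NA_integer_
  sect <- grep("^@<TRIPOS>", trimws(txt))
  sect_name <- sub("^@<TRIPOS>", "", trimws(txt)[sect])
  secOf <- function(name) {
    i <- which(sect_name == name)
    if (length(i) == 0) return(integer(0))
    i <- i[1]
    lo <- sect[i] + 1L
    hi <- if (i < length(sect)) sect[i + 1L] - 1L else length(txt)
    if (hi < lo) return(integer(0))
    idx <- lo:hi
    idx[nzchar(trimws(txt[idx])) & !startsWith(trimws(txt[idx]), "#")]
  }
  atom_idx <- secOf("ATOM")
  if (length(atom_idx) == 0)
    stop(sprintf("entry '%s' has zero atoms (line %d)", hdr_name, block[1]))
  missing_charge <- FALSE
  n <- length(atom_idx)
  atom_id <- integer(n); aname <- character(n); sy <- character(n)
  x <- numeric(n); y <- numeric(n); z <- numeric(n); q <- numeric(n)
  for (j in seq_len(n)) {
    lineno <- block[atom_idx[j]]
    f <- strsplit(trimws(txt[atom_idx[j]]), "\\s+")[[1]]
    if (length(f) < 6)
      stop(sprintf("malformed ATOM line %d: '%s'", lineno, txt[atom_idx[j]]))
    id <- suppressWarnings(as.integer(f[1]))
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (is.na(id) || any(is.na(xyz)) || any(!is.finite(xyz)))
      stop(sprintf("malformed ATOM line %d: '%s'", lineno, txt[atom_idx[j]]))
    atom_id[j] <- id; aname[j] <- f[2]; sy[j] <- f[6]
    x[j] <- xyz[1]; y[j] <- xyz[2]; z[j] <- xyz[3]
    # full TRIPOS layout: id name x y z type subst_id subst_name charge [status]
    if (length(f) >= 9) {
      qq <- suppressWarnings(as.numeric(f[9]))
      if (is.na(qq))
        stop(sprintf("malformed ATOM line %d: bad charge '%s'", lineno, f[9]))
      q[j] <- qq
    } else {
      q[j] <- 0
      missing_charge <- TRUE
    }
  }
  if (!is.na(n_atoms_decl) && n_atoms_decl != n)
    stop(sprintf("entry '%s': header declares %d atoms but %d parsed",
                 hdr_name, n_atoms_decl, n))
  bond_idx <- secOf("BOND")
  if (length(bond_idx) > 0) {
    bf <- do.call(rbind, lapply(bond_idx, function(i) {
      f <- strsplit(trimws(txt[i]), "\\s+")[[1]]
      if (length(f) < 4)
        stop(sprintf("malformed BOND line %d: '%s'", block[i], txt[i]))
      f[2:4]
    }))
    bonds <- data.frame(from = as.integer(bf[, 1]), to = as.integer(bf[, 2]),
                        order = bf[, 3], stringsAsFactors = FALSE)
    bad <- !(bonds$from %in% atom_id) | !(bonds$to %in% atom_id)
    if (any(bad))
      stop(sprintf("entry '%s': bond references nonexistent atom id %s",
                   hdr_name,
                   paste(unique(c(bonds$from[bad], bonds$to[bad])[
                     !c(bonds$from[bad], bonds$to[bad]) %in% atom_id]),
                     collapse = ", ")))
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0),
                        order = character(0), stringsAsFactors = FALSE)
  }
  atoms <- data.frame(atom_id = atom_id, name = aname, sybyl_type = sy,
                      x = x, y = y, z = z, charge = q,
                      stringsAsFactors = FALSE)
  list(entry = new("Mol2Molecule", name = hdr_name, atoms = atoms,
                   bonds = bonds),
       missing_charge = missing_charge)
}

#' Write molecule entries to a multi-entry TRIPOS MOL2 file
#'
#' Coordinates and charges are written with 4 decimals. When
#' `includeBonds` is `FALSE` the declared bond count is 0 and the BOND
#' section is empty — the bond-free representation used for merged
#' clustering input and for cavity models.
#'
#' @param entries list of [Mol2Molecule-class] (a single molecule is also
#'   accepted).
#' @param path output file path.
#' @param includeBonds write bond records? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
writeMol2 <- function(entries, path, includeBonds = TRUE) {
  if (is(entries, "Mol2Molecule")) entries <- list(entries)
  if (length(entries) == 0) stop("no entries to write")
  out <- character(0)
  for (e in entries) {
    a <- e@atoms
    b <- if (includeBonds) e@bonds else e@bonds[0, , drop = FALSE]
    out <- c(out,
      "@<TRIPOS>MOLECULE",
      e@name,
      sprintf("%5d %5d %5d %5d %5d", nrow(a), nrow(b), 0L, 0L, 0L),
      "SMALL",
      "USER_CHARGES",
      "@<TRIPOS>ATOM",
      sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %5d %-8s %10.4f",
              a$atom_id, a$name, a$x, a$y, a$z, a$sybyl_type,
              1L, "LIG", a$charge),
      "@<TRIPOS>BOND")
    if (nrow(b) > 0)
      out <- c(out, sprintf("%6d %5d %5d %s",
                            seq_len(nrow(b)), b$from, b$to, b$order))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write a cavity model as a single-entry MOL2 file
#'
#' The model is written as one bond-free molecule entry; cluster sizes go
#' into the atom name (`<type>_<size>`) so provenance survives the format.
#'
#' @param model a [CavityModel-class].
#' @param path output file path.
#' @param name molecule entry name.
#' @return `path`, invisibly.
#' @export
writeModelMol2 <- function(model, path, name = "cavity_model") {
  stopifnot(is(model, "CavityModel"))
  a <- model@atoms
  df <- data.frame(atom_id = seq_len(nrow(a)),
                   name = sprintf("%s_%d", sub("\\..*$", "", a$sybyl_type),
                                  a$cluster_size),
                   sybyl_type = a$sybyl_type, x = a$x, y = a$y, z = a$z,
                   charge = a$charge, stringsAsFactors = FALSE)
  writeMol2(list(new("Mol2Molecule", name = name, atoms = df,
                     bonds = data.frame(from = integer(0), to = integer(0),
                                        order = character(0)))),
            path, includeBonds = FALSE)
}

#' Interpret a molecule entry as a cavity model
#'
#' Used to reload a model written by [writeModelMol2()]: cluster sizes are
#' recovered from the `<type>_<size>` atom names when present, else 1.
#'
#' @param entry a [Mol2Molecule-class].
#' @return a [CavityModel-class].
#' @export
asCavityModel <- function(entry) {
  stopifnot(is(entry, "Mol2Molecule"))
  a <- entry@atoms
  sz <- suppressWarnings(as.integer(sub("^.*_", "", a$name)))
  sz[is.na(sz) | sz < 1] <- 1L
  cavityModel(data.frame(atom_id = a$atom_id, sybyl_type = a$sybyl_type,
                         x = a$x, y = a$y, z = a$z, charge = a$charge,
                         cluster_size = sz, stringsAsFactors = FALSE),
              settings = list(source = "mol2"))
}
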