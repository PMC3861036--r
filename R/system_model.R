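#' Default residue/atom classification tables
#'
#' The classification used throughout the package: solvent and ion residue
#' names, and the three-way polarity grouping of the standard amino acids
#' (Kyte-Doolittle-style; HIS treated as polar at neutral pH). All tables are
#' user-overridable, e.g. to move HIS to the charged class or to register
#' non-standard solvent residue names.
#'
#' @return A named list with character vectors `water`, `urea`, `ions`,
#'   `hydrophobic`, `polar`, `charged`.
#' @export
classification_defaults <- function() {
  list(
    water = c("HOH", "WAT", "TIP3", "SPC", "SOL"),
    urea = c("URE", "UREA"),
    ions = c("NA", "NA+", "CL", "CL-", "SOD", "CLA", "K", "K+", "MG", "ZN"),
    hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
                    "GLY", "CYS"),
    polar = c("SER", "THR", "ASN", "GLN", "TYR", "HIS"),
    charged = c("ASP", "GLU", "LYS", "ARG")
  )
}

# PDB atom-name -> element inference for files lacking the element column.
# Digits and primes are stripped; a leading digit (as in "1HB") is removed
# first. Two-letter elements are only assigned for ion residue names, so that
# "HG21" in a protein residue is hydrogen, not mercury.
infer_element <- function(name, resname) {
  nm <- toupper(trimws(name))
  rs <- toupper(trimws(resname))
  ion_map <- c("NA" = "Na", "NA+" = "Na", "SOD" = "Na", "CL" = "Cl",
               "CL-" = "Cl", "CLA" = "Cl", "K" = "K", "K+" = "K",
               "MG" = "Mg", "ZN" = "Zn", "FE" = "Fe", "CA" = "Ca")
  out <- character(length(nm))
  for (k in seq_along(nm)) {
    n <- nm[k]
    if (rs[k] %in% names(ion_map)) {
      out[k] <- ion_map[[rs[k]]]
      next
    }
    n <- gsub("[0-9'\"]", "", n)
    if (nchar(n) == 0L) stop("cannot infer element from atom name '",
                             name[k], "'")
    first <- substr(n, 1, 1)
    out[k] <- switch(first,
                     "H" = "H", "D" = "H",
                     "C" = "C", "N" = "N", "O" = "O", "S" = "S",
                     "P" = "P",
                     stop("cannot infer element from atom name '",
                          name[k], "' in residue '", resname[k], "'"))
  }
  out
}

new_mdsystem <- function(atoms, residues, selections = list()) {
  structure(list(atoms = atoms, residues = residues, selections = selections),
            class = "mdsystem")
}

#' @export
print.mdsystem <- function(x, ...) {
  cat("<mdsystem>", nrow(x$atoms), "atoms,", nrow(x$residues), "residues\n")
  if ("species" %in% names(x$residues) && !all(is.na(x$residues$species))) {
    tb <- table(x$residues$species)
    cat("  residues:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a PDB topology into a molecular system
#'
#' Reads the first model of a PDB file (via bio3d) and builds the atom and
#' residue tables used by every analysis in the package. Elements are taken
#' from the PDB element column when present and otherwise inferred from atom
#' names. Residue and atom classification (species, polarity, role) is filled
#' in by [classify_system()]; `load_topology()` already assigns the
#' backbone/sidechain role from atom names so that purely geometric analyses
#' can run unclassified.
#'
#' @param path path to a readable PDB file.
#' @return An object of class `mdsystem` with elements `atoms` (data frame:
#'   serial, name, element, is_heavy, residue_index, residue_name, chain,
#'   role) and `residues` (data frame: index, name, chain, species,
#'   polarity_class, is_core). Residue and atom indices are 1-based.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms found in ", path)

  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (chain, residue, atom-name) entries in ", path,
         ": first duplicate is atom serial ", at$eleno[which(dup)[1]],
         " (", key[which(dup)[1]], ")")
  }

  rkey <- paste(at$chain, at$resno, at$insert, at$resid, sep = "|")
  residue_index <- match(rkey, unique(rkey))

  elem <- trimws(at$elesy %||% "")
  if (length(elem) == 0L) elem <- rep("", nrow(at))
  missing_el <- is.na(elem) | elem == ""
  if (any(missing_el)) {
    elem[missing_el] <- infer_element(at$elety[missing_el],
                                      at$resid[missing_el])
  }
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 10)))

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    is_heavy = !(elem %in% c("H", "D")),
    residue_index = residue_index,
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    role = NA_character_,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )

  first <- !duplicated(residue_index)
  residues <- data.frame(
    index = residue_index[first],
    name = atoms$residue_name[first],
    chain = atoms$chain[first],
    species = NA_character_,
    polarity_class = NA_character_,
    is_core = NA,
    stringsAsFactors = FALSE
  )

  sys <- new_mdsystem(atoms, residues)
  assign_roles(sys)
}

# Backbone role from the PDB naming convention; requires species when known,
# falls back to "looks like an amino acid" (has N, CA, C) per residue.
assign_roles <- function(system, tables = classification_defaults()) {
  atoms <- system$atoms
  res <- system$residues
  solvent_names <- c(tables$water, tables$urea)
  ion_names <- tables$ions
  bb_names <- c("N", "CA", "C", "O", "OXT")

  by_res <- split(seq_len(nrow(atoms)), atoms$residue_index)
  role <- character(nrow(atoms))
  for (idx in by_res) {
    rn <- atoms$residue_name[idx[1]]
    if (rn %in% ion_names) {
      role[idx] <- "ion"
    } else if (rn %in% solvent_names) {
      role[idx] <- "solvent"
    } else {
      nm <- atoms$name[idx]
      role[idx] <- ifelse(nm %in% bb_names, "backbone", "sidechain")
    }
  }
  system$atoms$role <- role
  system
}

#' Classify residues and atoms of a molecular system
#'
#' Assigns every residue a species (protein, water, urea, ion) and, for
#' protein residues, a polarity class (hydrophobic, polar, charged), from the
#' lookup tables. Unknown residue names are an error -- there is no silent
#' guessing. The operation is idempotent.
#'
#' @param system an `mdsystem`.
#' @param tables classification tables, see [classification_defaults()].
#' @return The classified `mdsystem`.
#' @export
classify_system <- function(system, tables = classification_defaults()) {
  stopifnot(inherits(system, "mdsystem"))
  res <- system$residues
  known_protein <- c(tables$hydrophobic, tables$polar, tables$charged)
  species <- character(nrow(res))
  polarity <- rep(NA_character_, nrow(res))
  unknown <- character(0)
  for (k in seq_len(nrow(res))) {
    nm <- res$name[k]
    if (nm %in% tables$water) {
      species[k] <- "water"
    } else if (nm %in% tables$urea) {
      species[k] <- "urea"
    } else if (nm %in% tables$ions) {
      species[k] <- "ion"
    } else if (nm %in% known_protein) {
      species[k] <- "protein"
      polarity[k] <- if (nm %in% tables$hydrophobic) "hydrophobic"
      else if (nm %in% tables$polar) "polar" else "charged"
    } else {
      unknown <- c(unknown, nm)
    }
  }
  if (length(unknown) > 0L) {
    stop("unknown residue name(s) with no classification table entry: ",
         paste(unique(unknown), collapse = ", "))
  }
  system$residues$species <- species
  system$residues$polarity_class <- polarity
  assign_roles(system, tables)
}

new_mdtraj <- function(coords, times, box = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    if (any(box <= 0)) stop("box lengths must be positive")
    if (nrow(box) == 1L) box <- box[rep(1L, dim(coords)[3]), , drop = FALSE]
  }
  structure(list(coords = coords, times = times, box = box),
            class = "mdtraj")
}

#' @export
print.mdtraj <- function(x, ...) {
  cat("<mdtraj>", dim(x$coords)[3], "frames x", dim(x$coords)[1], "atoms,",
      "t =", x$times[1], "..", x$times[length(x$times)], "ns",
      if (!is.null(x$box)) "(periodic)" else "", "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mdtraj`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj an `mdtraj`.
#' @param i frame number (1-based).
#' @export
traj_frame <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Load a trajectory (multi-model PDB or DCD)
#'
#' @param path trajectory file; format chosen by extension (`.pdb` or `.dcd`).
#' @param system the `mdsystem` the coordinates belong to; atom counts must
#'   match.
#' @param dt_ns frame spacing in ns used to synthesize times 0, dt, 2dt, ...
#'   (trajectory formats used here carry no reliable time metadata).
#' @param box optional per-frame (or single) orthorhombic box lengths in
#'   Angstrom.
#' @return An `mdtraj`.
#' @export
load_trajectory <- function(path, system, dt_ns = NULL, box = NULL) {
  stopifnot(inherits(system, "mdsystem"))
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  }
  nat <- ncol(xyz) / 3
  nf <- nrow(xyz)
  if (nf == 0L) stop("trajectory has zero frames: ", path)
  if (nat != nrow(system$atoms)) {
    stop("atom-count mismatch: trajectory has ", nat, " atoms, system has ",
         nrow(system$atoms))
  }
  dt <- dt_ns %||% 1
  coords <- array(NA_real_, dim = c(nat, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  new_mdtraj(coords, times = (seq_len(nf) - 1) * dt, box = box)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param system the `mdsystem` providing atom records.
#' @param traj the `mdtraj` to write.
#' @param path output file.
#' @export
write_trajectory_pdb <- function(system, traj, path) {
  nat <- nrow(system$atoms)
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * nat)
  for (f in seq_len(nf)) {
    xyz[f, ] <- t(traj$coords[, , f])
  }
  a <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  pad_name <- function(nm) {
    # standard PDB alignment: 1-3 char names start in column 14
    ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
  }
  nm <- pad_name(a$name)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    crd <- traj$coords[, , f]
    lines <- sprintf(fmt, a$serial %% 100000, nm, a$residue_name, a$chain,
                     a$residue_index %% 10000, crd[, 1], crd[, 2], crd[, 3],
                     toupper(a$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in CHARMM DCD format
#'
#' Minimal single-precision DCD writer (no unit cell record); readable by
#' bio3d and the common MD tool chains.
#'
#' @param traj the `mdtraj` to write.
#' @param path output file.
#' @export
write_trajectory_dcd <- function(traj, path) {
  nat <- dim(traj$coords)[1]
  nf <- n_frames(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length prefix + payload + length suffix
    tmp <- raw(0)
    rc <- rawConnection(tmp, "wb")
    writer(rc)
    payload <- rawConnectionValue(rc)
    close(rc)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf       # frames
    icntrl[2] <- 1L       # first step
    icntrl[3] <- 1L       # step interval
    icntrl[4] <- nf
    icntrl[20] <- 24L     # CHARMM version stamp
    writeBin(icntrl, c2, size = 4L)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4L)
    writeChar(formatC("created by ureatraj", width = 80, flag = "-"),
              c2, nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(nat, c2, size = 4L))
  for (f in seq_len(nf)) {
    crd <- traj$coords[, , f]
    for (d in 1:3) {
      rec(function(c2) writeBin(as.numeric(crd[, d]), c2, size = 4L))
    }
  }
  invisible(path)
}

# ---- common selections -------------------------------------------------

#' Atom index selections
#'
#' Convenience selectors returning integer atom indices (row numbers of
#' `system$atoms`). `select_atoms` is the general form.
#'
#' @param system a classified `mdsystem`.
#' @param species restrict to residues of these species.
#' @param heavy_only drop hydrogens.
#' @param role restrict to atom roles (backbone, sidechain, solvent, ion).
#' @param residues restrict to these residue indices.
#' @param names restrict to these atom names.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(system, species = NULL, heavy_only = FALSE,
                         role = NULL, residues = NULL, names = NULL) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(species)) {
    rsp <- system$residues$species[a$residue_index]
    keep <- keep & rsp %in% species
  }
  if (heavy_only) keep <- keep & a$is_heavy
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(residues)) keep <- keep & a$residue_index %in% residues
  if (!is.null(names)) keep <- keep & a$name %in% names
  which(keep)
}

#' @rdname select_atoms
#' @export
protein_heavy_atoms <- function(system) {
  select_atoms(system, species = "protein", heavy_only = TRUE)
}

#' @rdname select_atoms
#' @export
ca_atoms <- function(system) {
  select_atoms(system, species = "protein", names = "CA")
}

#' Per-residue atom index lists for a set of residues
#' @param system an `mdsystem`.
#' @param residues residue indices (default: all protein residues).
#' @param heavy_only restrict to heavy atoms.
#' @return named list of integer vectors, names are residue indices.
#' @export
residue_atom_sets <- function(system, residues = NULL, heavy_only = TRUE) {
  if (is.null(residues)) {
    residues <- system$residues$index[system$residues$species %in% "protein"]
  }
  a <- system$atoms
  keep <- a$residue_index %in% residues & (!heavy_only | a$is_heavy)
  split(which(keep), a$residue_index[keep])
}
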