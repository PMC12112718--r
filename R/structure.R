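# Structure I/O, apo/holo superposition, ligand transfer and steric-clash
# analysis. Cryptic sites are operationalised here: residues of the apo
# structure whose heavy atoms lie strictly closer than a cutoff (default
# 2.5 Angstrom) to any heavy atom of the holo ligand after superposition.

WATER_ION_RESNAMES <- c("HOH", "WAT", "DOD", "SOL", "TIP", "TIP3", "NA", "CL",
                        "K", "MG", "ZN", "MN", "FE", "CA", "CD", "NI", "CU",
                        "SO4", "PO4", "GOL", "EDO_ION_NEVER")

#' Construct a structure3d object
#'
#' A light atom-table container for protein structures. One row per atom with
#' chain, residue, element and Cartesian coordinates in Angstrom. Residue
#' numbers are stored as character keys so PDB insertion codes can be
#' concatenated without ambiguity.
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `resno` (character), `resname`, `chain`, `record` ("ATOM"/"HETATM"),
#'   `x`, `y`, `z`. `is_heavy` is derived from `element`.
#' @param id character identifier for the structure.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, id = "structure") {
  req <- c("atom_id", "atom_name", "element", "resno", "resname", "chain",
           "record", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop_cryptohot(paste("atoms table missing columns:",
                         paste(missing_cols, collapse = ", ")),
                   "cryptohot_format_error")
  atoms$resno <- as.character(atoms$resno)
  atoms$is_heavy <- !(toupper(atoms$element) %in% c("H", "D"))
  if (anyDuplicated(atoms$atom_id))
    stop_cryptohot("duplicate atom_id values", "cryptohot_format_error")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop_cryptohot("non-finite coordinates", "cryptohot_format_error")
  structure(list(atoms = atoms, id = id), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d '%s': %d atoms (%d heavy), %d residues, chains: %s\n",
              x$id, nrow(a), sum(a$is_heavy),
              length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records of one model. Alternate locations are resolved
#' to the highest-occupancy conformer (ties broken in favour of altloc "A"),
#' and waters/common ions are dropped. Insertion codes are concatenated into
#' the residue-number key.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based model number for multi-model files.
#' @param drop_waters drop water and common monatomic/buffer ions.
#' @return A [structure3d] object.
#' @export
read_structure <- function(path, model_index = 1L, drop_waters = TRUE) {
  if (!file.exists(path))
    stop_cryptohot(paste("file not found:", path), "cryptohot_format_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop_cryptohot(paste("unparseable PDB:",
                                             conditionMessage(e)),
                                       "cryptohot_format_error"))
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models)
    stop_cryptohot(sprintf("model_index %d out of range (file has %d model(s))",
                           model_index, n_models), "cryptohot_empty_error")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- guess_element(at$elety[bad])
  resno_key <- paste0(at$resno, ifelse(is.na(at$insert) | at$insert == "",
                                       "", at$insert))
  atoms <- data.frame(
    atom_id = at$eleno, atom_name = at$elety, element = toupper(elem),
    resno = resno_key, resname = at$resid, chain = at$chain,
    record = at$type, x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)

  if (drop_waters)
    atoms <- atoms[!(atoms$resname %in% WATER_ION_RESNAMES), , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop_cryptohot("no atoms left in selected model", "cryptohot_empty_error")

  # altloc resolution: keep highest occupancy, then prefer "" or "A"
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$atom_name)
  if (anyDuplicated(key)) {
    pref <- order(key, -atoms$occupancy,
                  match(atoms$altloc, c("", "A", sort(unique(atoms$altloc)))))
    atoms <- atoms[pref, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resname,
                                     atoms$atom_name)), , drop = FALSE]
    atoms <- atoms[order(atoms$atom_id), , drop = FALSE]
  }
  atoms$occupancy <- NULL; atoms$altloc <- NULL
  structure3d(atoms, id = sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
}

guess_element <- function(atom_names) {
  nm <- gsub("[0-9']", "", trimws(atom_names))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), two, one)
}

#' Write a structure3d to a PDB file
#'
#' @param s a [structure3d].
#' @param path output path.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  resno_num <- as.integer(gsub("[^0-9-]", "", a$resno))
  insert <- gsub("[0-9-]", "", a$resno)
  suppressWarnings(bio3d::write.pdb(
    file = path, type = a$record, eleno = a$atom_id, elety = a$atom_name,
    resid = a$resname, chain = a$chain, resno = resno_num,
    insert = ifelse(insert == "", NA, insert),
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    elesy = a$element))
  invisible(path)
}

#' Superpose one structure onto another (Kabsch)
#'
#' Least-squares rigid-body superposition over matched atoms. The default
#' correspondence is C-alpha atoms of residues shared by chain and residue
#' number, which is robust to apo/holo side-chain differences.
#'
#' @param mobile,reference [structure3d] objects.
#' @param selection atom-matching rule: `"calpha"` (default) or `"heavy"`
#'   (all heavy atoms matched by chain, residue and atom name).
#' @return A `superposition` object: `rotation` (3x3 proper rotation),
#'   `translation` (Angstrom triple), post-fit `rmsd`, `n_atoms_used`.
#' @export
superpose <- function(mobile, reference, selection = c("calpha", "heavy")) {
  selection <- match.arg(selection)
  key_cols <- function(a) {
    if (selection == "calpha") {
      a <- a[a$record == "ATOM" & a$atom_name == "CA" & a$is_heavy, ,
             drop = FALSE]
      a$key <- paste(a$chain, a$resno)
    } else {
      a <- a[a$record == "ATOM" & a$is_heavy, , drop = FALSE]
      a$key <- paste(a$chain, a$resno, a$atom_name)
    }
    a[!duplicated(a$key), , drop = FALSE]
  }
  am <- key_cols(mobile$atoms); ar <- key_cols(reference$atoms)
  shared <- intersect(am$key, ar$key)
  if (length(shared) < 3L)
    stop_cryptohot(sprintf("only %d matched atom pairs (need >= 3)",
                           length(shared)), "cryptohot_correspondence_error")
  P <- as.matrix(am[match(shared, am$key), c("x", "y", "z")])
  Q <- as.matrix(ar[match(shared, ar$key), c("x", "y", "z")])
  res <- kabsch(P, Q)
  structure(res, class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d atoms, rmsd %.4f A\n", x$n_atoms_used, x$rmsd))
  invisible(x)
}

#' Transfer a ligand from the holo structure into the apo frame
#'
#' Extracts the heavy atoms of a HETATM residue from the holo structure and
#' applies the holo-to-apo superposition transform, yielding the ligand pose
#' used for clash-based cryptic-site definition.
#'
#' @param holo [structure3d] containing the ligand as HETATM records.
#' @param ligand_resname residue name of the ligand.
#' @param transform a `superposition` (holo as mobile, apo as reference), or
#'   `NULL` for identity.
#' @return A `ligand_pose`: atom table (name, element, coords) plus source id.
#' @export
transfer_ligand <- function(holo, ligand_resname, transform = NULL) {
  a <- holo$atoms
  lig <- a[a$record == "HETATM" & a$resname == ligand_resname & a$is_heavy, ,
           drop = FALSE]
  if (nrow(lig) == 0L)
    stop_cryptohot(sprintf("ligand resname '%s' not found in HETATM records",
                           ligand_resname), "cryptohot_notfound_error")
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  if (!is.null(transform))
    xyz <- apply_rigid(xyz, transform$rotation, transform$translation)
  structure(list(
    atoms = data.frame(atom_name = lig$atom_name, element = lig$element,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    resname = ligand_resname, source_structure = holo$id),
    class = "ligand_pose")
}

#' Detect apo residues in steric clash with a superposed ligand
#'
#' A residue is flagged iff any of its heavy atoms lies strictly closer than
#' `cutoff` to any ligand heavy atom (Euclidean distance, heavy atoms only).
#' The flagged residues define the cryptic site of the apo structure.
#'
#' @param apo [structure3d] in whose frame the ligand pose is expressed.
#' @param ligand a `ligand_pose` from [transfer_ligand()].
#' @param cutoff clash distance in Angstrom (default 2.5).
#' @return A `cryptic_site`: `clash_residues` data.frame (chain, resno,
#'   resname), the ligand pose, and the cutoff used.
#' @export
detect_clashes <- function(apo, ligand, cutoff = 2.5) {
  if (cutoff <= 0) stop_cryptohot("cutoff must be > 0", "cryptohot_argument_error")
  lig_xyz <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  if (nrow(lig_xyz) == 0L)
    stop_cryptohot("ligand has no heavy atoms", "cryptohot_invalid_ligand_error")
  a <- apo$atoms[apo$atoms$record == "ATOM" & apo$atoms$is_heavy, , drop = FALSE]
  dmin <- cross_mindist(cbind(a$x, a$y, a$z), lig_xyz)
  hit <- dmin < cutoff
  res <- unique(a[hit, c("chain", "resno", "resname")])
  rownames(res) <- NULL
  structure(list(clash_residues = res, ligand = ligand, clash_cutoff = cutoff),
            class = "cryptic_site")
}

#' @export
print.cryptic_site <- function(x, ...) {
  cat(sprintf("cryptic_site: %d clashing residue(s) at < %.2f A\n",
              nrow(x$clash_residues), x$clash_cutoff))
  if (nrow(x$clash_residues))
    cat(paste0("  ", x$clash_residues$resname, x$clash_residues$resno,
               " (chain ", x$clash_residues$chain, ")", collapse = "\n"), "\n")
  invisible(x)
}
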