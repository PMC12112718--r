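# Per-hotspot feature extraction: surface-patch definition, geometric and
# physicochemical patch descriptors (trajectory-averaged where they depend on
# coordinates), per-residue flexibility (RMSF), and probe-derived hotspot
# features (GFE, probe-molecule counts).

# Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5,
                    MET = 1.9, ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
                    TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2,
                    GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
                    LYS = -3.9, ARG = -4.5)

#' Surface-patch parameters
#'
#' @param patch_cutoff residues with a heavy atom within this distance of a
#'   hotspot voxel center belong to the patch (default 4.5 A, inclusive).
#' @param protrusion_inner,protrusion_outer neighbour-counting shell
#'   (half-open, default (8, 12] A around the residue centroid).
#' @param protrusion_neighbor_max a residue protrudes if its shell count is
#'   strictly below this (default 120 atoms).
#' @param frame_stride use every k-th trajectory frame for averaged features.
#' @return A `patch_params` list.
#' @export
patch_params <- function(patch_cutoff = 4.5, protrusion_inner = 8,
                         protrusion_outer = 12, protrusion_neighbor_max = 120L,
                         frame_stride = 1L) {
  stopifnot(patch_cutoff > 0, protrusion_inner > 0,
            protrusion_outer > protrusion_inner, frame_stride >= 1)
  structure(list(patch_cutoff = patch_cutoff,
                 protrusion_inner = protrusion_inner,
                 protrusion_outer = protrusion_outer,
                 protrusion_neighbor_max = as.integer(protrusion_neighbor_max),
                 frame_stride = as.integer(frame_stride)),
            class = "patch_params")
}

#' Define the protein surface patch near a hotspot
#'
#' A residue belongs to the patch iff any of its heavy atoms lies within
#' `patch_cutoff` of any hotspot voxel center.
#'
#' @param h a `hotspot`.
#' @param s the protein [structure3d].
#' @param params [patch_params()].
#' @return A `surface_patch`: data.frame of (chain, resno) plus hotspot id.
#' @export
define_patch <- function(h, s, params = patch_params()) {
  centers <- as.matrix(h$voxels[, c("x", "y", "z")])
  a <- s$atoms[s$atoms$record == "ATOM" & s$atoms$is_heavy, , drop = FALSE]
  dmin <- cross_mindist(cbind(a$x, a$y, a$z), centers)
  hit <- dmin <= params$patch_cutoff
  res <- unique(a[hit, c("chain", "resno")])
  rownames(res) <- NULL
  if (nrow(res) == 0L)
    warning(sprintf("hotspot %s: empty surface patch", h$id))
  structure(list(residues = res, hotspot_id = h$id), class = "surface_patch")
}

patch_atom_rows <- function(patch, s) {
  a <- s$atoms[s$atoms$record == "ATOM" & s$atoms$is_heavy, , drop = FALSE]
  a[paste(a$chain, a$resno) %in%
      paste(patch$residues$chain, patch$residues$resno), , drop = FALSE]
}

# Frames: list of n_atoms x 3 matrices matching rows of s$atoms, or NULL for
# the static structure. Applies the stride, always keeping the first frame.
stride_frames <- function(frames, stride) {
  if (is.null(frames)) return(NULL)
  frames[seq(1, length(frames), by = stride)]
}

structure_with_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Patch accessible surface area (size), trajectory-averaged
#'
#' Shrake-Rupley SASA (probe radius 1.4 A) of the whole protein, summed over
#' the patch residues' atoms, averaged over frames sampled at the stride.
#'
#' @param patch a `surface_patch`.
#' @param s the protein [structure3d].
#' @param frames optional list of full-structure coordinate matrices
#'   (n_atoms x 3, matching `s$atoms` rows); `NULL` uses the static structure.
#' @param params [patch_params()].
#' @return SASA in Angstrom^2.
#' @export
compute_size <- function(patch, s, frames = NULL, params = patch_params()) {
  if (nrow(patch$residues) == 0L) return(0)
  frames <- stride_frames(frames, params$frame_stride)
  one <- function(st) {
    a <- st$atoms[st$atoms$record == "ATOM" & st$atoms$is_heavy, , drop = FALSE]
    sasa <- sasa_atoms(cbind(a$x, a$y, a$z), a$element)
    inpatch <- paste(a$chain, a$resno) %in%
      paste(patch$residues$chain, patch$residues$resno)
    sum(sasa[inpatch])
  }
  if (is.null(frames)) return(one(s))
  mean(vapply(frames, function(f) one(structure_with_coords(s, f)), 1))
}

#' Patch compactness
#'
#' Mean over unordered residue pairs of the minimum heavy-atom distance
#' between the two residues; smaller values mean tighter packing.
#'
#' @inheritParams compute_size
#' @return distance in Angstrom; 0 for patches with fewer than 2 residues.
#' @export
compute_compactness <- function(patch, s) {
  res <- patch$residues
  if (nrow(res) < 2L) return(0)
  a <- patch_atom_rows(patch, s)
  key <- paste(a$chain, a$resno)
  split_xyz <- lapply(split(seq_len(nrow(a)), key),
                      function(i) cbind(a$x[i], a$y[i], a$z[i]))
  ids <- names(split_xyz)
  tot <- 0; np <- 0L
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1L):length(ids)) {
    tot <- tot + min(dist_matrix(split_xyz[[i]], split_xyz[[j]]))
    np <- np + 1L
  }
  tot / np
}

#' Patch protrusion
#'
#' Fraction of patch residues whose centroid has strictly fewer than
#' `protrusion_neighbor_max` protein heavy atoms in the (inner, outer]
#' distance shell. Exposed, protruding residues have sparse shells.
#'
#' @inheritParams compute_size
#' @return fraction in [0, 1].
#' @export
compute_protrusion <- function(patch, s, params = patch_params()) {
  res <- patch$residues
  if (nrow(res) == 0L) return(0)
  all_atoms <- s$atoms[s$atoms$record == "ATOM" & s$atoms$is_heavy, , drop = FALSE]
  A <- cbind(all_atoms$x, all_atoms$y, all_atoms$z)
  prot <- vapply(seq_len(nrow(res)), function(i) {
    ra <- all_atoms[all_atoms$chain == res$chain[i] &
                      all_atoms$resno == res$resno[i], , drop = FALSE]
    cen <- colMeans(cbind(ra$x, ra$y, ra$z))
    d <- sqrt(colSums((t(A) - cen)^2))
    cnt <- sum(d > params$protrusion_inner & d <= params$protrusion_outer)
    cnt < params$protrusion_neighbor_max
  }, TRUE)
  mean(prot)
}

#' Patch convexity
#'
#' For each pair of adjacent patch residues (centroid distance below
#' `adjacency_cutoff`), the ratio of the distance between their closest
#' solvent-exposed heavy atoms to the centroid distance; the feature is the
#' mean ratio. Convex (outward-curved) patches give smaller ratios than
#' concave pockets, whose surface path between residues detours around the
#' cavity rim.
#'
#' @inheritParams compute_size
#' @param adjacency_cutoff centroid distance defining neighbouring residues
#'   (default 8 A).
#' @param exposure_min per-atom SASA (Angstrom^2) above which an atom counts
#'   as solvent-exposed.
#' @return mean ratio; 0 (imputed) when no adjacent pair exists.
#' @export
compute_convexity <- function(patch, s, adjacency_cutoff = 8,
                              exposure_min = 0.1) {
  res <- patch$residues
  if (nrow(res) < 2L) return(0)
  a <- s$atoms[s$atoms$record == "ATOM" & s$atoms$is_heavy, , drop = FALSE]
  sasa <- sasa_atoms(cbind(a$x, a$y, a$z), a$element)
  key <- paste(a$chain, a$resno)
  ratios <- c()
  rkeys <- paste(res$chain, res$resno)
  cents <- t(vapply(rkeys, function(k) {
    i <- key == k
    colMeans(cbind(a$x[i], a$y[i], a$z[i]))
  }, numeric(3)))
  for (i in seq_along(rkeys)[-length(rkeys)]) for (j in (i + 1L):length(rkeys)) {
    cd <- sqrt(sum((cents[i, ] - cents[j, ])^2))
    if (cd >= adjacency_cutoff || cd == 0) next
    ei <- key == rkeys[i] & sasa > exposure_min
    ej <- key == rkeys[j] & sasa > exposure_min
    if (!any(ei) || !any(ej)) next
    sd_ <- min(dist_matrix(cbind(a$x[ei], a$y[ei], a$z[ei]),
                           cbind(a$x[ej], a$y[ej], a$z[ej])))
    ratios <- c(ratios, sd_ / cd)
  }
  if (!length(ratios)) {
    warning(sprintf("hotspot %s: no adjacent residue pairs for convexity",
                    patch$hotspot_id))
    return(0)
  }
  mean(ratios)
}

#' Patch hydrophobicity
#'
#' Mean Kyte-Doolittle hydropathy over the patch residues (composition-based,
#' trajectory-independent).
#'
#' @inheritParams compute_size
#' @return mean hydropathy in Kyte-Doolittle units.
#' @export
compute_hydrophobicity <- function(patch, s) {
  a <- patch_atom_rows(patch, s)
  res <- unique(a[, c("chain", "resno", "resname")])
  vals <- KYTE_DOOLITTLE[res$resname]
  if (any(is.na(vals))) {
    warning(sprintf("unknown residue name(s): %s",
                    paste(unique(res$resname[is.na(vals)]), collapse = ",")))
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) return(0)
  mean(vals)
}

#' Patch charge density
#'
#' Net formal charge (+1 Arg/Lys, -1 Asp/Glu, His neutral) divided by the
#' (trajectory-averaged) patch accessible surface area.
#'
#' @inheritParams compute_size
#' @param size patch SASA in Angstrom^2, from [compute_size()].
#' @return charge density in e/Angstrom^2; 0 (imputed) when size is 0.
#' @export
compute_charge_density <- function(patch, s, size) {
  if (size <= 0) {
    warning("zero patch size: charge density imputed as 0")
    return(0)
  }
  a <- patch_atom_rows(patch, s)
  res <- unique(a[, c("chain", "resno", "resname")])
  q <- sum(res$resname %in% c("ARG", "LYS")) - sum(res$resname %in% c("ASP", "GLU"))
  q / size
}

#' Per-patch residue flexibility (RMSF)
#'
#' Two-pass C-alpha RMSF: frames are aligned to the reference, the mean
#' structure is computed, frames are re-aligned to that mean, and the
#' per-residue fluctuation is the root mean square deviation from the mean
#' position. The feature is the mean RMSF over the patch residues.
#'
#' @param patch a `surface_patch`.
#' @param s the protein [structure3d] (reference for the first alignment).
#' @param frames list of full-structure coordinate matrices matching
#'   `s$atoms` rows.
#' @return mean RMSF over patch residues, in Angstrom.
#' @export
compute_rmsf <- function(patch, s, frames) {
  if (length(frames) < 2L)
    stop_cryptohot("RMSF needs at least 2 frames", "cryptohot_argument_error")
  ca_idx <- which(s$atoms$record == "ATOM" & s$atoms$atom_name == "CA" &
                    s$atoms$is_heavy)
  ref <- as.matrix(s$atoms[ca_idx, c("x", "y", "z")])
  ca_frames <- lapply(frames, function(f) rbind(f)[ca_idx, , drop = FALSE])
  pass <- function(target) lapply(ca_frames, function(fr) {
    fit <- kabsch(fr, target)
    apply_rigid(fr, fit$rotation, fit$translation)
  })
  aligned <- pass(ref)
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  aligned <- pass(mean_xyz)
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  dev2 <- Reduce(`+`, lapply(aligned, function(fr) rowSums((fr - mean_xyz)^2))) /
    length(aligned)
  rmsf <- sqrt(dev2)
  keys <- paste(s$atoms$chain[ca_idx], s$atoms$resno[ca_idx])
  sel <- keys %in% paste(patch$residues$chain, patch$residues$resno)
  if (!any(sel)) return(0)
  mean(rmsf[sel])
}

#' Probe-derived hotspot features: GFE and probe-molecule count
#'
#' GFE is aggregated over the hotspot voxels of the probe's GFE grid (mean by
#' default, minimum by option). The probe count is the frame-averaged number
#' of distinct probe molecules with at least one heavy atom inside the
#' hotspot voxel set.
#'
#' @param h a `hotspot`.
#' @param grid the probe's normalized `voxel_grid` (defines the lattice).
#' @param gfe the probe's `gfe_grid`.
#' @param bundle the probe's [trajectory_bundle()].
#' @param gfe_aggregate `"mean"` (default) or `"min"`.
#' @return list with `gfe` (kcal/mol) and `probe_count` (molecules/frame).
#' @export
hotspot_probe_features <- function(h, grid, gfe, bundle,
                                   gfe_aggregate = c("mean", "min")) {
  gfe_aggregate <- match.arg(gfe_aggregate)
  if (!identical(grid$shape, gfe$shape))
    stop_cryptohot("grid and gfe_grid lattices differ", "cryptohot_lattice_error")
  lin <- h$voxels$linear
  gvals <- as.vector(gfe$gfe)[lin]
  gfe_val <- if (gfe_aggregate == "mean") mean(gvals) else min(gvals)
  vox_set <- rep(FALSE, prod(grid$shape))
  vox_set[lin] <- TRUE
  total <- 0; nf <- 0L
  for (run in bundle$runs) {
    for (f in seq_len(dim(run$probe_xyz)[1])) {
      pxyz <- run$probe_xyz[f, , , drop = TRUE]
      if (is.null(dim(pxyz))) pxyz <- matrix(pxyz, ncol = 3)
      b <- bin_points(grid, pxyz)
      inside <- b$in_bounds & vox_set[ifelse(is.na(b$linear), 1L, b$linear)]
      total <- total + length(unique(run$molecule_id[inside]))
      nf <- nf + 1L
    }
  }
  list(gfe = gfe_val, probe_count = total / nf)
}

#' Assemble per-hotspot feature rows into a feature table
#'
#' @param rows list of named lists/one-row data.frames with identical names;
#'   must include `hotspot_id` and `protein_id`.
#' @param impute named list of values used to fill `NA` entries (defaults:
#'   gfe columns to `gfe_cap`, everything else to 0).
#' @param gfe_cap cap used for missing per-probe GFE values (default +3).
#' @return data.frame with stable column order.
#' @export
assemble_features <- function(rows, impute = NULL, gfe_cap = 3) {
  stopifnot(length(rows) >= 1L)
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (anyDuplicated(paste(tab$protein_id, tab$hotspot_id)))
    stop_cryptohot("duplicate (protein_id, hotspot_id)", "cryptohot_argument_error")
  num_cols <- names(tab)[vapply(tab, is.numeric, TRUE)]
  for (cn in num_cols) {
    na <- is.na(tab[[cn]])
    if (!any(na)) next
    fill <- if (!is.null(impute[[cn]])) impute[[cn]]
            else if (grepl("^(water_)?gfe_", cn)) gfe_cap else 0
    tab[[cn]][na] <- fill
  }
  id_cols <- intersect(c("protein_id", "hotspot_id", "label"), names(tab))
  tab[, c(id_cols, sort(setdiff(names(tab), id_cols))), drop = FALSE]
}
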