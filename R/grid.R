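# Probe-density voxel grids. Probe heavy-atom positions from MSMD frames are
# binned on a protein-fixed 1 A lattice, normalized per probe molecule size,
# and optionally converted to grid free energies relative to bulk.

BOLTZMANN_KCAL <- 0.0019872041  # kcal/mol/K

STANDARD_PROBES <- data.frame(
  name = c("benzene", "dimethyl-ether", "phenol", "methyl-imidazole",
           "acetonitrile", "ethylene-glycol"),
  n_heavy_atoms = c(6L, 3L, 7L, 6L, 3L, 4L),
  stringsAsFactors = FALSE)

#' Describe a cosolvent probe molecule
#'
#' The six standard probes carry their heavy-atom counts; user-defined probes
#' must state `n_heavy_atoms`. The heavy-atom count is the per-molecule
#' normalisation constant for occupancy grids.
#'
#' @param name probe name; one of the six standard probes or user-defined.
#' @param n_heavy_atoms heavy atoms per probe molecule (looked up for
#'   standard probes when omitted).
#' @return A `probe_spec` object.
#' @export
probe_spec <- function(name, n_heavy_atoms = NULL) {
  if (is.null(n_heavy_atoms)) {
    i <- match(name, STANDARD_PROBES$name)
    if (is.na(i))
      stop_cryptohot(sprintf("unknown probe '%s': give n_heavy_atoms", name),
                     "cryptohot_argument_error")
    n_heavy_atoms <- STANDARD_PROBES$n_heavy_atoms[i]
  }
  if (n_heavy_atoms < 1L)
    stop_cryptohot("n_heavy_atoms must be >= 1", "cryptohot_argument_error")
  structure(list(name = name, n_heavy_atoms = as.integer(n_heavy_atoms)),
            class = "probe_spec")
}

#' Bundle probe trajectory frames for one probe
#'
#' Frames are given as runs; each run holds an array of probe heavy-atom
#' coordinates, a molecule id per probe atom, and (optionally) protein
#' heavy-atom coordinates per frame for alignment.
#'
#' @param probe a [probe_spec].
#' @param runs list of runs; each run is a list with `probe_xyz`
#'   (frames x atoms x 3 array), `molecule_id` (integer per atom) and
#'   optionally `protein_xyz` (frames x atoms x 3 array).
#' @param reference [structure3d] defining the protein-fixed frame.
#' @return A `trajectory_bundle`.
#' @export
trajectory_bundle <- function(probe, runs, reference) {
  stopifnot(inherits(probe, "probe_spec"), length(runs) >= 1L)
  n_atoms <- dim(runs[[1]]$probe_xyz)[2]
  for (r in runs) {
    if (length(dim(r$probe_xyz)) != 3L || dim(r$probe_xyz)[3] != 3L)
      stop_cryptohot("probe_xyz must be frames x atoms x 3",
                     "cryptohot_trajectory_error")
    if (dim(r$probe_xyz)[2] != n_atoms)
      stop_cryptohot("mismatched probe atom counts across runs",
                     "cryptohot_trajectory_error")
  }
  n_frames <- sum(vapply(runs, function(r) dim(r$probe_xyz)[1], 1L))
  structure(list(probe = probe, runs = runs, reference = reference,
                 n_frames_total = n_frames),
            class = "trajectory_bundle")
}

#' Build an empty occupancy grid over a reference structure
#'
#' Axis-aligned box covering the protein heavy atoms plus padding, with the
#' origin (minimum corner) snapped down to the spacing lattice. Voxels are
#' half-open intervals per axis, so no atom is double counted.
#'
#' @param reference [structure3d] whose heavy atoms define the box.
#' @param padding Angstrom added on every side (default 8).
#' @param spacing voxel edge length in Angstrom (default 1).
#' @param probe optional [probe_spec] attached to the grid.
#' @return A `voxel_grid` with zero counts.
#' @export
build_grid <- function(reference, padding = 8, spacing = 1, probe = NULL) {
  if (padding < 0) stop_cryptohot("padding must be >= 0", "cryptohot_argument_error")
  if (spacing <= 0) stop_cryptohot("spacing must be > 0", "cryptohot_argument_error")
  xyz <- xyz_of(reference)
  if (nrow(xyz) == 0L)
    stop_cryptohot("reference structure has no heavy atoms",
                   "cryptohot_empty_error")
  mn <- unname(apply(xyz, 2, min)) - padding
  mx <- unname(apply(xyz, 2, max)) + padding
  origin <- floor(mn / spacing) * spacing
  shape <- as.integer(floor((mx - origin) / spacing)) + 1L
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 raw_counts = array(0, dim = shape), occupancy = NULL,
                 probe = probe, n_frames = 0L, spill = 0,
                 ref_xyz = xyz),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %dx%dx%d, spacing %.2f A, origin (%.1f, %.1f, %.1f), %d frame(s)%s\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3], x$n_frames,
              if (is.null(x$occupancy)) "" else ", normalized"))
  invisible(x)
}

grid_lattice_signature <- function(grid) {
  paste(c(sprintf("%.6f", grid$origin), sprintf("%.6f", grid$spacing),
          grid$shape), collapse = "/")
}

# Voxel centers for 0-based index triples (matrix ix,iy,iz).
voxel_centers <- function(grid, ijk) {
  sweep(ijk * grid$spacing, 2, grid$origin + grid$spacing / 2, "+")
}

# Bin row coordinates; returns list(linear 1-based index or NA, ijk matrix).
bin_points <- function(grid, xyz) {
  ijk <- floor(sweep(rbind(xyz), 2, grid$origin) / grid$spacing)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
        ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
        ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
  lin <- rep(NA_integer_, nrow(ijk))
  lin[ok] <- 1L + ijk[ok, 1] + grid$shape[1] * (ijk[ok, 2] + grid$shape[2] * ijk[ok, 3])
  list(linear = lin, ijk = ijk, in_bounds = ok)
}

#' Accumulate probe heavy-atom counts into a grid
#'
#' Pools all runs and frames of a bundle. Frames must be expressed in the
#' protein-fixed frame; with `align = TRUE` each frame's protein coordinates
#' are rigid-body superposed (Kabsch, all protein atoms in the run arrays)
#' onto the bundle's reference before the probe atoms are binned. Atoms that
#' fall outside the box are ignored but counted in the `spill` statistic.
#'
#' @param bundle a [trajectory_bundle].
#' @param grid a `voxel_grid` from [build_grid()].
#' @param align superpose each frame's protein onto the reference first.
#' @return The grid with updated `raw_counts`, `n_frames`, `spill`.
#' @export
accumulate_occupancy <- function(bundle, grid, align = FALSE) {
  stopifnot(inherits(bundle, "trajectory_bundle"), inherits(grid, "voxel_grid"))
  n_vox <- prod(grid$shape)
  counts <- as.vector(grid$raw_counts)
  spill <- grid$spill
  ref_xyz <- if (align) xyz_of(bundle$reference) else NULL
  for (run in bundle$runs) {
    nf <- dim(run$probe_xyz)[1]
    for (f in seq_len(nf)) {
      pxyz <- run$probe_xyz[f, , , drop = TRUE]
      if (is.null(dim(pxyz))) pxyz <- matrix(pxyz, ncol = 3)
      if (align) {
        if (is.null(run$protein_xyz))
          stop_cryptohot("align=TRUE requires protein_xyz in each run",
                         "cryptohot_trajectory_error")
        prot <- run$protein_xyz[f, , , drop = TRUE]
        if (is.null(dim(prot))) prot <- matrix(prot, ncol = 3)
        if (nrow(prot) != nrow(ref_xyz))
          stop_cryptohot("frame protein atom count differs from reference",
                         "cryptohot_trajectory_error")
        fit <- kabsch(prot, ref_xyz)
        pxyz <- apply_rigid(pxyz, fit$rotation, fit$translation)
      }
      b <- bin_points(grid, pxyz)
      spill <- spill + sum(!b$in_bounds)
      if (any(b$in_bounds))
        counts <- counts + tabulate(b$linear[b$in_bounds], nbins = n_vox)
    }
  }
  grid$raw_counts <- array(counts, dim = grid$shape)
  grid$n_frames <- grid$n_frames + bundle$n_frames_total
  grid$spill <- spill
  grid$probe <- grid$probe %||% bundle$probe
  grid
}

#' Normalize raw voxel counts to per-probe occupancy
#'
#' Occupancy is the raw count divided by the number of frames times the
#' heavy-atom count of the probe molecule, so probes of different sizes are
#' comparable on one scale.
#'
#' @param grid accumulated `voxel_grid` with an attached probe.
#' @return The grid with `occupancy` filled in.
#' @export
normalize_occupancy <- function(grid) {
  if (grid$n_frames == 0L)
    stop_cryptohot("cannot normalize a grid with 0 frames",
                   "cryptohot_division_error")
  if (is.null(grid$probe))
    stop_cryptohot("grid has no probe_spec attached", "cryptohot_argument_error")
  grid$occupancy <- grid$raw_counts / (grid$n_frames * grid$probe$n_heavy_atoms)
  grid
}

#' Convert occupancy to grid free energy (GFE)
#'
#' GFE per voxel is -kT log(occupancy / bulk), clipped above at `cap`;
#' empty voxels take the cap value. The default bulk occupancy is the mean
#' occupancy over solvent voxels, i.e. voxels whose centers lie more than
#' `solvent_distance` from any protein heavy atom.
#'
#' @param grid normalized `voxel_grid`.
#' @param temperature Kelvin (default 300).
#' @param bulk_occupancy reference occupancy; `NULL` for the solvent-voxel mean.
#' @param cap upper clip in kcal/mol (default +3), also the empty-voxel value.
#' @param solvent_distance Angstrom defining "far from protein" (default 5).
#' @return A `gfe_grid` on the same lattice.
#' @export
compute_gfe <- function(grid, temperature = 300, bulk_occupancy = NULL,
                        cap = 3, solvent_distance = 5) {
  if (is.null(grid$occupancy))
    stop_cryptohot("grid is not normalized", "cryptohot_argument_error")
  if (is.null(bulk_occupancy)) {
    ijk <- as.matrix(expand.grid(ix = 0:(grid$shape[1] - 1L),
                                 iy = 0:(grid$shape[2] - 1L),
                                 iz = 0:(grid$shape[3] - 1L)))
    centers <- voxel_centers(grid, ijk)
    dmin <- cross_mindist(centers, grid$ref_xyz)
    solvent <- dmin > solvent_distance
    if (!any(solvent))
      stop_cryptohot("no solvent voxels to define bulk occupancy",
                     "cryptohot_argument_error")
    # expand.grid varies ix fastest, matching R array linearisation
    bulk_occupancy <- mean(as.vector(grid$occupancy)[solvent])
  }
  if (!is.finite(bulk_occupancy) || bulk_occupancy <= 0)
    stop_cryptohot("bulk_occupancy must be > 0", "cryptohot_argument_error")
  occ <- grid$occupancy
  gfe <- array(cap, dim = grid$shape)
  pos <- occ > 0
  gfe[pos] <- pmin(-BOLTZMANN_KCAL * temperature * log(occ[pos] / bulk_occupancy),
                   cap)
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 shape = grid$shape, gfe = gfe, temperature = temperature,
                 bulk_occupancy = bulk_occupancy, gfe_cap = cap,
                 probe = grid$probe),
            class = "gfe_grid")
}

#' Write a scalar grid to an OpenDX file
#'
#' Serialises origin, spacing, shape and values (z varying fastest, the
#' OpenDX convention) as a `class gridpositions` scalar field.
#'
#' @param grid a `voxel_grid` (occupancy written if present, else raw counts)
#'   or `gfe_grid`.
#' @param path output path.
#' @param field which field of a voxel grid to write.
#' @export
write_dx <- function(grid, path, field = c("auto", "occupancy", "raw_counts", "gfe")) {
  field <- match.arg(field)
  vals <- switch(field,
    auto = if (inherits(grid, "gfe_grid")) grid$gfe
           else grid$occupancy %||% grid$raw_counts,
    occupancy = grid$occupancy, raw_counts = grid$raw_counts, gfe = grid$gfe)
  if (is.null(vals)) stop_cryptohot("requested field is empty", "cryptohot_argument_error")
  sh <- grid$shape
  # reorder so z varies fastest: index (ix, iy, iz) -> position with x slowest
  v <- aperm(vals, c(3, 2, 1))  # now dims (z, y, x); as.vector varies z fastest per (y,x)
  flat <- as.vector(v)          # z fastest, then y, then x: DX ordering
  n <- length(flat)
  pad <- (3 - n %% 3) %% 3
  flat_p <- c(flat, rep(NA_real_, pad))
  rows <- matrix(flat_p, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r)
    paste(sprintf("%.10g", r[!is.na(r)]), collapse = " "))
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  writeLines(c(hdr, data_lines,
               'attribute "dep" string "positions"',
               'object "density" class field'), path)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path a `.dx` file written by [write_dx()] or another tool using the
#'   standard gridpositions layout with uniform axis-aligned deltas.
#' @return A `voxel_grid` whose `occupancy` holds the values.
#' @export
read_dx <- function(path) {
  if (!file.exists(path))
    stop_cryptohot(paste("file not found:", path), "cryptohot_format_error")
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)
  if (!length(gp)) stop_cryptohot("malformed DX: no gridpositions object",
                                  "cryptohot_format_error")
  sh <- as.integer(strsplit(sub(".*counts", "", gp[1]), "\\s+")[[1]][-1])
  ol <- grep("^origin", lines, value = TRUE)
  if (!length(ol)) stop_cryptohot("malformed DX: no origin", "cryptohot_format_error")
  origin <- unname(as.numeric(strsplit(trimws(sub("origin", "", ol[1])),
                                       "\\s+")[[1]]))
  dl <- grep("^delta", lines, value = TRUE)
  if (length(dl) < 3) stop_cryptohot("malformed DX: missing deltas",
                                     "cryptohot_format_error")
  deltas <- t(vapply(dl[1:3], function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]]), numeric(3)))
  spacing <- unname(deltas[1, 1])
  start <- grep("data follows", lines)
  if (!length(start)) stop_cryptohot("malformed DX: no data section",
                                     "cryptohot_format_error")
  end <- grep("^(attribute|object\\s+\")", lines)
  end <- end[end > start[1]]
  data_lines <- lines[(start[1] + 1):(if (length(end)) min(end) - 1 else length(lines))]
  vals <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sh))
    stop_cryptohot("malformed DX: value count does not match shape",
                   "cryptohot_format_error")
  arr <- aperm(array(vals, dim = rev(sh)), c(3, 2, 1))  # undo z-fastest order
  structure(list(origin = origin, spacing = spacing, shape = sh,
                 raw_counts = NULL, occupancy = arr, probe = NULL,
                 n_frames = NA_integer_, spill = NA_real_, ref_xyz = NULL),
            class = "voxel_grid")
}
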