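# Synthetic-data generators. These create every input the pipeline needs
# without MD runs or downloads: toy poly-Ala proteins, probe trajectories
# with planted accumulation sites over a Poisson-uniform cosolvent
# background, apo/holo pairs with known clashing residues, and labelled
# Gaussian feature tables with controllable class separation.
#
# Every generator is a pure function of its seed.

#' Build a toy poly-alanine protein
#'
#' Backbone heavy atoms (N, CA, C, O, CB) on an ideal alpha-helix
#' (2.3 A radius, 1.5 A rise, 100 degrees per residue; consecutive CA-CA
#' distance about 3.8 A) or a cubic lattice.
#'
#' @param n_residues number of residues (>= 2).
#' @param geometry `"helix"` or `"lattice"`.
#' @param chain chain id.
#' @return A [structure3d].
#' @export
make_toy_protein <- function(n_residues, geometry = c("helix", "lattice"),
                             chain = "A") {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 2L)
  rows <- vector("list", n_residues)
  if (geometry == "helix") {
    radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
    for (i in seq_len(n_residues)) {
      th <- (i - 1L) * twist
      ca <- c(radius * cos(th), radius * sin(th), (i - 1L) * rise)
      radial <- c(cos(th), sin(th), 0)
      tang <- c(-sin(th), cos(th), 0)
      axis <- c(0, 0, 1)
      atoms <- rbind(
        N  = ca - 1.2 * tang - 0.8 * axis,
        CA = ca,
        C  = ca + 1.2 * tang + 0.7 * axis,
        O  = ca + 1.2 * tang + 1.3 * axis + 0.9 * radial,
        CB = ca + 1.5 * radial)
      rows[[i]] <- data.frame(
        atom_name = unname(rownames(atoms)),
        element = c("N", "C", "C", "O", "C"),
        resno = as.character(i), resname = "ALA", chain = chain,
        record = "ATOM", x = unname(atoms[, 1]), y = unname(atoms[, 2]), z = unname(atoms[, 3]),
        stringsAsFactors = FALSE)
    }
  } else {
    side <- ceiling(n_residues^(1 / 3))
    sp <- 6
    for (i in seq_len(n_residues)) {
      k <- i - 1L
      ca <- c(k %% side, (k %/% side) %% side, k %/% side^2) * sp
      atoms <- rbind(N = ca + c(-1.4, 0, 0), CA = ca, C = ca + c(1.4, 0.4, 0),
                     O = ca + c(2.2, 1.2, 0), CB = ca + c(0, 1.5, 0.6))
      rows[[i]] <- data.frame(
        atom_name = unname(rownames(atoms)),
        element = c("N", "C", "C", "O", "C"),
        resno = as.character(i), resname = "ALA", chain = chain,
        record = "ATOM", x = unname(atoms[, 1]), y = unname(atoms[, 2]), z = unname(atoms[, 3]),
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure3d(atoms, id = sprintf("toy_%s_%d", geometry, n_residues))
}

#' Jittered multi-frame trajectory of a structure
#'
#' Independent Gaussian displacement of every atom in every frame; frame 1
#' onward all share the same base coordinates, so after alignment the
#' per-atom RMSF approaches `jitter_sd * sqrt(3)` (3-D isotropic noise).
#'
#' @param s a [structure3d].
#' @param n_frames number of frames.
#' @param jitter_sd per-axis displacement standard deviation in Angstrom.
#' @param seed RNG seed.
#' @return list of n_atoms x 3 coordinate matrices.
#' @export
make_toy_trajectory <- function(s, n_frames, jitter_sd = 0.3, seed = 1L) {
  set.seed(seed)
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  lapply(seq_len(n_frames), function(f)
    base + matrix(rnorm(length(base), sd = jitter_sd), ncol = 3))
}

#' Define a synthetic probe-accumulation scenario
#'
#' @param protein toy protein [structure3d] (alignment reference).
#' @param sites list of planted sites, each
#'   `list(center = c(x,y,z), intensity = <expected probe heavy atoms/frame>,
#'   spread = <Gaussian sd, A>)`.
#' @param background_rate expected background probe heavy atoms per
#'   Angstrom^3 per frame (Poisson-uniform dilute-cosolvent model).
#' @param n_frames frames to generate.
#' @param probe a [probe_spec()].
#' @param padding box padding passed to [build_grid()].
#' @param seed RNG seed.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(protein, sites, background_rate = 2e-5,
                               n_frames = 100L, probe = probe_spec("benzene"),
                               padding = 8, seed = 1L) {
  structure(list(protein = protein, sites = sites,
                 background_rate = background_rate,
                 n_frames = as.integer(n_frames), probe = probe,
                 padding = padding, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a probe trajectory with planted accumulation sites
#'
#' A fixed population of probe molecules is placed every frame: site
#' molecules are drawn around their planted center (molecule center
#' Gaussian with the site spread; atoms tightly clustered around the
#' molecule center), background molecules uniform in the grid box. The
#' expected number of molecules at a site is `intensity / n_heavy_atoms`,
#' and the background population matches `background_rate x box volume`.
#' Atom counts are identical in every frame.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [trajectory_bundle()] (single run) with static protein frames.
#' @export
plant_probe_trajectory <- function(scenario) {
  set.seed(scenario$seed)
  probe <- scenario$probe
  grid <- build_grid(scenario$protein, padding = scenario$padding)
  lo <- grid$origin
  hi <- grid$origin + grid$shape * grid$spacing
  vol <- prod(hi - lo)
  n_bg <- as.integer(round(scenario$background_rate * vol / probe$n_heavy_atoms))
  n_site <- vapply(scenario$sites, function(s)
    max(1L, as.integer(round(s$intensity / probe$n_heavy_atoms))), 1L)
  for (s in scenario$sites) {
    if (any(s$center < lo) || any(s$center > hi))
      stop_cryptohot("planted site lies outside the grid box",
                     "cryptohot_argument_error")
  }
  n_mol <- n_bg + sum(n_site)
  n_atoms <- n_mol * probe$n_heavy_atoms
  molecule_id <- rep(seq_len(n_mol), each = probe$n_heavy_atoms)
  site_of_mol <- rep(c(seq_along(scenario$sites), 0L), c(n_site, n_bg))
  probe_xyz <- array(NA_real_, dim = c(scenario$n_frames, n_atoms, 3))
  for (f in seq_len(scenario$n_frames)) {
    centers <- matrix(NA_real_, n_mol, 3)
    for (m in seq_len(n_mol)) {
      sid <- site_of_mol[m]
      centers[m, ] <- if (sid == 0L) runif(3, lo, hi)
      else scenario$sites[[sid]]$center +
        rnorm(3, sd = scenario$sites[[sid]]$spread)
    }
    atom_xyz <- centers[molecule_id, ] +
      matrix(rnorm(n_atoms * 3, sd = 0.3), ncol = 3)
    probe_xyz[f, , ] <- atom_xyz
  }
  prot <- as.matrix(scenario$protein$atoms[
    scenario$protein$atoms$is_heavy, c("x", "y", "z")])
  protein_xyz <- array(rep(t(prot), scenario$n_frames),
                       dim = c(3, nrow(prot), scenario$n_frames))
  protein_xyz <- aperm(protein_xyz, c(3, 2, 1))
  trajectory_bundle(probe,
                    list(list(probe_xyz = probe_xyz, molecule_id = molecule_id,
                              protein_xyz = protein_xyz)),
                    reference = scenario$protein)
}

# Rigid 5-atom cross ligand: center plus 4 arms of the given length.
toy_ligand_coords <- function(center, arm = 1.5, rotation = diag(3)) {
  base <- rbind(c(0, 0, 0), c(arm, 0, 0), c(-arm, 0, 0), c(0, arm, 0),
                c(0, -arm, 0))
  sweep(base %*% t(rotation), 2, center, "+")
}

#' Build an apo/holo pair with planted clashing residues
#'
#' The apo structure is a toy protein; a rigid 5-atom cross ligand is placed
#' (seeded random search) so that exactly the planted residues have heavy
#' atoms strictly within `cutoff` of ligand atoms. The holo structure is the
#' apo plus ligand under a random rigid transform, so superposition followed
#' by ligand transfer recovers the planted clash set.
#'
#' @param n_residues residues in the toy helix.
#' @param clash_resnos integer residue numbers that must clash (and no others).
#' @param cutoff clash distance (default 2.5 A).
#' @param seed RNG seed.
#' @param max_tries placement attempts before giving up.
#' @return list with `apo`, `holo` ([structure3d]s), `ligand_resname`, and
#'   the planted `clash_resnos`.
#' @export
make_clash_pair <- function(n_residues = 20L, clash_resnos = c(6L, 9L),
                            cutoff = 2.5, seed = 1L, max_tries = 2000L) {
  set.seed(seed)
  apo <- make_toy_protein(n_residues, "helix")
  a <- apo$atoms
  targets <- lapply(clash_resnos, function(r)
    as.matrix(a[a$resno == as.character(r) & a$atom_name == "CB",
                c("x", "y", "z")]))
  anchor <- colMeans(do.call(rbind, targets))
  axis_point <- c(0, 0, anchor[3])
  outward <- anchor - axis_point
  outward <- outward / sqrt(sum(outward^2))
  prot_xyz <- as.matrix(a[, c("x", "y", "z")])
  res_key <- a$resno
  placed <- NULL
  for (try in seq_len(max_tries)) {
    center <- anchor + outward * runif(1, 1.5, 4.0) +
      rnorm(3, sd = 0.8)
    lig <- toy_ligand_coords(center, arm = 1.5, rotation = random_rotation())
    dmin_per_atom <- cross_mindist(prot_xyz, lig)
    res_min <- tapply(dmin_per_atom, res_key, min)
    clashing <- names(res_min)[res_min < cutoff]
    if (setequal(clashing, as.character(clash_resnos)) &&
        all(res_min[as.character(clash_resnos)] < cutoff - 0.05) &&
        all(res_min[!(names(res_min) %in% as.character(clash_resnos))] >
              cutoff + 0.05)) {
      placed <- lig
      break
    }
  }
  if (is.null(placed))
    stop_cryptohot("could not place ligand to clash exactly the planted residues",
                   "cryptohot_placement_error")
  # holo = rigid transform of apo + ligand
  R <- random_rotation()
  tvec <- runif(3, -10, 10)
  holo_atoms <- a
  hxyz <- apply_rigid(prot_xyz, R, tvec)
  holo_atoms$x <- hxyz[, 1]; holo_atoms$y <- hxyz[, 2]; holo_atoms$z <- hxyz[, 3]
  lxyz <- apply_rigid(placed, R, tvec)
  lig_atoms <- data.frame(
    atom_id = max(a$atom_id) + seq_len(nrow(lxyz)),
    atom_name = c("C1", "C2", "C3", "C4", "C5"), element = "C",
    resno = "900", resname = "LIG", chain = "A", record = "HETATM",
    x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3], stringsAsFactors = FALSE)
  holo_atoms$is_heavy <- NULL
  holo <- structure3d(rbind(holo_atoms, lig_atoms), id = "toy_holo")
  list(apo = apo, holo = holo, ligand_resname = "LIG",
       clash_resnos = clash_resnos)
}

#' Synthetic androgen-receptor-like apo/holo worked example
#'
#' A fully synthetic stand-in emulating the clash geometry of the androgen
#' receptor ligand-binding domain: a two-helix bundle (residues 711-740,
#' chain A) with LYS720 on one helix and MET734/GLN738 on the facing helix,
#' and a rigid 5-atom ligand placed in the inter-helix groove so that exactly
#' those three residues have heavy atoms strictly within 2.5 A of ligand
#' heavy atoms. The holo structure is the apo plus ligand under a seeded
#' random rigid transform. No experimental coordinates are used.
#'
#' @param seed RNG seed for the holo transform.
#' @return list with `apo`, `holo`, `ligand_resname` and the planted
#'   `clash_residues` ("720", "734", "738").
#' @export
make_synthetic_ar_pair <- function(seed = 1L) {
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  mk_res <- function(resno, resname, axis_x, phase, z) {
    th <- phase
    axc <- c(axis_x, 0)
    ca <- c(axc[1] + radius * cos(th), axc[2] + radius * sin(th), z)
    radial <- c(cos(th), sin(th), 0)
    tang <- c(-sin(th), cos(th), 0)
    axis <- c(0, 0, 1)
    atoms <- rbind(N = ca - 1.2 * tang - 0.8 * axis, CA = ca,
                   C = ca + 1.2 * tang + 0.7 * axis,
                   O = ca + 1.2 * tang + 1.3 * axis + 0.9 * radial,
                   CB = ca + 1.5 * radial)
    data.frame(atom_name = unname(rownames(atoms)), element = c("N", "C", "C", "O", "C"),
               resno = as.character(resno), resname = unname(resname), chain = "A",
               record = "ATOM", x = unname(atoms[, 1]), y = unname(atoms[, 2]), z = unname(atoms[, 3]),
               stringsAsFactors = FALSE)
  }
  resnames <- stats::setNames(rep("ALA", 30), as.character(711:740))
  resnames["720"] <- "LYS"; resnames["734"] <- "MET"; resnames["738"] <- "GLN"
  rows <- list()
  # helix A: residues 711-725 around axis x = 0; phase puts 720's CB at +x
  for (i in 711:725)
    rows[[length(rows) + 1L]] <- mk_res(i, resnames[as.character(i)], 0,
                                        (i - 720) * twist, (i - 711) * rise)
  # helix B: residues 726-740 around axis x = 10; 734's CB faces helix A
  for (i in 726:740)
    rows[[length(rows) + 1L]] <- mk_res(i, resnames[as.character(i)], 10,
                                        pi + (i - 734) * twist,
                                        (i - 726) * rise + 2)
  atoms <- do.call(rbind, rows)
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  apo <- structure3d(atoms, id = "synthetic_ar_apo")

  # ligand: one atom 2.2 A outside each target CB (along its radial
  # direction), plus midpoint linker atoms
  cb_of <- function(r) unlist(atoms[atoms$resno == r & atoms$atom_name == "CB",
                                    c("x", "y", "z")])
  rad_of <- function(r, axis_x) {
    cb <- cb_of(r)
    v <- c(cb[1] - axis_x, cb[2], 0)
    v / sqrt(sum(v^2))
  }
  a1 <- cb_of("720") + 2.2 * rad_of("720", 0)
  a2 <- cb_of("734") + 2.2 * rad_of("734", 10)
  a3 <- cb_of("738") + 2.2 * rad_of("738", 10)
  lig <- rbind(a1, (a1 + a2) / 2, a2, (a2 + a3) / 2, a3)
  ligand_pose <- structure(list(
    atoms = data.frame(atom_name = paste0("C", 1:5), element = "C",
                       x = lig[, 1], y = lig[, 2], z = lig[, 3],
                       stringsAsFactors = FALSE),
    resname = "LIG", source_structure = "synthetic_ar_holo"),
    class = "ligand_pose")
  site <- detect_clashes(apo, ligand_pose, cutoff = 2.5)
  if (!setequal(site$clash_residues$resno, c("720", "734", "738")))
    stop_cryptohot("synthetic AR pair construction failed verification",
                   "cryptohot_placement_error")

  set.seed(seed)
  R <- random_rotation(); tvec <- runif(3, -10, 10)
  pxyz <- apply_rigid(as.matrix(atoms[, c("x", "y", "z")]), R, tvec)
  holo_atoms <- atoms
  holo_atoms$x <- pxyz[, 1]; holo_atoms$y <- pxyz[, 2]; holo_atoms$z <- pxyz[, 3]
  lxyz <- apply_rigid(lig, R, tvec)
  lig_atoms <- data.frame(atom_id = max(atoms$atom_id) + 1:5,
                          atom_name = paste0("C", 1:5), element = "C",
                          resno = "900", resname = "LIG", chain = "A",
                          record = "HETATM", x = lxyz[, 1], y = lxyz[, 2],
                          z = lxyz[, 3], stringsAsFactors = FALSE)
  holo <- structure3d(rbind(holo_atoms, lig_atoms), id = "synthetic_ar_holo")
  list(apo = apo, holo = holo, ligand_resname = "LIG",
       clash_residues = c("720", "734", "738"))
}

#' Generate a labelled Gaussian feature table
#'
#' Negatives are drawn from a spherical standard Gaussian; positives are
#' shifted by `delta` in every feature, so each single feature separates the
#' classes by `delta` (per-feature Bayes accuracy `pnorm(delta/2)`) and the
#' multivariate separation is `delta * sqrt(n_features)`. Class sizes
#' default to the 60 positive / 125 negative composition of the hotspot
#' training set.
#'
#' @param n_pos,n_neg class sizes (defaults 60 and 125).
#' @param n_features feature count (default 10).
#' @param delta per-feature class separation (>= 0).
#' @param noise_sd within-class standard deviation (default 1).
#' @param n_pos_proteins,n_neg_proteins protein ids to spread rows over
#'   (defaults 34 and 10, mirroring the curated protein sets).
#' @param seed RNG seed.
#' @return data.frame with `protein_id`, `hotspot_id`, `label` and features
#'   `f1..fK`.
#' @export
make_feature_dataset <- function(n_pos = 60L, n_neg = 125L, n_features = 10L,
                                 delta = 1, noise_sd = 1,
                                 n_pos_proteins = 34L, n_neg_proteins = 10L,
                                 seed = 1L) {
  stopifnot(delta >= 0, n_pos >= 1L, n_neg >= 1L)
  set.seed(seed)
  Xp <- matrix(rnorm(n_pos * n_features, sd = noise_sd), n_pos) + delta
  Xn <- matrix(rnorm(n_neg * n_features, sd = noise_sd), n_neg)
  X <- rbind(Xp, Xn)
  colnames(X) <- paste0("f", seq_len(n_features))
  data.frame(
    protein_id = c(sprintf("pos%02d", rep_len(seq_len(n_pos_proteins), n_pos)),
                   sprintf("neg%02d", rep_len(seq_len(n_neg_proteins), n_neg))),
    hotspot_id = sprintf("HS%03d", seq_len(n_pos + n_neg)),
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    X, stringsAsFactors = FALSE)
}
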