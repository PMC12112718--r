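# Surface patches, SASA, geometric/physicochemical descriptors, RMSF and
# probe-derived hotspot features.

mk_hotspot_at <- function(centers) {
  centers <- rbind(centers)
  structure(list(id = "HS01",
                 voxels = data.frame(ix = 0L, iy = 0L, iz = 0L,
                                     x = centers[, 1], y = centers[, 2],
                                     z = centers[, 3],
                                     linear = seq_len(nrow(centers)),
                                     occupancy = 1),
                 contributing_probes = "benzene",
                 per_probe_occupancy = list(benzene = 1),
                 total_occupancy = nrow(centers),
                 centroid = colMeans(centers), label = "unlabeled",
                 manual_flag = NA_character_, lattice = "L"),
            class = "hotspot")
}

mk_point_structure <- function(xyz, resno = NULL, resname = "ALA",
                               element = "C") {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  structure3d(data.frame(
    atom_id = seq_len(n), atom_name = "CA", element = element,
    resno = as.character(resno %||% seq_len(n)), resname = resname,
    chain = "A", record = "ATOM", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), id = "pts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("define_patch uses an inclusive 4.5 A heavy-atom cutoff", {
  s <- make_toy_protein(10, "helix")
  ca1 <- unlist(s$atoms[s$atoms$resno == "1" & s$atoms$atom_name == "CA",
                        c("x", "y", "z")])
  h <- mk_hotspot_at(ca1)
  patch <- define_patch(h, s)
  expect_true("1" %in% patch$residues$resno)

  # residue 4.6 A away from the only voxel center is excluded
  s2 <- mk_point_structure(rbind(c(0, 0, 0), c(4.6, 0, 0), c(4.4, 0, 4.4)))
  h2 <- mk_hotspot_at(c(0, 0, 0))
  p2 <- define_patch(h2, s2)
  expect_setequal(p2$residues$resno, "1")

  # random geometry equals brute-force membership
  for (seed in 1:3) {
    s3 <- random_point_structure(40, seed = seed)
    set.seed(seed + 50)
    centers <- matrix(runif(12, -15, 15), ncol = 3)
    p3 <- define_patch(mk_hotspot_at(centers), s3)
    dmin <- oracle_mindist(as.matrix(s3$atoms[, c("x", "y", "z")]), centers)
    expect_setequal(p3$residues$resno, s3$atoms$resno[dmin <= 4.5])
  }

  expect_warning(define_patch(mk_hotspot_at(c(99, 99, 99)), s2), "empty")
})

test_that("Shrake-Rupley SASA matches analytic and Monte-Carlo references", {
  # isolated atom: exact expanded-sphere area
  a1 <- sasa_atoms(rbind(c(0, 0, 0)), "C")
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)

  # two overlapping carbons: analytic spherical-cap area
  d <- 2.5; R <- 1.7 + 1.4
  a2 <- sasa_atoms(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"))
  cap_h <- R - d / 2
  exact <- 4 * pi * R^2 - 2 * pi * R * cap_h
  expect_equal(a2[1], exact, tolerance = 0.02 * exact)
  expect_equal(a2[2], exact, tolerance = 0.02 * exact)

  # random cluster vs Monte-Carlo oracle, within 2%
  set.seed(12)
  xyz <- matrix(rnorm(24, sd = 2), ncol = 3)
  elems <- rep(c("C", "N", "O", "S"), 2)
  got <- sasa_atoms(xyz, elems, n_points = 960)
  ref <- oracle_sasa_mc(xyz, cryptohot:::vdw_radius(elems) + 1.4)
  expect_lt(max(abs(got - ref)) / (4 * pi * 3.2^2), 0.02)
})

test_that("compute_size averages patch SASA over frames and sees burial", {
  s <- make_toy_protein(8, "helix")
  h <- mk_hotspot_at(unlist(s$atoms[s$atoms$resno == "4" &
                                      s$atoms$atom_name == "CB",
                                    c("x", "y", "z")]))
  patch <- define_patch(h, s)
  static_val <- compute_size(patch, s)
  expect_gt(static_val, 0)

  # static trajectory of identical frames equals the single-frame value
  frames <- replicate(4, as.matrix(s$atoms[, c("x", "y", "z")]),
                      simplify = FALSE)
  expect_equal(compute_size(patch, s, frames), static_val)

  # a residue fully caged by neighbours contributes ~0
  shell <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                 z = c(-2, 0, 2)))
  caged <- mk_point_structure(rbind(c(0, 0, 0), shell[rowSums(shell^2) > 0, ]))
  sasa <- sasa_atoms(as.matrix(caged$atoms[, c("x", "y", "z")]),
                     caged$atoms$element)
  expect_lt(sasa[1] / (4 * pi * 3.1^2), 0.05)
})

test_that("compactness is the mean pairwise closest heavy-atom distance", {
  # two single-atom residues 5 A apart
  s <- mk_point_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  patch <- structure(list(residues = data.frame(chain = "A",
                                                resno = c("1", "2")),
                          hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_compactness(patch, s), 5)

  # three residues with pairwise minima {3, 4, 5} -> mean 4
  s3 <- mk_point_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  patch3 <- structure(list(residues = data.frame(chain = "A",
                                                 resno = c("1", "2", "3")),
                           hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_compactness(patch3, s3), 4)

  # random multi-atom residues match an explicit brute force
  set.seed(31)
  s4 <- make_toy_protein(6, "helix")
  patch4 <- structure(list(residues = data.frame(chain = "A",
                                                 resno = as.character(1:6)),
                           hotspot_id = "H"), class = "surface_patch")
  a <- s4$atoms
  resl <- split(seq_len(nrow(a)), a$resno)
  pairs <- combn(names(resl), 2)
  ref <- mean(apply(pairs, 2, function(pr) {
    A <- as.matrix(a[resl[[pr[1]]], c("x", "y", "z")])
    B <- as.matrix(a[resl[[pr[2]]], c("x", "y", "z")])
    min(oracle_mindist(A, B))
  }))
  expect_equal(compute_compactness(patch4, s4), ref)
})

test_that("protrusion counts shell neighbours against the 120-atom rule", {
  # isolated residue: shell empty -> protruding fraction 1
  s <- mk_point_structure(c(0, 0, 0))
  patch <- structure(list(residues = data.frame(chain = "A", resno = "1"),
                          hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_protrusion(patch, s), 1)

  # residue at the center of a dense 10 A-radius shell with >= 120 atoms -> 0
  set.seed(6)
  v <- matrix(rnorm(150 * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * runif(150, 8.5, 11.5)
  dense <- mk_point_structure(rbind(c(0, 0, 0), v))
  patch_d <- structure(list(residues = data.frame(chain = "A", resno = "1"),
                            hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_protrusion(patch_d, dense), 0)

  # random packing matches brute-force shell counting over (8, 12]
  s5 <- random_point_structure(80, spread = 12, seed = 77)
  patch5 <- structure(list(residues = data.frame(chain = "A",
                                                 resno = as.character(1:10)),
                           hotspot_id = "H"), class = "surface_patch")
  got <- compute_protrusion(patch5, s5)
  A <- as.matrix(s5$atoms[, c("x", "y", "z")])
  ref <- mean(vapply(1:10, function(i) {
    d <- sqrt(colSums((t(A) - A[i, ])^2))
    sum(d > 8 & d <= 12) < 120
  }, TRUE))
  expect_equal(got, ref)
})

test_that("convexity is the exposed-atom to centroid distance ratio", {
  # hand-built: single-atom residues are their own centroids -> ratio 1
  s <- mk_point_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  patch <- structure(list(residues = data.frame(chain = "A",
                                                resno = c("1", "2")),
                          hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_convexity(patch, s), 1)

  # two 2-atom residues: exposed-closest distance 3, centroid distance 6
  s2 <- mk_point_structure(rbind(c(-1.5, 0, 0), c(1.5, 0, 0),
                                 c(4.5, 0, 0), c(7.5, 0, 0)),
                           resno = c(1, 1, 2, 2))
  patch2 <- structure(list(residues = data.frame(chain = "A",
                                                 resno = c("1", "2")),
                           hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_convexity(patch2, s2), 0.5)

  # convex exposed ridge vs concave pocket: in the pocket the residues'
  # facing atoms are solvent-excluded, so the closest *exposed* atoms sit at
  # the rim and the ratio grows; on the open (convex) surface the facing
  # atoms are exposed and close. Two 2-atom residues + cage context atoms.
  A1 <- c(-2.5, 0, 0); B1 <- c(-1.2, 0, -1.5)
  A2 <- c(2.5, 0, 0);  B2 <- c(1.2, 0, -1.5)
  cage <- rbind(c(0, 0, -3.6), c(-3.4, 0, -2.2), c(3.4, 0, -2.2),
                c(-1.2, 2.2, -1.8), c(-1.2, -2.2, -1.8),
                c(1.2, 2.2, -1.8), c(1.2, -2.2, -1.8),
                c(-2.8, 1.8, -0.5), c(-2.8, -1.8, -0.5),
                c(2.8, 1.8, -0.5), c(2.8, -1.8, -0.5),
                c(0, 1.8, -3.0), c(0, -1.8, -3.0))
  s_concave <- mk_point_structure(rbind(A1, B1, A2, B2, cage),
                                  resno = c(1, 1, 2, 2, rep(3, nrow(cage))))
  s_convex <- mk_point_structure(rbind(A1, B1, A2, B2),
                                 resno = c(1, 1, 2, 2))
  patch_c <- structure(list(residues = data.frame(chain = "A",
                                                  resno = c("1", "2")),
                            hotspot_id = "H"), class = "surface_patch")
  cx <- compute_convexity(patch_c, s_convex)
  cv <- compute_convexity(patch_c, s_concave)
  expect_lt(cx, cv)
})

test_that("hydrophobicity and charge density follow residue composition", {
  s_ile <- mk_point_structure(rbind(c(0, 0, 0), c(6, 0, 0)), resname = "ILE")
  patch <- structure(list(residues = data.frame(chain = "A",
                                                resno = c("1", "2")),
                          hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_hydrophobicity(patch, s_ile), 4.5)

  s_mix <- mk_point_structure(rbind(c(0, 0, 0), c(6, 0, 0)))
  s_mix$atoms$resname <- c("ILE", "ARG")
  expect_equal(compute_hydrophobicity(patch, s_mix), 0)

  s_unk <- s_mix
  s_unk$atoms$resname <- c("ILE", "XXX")
  expect_warning(v <- compute_hydrophobicity(patch, s_unk), "unknown")
  expect_equal(v, 4.5)

  # random compositions match the hand-computed mean
  set.seed(23)
  for (k in 1:3) {
    res <- sample(names(cryptohot:::KYTE_DOOLITTLE), 6, replace = TRUE)
    s_r <- mk_point_structure(cbind(seq(0, 30, length.out = 6), 0, 0))
    s_r$atoms$resname <- res
    patch_r <- structure(list(residues = data.frame(chain = "A",
                                                    resno = as.character(1:6)),
                              hotspot_id = "H"), class = "surface_patch")
    expect_equal(compute_hydrophobicity(patch_r, s_r),
                 mean(cryptohot:::KYTE_DOOLITTLE[res]))
  }

  # charge density: neutral patch 0; one Lys over 100 A^2 -> +0.01
  expect_equal(compute_charge_density(patch, s_ile, size = 100), 0)
  s_lys <- s_ile; s_lys$atoms$resname <- c("LYS", "ALA")
  expect_equal(compute_charge_density(patch, s_lys, size = 100), 0.01)
  s_dek <- s_ile; s_dek$atoms$resname <- c("ASP", "GLU")
  expect_equal(compute_charge_density(patch, s_dek, size = 50), -0.04)
  expect_warning(z <- compute_charge_density(patch, s_lys, size = 0), "zero")
  expect_equal(z, 0)
})

test_that("RMSF is zero for rigid motion and recovers planted fluctuations", {
  s <- make_toy_protein(10, "helix")
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  patch <- structure(list(residues = data.frame(chain = "A",
                                                resno = as.character(1:10)),
                          hotspot_id = "H"), class = "surface_patch")

  # static trajectory -> 0
  frames <- replicate(5, base, simplify = FALSE)
  expect_equal(compute_rmsf(patch, s, frames), 0, tolerance = 1e-12)

  # rigidly transformed frames -> 0 after alignment
  rigid <- lapply(1:6, function(f)
    cryptohot:::apply_rigid(base, seeded_rotation(f), c(f, 2 * f, -f)))
  expect_equal(compute_rmsf(patch, s, rigid), 0, tolerance = 1e-9)

  # one CA alternating +/- d along x about its mean: RMSF ~ d for that
  # residue (a large protein so the alignment barely absorbs the motion)
  d <- 0.4
  s_big <- make_toy_protein(40, "helix")
  base_big <- as.matrix(s_big$atoms[, c("x", "y", "z")])
  ca5 <- which(s_big$atoms$resno == "21" & s_big$atoms$atom_name == "CA")
  alt <- lapply(1:10, function(f) {
    m <- base_big
    m[ca5, 1] <- m[ca5, 1] + ifelse(f %% 2 == 0, d, -d)
    m
  })
  patch5 <- structure(list(residues = data.frame(chain = "A", resno = "21"),
                           hotspot_id = "H"), class = "surface_patch")
  expect_equal(compute_rmsf(patch5, s_big, alt), d, tolerance = 0.05)

  # random-walk jitter matches a brute-force two-pass computation
  frames_j <- make_toy_trajectory(s, 30, jitter_sd = 0.3, seed = 2)
  got <- compute_rmsf(patch, s, frames_j)
  ca_idx <- which(s$atoms$atom_name == "CA")
  ref_ca <- base[ca_idx, , drop = FALSE]
  al <- lapply(frames_j, function(fr) {
    k <- cryptohot:::kabsch(fr[ca_idx, ], ref_ca)
    cryptohot:::apply_rigid(fr[ca_idx, ], k$rotation, k$translation)
  })
  mu <- Reduce(`+`, al) / length(al)
  al2 <- lapply(frames_j, function(fr) {
    k <- cryptohot:::kabsch(fr[ca_idx, ], mu)
    cryptohot:::apply_rigid(fr[ca_idx, ], k$rotation, k$translation)
  })
  mu2 <- Reduce(`+`, al2) / length(al2)
  ref_rmsf <- sqrt(Reduce(`+`, lapply(al2, function(fr)
    rowSums((fr - mu2)^2))) / length(al2))
  expect_equal(got, mean(ref_rmsf), tolerance = 1e-6)
  # isotropic jitter: RMSF near sd * sqrt(3) (alignment absorbs a little)
  expect_equal(got, 0.3 * sqrt(3), tolerance = 0.15)

  expect_error(compute_rmsf(patch, s, frames[1]),
               class = "cryptohot_argument_error")
})

test_that("hotspot probe features aggregate GFE and count molecules", {
  ref <- make_toy_protein(6, "helix")
  grid <- build_grid(ref, padding = 6)
  # a molecule parked inside the hotspot every frame, another far away
  inside <- c(2.5, 0.5, 3.5); outside <- c(9.5, 9.5, 9.5)
  n_frames <- 8
  arr <- array(NA_real_, dim = c(n_frames, 6, 3))
  for (f in seq_len(n_frames)) {
    arr[f, 1:3, ] <- matrix(rep(inside, 3), ncol = 3, byrow = TRUE)
    arr[f, 4:6, ] <- matrix(rep(outside, 3), ncol = 3, byrow = TRUE)
  }
  bundle <- trajectory_bundle(probe_spec("acetonitrile"),
                              list(list(probe_xyz = arr,
                                        molecule_id = rep(1:2, each = 3))), ref)
  grid <- normalize_occupancy(accumulate_occupancy(bundle, grid))
  b <- cryptohot:::bin_points(grid, rbind(inside))
  h <- structure(list(id = "HS01",
                      voxels = data.frame(ix = b$ijk[1], iy = b$ijk[2],
                                          iz = b$ijk[3],
                                          x = inside[1], y = inside[2],
                                          z = inside[3], linear = b$linear,
                                          occupancy = 1),
                      contributing_probes = "acetonitrile",
                      per_probe_occupancy = list(acetonitrile = 1),
                      total_occupancy = 1, centroid = inside,
                      label = "unlabeled", manual_flag = NA_character_,
                      lattice = "L"), class = "hotspot")
  gfe <- compute_gfe(grid, bulk_occupancy = max(grid$occupancy))
  out <- hotspot_probe_features(h, grid, gfe, bundle)
  expect_equal(out$probe_count, 1)          # exactly one molecule inside
  expect_equal(out$gfe, 0, tolerance = 1e-9) # occupancy equals chosen bulk

  # bulk-occupancy voxels give gfe 0 by construction; min aggregation <= mean
  out_min <- hotspot_probe_features(h, grid, gfe, bundle,
                                    gfe_aggregate = "min")
  expect_lte(out_min$gfe, out$gfe + 1e-12)
})

test_that("assemble_features fixes column order, imputes, round-trips CSV", {
  rows <- list(
    list(protein_id = "p1", hotspot_id = "H1", label = "cryptic",
         gfe_benzene = -1.2, probe_count_benzene = 2, size = 120.5,
         protrusion = 0.4),
    list(protein_id = "p1", hotspot_id = "H2", label = "non_cryptic",
         gfe_benzene = NA_real_, probe_count_benzene = NA_real_, size = 80,
         protrusion = 0.9))
  tab <- assemble_features(rows, gfe_cap = 3)
  expect_equal(names(tab)[1:3], c("protein_id", "hotspot_id", "label"))
  expect_equal(tab$gfe_benzene[2], 3)        # missing probe grid -> cap
  expect_equal(tab$probe_count_benzene[2], 0)

  p <- tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back, tab, tolerance = 1e-12)

  rows_dup <- c(rows, rows[1])
  expect_error(assemble_features(rows_dup), class = "cryptohot_argument_error")
})

test_that("geometric features are invariant under joint rigid transforms", {
  s <- make_toy_protein(10, "helix")
  centers <- rbind(unlist(s$atoms[s$atoms$resno == "5" &
                                    s$atoms$atom_name == "CB",
                                  c("x", "y", "z")]))
  h <- mk_hotspot_at(centers)
  patch <- define_patch(h, s)
  base <- c(size = compute_size(patch, s),
            compact = compute_compactness(patch, s),
            protr = compute_protrusion(patch, s),
            convex = compute_convexity(patch, s))

  R <- seeded_rotation(55); tv <- c(12, -3, 9)
  s2 <- s
  xyz <- cryptohot:::apply_rigid(as.matrix(s$atoms[, c("x", "y", "z")]), R, tv)
  s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
  h2 <- mk_hotspot_at(cryptohot:::apply_rigid(centers, R, tv))
  patch2 <- define_patch(h2, s2)
  expect_setequal(patch2$residues$resno, patch$residues$resno)
  moved <- c(size = compute_size(patch2, s2),
             compact = compute_compactness(patch2, s2),
             protr = compute_protrusion(patch2, s2),
             convex = compute_convexity(patch2, s2))
  # SASA uses a fixed deterministic point lattice, so rotation changes it
  # within the method's ~2% resolution; the other features are exact
  expect_equal(moved[["size"]], base[["size"]],
               tolerance = 0.02 * base[["size"]])
  expect_equal(moved[["compact"]], base[["compact"]], tolerance = 1e-9)
  expect_equal(moved[["protr"]], base[["protr"]], tolerance = 1e-9)
  expect_equal(moved[["convex"]], base[["convex"]], tolerance = 0.05)
})
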