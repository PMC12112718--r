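# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# O(n*m) all-pairs minimum distance per row of A.
oracle_mindist <- function(A, B) {
  apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))
}

# Brute-force clash scan: residues of `atoms` (chain/resno keyed data.frame
# with heavy-atom coords) with any atom strictly < cutoff from any row of
# lig_xyz.
oracle_clash_set <- function(atoms, lig_xyz, cutoff) {
  keys <- unique(paste(atoms$chain, atoms$resno))
  hit <- vapply(keys, function(k) {
    sub <- atoms[paste(atoms$chain, atoms$resno) == k, , drop = FALSE]
    any(oracle_mindist(cbind(sub$x, sub$y, sub$z), lig_xyz) < cutoff)
  }, TRUE)
  sort(keys[hit])
}

# Literal density-reachability DBSCAN: O(n^2), closed eps-balls, min_pts
# counts the point itself. Returns cluster membership as a partition
# (list of sorted index vectors); border points may join any reachable
# cluster, so comparisons on border points use set containment.
oracle_dbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps + 1e-9))
  core <- vapply(nb, length, 1L) >= min_pts
  visited <- rep(FALSE, n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    members <- i; visited[i] <- TRUE
    frontier <- i
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[!visited[nxt]]
      visited[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt[core[nxt]]
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
  }
  clusters
}

# Core-point partition signature (border points dropped): DBSCAN's core
# clusters are unique regardless of scan order.
oracle_core_partition <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps + 1e-9))
  core <- which(vapply(nb, length, 1L) >= min_pts)
  cl <- oracle_dbscan(X, eps, min_pts)
  lapply(cl, function(m) sort(intersect(m, core)))
}

# Brute-force 3-D histogram over frames x atoms coordinates.
oracle_histogram3d <- function(coord_list, origin, spacing, shape) {
  counts <- array(0, dim = shape)
  spill <- 0
  for (m in coord_list) {
    for (r in seq_len(nrow(m))) {
      i <- floor((m[r, ] - origin) / spacing)
      if (all(i >= 0) && all(i < shape)) {
        counts[i[1] + 1, i[2] + 1, i[3] + 1] <-
          counts[i[1] + 1, i[2] + 1, i[3] + 1] + 1
      } else spill <- spill + 1
    }
  }
  list(counts = counts, spill = spill)
}

# Monte-Carlo per-atom SASA (independent of the deterministic lattice used
# by the implementation).
oracle_sasa_mc <- function(xyz, radii_expanded, n_samples = 4000L, seed = 99L) {
  set.seed(seed)
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- matrix(rnorm(n_samples * 3), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * radii_expanded[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      acc <- acc & d2 >= radii_expanded[j]^2
    }
    out[i] <- 4 * pi * radii_expanded[i]^2 * mean(acc)
  }
  out
}

# Random small structure3d for property tests: n single-atom "residues".
random_point_structure <- function(n, spread = 15, seed = 1L, chain = "A") {
  set.seed(seed)
  structure3d(data.frame(
    atom_id = seq_len(n), atom_name = "CA", element = "C",
    resno = as.character(seq_len(n)), resname = "ALA", chain = chain,
    record = "ATOM",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread), stringsAsFactors = FALSE),
    id = sprintf("rand%d", seed))
}

seeded_rotation <- function(seed) { set.seed(seed); cryptohot:::random_rotation() }
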