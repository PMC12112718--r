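# Hotspot detection: threshold the per-probe occupancy grids, cluster the
# selected voxel centers with DBSCAN, merge overlapping clusters across
# probes into hotspots, and label hotspots cryptic/non-cryptic against a
# clash-defined cryptic site.

#' Hotspot detection parameters
#'
#' Defaults are the operating point used throughout: occupancy threshold
#' 0.0004 (strict >), DBSCAN epsilon 3.0 A with min_samples 7, and merging of
#' clusters sharing more than 20% of their voxels.
#'
#' @param occupancy_threshold voxels with occupancy strictly above this are kept.
#' @param eps DBSCAN neighbourhood radius in Angstrom.
#' @param min_samples DBSCAN core-point threshold (neighbourhood size, self
#'   included).
#' @param overlap_fraction clusters overlapping more than this are merged.
#' @param overlap_method denominator of the overlap: `"min"` (default;
#'   containment always merges) or `"jaccard"`.
#' @return A `detection_params` list.
#' @export
detection_params <- function(occupancy_threshold = 4e-4, eps = 3.0,
                             min_samples = 7L, overlap_fraction = 0.20,
                             overlap_method = c("min", "jaccard")) {
  overlap_method <- match.arg(overlap_method)
  stopifnot(occupancy_threshold > 0, eps > 0, min_samples >= 1,
            overlap_fraction > 0, overlap_fraction < 1)
  structure(list(occupancy_threshold = occupancy_threshold, eps = eps,
                 min_samples = as.integer(min_samples),
                 overlap_fraction = overlap_fraction,
                 overlap_method = overlap_method),
            class = "detection_params")
}

#' Cryptic-labeling parameters
#'
#' A hotspot is labelled cryptic iff at least `clash_fraction` of its voxel
#' centers lie within `clash_distance` of a heavy atom of a clashing residue
#' AND at least one voxel center lies within `ligand_distance` of a ligand
#' heavy atom.
#'
#' @param clash_fraction inclusive fraction threshold (default 0.80).
#' @param clash_distance Angstrom (default 3.5).
#' @param ligand_distance Angstrom (default 4.5).
#' @return A `label_params` list.
#' @export
label_params <- function(clash_fraction = 0.80, clash_distance = 3.5,
                         ligand_distance = 4.5) {
  stopifnot(clash_fraction > 0, clash_fraction <= 1,
            clash_distance > 0, ligand_distance > 0)
  structure(list(clash_fraction = clash_fraction,
                 clash_distance = clash_distance,
                 ligand_distance = ligand_distance),
            class = "label_params")
}

#' Select voxels above the occupancy threshold
#'
#' @param grid a normalized `voxel_grid`.
#' @param params [detection_params()].
#' @return data.frame with 0-based lattice indices `ix,iy,iz`, voxel-center
#'   coordinates `x,y,z`, linear index `linear`, and `occupancy`.
#' @export
select_voxels <- function(grid, params = detection_params()) {
  if (is.null(grid$occupancy))
    stop_cryptohot("grid is not normalized", "cryptohot_argument_error")
  keep <- which(grid$occupancy > params$occupancy_threshold)
  sh <- grid$shape
  if (!length(keep)) {
    return(data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      linear = integer(0), occupancy = numeric(0)))
  }
  k0 <- keep - 1L
  ix <- k0 %% sh[1]
  iy <- (k0 %/% sh[1]) %% sh[2]
  iz <- k0 %/% (sh[1] * sh[2])
  centers <- voxel_centers(grid, cbind(ix, iy, iz))
  data.frame(ix = ix, iy = iy, iz = iz,
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             linear = keep, occupancy = grid$occupancy[keep])
}

# DBSCAN over points (rows of X). Returns integer labels, 0 = noise.
# Neighbourhoods are closed balls (d <= eps); min_pts counts the point itself.
# Border points join the first core cluster that reaches them in input order.
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  if (n == 0L) return(integer(0))
  # neighbour lists, chunked to bound memory
  nb <- vector("list", n)
  chunk <- max(1L, min(n, as.integer(2^22 / max(n, 1L))))
  i0 <- 1L
  x2 <- rowSums(X^2)
  while (i0 <= n) {
    idx <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(x2[idx], x2, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    hit <- d2 <= eps^2 + 1e-9
    for (j in seq_along(idx)) nb[[idx[j]]] <- which(hit[j, ])
    i0 <- i0 + chunk
  }
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      reach <- nb[[j]]
      new <- reach[labels[reach] == 0L]
      labels[new] <- cl
      queue <- c(queue, new[core[new]])
    }
  }
  labels
}

#' Cluster selected voxels with DBSCAN
#'
#' Euclidean DBSCAN over voxel centers; noise voxels are discarded. Clusters
#' are returned sorted by total occupancy, largest first. Border voxels are
#' assigned to the first core cluster reaching them in deterministic input
#' order, so results are reproducible.
#'
#' @param voxels data.frame from [select_voxels()].
#' @param params [detection_params()].
#' @param probe [probe_spec] the voxels came from.
#' @param lattice lattice signature string (taken from the source grid) used
#'   to guard cross-probe merging; see [merge_clusters()].
#' @return list of `probe_cluster` objects (voxel table, occupancy_sum,
#'   occupancy-weighted centroid).
#' @export
cluster_voxels <- function(voxels, params = detection_params(), probe = NULL,
                           lattice = NULL) {
  X <- as.matrix(voxels[, c("x", "y", "z")])
  labels <- dbscan_labels(X, params$eps, params$min_samples)
  out <- list()
  for (cl in seq_len(max(labels, 0L))) {
    v <- voxels[labels == cl, , drop = FALSE]
    w <- v$occupancy / sum(v$occupancy)
    out[[cl]] <- structure(list(
      probe = probe, voxels = v, occupancy_sum = sum(v$occupancy),
      centroid = c(sum(v$x * w), sum(v$y * w), sum(v$z * w)),
      lattice = lattice), class = "probe_cluster")
  }
  ord <- order(-vapply(out, function(c) c$occupancy_sum, 1))
  out[ord]
}

#' Merge per-probe clusters into hotspots
#'
#' Two clusters overlap by `|A intersect B| / min(|A|,|B|)` over voxel sets
#' (or Jaccard, by parameter); pairs exceeding the overlap fraction are
#' linked and hotspots are the connected components, so the result is
#' independent of input order. Hotspot voxels are the union; per-probe
#' occupancy sums are accumulated per contributing probe.
#'
#' @param clusters list of `probe_cluster`s from all probes (one lattice).
#' @param params [detection_params()].
#' @return list of `hotspot` objects, ids assigned by descending total
#'   occupancy then lexicographic centroid.
#' @export
merge_clusters <- function(clusters, params = detection_params()) {
  n <- length(clusters)
  if (n == 0L) return(list())
  latt <- unique(vapply(clusters, function(c) c$lattice %||% "", ""))
  if (length(latt) > 1L)
    stop_cryptohot("clusters come from different lattices",
                   "cryptohot_lattice_error")
  vox_sets <- lapply(clusters, function(c) c$voxels$linear)
  # union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(vox_sets[[i]], vox_sets[[j]]))
    if (inter == 0L) next
    denom <- if (params$overlap_method == "min")
      min(length(vox_sets[[i]]), length(vox_sets[[j]]))
    else length(union(vox_sets[[i]], vox_sets[[j]]))
    if (inter / denom > params$overlap_fraction) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(seq_len(n), roots)
  hs <- lapply(comps, function(members) {
    vox <- do.call(rbind, lapply(clusters[members], function(c) c$voxels))
    # per-voxel occupancy summed across contributing clusters
    agg <- stats::aggregate(occupancy ~ linear + ix + iy + iz + x + y + z,
                            data = vox, FUN = sum)
    agg <- agg[order(agg$linear), , drop = FALSE]
    probes <- vapply(clusters[members], function(c)
      if (is.null(c$probe)) "probe" else c$probe$name, "")
    ppo <- tapply(vapply(clusters[members], function(c) c$occupancy_sum, 1),
                  probes, sum)
    w <- agg$occupancy / sum(agg$occupancy)
    structure(list(
      id = NA_character_, voxels = agg,
      contributing_probes = sort(unique(probes)),
      per_probe_occupancy = as.list(ppo),
      total_occupancy = sum(vapply(clusters[members], function(c) c$occupancy_sum, 1)),
      centroid = c(sum(agg$x * w), sum(agg$y * w), sum(agg$z * w)),
      label = "unlabeled", manual_flag = NA_character_,
      lattice = clusters[[members[1]]]$lattice), class = "hotspot")
  })
  ord <- order(-vapply(hs, function(h) h$total_occupancy, 1),
               vapply(hs, function(h) sprintf("%012.4f/%012.4f/%012.4f",
                                              h$centroid[1] + 1e5,
                                              h$centroid[2] + 1e5,
                                              h$centroid[3] + 1e5), ""))
  hs <- hs[ord]
  for (i in seq_along(hs)) hs[[i]]$id <- sprintf("HS%02d", i)
  unname(hs)
}

#' @export
print.hotspot <- function(x, ...) {
  cat(sprintf("hotspot %s: %d voxel(s), probes [%s], label=%s, centroid (%.1f, %.1f, %.1f)\n",
              x$id, nrow(x$voxels), paste(x$contributing_probes, collapse = ","),
              x$label, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Label a hotspot as cryptic or non-cryptic
#'
#' Applies the two geometric criteria against a clash-defined cryptic site:
#' (1) at least `clash_fraction` of the hotspot's voxel centers within
#' `clash_distance` of any heavy atom of any clashing residue, and (2) at
#' least one voxel center within `ligand_distance` of any ligand heavy atom.
#' A third, manual-inspection criterion is a stored annotation
#' (`manual_flag`) and is never set automatically.
#'
#' @param h a `hotspot`.
#' @param site a `cryptic_site` from [detect_clashes()], in the apo frame.
#' @param apo the apo [structure3d].
#' @param params [label_params()].
#' @return The hotspot with `label` set to `"cryptic"` or `"non_cryptic"`.
#' @export
label_cryptic <- function(h, site, apo, params = label_params()) {
  centers <- as.matrix(h$voxels[, c("x", "y", "z")])
  cr <- site$clash_residues
  if (nrow(cr) == 0L) {
    warning("empty clash set: labeling hotspot non_cryptic")
    h$label <- "non_cryptic"
    return(h)
  }
  a <- apo$atoms
  key <- paste(a$chain, a$resno)
  clash_atoms <- a[key %in% paste(cr$chain, cr$resno) & a$is_heavy &
                     a$record == "ATOM", , drop = FALSE]
  d_clash <- cross_mindist(centers, cbind(clash_atoms$x, clash_atoms$y,
                                          clash_atoms$z))
  frac <- mean(d_clash <= params$clash_distance)
  lig_xyz <- as.matrix(site$ligand$atoms[, c("x", "y", "z")])
  d_lig <- cross_mindist(centers, lig_xyz)
  near_lig <- any(d_lig <= params$ligand_distance)
  h$label <- if (frac >= params$clash_fraction && near_lig) "cryptic"
             else "non_cryptic"
  h
}

#' Tabulate a list of hotspots
#'
#' @param hotspots list of `hotspot` objects.
#' @return data.frame with id, probes, voxel count, centroid, total and
#'   per-probe occupancy, and label.
#' @export
hotspot_table <- function(hotspots) {
  if (!length(hotspots))
    return(data.frame(hotspot_id = character(0), probes = character(0),
                      n_voxels = integer(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0), total_occupancy = numeric(0),
                      label = character(0)))
  do.call(rbind, lapply(hotspots, function(h) data.frame(
    hotspot_id = h$id, probes = paste(h$contributing_probes, collapse = ";"),
    n_voxels = nrow(h$voxels), cx = h$centroid[1], cy = h$centroid[2],
    cz = h$centroid[3], total_occupancy = h$total_occupancy,
    label = h$label, stringsAsFactors = FALSE)))
}

#' Write hotspot voxels as PDB pseudo-atoms for visualisation
#'
#' One HETATM per voxel center, hotspots distinguished by residue number.
#'
#' @param hotspots list of `hotspot`s.
#' @param path output PDB path.
#' @export
write_hotspot_pdb <- function(hotspots, path) {
  rows <- list()
  aid <- 0L
  for (i in seq_along(hotspots)) {
    h <- hotspots[[i]]
    for (v in seq_len(nrow(h$voxels))) {
      aid <- aid + 1L
      rows[[aid]] <- data.frame(
        atom_id = aid, atom_name = "DU", element = "X", resno = as.character(i),
        resname = "HOT", chain = "Z", record = "HETATM",
        x = h$voxels$x[v], y = h$voxels$y[v], z = h$voxels$z[v],
        stringsAsFactors = FALSE)
    }
  }
  s <- structure3d(do.call(rbind, rows), id = "hotspots")
  # element "X" is not a real element; mark heavy explicitly
  s$atoms$is_heavy <- TRUE
  write_structure(s, path)
}
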