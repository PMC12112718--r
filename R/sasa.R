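# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic spherical point set (Fibonacci lattice) on each atom's
# solvent-expanded sphere; a point is accessible if it lies outside every
# neighbouring atom's expanded sphere. Per-atom SASA is the accessible
# fraction times the expanded-sphere area.

VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90, X = 1.70)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# n points quasi-uniform on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param xyz n x 3 heavy-atom coordinates (Angstrom).
#' @param elements element symbols, length n (sets van der Waals radii).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points test points per atom (default 192; accuracy ~1-2%).
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
sasa_atoms <- function(xyz, elements, probe_radius = 1.4, n_points = 192L) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  stopifnot(length(elements) == n)
  radii <- vdw_radius(elements) + probe_radius
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  if (n == 1L) return(4 * pi * radii^2)
  # neighbour candidates via full distance matrix (patch/protein scale)
  D <- dist_matrix(xyz)
  for (i in seq_len(n)) {
    nbr <- which(D[i, ] < radii[i] + radii & seq_len(n) != i)
    if (!length(nbr)) { out[i] <- 4 * pi * radii[i]^2; next }
    sp <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(acc)) break
      d2 <- (sp[acc, 1] - xyz[j, 1])^2 + (sp[acc, 2] - xyz[j, 2])^2 +
            (sp[acc, 3] - xyz[j, 3])^2
      keep <- d2 >= radii[j]^2
      acc[acc] <- keep
    }
    out[i] <- 4 * pi * radii[i]^2 * sum(acc) / n_points
  }
  out
}
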