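# Internal geometry and misc helpers shared across modules.

#' @importFrom stats rnorm runif predict sd
#' @importFrom utils read.csv write.csv
NULL

# Extract an n x 3 coordinate matrix from a structure3d atom table.
# record: optionally restrict to "ATOM" or "HETATM" records.
xyz_of <- function(s, heavy_only = TRUE, record = NULL) {
  a <- s$atoms
  if (!is.null(record)) a <- a[a$record %in% record, , drop = FALSE]
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

# Per-row minimum Euclidean distance from points A (n x 3) to set B (m x 3).
# Chunked so the full n x m matrix is never held for large n.
cross_mindist <- function(A, B, chunk = 4096L) {
  A <- rbind(A); B <- rbind(B)
  stopifnot(ncol(A) == 3L, ncol(B) == 3L, nrow(B) >= 1L)
  out <- numeric(nrow(A))
  b2 <- rowSums(B^2)
  i0 <- 1L
  while (i0 <= nrow(A)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(A))
    Ai <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), b2, "+") - 2 * tcrossprod(Ai, B)
    out[idx] <- sqrt(pmax(matrixStats_rowMins(d2), 0))
    i0 <- i0 + chunk
  }
  out
}

# rowMins without matrixStats (not available); d is a matrix.
matrixStats_rowMins <- function(d) {
  if (ncol(d) == 1L) return(d[, 1L])
  do.call(pmin, lapply(seq_len(ncol(d)), function(j) d[, j]))
}

# Full pairwise distance matrix (small inputs only).
dist_matrix <- function(A, B = A) {
  A <- rbind(A); B <- rbind(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Kabsch least-squares rigid superposition of row-coordinate matrices.
# Returns rotation R (3x3, det +1) and translation t so that the fitted
# mobile coordinates are X %*% t(R) + t (row convention).
kabsch <- function(mobile, reference) {
  P <- rbind(mobile); Q <- rbind(reference)
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  R <- unname(s$v %*% diag(c(1, 1, d)) %*% t(s$u))
  tvec <- unname(cq - as.vector(R %*% cp))
  fitted <- P %*% t(R) + matrix(tvec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd, n_atoms_used = nrow(P))
}

# Apply a rotation+translation (column convention x' = R x + t) to row coords.
apply_rigid <- function(X, rotation, translation) {
  rbind(X) %*% t(rotation) + matrix(translation, nrow(rbind(X)), 3, byrow = TRUE)
}

# Random proper rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# 32-bit FNV-1a hash of a character scalar, returned as 8-digit hex.
# Used for config / feature-column fingerprints in output sidecars.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  prime <- 16777619
  two32 <- 2^32
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    hi <- floor(h / 65536); lo <- h - hi * 65536
    h <- ((hi * prime) %% two32 * 65536 + lo * prime) %% two32
  }
  # h is a double holding a 32-bit unsigned value; format as hex manually
  digits <- integer(8)
  for (i in 8:1) { digits[i] <- h %% 16; h <- floor(h / 16) }
  paste(substring("0123456789abcdef", digits + 1, digits + 1), collapse = "")
}

# bitwXor for doubles holding 32-bit unsigned values.
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(a %% 2^16, b %% 2^16)
  hi <- bitwXor(floor(a / 2^16) %% 2^16, floor(b / 2^16) %% 2^16)
  hi * 2^16 + lo
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cryptohot <- function(msg, class) {
  stop(structure(class = c(class, "cryptohot_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
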