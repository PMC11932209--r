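# Geometry helpers ----------------------------------------------------------

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) return(c(0, 0, 0))
  v / n
}

angle3 <- function(a, b, c) {
  # included angle at vertex b
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  c2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  n2 <- sqrt(sum(b2 * b2))
  if (n2 < 1e-12 || sum(c1 * c1) < 1e-18 || sum(c2 * c2) < 1e-18) return(NA_real_)
  x <- sum(c1 * c2)
  y <- sum((c1[2] * c2[3] - c1[3] * c2[2]) * b2[1] / n2 +
           (c1[3] * c2[1] - c1[1] * c2[3]) * b2[2] / n2 +
           (c1[1] * c2[2] - c1[2] * c2[1]) * b2[3] / n2)
  atan2(y, x)
}

# Featurization --------------------------------------------------------------

#' Per-node geometric features
#'
#' For node `i` with atoms `P_i`, `C_i` (C4') and `N_i` (glycosidic N):
#' distances `d1 = |P_i - C_i|`, `d2 = |C_i - N_i|`, `d3 = |C_{i+1} - C_i|`;
#' angles `a1 = ang(P_i, C_i, N_i)`, `a2 = ang(C_{i-1}, C_i, C_{i+1})`,
#' `a3 = ang(N_i, C_i, C_{i+1})`; dihedrals
#' `t1 = dih(P_i, C_i, P_{i+1}, C_{i+1})`,
#' `t2 = dih(C_{i-1}, P_i, C_i, P_{i+1})`,
#' `t3 = dih(N_{i-1}, C_{i-1}, C_i, N_i)`.
#' Scalars are `sin, cos` of the six angles followed by the three distances
#' (15 values). Vectors are the four unit vectors
#' `P_i - C_i`, `P_{i+1} - C_i`, `N_i - C_i`, `N_{i-1} - C_i`. Terms that
#' reference a missing atom or run past a chain terminus are zero-filled.
#'
#' @param structure an [rna_structure()].
#' @return list with `scalars` (L x 15 matrix) and `vectors`
#'   (L x 4 x 3 array).
#' @export
node_features <- function(structure) {
  L <- length(structure)
  scalars <- matrix(0, L, 15)
  vectors <- array(0, dim = c(L, 4, 3))
  if (L == 0L) return(list(scalars = scalars, vectors = vectors))
  ok <- structure$atom_ok
  P <- structure$P; C <- structure$C4; N <- structure$N
  has <- function(i, a) i >= 1L && i <= L && ok[i, a]
  for (i in seq_len(L)) {
    ang <- rep(NA_real_, 6)
    d <- c(if (has(i, 1) && has(i, 2)) sqrt(sum((P[i, ] - C[i, ])^2)) else 0,
           if (has(i, 2) && has(i, 3)) sqrt(sum((C[i, ] - N[i, ])^2)) else 0,
           if (has(i + 1L, 2) && has(i, 2)) sqrt(sum((C[i + 1L, ] - C[i, ])^2)) else 0)
    if (has(i, 1) && has(i, 2) && has(i, 3)) ang[1] <- angle3(P[i, ], C[i, ], N[i, ])
    if (has(i - 1L, 2) && has(i, 2) && has(i + 1L, 2)) ang[2] <- angle3(C[i - 1L, ], C[i, ], C[i + 1L, ])
    if (has(i, 3) && has(i, 2) && has(i + 1L, 2)) ang[3] <- angle3(N[i, ], C[i, ], C[i + 1L, ])
    if (has(i, 1) && has(i, 2) && has(i + 1L, 1) && has(i + 1L, 2)) {
      ang[4] <- dihedral4(P[i, ], C[i, ], P[i + 1L, ], C[i + 1L, ])
    }
    if (has(i - 1L, 2) && has(i, 1) && has(i, 2) && has(i + 1L, 1)) {
      ang[5] <- dihedral4(C[i - 1L, ], P[i, ], C[i, ], P[i + 1L, ])
    }
    if (has(i - 1L, 3) && has(i - 1L, 2) && has(i, 2) && has(i, 3)) {
      ang[6] <- dihedral4(N[i - 1L, ], C[i - 1L, ], C[i, ], N[i, ])
    }
    sc <- numeric(12)
    for (k in 1:6) {
      if (!is.na(ang[k])) {
        sc[2 * k - 1] <- sin(ang[k])
        sc[2 * k] <- cos(ang[k])
      }
    }
    scalars[i, ] <- c(sc, d)
    if (has(i, 1) && has(i, 2)) vectors[i, 1, ] <- unit3(P[i, ] - C[i, ])
    if (has(i + 1L, 1) && has(i, 2)) vectors[i, 2, ] <- unit3(P[i + 1L, ] - C[i, ])
    if (has(i, 3) && has(i, 2)) vectors[i, 3, ] <- unit3(N[i, ] - C[i, ])
    if (has(i - 1L, 3) && has(i, 2)) vectors[i, 4, ] <- unit3(N[i - 1L, ] - C[i, ])
  }
  list(scalars = scalars, vectors = vectors)
}

#' Gaussian radial basis encoding of a distance
#'
#' `count` Gaussian bumps with centers evenly spaced on `[0, d_max]` and
#' width equal to the center spacing.
#'
#' @param d distances (vectorised).
#' @param count number of basis functions (default 16).
#' @param d_max upper end of the center range in Angstrom (default 40,
#'   covering the maximal spatial edge length `2 * eps`).
#' @return length(d) x count matrix.
#' @export
rbf_encode <- function(d, count = 16L, d_max = 40) {
  mu <- seq(0, d_max, length.out = count)
  sigma <- mu[2] - mu[1]
  outer(d, mu, function(x, m) exp(-((x - m) / sigma)^2))
}

#' Per-edge geometric features
#'
#' Identical featurization for all three edge types: the unit displacement
#' `(x_j - x_i)/|x_j - x_i|` between C4' coordinates and the distance
#' `|x_i - x_j|` encoded by `rbf_count` radial basis functions. No
#' positional encodings enter the edge representation.
#'
#' @param structure an [rna_structure()].
#' @param edges a `typed_edge_list` or a two-column index matrix.
#' @param rbf_count number of radial basis functions.
#' @param rbf_max RBF center range in Angstrom.
#' @return list with `scalars` (m x rbf_count) and `vectors` (m x 1 x 3).
#' @export
edge_features <- function(structure, edges, rbf_count = 16L, rbf_max = 40) {
  E <- if (inherits(edges, "typed_edge_list")) edges$edges else edges
  m <- nrow(E)
  if (m == 0L) {
    return(list(scalars = matrix(0, 0, rbf_count), vectors = array(0, c(0, 1, 3))))
  }
  disp <- structure$C4[E[, 2], , drop = FALSE] - structure$C4[E[, 1], , drop = FALSE]
  d <- sqrt(rowSums(disp^2))
  if (any(d < 1e-9)) {
    stop("zero-length displacement on an edge: endpoints share C4' coordinates")
  }
  vec <- disp / d
  vectors <- array(0, c(m, 1, 3))
  vectors[, 1, ] <- vec
  list(scalars = rbf_encode(d, rbf_count, rbf_max), vectors = vectors)
}

# Convert an L x k x 3 vector-feature array into the stacked 3L x k layout
# used by the network (rows 3i-2..3i hold node i's xyz).
stack_vectors <- function(arr) {
  L <- dim(arr)[1]; k <- dim(arr)[2]
  out <- matrix(0, 3 * L, k)
  if (L == 0L) return(out)
  for (ch in seq_len(k)) {
    out[, ch] <- as.vector(t(arr[, ch, , drop = TRUE]))
  }
  out
}

unstack_vectors <- function(mat) {
  L <- nrow(mat) %/% 3L; k <- ncol(mat)
  arr <- array(0, c(L, k, 3))
  for (ch in seq_len(k)) {
    arr[, ch, ] <- matrix(mat[, ch], L, 3, byrow = TRUE)
  }
  arr
}
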