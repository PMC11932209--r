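# Deterministic synthetic RNA 3D fixtures. Geometry is idealised A-form;
# the glycosidic nitrogen is placed at a base-specific offset from the C4'
# trace so that backbone geometry carries sequence information (a noise-free,
# exaggerated form of the signal that makes fixed-backbone design possible).

# base-specific C4' -> N distance (Angstrom)
GLYCO_DIST <- c(A = 3.0, C = 3.4, G = 3.8, U = 4.2)

#' Helical geometry parameters
#'
#' Defaults follow standard A-form values: rise 2.8 Angstrom and twist 32.7
#' degrees per residue, backbone radius 9.4 Angstrom.
#' @param rise rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param radius backbone radius (Angstrom).
#' @param seed RNG seed for sequence generation.
#' @export
helix_params <- function(rise = 2.8, twist = 32.7, radius = 9.4, seed = 0L) {
  stopifnot(rise > 0, twist > 0, twist < 360, radius > 0)
  list(rise = rise, twist = twist, radius = radius, seed = as.integer(seed))
}

COMPLEMENT <- c(A = "U", U = "A", C = "G", G = "C")

# Place the three tracked atoms of one residue from a cylindrical position
# (theta in radians, z) on a helix of radius r. The phosphate sits at a
# fixed offset along the trace; the glycosidic N points inwards with a
# base-dependent length.
place_residue <- function(theta, z, r, base) {
  cyl <- function(rad, th, zz) c(rad * cos(th), rad * sin(th), zz)
  C4 <- cyl(r, theta, z)
  P <- cyl(r + 1.2, theta - 0.22, z - 1.1)
  N <- cyl(r - GLYCO_DIST[[base]], theta, z + 0.3)
  list(P = P, C4 = C4, N = N)
}

random_sequence <- function(n) paste(sample(NT_LETTERS, n, replace = TRUE), collapse = "")

build_structure <- function(chain_id, seq_chars, atoms) {
  L <- length(seq_chars)
  P <- C4 <- N <- matrix(0, L, 3)
  for (i in seq_len(L)) {
    P[i, ] <- atoms[[i]]$P; C4[i, ] <- atoms[[i]]$C4; N[i, ] <- atoms[[i]]$N
  }
  rna_structure(chain_id, paste(seq_chars, collapse = ""), P, C4, N)
}

#' Idealised A-form double helix
#'
#' `2 * n_bp` nucleotides: strand one runs up the helix, strand two
#' antiparallel at a fixed 150-degree azimuthal offset; position `i` pairs
#' with `2 n_bp + 1 - i` (1-based). The sequence is Watson-Crick consistent
#' and drawn from the seed.
#'
#' @param n_bp number of base pairs.
#' @param params a [helix_params()].
#' @return list with `structure` ([rna_structure()]) and `pairs`
#'   ([basepair_set()]).
#' @export
make_helix <- function(n_bp, params = helix_params()) {
  stopifnot(n_bp >= 1)
  L <- 2L * n_bp
  tw <- params$twist * pi / 180
  seq1 <- with_seed(params$seed, sample(NT_LETTERS, n_bp, replace = TRUE))
  seq_chars <- c(seq1, rev(unname(COMPLEMENT[seq1])))
  atoms <- vector("list", L)
  for (i in seq_len(n_bp)) {
    atoms[[i]] <- place_residue((i - 1) * tw, (i - 1) * params$rise,
                                params$radius, seq_chars[i])
  }
  for (k in seq_len(n_bp)) {
    pos <- L + 1L - k      # pairs with k
    atoms[[pos]] <- place_residue((k - 1) * tw + 150 * pi / 180,
                                  (k - 1) * params$rise, params$radius,
                                  seq_chars[pos])
  }
  pairs <- cbind(seq_len(n_bp), L + 1L - seq_len(n_bp))
  list(structure = build_structure("A", seq_chars, atoms),
       pairs = basepair_set(pairs, L))
}

#' Hairpin: helical stem plus an unpaired loop arc
#'
#' Single chain of `2 * stem_bp + loop_n` nucleotides; only stem positions
#' pair (`i` with `L + 1 - i`).
#'
#' @param stem_bp stem length in base pairs.
#' @param loop_n loop length (>= 3).
#' @param seed sequence seed.
#' @param params a [helix_params()].
#' @export
make_hairpin <- function(stem_bp, loop_n, seed = 0L, params = helix_params(seed = seed)) {
  stopifnot(stem_bp >= 1, loop_n >= 3)
  L <- 2L * stem_bp + loop_n
  tw <- params$twist * pi / 180
  drawn <- with_seed(seed, {
    list(stem = sample(NT_LETTERS, stem_bp, replace = TRUE),
         loop = sample(NT_LETTERS, loop_n, replace = TRUE))
  })
  seq_chars <- character(L)
  seq_chars[seq_len(stem_bp)] <- drawn$stem
  seq_chars[stem_bp + seq_len(loop_n)] <- drawn$loop
  seq_chars[L + 1L - seq_len(stem_bp)] <- unname(COMPLEMENT[drawn$stem])
  atoms <- vector("list", L)
  for (i in seq_len(stem_bp)) {
    atoms[[i]] <- place_residue((i - 1) * tw, (i - 1) * params$rise,
                                params$radius, seq_chars[i])
  }
  # loop: arc between the two strand tops, lifted above the stem
  th0 <- (stem_bp - 1) * tw
  th1 <- th0 + 150 * pi / 180
  ztop <- (stem_bp - 1) * params$rise
  for (k in seq_len(loop_n)) {
    t <- k / (loop_n + 1)
    th <- th0 + t * (th1 - th0 + 2 * pi)   # the long way around
    z <- ztop + 6 * sin(pi * t)
    atoms[[stem_bp + k]] <- place_residue(th, z, params$radius, seq_chars[stem_bp + k])
  }
  for (k in seq_len(stem_bp)) {
    pos <- L + 1L - k
    atoms[[pos]] <- place_residue((k - 1) * tw + 150 * pi / 180,
                                  (k - 1) * params$rise, params$radius,
                                  seq_chars[pos])
  }
  pairs <- cbind(seq_len(stem_bp), L + 1L - seq_len(stem_bp))
  list(structure = build_structure("A", seq_chars, atoms),
       pairs = basepair_set(pairs, L))
}

# Extended single-strand segment starting at `origin`, stepping along `dir`.
place_strand <- function(seq_chars, origin, dir, step = 5.9) {
  dir <- dir / sqrt(sum(dir^2))
  perp <- if (abs(dir[3]) < 0.9) unit3(c(-dir[2], dir[1], 0)) else c(1, 0, 0)
  atoms <- vector("list", length(seq_chars))
  for (i in seq_along(seq_chars)) {
    C4 <- origin + (i - 1) * step * dir
    atoms[[i]] <- list(P = C4 + 1.2 * perp - 1.1 * dir,
                       C4 = C4,
                       N = C4 - GLYCO_DIST[[seq_chars[i]]] * perp)
  }
  atoms
}

#' Toy riboswitch: one sequence, two mutually exclusive pairings
#'
#' The chain is region1 - linker - region2 - linker - region3 with
#' region3 = region1 and region2 their reverse complement. Conformation one
#' pairs region1 with region2 (region3 dangles as an extended strand);
#' conformation two pairs region2 with region3 (region1 dangles). Both
#' members share the identical sequence but have different base-pair sets
#' and coordinates.
#'
#' @param stem_bp length of the switching stem.
#' @param seed sequence seed.
#' @param linker_n linker length between regions.
#' @return a [conformer_group()] with K = 2.
#' @export
make_two_state <- function(stem_bp, seed = 0L, linker_n = 4L) {
  stopifnot(stem_bp >= 1, linker_n >= 3)
  r1 <- with_seed(seed, sample(NT_LETTERS, stem_bp, replace = TRUE))
  l1 <- with_seed(seed + 1L, sample(NT_LETTERS, linker_n, replace = TRUE))
  l2 <- with_seed(seed + 2L, sample(NT_LETTERS, linker_n, replace = TRUE))
  r2 <- rev(unname(COMPLEMENT[r1]))
  r3 <- r1
  seq_chars <- c(r1, l1, r2, l2, r3)
  L <- length(seq_chars)
  i1 <- seq_len(stem_bp)
  i2 <- stem_bp + linker_n + seq_len(stem_bp)
  i3 <- 2L * stem_bp + 2L * linker_n + seq_len(stem_bp)

  hairpin_atoms <- function(first, loop, second) {
    # helix over `first`..`second` with `loop` as the connecting arc
    n <- length(first); ln <- length(loop)
    params <- helix_params()
    tw <- params$twist * pi / 180
    atoms <- vector("list", 2L * n + ln)
    sub_seq <- seq_chars[c(first, loop, second)]
    for (i in seq_len(n)) {
      atoms[[i]] <- place_residue((i - 1) * tw, (i - 1) * params$rise,
                                  params$radius, sub_seq[i])
    }
    th0 <- (n - 1) * tw; th1 <- th0 + 150 * pi / 180
    ztop <- (n - 1) * params$rise
    for (k in seq_len(ln)) {
      t <- k / (ln + 1)
      atoms[[n + k]] <- place_residue(th0 + t * (th1 - th0 + 2 * pi),
                                      ztop + 6 * sin(pi * t), params$radius,
                                      sub_seq[n + k])
    }
    for (k in seq_len(n)) {
      atoms[[2L * n + ln + 1L - k]] <- place_residue((k - 1) * tw + 150 * pi / 180,
                                                     (k - 1) * params$rise,
                                                     params$radius,
                                                     sub_seq[2L * n + ln + 1L - k])
    }
    atoms
  }

  state_atoms <- function(pair_first, loop_idx, pair_second, dangle_idx, dangle_after) {
    atoms <- vector("list", L)
    hp <- hairpin_atoms(pair_first, loop_idx, pair_second)
    ord <- c(pair_first, loop_idx, pair_second)
    for (k in seq_along(ord)) atoms[[ord[k]]] <- hp[[k]]
    anchor <- if (dangle_after) atoms[[max(ord)]]$C4 else atoms[[min(ord)]]$C4
    dir <- c(1, 0.3, -0.4)
    if (!dangle_after) dir <- -dir
    strand <- place_strand(seq_chars[dangle_idx],
                           anchor + 5.9 * dir / sqrt(sum(dir^2)), dir)
    for (k in seq_along(dangle_idx)) atoms[[dangle_idx[k]]] <- strand[[k]]
    atoms
  }

  lk1 <- stem_bp + seq_len(linker_n)
  lk2 <- 2L * stem_bp + linker_n + seq_len(linker_n)
  # state 1: region1-region2 hairpin; linker2+region3 dangle 3'
  atoms1 <- state_atoms(i1, lk1, i2, c(lk2, i3), dangle_after = TRUE)
  # state 2: region2-region3 hairpin; region1+linker1 dangle 5'
  atoms2 <- state_atoms(i2, lk2, i3, c(i1, lk1), dangle_after = FALSE)
  bp1 <- basepair_set(cbind(i1, rev(i2)), L)
  bp2 <- basepair_set(cbind(i2, rev(i3)), L)
  conformer_group(list(
    list(structure = build_structure("A", seq_chars, atoms1), pairs = bp1),
    list(structure = build_structure("A", seq_chars, atoms2), pairs = bp2)
  ))
}

#' Long compact random coil (exercises spatial edge construction)
#'
#' A confined random walk with ~5.9 Angstrom steps inside a sphere whose
#' radius scales with `compactness * L^(1/3)`, dense enough that DBSCAN at
#' the default eps forms clusters containing positions far apart in
#' sequence.
#'
#' @param L chain length (>= 1000 to be useful for spatial edges).
#' @param compactness sphere radius multiplier (default 3).
#' @param seed RNG seed; coordinates are a pure function of (L, compactness,
#'   seed).
#' @return an [rna_structure()] (all positions unpaired).
#' @export
make_long_coil <- function(L, compactness = 3, seed = 0L) {
  stopifnot(L >= 2)
  R <- compactness * L^(1 / 3)
  with_seed(seed, {
    seq_chars <- sample(NT_LETTERS, L, replace = TRUE)
    C4 <- matrix(0, L, 3)
    pos <- c(0, 0, 0)
    for (i in 2:L) {
      step <- stats::rnorm(3)
      step <- 5.9 * step / sqrt(sum(step^2))
      cand <- pos + step
      if (sqrt(sum(cand^2)) > R) cand <- pos - step   # reflect inward
      pos <- cand
      C4[i, ] <- pos
    }
    atoms <- vector("list", L)
    for (i in seq_len(L)) {
      dir <- if (i < L) C4[i + 1L, ] - C4[i, ] else C4[i, ] - C4[i - 1L, ]
      dir <- unit3(dir)
      perp <- if (abs(dir[3]) < 0.9) unit3(c(-dir[2], dir[1], 0)) else c(1, 0, 0)
      atoms[[i]] <- list(P = C4[i, ] + 1.2 * perp - 1.1 * dir,
                         C4 = C4[i, ],
                         N = C4[i, ] - GLYCO_DIST[[seq_chars[i]]] * perp)
    }
    build_structure("A", seq_chars, atoms)
  })
}
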