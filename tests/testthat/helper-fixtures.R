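# Shared fixtures and independent oracles, all built in code.

# Uniformly random proper rotation matrix (QR of a Gaussian matrix).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid motion (x -> x R + t) to every atom of a structure.
transform_structure <- function(st, R = diag(3), t = c(0, 0, 0)) {
  tr <- function(X) sweep(X %*% R, 2, -t)
  st$P <- tr(st$P); st$C4 <- tr(st$C4); st$N <- tr(st$N)
  st
}

transform_group <- function(group, R = diag(3), t = c(0, 0, 0)) {
  group$structures <- lapply(group$structures, function(m) {
    m$structure <- transform_structure(m$structure, R, t)
    m
  })
  group
}

# Small model configuration used across network tests.
tiny_config <- function(...) {
  design_config(num_layers = 2L, node_dims = c(12L, 3L), edge_dims = c(8L, 1L),
                dropout = 0, ...)
}

tiny_model <- function(config) {
  structure(list(params = ribodesign:::init_params(config), config = config,
                 log = data.frame(), epochs_trained = 0L),
            class = "ribodesign_model")
}

hairpin_group <- function(seed = 1, stem_bp = 3, loop_n = 4) {
  hp <- make_hairpin(stem_bp, loop_n, seed = seed)
  conformer_group(list(list(structure = hp$structure, pairs = hp$pairs)))
}

# Minimal hand-written PDB text: one G nucleotide (P, C4', N9).
single_g_pdb <- function() {
  paste(c(
    "ATOM      1  P   G   A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  C4' G   A   1       3.000   1.000   0.000  1.00  0.00           C",
    "ATOM      3  N9  G   A   1       5.500   0.500   1.000  1.00  0.00           N",
    "END"), collapse = "\n")
}

# Plain, loop-free GVP on numeric matrices, written independently of the
# package's tape ops (direct formulas only).
gvp_plain <- function(p, s, V, act) {
  dims <- attr(p, "dims")
  bcast <- function(b, n) matrix(b, n, ncol(b), byrow = TRUE)
  if (dims[["vi"]] > 0L) {
    Vh <- V %*% p$Wh
    n <- nrow(Vh) %/% 3L
    i1 <- seq(1L, by = 3L, length.out = n)
    vn <- sqrt(Vh[i1, , drop = FALSE]^2 + Vh[i1 + 1L, , drop = FALSE]^2 +
                 Vh[i1 + 2L, , drop = FALSE]^2 + 1e-8)
    s_cat <- cbind(s, vn)
  } else {
    Vh <- NULL
    s_cat <- s
  }
  s_pre <- s_cat %*% p$Wm + bcast(p$bm, nrow(s_cat))
  s_out <- if (act) pmax(s_pre, 0) else s_pre
  V_out <- NULL
  if (dims[["vo"]] > 0L) {
    Vu <- Vh %*% p$Wu
    gate <- 1 / (1 + exp(-(s_pre %*% p$Wg + bcast(p$bg, nrow(s_pre)))))
    V_out <- gate[rep(seq_len(nrow(gate)), each = 3L), , drop = FALSE] * Vu
  }
  list(s = s_out, V = V_out)
}

# Brute-force single-component GVP-GNN layer: explicit per-edge loops and
# plain arithmetic, independent of the package's vectorised message path.
plain_layer_oracle <- function(lp_msg, w, lp_ff, s, Varr, E, ef_s, ef_varr) {
  n <- nrow(s)
  sd <- ncol(s)
  vd <- ncol(Varr)
  msum <- matrix(0, n, sd)
  vsum <- matrix(0, 3 * n, vd)
  r3 <- function(k) (3 * k - 2):(3 * k)
  for (e in seq_len(nrow(E))) {
    i <- E[e, 1]; j <- E[e, 2]
    s_in <- cbind(s[i, , drop = FALSE], s[j, , drop = FALSE],
                  ef_s[e, , drop = FALSE])
    V_in <- cbind(Varr[r3(i), , drop = FALSE], Varr[r3(j), , drop = FALSE],
                  ef_varr[r3(e), , drop = FALSE])
    h1 <- gvp_plain(lp_msg$g1, s_in, V_in, act = TRUE)
    h2 <- gvp_plain(lp_msg$g2, h1$s, h1$V, act = FALSE)
    msum[i, ] <- msum[i, ] + w * h2$s
    vsum[r3(i), ] <- vsum[r3(i), ] + w * h2$V
  }
  ln <- function(X) {
    m <- rowMeans(X); xc <- X - m
    xc / sqrt(rowMeans(xc * xc) + 1e-5)
  }
  s1 <- ln(s + msum)
  V1 <- Varr + vsum
  ff <- gvp_plain(lp_ff, s1, V1, act = TRUE)
  list(s = ln(s1 + ff$s), V = V1 + ff$V)
}

# Brute-force spatial-edge candidate set: explicit double loop over the
# admissible (i, j) window, checking every constraint directly.
spatial_candidates_oracle <- function(structure, bp, params) {
  L <- length(structure)
  paired <- unique(as.integer(bp$pairs))
  unpaired <- setdiff(seq_len(L), paired)
  labels_all <- rep(NA_integer_, L)
  labels_all[unpaired] <- dbscan_cluster(structure$C4[unpaired, , drop = FALSE],
                                         params$dbscan_eps, params$min_samples)
  out <- matrix(integer(0), 0, 2)
  if (L <= params$primary_dist) return(out)
  for (i in seq_len(L - params$primary_dist)) {
    for (j in (i + params$primary_dist):L) {
      if (i %in% paired || j %in% paired) next
      if (is.na(labels_all[i]) || labels_all[i] == 0L) next
      if (!identical(labels_all[i], labels_all[j])) next
      d <- sqrt(sum((structure$C4[i, ] - structure$C4[j, ])^2))
      if (d < params$min_edge_len || d >= 2 * params$dbscan_eps) next
      out <- rbind(out, c(i, j))
    }
  }
  out
}

# Central finite-difference gradient of f with respect to matrix entry
# (r, c) of the parameter retrieved/replaced by get/set closures.
fd_grad <- function(fun, params, path, r, c, h = 1e-5) {
  get_ <- function(p) {
    for (k in path) p <- p[[k]]
    p
  }
  set_ <- function(p, val) {
    expr <- p
    if (length(path) == 1L) {
      p[[path[1]]] <- val
    } else if (length(path) == 2L) {
      p[[path[1]]][[path[2]]] <- val
    } else if (length(path) == 3L) {
      p[[path[1]]][[path[2]]][[path[3]]] <- val
    } else stop("path too deep")
    p
  }
  m <- get_(params)
  mp <- m; mp[r, c] <- m[r, c] + h
  mm <- m; mm[r, c] <- m[r, c] - h
  (fun(set_(params, mp)) - fun(set_(params, mm))) / (2 * h)
}
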