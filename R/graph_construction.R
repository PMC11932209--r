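#' Spatial edge construction parameters
#'
#' Defaults follow the model's published operating point: DBSCAN on the C4'
#' coordinates of unpaired nucleotides with `eps = 20` Angstrom and
#' `min_samples = 5`; candidate pairs must lie in one cluster, be separated
#' by at least `primary_dist = 500` nt along the sequence, and have spatial
#' distance in `[min_edge_len, 2 * eps)`. When the directed edge count would
#' exceed `cap_multiplier * L`, undirected pairs are down-sampled uniformly
#' without replacement under `seed`.
#'
#' @param dbscan_eps DBSCAN radius in Angstrom.
#' @param min_samples DBSCAN core-point threshold.
#' @param primary_dist minimum sequence separation (nt).
#' @param cap_multiplier directed-count cap as a multiple of L.
#' @param min_edge_len minimum spatial edge length in Angstrom.
#' @param seed RNG seed for down-sampling.
#' @export
spatial_params <- function(dbscan_eps = 20, min_samples = 5, primary_dist = 500,
                           cap_multiplier = 4, min_edge_len = 2, seed = 0L) {
  stopifnot(dbscan_eps > 0, min_samples > 0, primary_dist > 0,
            cap_multiplier > 0, min_edge_len > 0,
            min_edge_len < 2 * dbscan_eps)
  structure(list(dbscan_eps = dbscan_eps, min_samples = min_samples,
                 primary_dist = primary_dist, cap_multiplier = cap_multiplier,
                 min_edge_len = min_edge_len, seed = as.integer(seed)),
            class = "spatial_params")
}

typed_edge_list <- function(edges, type) {
  edges <- matrix(as.integer(edges), ncol = 2)
  structure(list(edges = edges, edge_type = type), class = "typed_edge_list")
}

#' @export
print.typed_edge_list <- function(x, ...) {
  cat(sprintf("%s edges: %d directed\n", x$edge_type, nrow(x$edges)))
  invisible(x)
}

#' Backbone-adjacency (primary-structure) edges
#'
#' Both directions for each consecutive pair of nucleotides: `2(L-1)`
#' directed edges.
#' @param L chain length.
#' @export
build_primary_edges <- function(L) {
  stopifnot(L >= 1)
  if (L == 1L) return(typed_edge_list(matrix(integer(0), 0, 2), "primary"))
  i <- seq_len(L - 1L)
  typed_edge_list(rbind(cbind(i, i + 1L), cbind(i + 1L, i)), "primary")
}

#' Base-pair (secondary-structure) edges
#'
#' Two directed edges per annotated pair: `2 |BP|` in total.
#' @param bp a [basepair_set()].
#' @export
build_secondary_edges <- function(bp) {
  stopifnot(inherits(bp, "basepair_set"))
  p <- bp$pairs
  if (nrow(p) == 0L) return(typed_edge_list(matrix(integer(0), 0, 2), "secondary"))
  typed_edge_list(rbind(p, p[, 2:1, drop = FALSE]), "secondary")
}

#' DBSCAN clustering of 3D points
#'
#' Classic density-based clustering (Euclidean metric). Returns integer
#' labels with 0 marking noise points. Written in-package because no
#' DBSCAN implementation ships with the installed R stack.
#'
#' @param X n x 3 coordinate matrix.
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbourhood size (the point itself counts)
#'   for a core point.
#' @export
dbscan_cluster <- function(X, eps, min_samples) {
  n <- nrow(X)
  if (n == 0L) return(integer(0))
  D <- as.matrix(stats::dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, 1L) >= min_samples
  labels <- integer(n)           # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nbrs[[i]], i)
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, setdiff(nbrs[[j]], j))
      }
    }
  }
  # border points claimed above; remaining non-core stay noise (0)
  labels
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Spatial (long-range proximity) edges between unpaired nucleotides
#'
#' Unpaired nucleotides (no occurrence in any base pair, C4' present) are
#' clustered with DBSCAN on their C4' coordinates; pairs within one cluster
#' whose distance lies in `[min_edge_len, 2 * eps)` and whose sequence
#' separation is at least `primary_dist` become candidate edges. Both
#' directions are emitted per retained undirected pair; if the directed
#' count would exceed `cap_multiplier * L`, undirected pairs are sampled
#' uniformly without replacement under `params$seed`.
#'
#' @param structure an [rna_structure()].
#' @param bp a [basepair_set()].
#' @param params a [spatial_params()].
#' @export
build_spatial_edges <- function(structure, bp, params = spatial_params()) {
  L <- length(structure)
  empty <- typed_edge_list(matrix(integer(0), 0, 2), "spatial")
  if (L < params$primary_dist) return(empty)
  paired <- unique(as.integer(bp$pairs))
  unpaired <- setdiff(seq_len(L), paired)
  unpaired <- unpaired[structure$atom_ok[unpaired, 2]]
  if (length(unpaired) < params$min_samples) return(empty)
  X <- structure$C4[unpaired, , drop = FALSE]
  labels <- dbscan_cluster(X, params$dbscan_eps, params$min_samples)
  cand <- matrix(integer(0), 0, 2)
  for (cl in setdiff(unique(labels), 0L)) {
    members <- unpaired[labels == cl]
    if (length(members) < 2L) next
    # sequence-separation prefilter keeps the pair loop small
    cmb <- which(outer(members, members, function(a, b) b - a) >= params$primary_dist,
                 arr.ind = TRUE)
    if (nrow(cmb) == 0L) next
    ii <- members[cmb[, 1]]
    jj <- members[cmb[, 2]]
    d <- sqrt(rowSums((structure$C4[ii, , drop = FALSE] -
                       structure$C4[jj, , drop = FALSE])^2))
    keep <- d >= params$min_edge_len & d < 2 * params$dbscan_eps
    cand <- rbind(cand, cbind(ii[keep], jj[keep]))
  }
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  max_undirected <- floor(params$cap_multiplier * L / 2)
  if (nrow(cand) > max_undirected) {
    pick <- with_seed(params$seed, sample.int(nrow(cand), max_undirected))
    cand <- cand[sort(pick), , drop = FALSE]
  }
  typed_edge_list(rbind(cand, cand[, 2:1, drop = FALSE]), "spatial")
}

#' Build the full typed graph for one structure
#'
#' Attaches the three mutually exclusive directed edge sets. Spatial
#' construction is skipped outright when `L < primary_dist` (no candidate
#' can satisfy the sequence-separation constraint).
#'
#' @inheritParams build_spatial_edges
#' @return object of class `typed_graph` with elements `structure`, `bp`,
#'   `edges` (named list of [typed_edge_list]s).
#' @export
build_graph <- function(structure, bp, params = spatial_params()) {
  ep <- build_primary_edges(length(structure))
  es <- build_secondary_edges(bp)
  et <- if (length(structure) < params$primary_dist) {
    typed_edge_list(matrix(integer(0), 0, 2), "spatial")
  } else {
    build_spatial_edges(structure, bp, params)
  }
  key <- function(e) paste(e$edges[, 1], e$edges[, 2])
  if (length(intersect(key(ep), key(es))) || length(intersect(key(ep), key(et))) ||
      length(intersect(key(es), key(et)))) {
    stop("internal consistency error: typed edge sets are not mutually exclusive")
  }
  structure(list(structure = structure, bp = bp,
                 edges = list(primary = ep, secondary = es, spatial = et),
                 params = params),
            class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  cat(sprintf("typed_graph: L = %d | primary %d, secondary %d, spatial %d directed edges\n",
              length(x$structure), nrow(x$edges$primary$edges),
              nrow(x$edges$secondary$edges), nrow(x$edges$spatial$edges)))
  invisible(x)
}

#' Export a graph's edges as TSV (i, j, type, length)
#' @param graph a `typed_graph`.
#' @param path optional output file.
#' @export
write_edges_tsv <- function(graph, path = NULL) {
  rows <- character(0)
  for (e in graph$edges) {
    if (nrow(e$edges) == 0L) next
    d <- sqrt(rowSums((graph$structure$C4[e$edges[, 1], , drop = FALSE] -
                       graph$structure$C4[e$edges[, 2], , drop = FALSE])^2))
    rows <- c(rows, sprintf("%d\t%d\t%s\t%.3f", e$edges[, 1], e$edges[, 2],
                            e$edge_type, d))
  }
  txt <- if (length(rows)) paste0(paste(rows, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}
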