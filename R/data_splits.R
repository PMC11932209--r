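#' Mean pairwise superposition RMSD within a conformer group
#'
#' Optimal-superposition (Kabsch) RMSD on C4' atoms, averaged over all
#' unordered pairs of member structures; a single-structure group scores 0.
#' Positions with a missing C4' in either member are excluded from a pair's
#' superposition.
#'
#' @param group a [conformer_group()].
#' @export
intra_group_rmsd <- function(group) {
  K <- length(group$structures)
  if (K < 2L) return(0)
  vals <- numeric(0)
  for (a in seq_len(K - 1L)) {
    for (b in (a + 1L):K) {
      sa <- group$structures[[a]]$structure
      sb <- group$structures[[b]]$structure
      if (length(sa) != length(sb)) stop("length mismatch within conformer group")
      keep <- sa$atom_ok[, 2] & sb$atom_ok[, 2]
      xa <- as.numeric(t(sa$C4[keep, , drop = FALSE]))
      xb <- as.numeric(t(sb$C4[keep, , drop = FALSE]))
      vals <- c(vals, bio3d::rmsd(xa, xb, fit = TRUE))
    }
  }
  mean(vals)
}

#' Greedy sequence-identity clustering (CD-HIT scheme)
#'
#' Sequences are sorted by decreasing length; each sequence joins the first
#' existing cluster whose representative shares at least `threshold`
#' identity (matches / alignment length under exact global alignment via
#' Biostrings), otherwise it founds a new cluster with itself as
#' representative.
#'
#' @param sequences character vector.
#' @param threshold identity threshold (default 0.9).
#' @return integer cluster labels aligned with the input order.
#' @export
cluster_by_identity <- function(sequences, threshold = 0.9) {
  stopifnot(length(sequences) >= 1L)
  ord <- order(-nchar(sequences), seq_along(sequences))
  reps <- integer(0)           # indices (original) of representatives
  labels <- integer(length(sequences))
  ncl <- 0L
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      if (pair_identity(sequences[reps[ci]], sequences[i]) >= threshold) {
        labels[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      ncl <- ncl + 1L
      reps <- c(reps, i)
      labels[i] <- ncl
    }
  }
  labels
}

# Global-alignment identity = matches / alignment length.
pair_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Read CD-HIT .clstr output into cluster labels
#'
#' @param text contents of a `.clstr` file.
#' @param names sequence names in the order labels should be returned.
#' @export
read_clstr <- function(text, names) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  cl <- 0L
  out <- stats::setNames(rep(NA_integer_, length(names)), names)
  for (ln in lines) {
    if (grepl("^>Cluster", ln)) {
      cl <- cl + 1L
    } else if (nzchar(trimws(ln))) {
      nm <- sub("^.*>([^.]+?)\\.{3}.*$", "\\1", ln)
      if (nm %in% names) out[nm] <- cl
    }
  }
  as.integer(out)
}

#' Read a tool-agnostic cluster label TSV (group_id, cluster_id)
#' @param text TSV contents.
#' @param names group names in return order.
#' @export
read_cluster_tsv <- function(text, names) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- do.call(rbind, strsplit(trimws(lines), "[[:space:]]+"))
  lab <- stats::setNames(as.integer(parts[, 2]), parts[, 1])
  as.integer(lab[names])
}

#' Cluster-aware train/validation/test assignment
#'
#' Entire clusters go to one side. Clusters are ranked by the mean
#' intra-group structural RMSD of their members: low-RMSD clusters are
#' favoured for training, while validation and test are filled to exactly
#' `val_n` and `test_n` groups from the high-RMSD end (test takes the
#' highest). Ties in the ranking break by a seeded shuffle.
#'
#' @param groups list of [conformer_group()].
#' @param cluster_labels integer labels per group (from
#'   [cluster_by_identity()] for the seqid strategy, or loaded from a
#'   structural-similarity tool's label file for structsim).
#' @param val_n,test_n exact validation / test sizes in groups.
#' @param seed tie-break seed.
#' @return object of class `split_assignment`: list with `split` (factor
#'   train/val/test per group), `cluster` labels and per-group `rmsd`.
#' @export
assign_splits <- function(groups, cluster_labels, val_n = 100L, test_n = 100L,
                          seed = 0L) {
  n <- length(groups)
  stopifnot(length(cluster_labels) == n)
  rmsd <- vapply(groups, intra_group_rmsd, 1)
  cl_ids <- sort(unique(cluster_labels))
  cl_rmsd <- vapply(cl_ids, function(c) mean(rmsd[cluster_labels == c]), 1)
  cl_size <- vapply(cl_ids, function(c) sum(cluster_labels == c), 1L)
  ord <- with_seed(seed, {
    jitter_rank <- sample.int(length(cl_ids))
    order(cl_rmsd, jitter_rank)      # ascending RMSD; seeded tie-break
  })
  cl_ids <- cl_ids[ord]; cl_size <- cl_size[ord]
  # fill test then val from the high-RMSD end, whole clusters at a time
  split_of_cluster <- stats::setNames(rep("train", length(cl_ids)), cl_ids)
  need <- c(test = test_n, val = val_n)
  idx <- length(cl_ids)
  for (side in c("test", "val")) {
    got <- 0L
    while (got < need[[side]] && idx >= 1L) {
      if (got + cl_size[idx] <= need[[side]]) {
        split_of_cluster[as.character(cl_ids[idx])] <- side
        got <- got + cl_size[idx]
      }
      idx <- idx - 1L
    }
    if (got < need[[side]]) {
      stop(sprintf("cannot fill the %s set with %d groups without splitting a cluster",
                   side, need[[side]]))
    }
  }
  split <- factor(split_of_cluster[as.character(cluster_labels)],
                  levels = c("train", "val", "test"))
  structure(list(split = unname(split), cluster = cluster_labels, rmsd = rmsd),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  print(table(x$split))
  invisible(x)
}
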