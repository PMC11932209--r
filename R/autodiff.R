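# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The model code below is written once against these ops and runs in two
# modes: with plain numeric inputs everything evaluates eagerly and returns
# plain matrices (prediction/sampling); when at least one input is a tape
# node the op is recorded and gradients flow back through `ad_backward()`.
# Gradient correctness is checked against central finite differences in the
# test suite.

.ad <- new.env(parent = emptyenv())
.ad$nodes <- vector("list", 1024L)
.ad$n <- 0L
.ad$training <- FALSE

ad_reset <- function() {
  .ad$nodes <- vector("list", 1024L)
  .ad$n <- 0L
  invisible(NULL)
}

is_adnode <- function(x) inherits(x, "adnode")

adval <- function(x) if (is_adnode(x)) .ad$nodes[[x$id]]$value else x

ad_new <- function(value, parents = integer(0), back = NULL) {
  n <- .ad$n + 1L
  if (n > length(.ad$nodes)) {
    .ad$nodes <- c(.ad$nodes, vector("list", length(.ad$nodes)))
  }
  .ad$nodes[[n]] <- list(value = value, parents = parents, back = back)
  .ad$n <- n
  structure(list(id = n), class = "adnode")
}

# Leaf node carrying a parameter matrix.
ad_param <- function(value) ad_new(value)

# Record `value` if any input is a tape node. `backs` is one gradient
# function per input; only those matching tape nodes are kept.
ad_record <- function(value, inputs, backs) {
  live <- vapply(inputs, is_adnode, logical(1))
  if (!any(live)) return(value)
  ids <- vapply(inputs[live], function(x) x$id, integer(1))
  backs <- backs[live]
  ad_new(value, parents = ids, back = function(g) lapply(backs, function(f) f(g)))
}

# Backward sweep from a scalar loss node; returns a list of gradients
# indexed by node id (NULL where no gradient reached).
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss))
  grads <- vector("list", loss$id)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- .ad$nodes[[i]]
    if (is.null(nd$back)) next
    pg <- nd$back(g)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

## ---- primitive ops ----

ad_matmul <- function(A, B) {
  Av <- adval(A); Bv <- adval(B)
  ad_record(Av %*% Bv, list(A, B), list(
    function(g) g %*% t(Bv),
    function(g) t(Av) %*% g
  ))
}

# Same-shape addition, or addition of a 1-row bias broadcast over rows.
ad_add <- function(A, B) {
  Av <- adval(A); Bv <- adval(B)
  if (is.matrix(Bv) && nrow(Bv) == 1L && nrow(Av) > 1L) {
    val <- Av + matrix(Bv, nrow(Av), ncol(Av), byrow = TRUE)
    ad_record(val, list(A, B), list(
      function(g) g,
      function(g) matrix(colSums(g), 1L)
    ))
  } else {
    ad_record(Av + Bv, list(A, B), list(function(g) g, function(g) g))
  }
}

ad_sub <- function(A, B) {
  Av <- adval(A); Bv <- adval(B)
  ad_record(Av - Bv, list(A, B), list(function(g) g, function(g) -g))
}

ad_mul <- function(A, B) {
  Av <- adval(A); Bv <- adval(B)
  ad_record(Av * Bv, list(A, B), list(function(g) g * Bv, function(g) g * Av))
}

ad_scale <- function(A, k) {
  Av <- adval(A)
  ad_record(Av * k, list(A), list(function(g) g * k))
}

# Multiply a matrix by a learned 1x1 scalar (edge-type weight).
ad_smul <- function(A, w) {
  Av <- adval(A); wv <- as.numeric(adval(w))
  ad_record(Av * wv, list(A, w), list(
    function(g) g * wv,
    function(g) matrix(sum(g * Av), 1L, 1L)
  ))
}

ad_relu <- function(A) {
  Av <- adval(A)
  mask <- Av > 0
  ad_record(Av * mask, list(A), list(function(g) g * mask))
}

ad_sigmoid <- function(A) {
  Av <- adval(A)
  s <- 1 / (1 + exp(-Av))
  ad_record(s, list(A), list(function(g) g * s * (1 - s)))
}

ad_cbind <- function(...) {
  inputs <- list(...)
  vals <- lapply(inputs, adval)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  backs <- lapply(seq_along(inputs), function(k) {
    a <- starts[k]; b <- ends[k]
    function(g) g[, a:b, drop = FALSE]
  })
  ad_record(do.call(cbind, vals), inputs, backs)
}

# Row gather; gradient is scatter-add.
ad_rows <- function(A, idx) {
  Av <- adval(A)
  nr <- nrow(Av); nc <- ncol(Av)
  ad_record(Av[idx, , drop = FALSE], list(A), list(function(g) {
    out <- matrix(0, nr, nc)
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }))
}

# Scatter-add rows of A into `nout` rows by index; gradient is gather.
ad_scatter <- function(A, idx, nout) {
  Av <- adval(A)
  val <- matrix(0, nout, ncol(Av))
  if (nrow(Av) > 0L) {
    rs <- rowsum(Av, idx)
    val[as.integer(rownames(rs)), ] <- rs
  }
  ad_record(val, list(A), list(function(g) g[idx, , drop = FALSE]))
}

# Vector-feature norms. X has 3n rows (rows 3i-2..3i are the xyz of node i's
# vector channels); returns the n x h matrix of channel norms.
ad_vnorm <- function(X, eps = 1e-8) {
  Xv <- adval(X)
  n <- nrow(Xv) %/% 3L
  i1 <- seq(1L, by = 3L, length.out = n)
  sq <- Xv * Xv
  S <- sq[i1, , drop = FALSE] + sq[i1 + 1L, , drop = FALSE] + sq[i1 + 2L, , drop = FALSE]
  N <- sqrt(S + eps)
  ad_record(N, list(X), list(function(g) {
    E <- (g / N)[rep(seq_len(n), each = 3L), , drop = FALSE]
    Xv * E
  }))
}

# Repeat each row of an n x h matrix three times (to 3n x h).
ad_expand3 <- function(S) {
  Sv <- adval(S)
  n <- nrow(Sv)
  idx <- rep(seq_len(n), each = 3L)
  ad_record(Sv[idx, , drop = FALSE], list(S), list(function(g) {
    i1 <- seq(1L, by = 3L, length.out = n)
    g[i1, , drop = FALSE] + g[i1 + 1L, , drop = FALSE] + g[i1 + 2L, , drop = FALSE]
  }))
}

ad_layernorm <- function(A, eps = 1e-5) {
  Av <- adval(A)
  m <- rowMeans(Av)
  xc <- Av - m
  v <- rowMeans(xc * xc)
  s <- sqrt(v + eps)
  y <- xc / s
  ad_record(y, list(A), list(function(g) {
    (g - rowMeans(g) - y * rowMeans(g * y)) / s
  }))
}

# Inverted dropout; active only while .ad$training is TRUE.
ad_dropout <- function(A, p) {
  if (!isTRUE(.ad$training) || p <= 0) return(if (is_adnode(A)) A else adval(A))
  Av <- adval(A)
  mask <- (matrix(stats::runif(length(Av)), nrow(Av)) >= p) / (1 - p)
  ad_record(Av * mask, list(A), list(function(g) g * mask))
}

# Row-wise softmax (numerically stabilised).
ad_softmax <- function(Z) {
  Zv <- adval(Z)
  m <- apply(Zv, 1L, max)
  E <- exp(Zv - m)
  S <- E / rowSums(E)
  ad_record(S, list(Z), list(function(g) {
    S * (g - rowSums(g * S))
  }))
}

# Masked mean negative log-likelihood of integer labels under row
# distributions P. `w` are per-row weights (0 masks a row out).
ad_nll <- function(P, labels, w) {
  Pv <- adval(P)
  n <- nrow(Pv)
  stopifnot(length(labels) == n, length(w) == n)
  sel <- cbind(seq_len(n), labels)
  keep <- w > 0
  psel <- pmax(Pv[sel], 1e-12)
  tot <- sum(w)
  val <- -sum(w[keep] * log(psel[keep])) / tot
  ad_record(val, list(P), list(function(g) {
    dP <- matrix(0, n, ncol(Pv))
    dP[sel] <- -w / (psel * tot)
    dP * g
  }))
}
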