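# Geometric vector perceptron (GVP) modules and the relational
# message-passing layer. All functions work on plain numeric matrices for
# inference and on autodiff tape nodes during training; vector features use
# the stacked 3n x channels layout (rows 3i-2..3i are node i's xyz).

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# Parameter set for one GVP: scalar (si -> so) and vector (vi -> vo)
# channels, vector hidden width h = max(vi, vo).
gvp_init <- function(si, vi, so, vo) {
  h <- max(vi, vo, 1L)
  p <- list(Wh = glorot(vi, h),
            Wm = glorot(si + h, so),
            bm = matrix(0, 1, so))
  if (vo > 0L) {
    p$Wu <- glorot(h, vo)
    p$Wg <- matrix(0, so, vo)   # vector gate starts neutral (sigmoid(0) = 0.5)
    p$bg <- matrix(0, 1, vo)
  }
  attr(p, "dims") <- c(si = si, vi = vi, so = so, vo = vo, h = h)
  p
}

# Forward pass of one GVP. `s` is n x si, `V` is 3n x vi (or NULL when
# vi = 0). Scalar activation is ReLU unless `act = FALSE` (final layers);
# the vector channel uses sigmoid gating from the scalar pathway, which
# keeps the whole unit O(3)-equivariant: vectors only ever enter scalars
# through their norms, and vector outputs are linear maps of input vectors
# scaled by invariant gates.
gvp_forward <- function(p, s, V, act = TRUE) {
  dims <- attr(p, "dims")
  if (dims[["vi"]] > 0L) {
    Vh <- ad_matmul(V, p$Wh)
    vn <- ad_vnorm(Vh)
    s_cat <- ad_cbind(s, vn)
  } else {
    Vh <- NULL
    s_cat <- s
  }
  s_pre <- ad_add(ad_matmul(s_cat, p$Wm), p$bm)
  s_out <- if (act) ad_relu(s_pre) else s_pre
  V_out <- NULL
  if (dims[["vo"]] > 0L) {
    Vu <- ad_matmul(Vh, p$Wu)
    gate <- ad_sigmoid(ad_add(ad_matmul(s_pre, p$Wg), p$bg))
    V_out <- ad_mul(ad_expand3(gate), Vu)
  }
  list(s = s_out, V = V_out)
}

# Wrap a (possibly nested) list of numeric matrices as tape parameters,
# preserving list attributes (GVP dimension tags ride along).
params_to_nodes <- function(p) {
  if (is.matrix(p)) return(ad_param(p))
  if (is.list(p) && !is_adnode(p)) {
    out <- lapply(p, params_to_nodes)
    attributes(out) <- attributes(p)
    return(out)
  }
  p
}

# Collect gradients for a nested parameter list wrapped by params_to_nodes.
params_grads <- function(pn, grads) {
  if (is_adnode(pn)) {
    g <- if (pn$id <= length(grads)) grads[[pn$id]] else NULL
    if (is.null(g)) g <- adval(pn) * 0
    return(g)
  }
  if (is.list(pn)) {
    out <- lapply(pn, params_grads, grads = grads)
    attributes(out) <- attributes(pn)
    return(out)
  }
  pn
}

# Message network: a stack of two GVPs applied to the concatenated sender,
# receiver and edge features.
msg_init <- function(sd, vd, se, ve) {
  list(g1 = gvp_init(2L * sd + se, 2L * vd + ve, sd, vd),
       g2 = gvp_init(sd, vd, sd, vd))
}

# Compute the aggregated (summed) messages of one edge-type component.
# s: n x sd, V: 3n x vd; E: m x 2 directed (receiver, sender); ef: embedded
# edge features list(s = m x se, V = 3m x ve). Returns list(s = n x sd,
# V = 3n x vd) of per-node message sums (zero rows for empty neighbourhoods).
gvp_component_messages <- function(mp, s, V, E, ef, n) {
  sd <- attr(mp$g2, "dims")[["so"]]
  vd <- attr(mp$g2, "dims")[["vo"]]
  if (nrow(E) == 0L) {
    return(list(s = matrix(0, n, sd), V = matrix(0, 3L * n, vd)))
  }
  recv <- E[, 1]; send <- E[, 2]
  row3 <- function(i) rep(3L * (i - 1L), each = 3L) + rep(1:3, length(i))
  s_i <- ad_rows(s, recv); s_j <- ad_rows(s, send)
  V_i <- ad_rows(V, row3(recv)); V_j <- ad_rows(V, row3(send))
  s_in <- ad_cbind(s_i, s_j, ef$s)
  V_in <- ad_cbind(V_i, V_j, ef$V)
  h1 <- gvp_forward(mp$g1, s_in, V_in, act = TRUE)
  h2 <- gvp_forward(mp$g2, h1$s, h1$V, act = FALSE)
  list(s = ad_scatter(h2$s, recv, n),
       V = ad_scatter(h2$V, row3(recv), 3L * n))
}

# One relational GNN layer: per-edge-type GVP message components pooled by
# learned weights, then a residual node update and a feed-forward GVP.
relational_layer_init <- function(sd, vd, se, ve, edge_types) {
  comps <- lapply(edge_types, function(t) msg_init(sd, vd, se, ve))
  names(comps) <- edge_types
  w <- lapply(edge_types, function(t) matrix(1, 1, 1))
  names(w) <- edge_types
  list(msg = comps, w = w, ff = gvp_init(sd, vd, sd, vd))
}

# graph_feats: list with, per edge type, E (matrix) and ef (embedded edge
# features). dropout applies only in training mode.
relational_layer_forward <- function(lp, s, V, graph_feats, n, dropout = 0) {
  types <- names(lp$msg)
  m_s <- NULL; m_V <- NULL
  for (t in types) {
    gf <- graph_feats[[t]]
    comp <- gvp_component_messages(lp$msg[[t]], s, V, gf$E, gf$ef, n)
    ws <- ad_smul(comp$s, lp$w[[t]])
    wV <- ad_smul(comp$V, lp$w[[t]])
    m_s <- if (is.null(m_s)) ws else ad_add(m_s, ws)
    m_V <- if (is.null(m_V)) wV else ad_add(m_V, wV)
  }
  s1 <- ad_layernorm(ad_add(s, ad_dropout(m_s, dropout)))
  V1 <- ad_add(V, ad_dropout(m_V, dropout))
  ff <- gvp_forward(lp$ff, s1, V1, act = TRUE)
  s2 <- ad_layernorm(ad_add(s1, ad_dropout(ff$s, dropout)))
  V2 <- ad_add(V1, ad_dropout(ff$V, dropout))
  list(s = s2, V = V2)
}
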