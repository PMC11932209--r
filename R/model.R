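NT_LETTERS <- c("A", "C", "G", "U")

seq_to_labels <- function(sequence) {
  match(strsplit(sequence, "")[[1]], NT_LETTERS)   # NA for 'N'
}

#' Model configuration
#'
#' @param num_layers number of relational encoder layers (2 or 4 are the
#'   studied settings).
#' @param node_dims c(scalar, vector) node channel widths.
#' @param edge_dims c(scalar, vector) edge channel widths.
#' @param edge_types `"3d"` (primary + secondary + spatial) or `"2d"`
#'   (primary + secondary).
#' @param decoder `"nar"` (one-shot) or `"ar"` (autoregressive, 5' to 3').
#' @param dropout dropout rate applied to messages during training.
#' @param lr Adam learning rate.
#' @param rbf_count,rbf_max radial basis encoding of edge lengths.
#' @param context_dim,context_decay autoregressive context: dimension of the
#'   previous-letter embedding and the exponential decay with which earlier
#'   letters enter the causal context.
#' @param n_samples default number of sampled sequences in design mode.
#' @param spatial a [spatial_params()] object used for graph building.
#' @param seed seed for parameter initialisation.
#' @export
design_config <- function(num_layers = 2L, node_dims = c(128L, 16L),
                          edge_dims = c(32L, 1L),
                          edge_types = c("3d", "2d"),
                          decoder = c("nar", "ar"),
                          dropout = 0.1, lr = 1e-3,
                          rbf_count = 16L, rbf_max = 40,
                          context_dim = 8L, context_decay = 0.9,
                          n_samples = 16L,
                          spatial = spatial_params(), seed = 1L) {
  edge_types <- match.arg(edge_types)
  decoder <- match.arg(decoder)
  stopifnot(num_layers >= 1L, all(node_dims >= 1L), all(edge_dims >= 1L))
  types <- if (edge_types == "3d") c("primary", "secondary", "spatial") else c("primary", "secondary")
  structure(list(num_layers = as.integer(num_layers),
                 node_dims = as.integer(node_dims),
                 edge_dims = as.integer(edge_dims),
                 edge_types = edge_types, types = types,
                 decoder = decoder, dropout = dropout, lr = lr,
                 rbf_count = as.integer(rbf_count), rbf_max = rbf_max,
                 context_dim = as.integer(context_dim),
                 context_decay = context_decay,
                 n_samples = as.integer(n_samples),
                 spatial = spatial, seed = as.integer(seed)),
            class = "ribodesign_config")
}

init_params <- function(config) {
  sd <- config$node_dims[1]; vd <- config$node_dims[2]
  se <- config$edge_dims[1]; ve <- config$edge_dims[2]
  with_seed(config$seed, {
    p <- list(embed_node = gvp_init(15L, 4L, sd, vd),
              embed_edge = gvp_init(config$rbf_count, 1L, se, ve),
              layers = lapply(seq_len(config$num_layers), function(l) {
                relational_layer_init(sd, vd, se, ve, config$types)
              }))
    if (config$decoder == "nar") {
      p$head <- list(g1 = gvp_init(sd, vd, sd, vd),
                     g2 = gvp_init(sd, vd, sd, vd),
                     Wout = glorot(sd, 4L), bout = matrix(0, 1, 4))
    } else {
      ce <- config$context_dim
      p$head <- list(Emb = glorot(5L, ce),   # A,C,G,U + unknown token
                     g1 = gvp_init(sd + ce, vd, sd, vd),
                     g2 = gvp_init(sd, vd, sd, vd),
                     Wout = glorot(sd, 4L), bout = matrix(0, 1, 4))
    }
    p
  })
}

# Precompute graphs and raw features for one conformer group so training
# epochs only run the network.
prepare_group <- function(group, config) {
  stopifnot(inherits(group, "conformer_group"))
  labels <- seq_to_labels(group$sequence)
  L <- length(labels)
  members <- lapply(group$structures, function(m) {
    g <- build_graph(m$structure, m$pairs, config$spatial)
    nf <- node_features(m$structure)
    feats <- list()
    for (t in config$types) {
      E <- g$edges[[t]]$edges
      ef <- edge_features(m$structure, E, config$rbf_count, config$rbf_max)
      feats[[t]] <- list(E = E,
                         s = ef$scalars,
                         V = stack_vectors(ef$vectors))
    }
    list(E_feats = feats,
         node_s = nf$scalars,
         node_V = stack_vectors(nf$vectors))
  })
  list(labels = labels, L = L, members = members, sequence = group$sequence)
}

# Encoder forward over one prepared structure: input embedding, then the
# stacked relational layers. Returns list(s, V).
forward_encoder <- function(pn, config, member, dropout = 0) {
  n <- nrow(member$node_s)
  emb <- gvp_forward(pn$embed_node, member$node_s, member$node_V, act = FALSE)
  graph_feats <- list()
  for (t in config$types) {
    f <- member$E_feats[[t]]
    ef <- if (nrow(f$E) > 0L) {
      gvp_forward(pn$embed_edge, f$s, f$V, act = FALSE)
    } else {
      list(s = matrix(0, 0, config$edge_dims[1]),
           V = matrix(0, 0, config$edge_dims[2]))
    }
    graph_feats[[t]] <- list(E = f$E, ef = list(s = ef$s, V = ef$V))
  }
  s <- emb$s; V <- emb$V
  for (lp in pn$layers) {
    upd <- relational_layer_forward(lp, s, V, graph_feats, n, dropout)
    s <- upd$s; V <- upd$V
  }
  list(s = s, V = V)
}

mean_of <- function(items) {
  out <- items[[1]]
  if (length(items) > 1L) {
    for (k in 2L:length(items)) out <- ad_add(out, items[[k]])
  }
  ad_scale(out, 1 / length(items))
}

# Multi-conformation pooling of final encoder embeddings (mean over K).
encode_structures <- function(pn, config, prep, dropout = 0) {
  per <- lapply(prep$members, function(m) forward_encoder(pn, config, m, dropout))
  pooled <- list(s = mean_of(lapply(per, `[[`, "s")),
                 V = mean_of(lapply(per, `[[`, "V")))
  list(per_structure = per, pooled = pooled)
}

# Causal context matrix: C[i, ] = sum_{j < i} decay^(i-1-j) Emb[y_j, ].
causal_context <- function(EmbNode, labels, decay) {
  n <- length(labels)
  y <- ifelse(is.na(labels), 5L, labels)
  Tm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- seq_len(i - 1L)
    if (length(j)) Tm[i, j] <- decay^(i - 1L - j)
  }
  ad_matmul(Tm, ad_rows(EmbNode, y))
}

decode_nar_forward <- function(pn, pooled, dropout = 0) {
  h1 <- gvp_forward(pn$head$g1, pooled$s, pooled$V, act = TRUE)
  h2 <- gvp_forward(pn$head$g2, h1$s, h1$V, act = TRUE)
  logits <- ad_add(ad_matmul(ad_dropout(h2$s, dropout), pn$head$Wout), pn$head$bout)
  ad_softmax(logits)
}

decode_ar_forward <- function(pn, per_structure, context, dropout = 0) {
  probs_k <- lapply(per_structure, function(e) {
    s_in <- ad_cbind(e$s, context)
    h1 <- gvp_forward(pn$head$g1, s_in, e$V, act = TRUE)
    h2 <- gvp_forward(pn$head$g2, h1$s, h1$V, act = TRUE)
    logits <- ad_add(ad_matmul(ad_dropout(h2$s, dropout), pn$head$Wout), pn$head$bout)
    ad_softmax(logits)
  })
  mean_of(probs_k)   # probability pooling over conformations
}

# Full forward to per-position probabilities; teacher-forced for AR.
forward_probs <- function(pn, config, prep, dropout = 0) {
  enc <- encode_structures(pn, config, prep, dropout)
  if (config$decoder == "nar") {
    decode_nar_forward(pn, enc$pooled, dropout)
  } else {
    ctx <- causal_context(pn$head$Emb, prep$labels, config$context_decay)
    decode_ar_forward(pn, enc$per_structure, ctx, dropout)
  }
}

group_loss <- function(pn, config, prep, dropout = 0) {
  probs <- forward_probs(pn, config, prep, dropout)
  w <- as.numeric(!is.na(prep$labels))
  labels <- ifelse(is.na(prep$labels), 1L, prep$labels)
  list(loss = ad_nll(probs, labels, w), probs = probs)
}

#' Encode a conformer group into node embeddings
#'
#' Runs the relational encoder on each conformation separately (shared
#' parameters) and pools the final per-structure embeddings by averaging.
#'
#' @param model a fitted or initialised `ribodesign_model`.
#' @param group a [conformer_group()].
#' @return list with `per_structure` (list of `list(s, V)`) and `pooled`
#'   (their element-wise mean); `s` is L x scalar-width, `V` is the stacked
#'   3L x vector-width matrix.
#' @export
encode_conformers <- function(model, group) {
  prep <- prepare_group(group, model$config)
  encode_structures(model$params, model$config, prep)
}

#' Pool per-structure node embeddings (mean over conformations)
#'
#' @param embeddings list of `list(s, V)` numeric embeddings.
#' @export
pool_embeddings <- function(embeddings) {
  list(s = Reduce(`+`, lapply(embeddings, `[[`, "s")) / length(embeddings),
       V = Reduce(`+`, lapply(embeddings, `[[`, "V")) / length(embeddings))
}

#' Pool per-structure probability matrices (mean over conformations)
#'
#' The final per-position distribution is the average of the per-structure
#' predictive distributions.
#' @param prob_list list of L x 4 row-stochastic matrices.
#' @export
pool_probabilities <- function(prob_list) {
  stopifnot(length(prob_list) >= 1L)
  Reduce(`+`, prob_list) / length(prob_list)
}

#' Predicted nucleotide probabilities for a conformer group
#'
#' @param object a `ribodesign_model`.
#' @param group a [conformer_group()].
#' @param teacher_sequence for the autoregressive decoder, the sequence used
#'   as causal context (defaults to the group's own sequence, i.e. teacher
#'   forcing as in evaluation of perplexity/accuracy).
#' @return L x 4 matrix with columns A, C, G, U; rows sum to 1.
#' @export
predict_probabilities <- function(object, group, teacher_sequence = NULL) {
  config <- object$config
  prep <- prepare_group(group, config)
  if (!is.null(teacher_sequence)) {
    stopifnot(nchar(teacher_sequence) == prep$L)
    prep$labels <- seq_to_labels(teacher_sequence)
  }
  probs <- forward_probs(object$params, config, prep, dropout = 0)
  probs <- adval(probs)
  colnames(probs) <- NT_LETTERS
  probs
}

#' Sample designed sequences
#'
#' NAR: positions sampled independently from the pooled probability matrix.
#' AR: sequential 5' to 3' sampling; at each position the per-structure
#' heads are evaluated under the causal context of the already-sampled
#' letters, pooled across conformations, and the next letter drawn.
#'
#' @param model a `ribodesign_model`.
#' @param group a [conformer_group()].
#' @param n number of sequences.
#' @param temperature sampling temperature (1 = model distribution).
#' @param seed RNG seed.
#' @return character vector of sampled sequences.
#' @export
sample_sequences <- function(model, group, n = model$config$n_samples,
                             temperature = 1, seed = 0L) {
  config <- model$config
  prep <- prepare_group(group, config)
  pn <- model$params
  with_seed(seed, {
    if (config$decoder == "nar") {
      probs <- adval(forward_probs(pn, config, prep, dropout = 0))
      vapply(seq_len(n), function(k) {
        paste(NT_LETTERS[apply(probs, 1, function(p) {
          p <- temper(p, temperature)
          sample.int(4L, 1L, prob = p)
        })], collapse = "")
      }, "")
    } else {
      enc <- encode_structures(pn, config, prep, dropout = 0)
      per <- lapply(enc$per_structure, function(e) list(s = adval(e$s), V = adval(e$V)))
      Emb <- adval(pn$head$Emb)
      vapply(seq_len(n), function(k) {
        ctx <- matrix(0, 1, config$context_dim)
        out <- integer(prep$L)
        for (i in seq_len(prep$L)) {
          pk <- lapply(per, function(e) {
            s_in <- cbind(e$s[i, , drop = FALSE], ctx)
            Vi <- e$V[(3L * i - 2L):(3L * i), , drop = FALSE]
            h1 <- gvp_forward(pn$head$g1, s_in, Vi, act = TRUE)
            h2 <- gvp_forward(pn$head$g2, h1$s, h1$V, act = TRUE)
            logits <- adval(h2$s) %*% adval(pn$head$Wout) +
              matrix(adval(pn$head$bout), 1, 4)
            z <- exp(logits - max(logits))
            z / sum(z)
          })
        p <- temper(as.numeric(pool_probabilities(pk)), temperature)
          out[i] <- sample.int(4L, 1L, prob = p)
          ctx <- config$context_decay * ctx + Emb[out[i], , drop = FALSE]
        }
        paste(NT_LETTERS[out], collapse = "")
      }, "")
    }
  })
}

temper <- function(p, temperature) {
  if (temperature == 1) return(p)
  # log-space so extreme temperatures cannot underflow the whole vector
  lq <- log(pmax(p, 1e-300)) / temperature
  q <- exp(lq - max(lq))
  q / sum(q)
}
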