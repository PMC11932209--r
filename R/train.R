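# Flatten / rebuild nested parameter lists for the optimiser.
flatten_params <- function(p, prefix = "") {
  if (is.matrix(p)) return(stats::setNames(list(p), prefix))
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  out <- list()
  for (k in seq_along(p)) {
    out <- c(out, flatten_params(p[[k]], paste0(prefix, if (nzchar(prefix)) "." else "", nms[k])))
  }
  out
}

adam_state <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# Write flat values back into the nested structure.
unflatten_into <- function(p, flat, prefix = "") {
  if (is.matrix(p)) return(flat[[prefix]])
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (k in seq_along(p)) {
    p[[k]] <- unflatten_into(p[[k]], flat, paste0(prefix, if (nzchar(prefix)) "." else "", nms[k]))
  }
  p
}

#' Fit the relational RNA inverse-design model
#'
#' Minimises the masked cross-entropy of the native nucleotides under the
#' decoder output (teacher-forced for the autoregressive decoder) with Adam.
#' Positions with letter `N` are excluded from the loss. One optimiser step
#' is taken per conformer group per epoch, in a fixed order.
#'
#' @param groups list of [conformer_group()] training inputs.
#' @param config a [design_config()].
#' @param epochs number of passes over the training set.
#' @param val_groups optional validation groups; perplexity and accuracy are
#'   logged each epoch.
#' @param seed seed controlling initialisation and dropout.
#' @param verbose print a line every `log_every` epochs.
#' @param log_every epoch interval for logging/printing.
#' @return an object of class `ribodesign_model` with elements `params`,
#'   `config`, `log` (data frame: epoch, loss, and validation metrics when
#'   available).
#' @export
ribodesign_fit <- function(groups, config = design_config(), epochs = 100L,
                           val_groups = NULL, seed = config$seed,
                           verbose = FALSE, log_every = 10L) {
  stopifnot(length(groups) >= 1L)
  config$seed <- as.integer(seed)
  params <- init_params(config)
  preps <- lapply(groups, prepare_group, config = config)
  flat <- flatten_params(params)
  state <- adam_state(flat)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_perplexity = numeric(0), val_accuracy = numeric(0))
  model <- structure(list(params = params, config = config, log = log,
                          epochs_trained = 0L),
                     class = "ribodesign_model")
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      .ad$training <- TRUE
      ep_loss <- 0
      for (prep in preps) {
        ad_reset()
        pn <- params_to_nodes(params)
        gl <- group_loss(pn, config, prep, dropout = config$dropout)
        if (!is.finite(adval(gl$loss))) {
          .ad$training <- FALSE
          stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", ep))
        }
        grads <- ad_backward(gl$loss)
        gflat <- flatten_params(params_grads(pn, grads))
        upd <- adam_step(flat, gflat, state, config$lr)
        flat <- upd$flat; state <- upd$state
        params <- unflatten_into(params, flat)
        ep_loss <- ep_loss + adval(gl$loss)
      }
      .ad$training <- FALSE
      model$params <- params
      model$epochs_trained <- ep
      row <- data.frame(epoch = ep, loss = ep_loss / length(preps),
                        val_perplexity = NA_real_, val_accuracy = NA_real_)
      if (!is.null(val_groups) && (ep %% log_every == 0L || ep == epochs)) {
        vm <- evaluate_groups(model, val_groups)
        row$val_perplexity <- vm$perplexity
        row$val_accuracy <- vm$accuracy
      }
      log <- rbind(log, row)
      if (verbose && (ep %% log_every == 0L || ep == epochs)) {
        message(sprintf("epoch %4d  loss %.4f%s", ep, row$loss,
                        if (!is.na(row$val_perplexity))
                          sprintf("  val ppl %.4f  val acc %.3f",
                                  row$val_perplexity, row$val_accuracy) else ""))
      }
    }
  })
  model$log <- log
  model
}

#' Mean perplexity and accuracy of a model over conformer groups
#' @param model a `ribodesign_model`.
#' @param groups list of [conformer_group()].
#' @export
evaluate_groups <- function(model, groups) {
  pp <- acc <- numeric(length(groups))
  for (k in seq_along(groups)) {
    probs <- predict_probabilities(model, groups[[k]])
    pp[k] <- seq_perplexity(probs, groups[[k]]$sequence)
    acc[k] <- seq_accuracy(probs, groups[[k]]$sequence)
  }
  list(perplexity = mean(pp), accuracy = mean(acc))
}

#' @export
print.ribodesign_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Relational GVP-GNN RNA inverse-design model (%s decoder, %s edges)\n",
              toupper(cfg$decoder), cfg$edge_types))
  cat(sprintf("  layers: %d | node dims: (%d, %d) | edge dims: (%d, %d)\n",
              cfg$num_layers, cfg$node_dims[1], cfg$node_dims[2],
              cfg$edge_dims[1], cfg$edge_dims[2]))
  cat(sprintf("  epochs trained: %d", x$epochs_trained))
  if (nrow(x$log)) cat(sprintf(" | final loss: %.4f", utils::tail(x$log$loss, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.ribodesign_model <- function(object, ...) {
  print(object)
  w <- coef(object)
  cat("Learned edge-type pooling weights:\n")
  print(round(w, 4))
  invisible(list(edge_type_weights = w, log = object$log))
}

#' Learned per-layer edge-type pooling weights
#' @param object a `ribodesign_model`.
#' @param ... unused.
#' @return matrix (layers x edge types).
#' @export
coef.ribodesign_model <- function(object, ...) {
  t(vapply(object$params$layers,
           function(lp) vapply(lp$w, as.numeric, 1),
           numeric(length(object$config$types))))
}

#' @export
predict.ribodesign_model <- function(object, group, ...) {
  predict_probabilities(object, group, ...)
}

#' @export
simulate.ribodesign_model <- function(object, nsim = object$config$n_samples,
                                      seed = 0L, group, temperature = 1, ...) {
  sample_sequences(object, group, n = nsim, temperature = temperature, seed = seed)
}

#' @export
plot.ribodesign_model <- function(x, ...) {
  if (!nrow(x$log)) {
    warning("no training log to plot")
    return(invisible(x))
  }
  graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "ribodesign training", ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are runtime artifacts; the RDS form reloads to bit-identical
#' evaluation. `write_checkpoint_json()` additionally exports parameters and
#' config as portable JSON.
#' @param model a `ribodesign_model`.
#' @param path file path.
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ribodesign_model"))
  model
}

#' @rdname write_checkpoint
#' @export
write_checkpoint_json <- function(model, path) {
  flat <- flatten_params(model$params)
  cfg <- unclass(model$config)
  cfg$spatial <- unclass(cfg$spatial)
  payload <- list(version = 1L,
                  config = cfg,
                  dims = lapply(flat, dim),
                  params = lapply(flat, as.numeric))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
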