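#' Perplexity of a reference sequence under predicted probabilities
#'
#' Exponential of the mean negative log-probability of the reference letters
#' over unmasked positions (letter `N` is masked out).
#'
#' @param probs L x 4 row-stochastic matrix (columns A, C, G, U).
#' @param reference reference sequence.
#' @export
seq_perplexity <- function(probs, reference) {
  labels <- seq_to_labels(reference)
  stopifnot(nrow(probs) == length(labels))
  keep <- !is.na(labels)
  p <- probs[cbind(which(keep), labels[keep])]
  if (any(p == 0)) {
    warning("zero probability at a reference letter; perplexity is infinite")
    return(Inf)
  }
  exp(-mean(log(p)))
}

#' Accuracy: fraction of positions whose argmax matches the reference
#'
#' Ties in the argmax break by fixed letter order A < C < G < U.
#' @inheritParams seq_perplexity
#' @export
seq_accuracy <- function(probs, reference) {
  labels <- seq_to_labels(reference)
  stopifnot(nrow(probs) == length(labels))
  keep <- !is.na(labels)
  pred <- apply(probs, 1, which.max)   # first max = fixed A<C<G<U tie-break
  mean(pred[keep] == labels[keep])
}

#' Native sequence recovery of a sample population
#'
#' Mean over sampled sequences of per-position identity to the reference
#' (masked positions excluded).
#' @param samples character vector of designed sequences.
#' @param reference native sequence.
#' @export
seq_recovery <- function(samples, reference) {
  stopifnot(length(samples) >= 1L)
  ref <- strsplit(reference, "")[[1]]
  keep <- ref != "N"
  per <- vapply(samples, function(s) {
    sc <- strsplit(s, "")[[1]]
    if (length(sc) != length(ref)) {
      stop(sprintf("sample length %d does not match reference length %d",
                   length(sc), length(ref)))
    }
    mean(sc[keep] == ref[keep])
  }, 1)
  mean(per)
}

#' Matthews correlation between two base-pair sets
#'
#' Confusion counts are taken over all `choose(L, 2)` unordered position
#' pairs. Both sets empty is defined as perfect agreement (1); a zero
#' denominator otherwise yields 0.
#' @param predicted,reference [basepair_set()] objects over the same L.
#' @param L sequence length.
#' @export
mcc_basepairs <- function(predicted, reference, L) {
  key <- function(bp) if (nrow(bp$pairs)) paste(bp$pairs[, 1], bp$pairs[, 2]) else character(0)
  kp <- key(predicted); kr <- key(reference)
  tp <- length(intersect(kp, kr))
  fp <- length(setdiff(kp, kr))
  fn <- length(setdiff(kr, kp))
  tn <- choose(L, 2) - tp - fp - fn
  if (tp + fp + fn == 0) return(1)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Secondary-structure self-consistency score
#'
#' For each sampled sequence, a secondary-structure predictor proposes a
#' base-pair set which is compared to the reference pairs by Matthews
#' correlation over all unordered position pairs; the score is the mean over
#' samples. Samples whose prediction fails are skipped and counted.
#'
#' @param samples character vector of designed sequences.
#' @param reference_pairs [basepair_set()] of the template.
#' @param predictor function(sequence) -> [basepair_set()]; e.g.
#'   [predict_pairs_nussinov()] or an adapter around an external tool.
#' @return the mean score, with attributes `n_used` and `n_failed`.
#' @export
sc_score <- function(samples, reference_pairs, predictor) {
  L <- reference_pairs$L
  vals <- numeric(0)
  failed <- 0L
  for (s in samples) {
    pred <- tryCatch(predictor(s), error = function(e) e)
    if (inherits(pred, "error")) {
      failed <- failed + 1L
      next
    }
    vals <- c(vals, mcc_basepairs(pred, reference_pairs, L))
  }
  if (length(vals) == 0L) stop("secondary-structure predictor failed on every sample")
  out <- mean(vals)
  attr(out, "n_used") <- length(vals)
  attr(out, "n_failed") <- failed
  out
}

can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

#' Maximum-pairing secondary structure (Nussinov stand-in predictor)
#'
#' A simple base-pair-maximisation dynamic program (Watson-Crick + wobble,
#' minimum loop length 3). This is a stand-in predictor for tests and
#' offline runs, NOT EternaFold or any thermodynamic model; plug an external
#' adapter into [sc_score()] for publication-grade self-consistency.
#'
#' @param sequence RNA sequence.
#' @param min_loop minimum unpaired span inside a hairpin.
#' @return [basepair_set()]
#' @export
predict_pairs_nussinov <- function(sequence, min_loop = 3L) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < min_loop + 2L) return(basepair_set(NULL, n))
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]                                  # i unpaired
      if (can_pair(s[i], s[j])) {
        inner <- if (i + 1L <= j - 1L) M[i + 1L, j - 1L] else 0L
        best <- max(best, inner + 1L)
      }
      if (j > i + 1L) {
        for (k in (i + 1L):(j - 1L)) {                      # bifurcation
          best <- max(best, M[i, k] + M[k + 1L, j])
        }
      }
      M[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  stack_ <- list(c(1L, n))
  while (length(stack_)) {
    ij <- stack_[[length(stack_)]]
    stack_[[length(stack_)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    if (M[i, j] == M[i + 1L, j]) {
      stack_[[length(stack_) + 1L]] <- c(i + 1L, j)
      next
    }
    inner <- if (i + 1L <= j - 1L) M[i + 1L, j - 1L] else 0L
    if (can_pair(s[i], s[j]) && M[i, j] == inner + 1L) {
      pairs <- rbind(pairs, c(i, j))
      stack_[[length(stack_) + 1L]] <- c(i + 1L, j - 1L)
      next
    }
    done <- FALSE
    for (k in (i + 1L):(j - 1L)) {
      if (M[i, j] == M[i, k] + M[k + 1L, j]) {
        stack_[[length(stack_) + 1L]] <- c(i, k)
        stack_[[length(stack_) + 1L]] <- c(k + 1L, j)
        done <- TRUE
        break
      }
    }
    if (!done) stack_[[length(stack_) + 1L]] <- c(i + 1L, j)
  }
  basepair_set(pairs, n)
}

#' Parse dot-bracket notation into a base-pair set
#'
#' Supports nested bracket alphabets `()`, `[]`, `{}`, `<>`.
#' @param db dot-bracket string.
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  openers <- c("(" = ")", "[" = "]", "{" = "}", "<" = ">")
  stacks <- list("(" = integer(0), "[" = integer(0), "{" = integer(0), "<" = integer(0))
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% names(openers)) {
      stacks[[ch]] <- c(stacks[[ch]], i)
    } else if (ch %in% openers) {
      op <- names(openers)[match(ch, openers)]
      k <- length(stacks[[op]])
      if (k == 0L) stop(sprintf("unbalanced '%s' at position %d", ch, i))
      pairs <- rbind(pairs, c(stacks[[op]][k], i))
      stacks[[op]] <- stacks[[op]][-k]
    }
  }
  if (any(vapply(stacks, length, 1L) > 0L)) stop("unbalanced brackets in dot-bracket string")
  basepair_set(pairs, length(chars))
}

#' RNAfold-based secondary structure predictor (external adapter)
#'
#' Returns a predictor closure around the ViennaRNA `RNAfold` command-line
#' tool (minimum free energy structure) when it is available on the PATH.
#' @export
predictor_rnafold <- function() {
  if (Sys.which("RNAfold") == "") stop("RNAfold not found on PATH")
  function(sequence) {
    out <- system2("RNAfold", c("--noPS"), input = sequence, stdout = TRUE)
    db <- strsplit(utils::tail(out, 1), " ")[[1]][1]
    parse_dotbracket(db)
  }
}

#' Bundle design samples with their evaluation metrics
#'
#' @param probs L x 4 probability matrix.
#' @param samples sampled sequences.
#' @param reference native sequence.
#' @param reference_pairs optional [basepair_set()] for the sc score.
#' @param predictor optional secondary-structure predictor for the sc score.
#' @return object of class `design_output` (list of metric values, samples
#'   and probabilities).
#' @export
design_output <- function(probs, samples, reference, reference_pairs = NULL,
                          predictor = NULL) {
  out <- list(probabilities = probs, samples = samples, reference = reference,
              perplexity = seq_perplexity(probs, reference),
              accuracy = seq_accuracy(probs, reference),
              recovery = seq_recovery(samples, reference),
              sc_score = if (!is.null(reference_pairs) && !is.null(predictor)) {
                as.numeric(sc_score(samples, reference_pairs, predictor))
              } else NA_real_)
  structure(out, class = "design_output")
}

#' @export
print.design_output <- function(x, ...) {
  cat(sprintf("design_output: %d samples over %d nt\n",
              length(x$samples), nchar(x$reference)))
  cat(sprintf("  perplexity %.4f | accuracy %.4f | recovery %.4f | sc %.4f\n",
              x$perplexity, x$accuracy, x$recovery, x$sc_score))
  invisible(x)
}
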