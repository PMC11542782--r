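# The Siamese metric-learning model.
#
# Twin subnetworks with a single shared parameter set:
#   token lookup table ((vocab_size + 1) x lookup_dim, row 1 = index 0)
#   -> LSTM with `recurrent_units` units (tanh cell activation), returning
#      the full per-position state sequence
#   -> flatten to max_len * recurrent_units
#   -> affine projection to `embedding_dim` (no nonlinearity).
# The similarity head is the Euclidean distance between the two embeddings;
# the model output s = sigmoid(distance_scale * (d - 1)) is regressed toward
# the pair target (0 same class, 1 different class) with binary
# cross-entropy, so same-class pairs are pulled toward distance 0 and
# different-class pairs pushed beyond distance 1. A contrastive loss
# (margin 1) is available behind `loss = "contrastive"`.
#
# Forward and backward passes are written as batched dense-matrix operations
# (BLAS); training uses Adam. All randomness (initialization, epoch
# shuffles) flows from `config$seed`, so training is reproducible.

#' Model configuration for the Siamese encoder
#'
#' Defaults follow the published recipe: 256-dimensional token lookup, an
#' LSTM with 64 units, a 32-dimensional embedding, 3 epochs at batch size
#' 64. No hyperparameter tuning is assumed anywhere.
#'
#' @param vocab_size number of known tokens (index 0 for OOV/padding is
#'   added internally).
#' @param max_len encoded sequence length.
#' @param lookup_dim token lookup dimension (default 256).
#' @param recurrent_units LSTM units (default 64).
#' @param embedding_dim output embedding dimension (default 32).
#' @param epochs,batch_size training schedule (defaults 3 and 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed driving initialization and shuffling.
#' @param distance_scale slope of the sigmoid head, s =
#'   sigmoid(distance_scale * (d - 1)); default 4 centers the decision
#'   boundary at d = 1.
#' @param loss `"bce"` (default) or `"contrastive"` (margin `margin`).
#' @param margin contrastive-loss margin (default 1).
#' @return A `siamese_config` list.
#' @export
siamese_config <- function(vocab_size, max_len, lookup_dim = 256L,
                           recurrent_units = 64L, embedding_dim = 32L,
                           epochs = 3L, batch_size = 64L,
                           learning_rate = 1e-3, seed = 1L,
                           distance_scale = 4, loss = c("bce", "contrastive"),
                           margin = 1) {
  loss <- match.arg(loss)
  dims <- c(vocab_size = vocab_size, max_len = max_len, lookup_dim = lookup_dim,
            recurrent_units = recurrent_units, embedding_dim = embedding_dim,
            epochs = epochs, batch_size = batch_size)
  if (any(dims < 1)) {
    stop("nonpositive model dimension/schedule value: ",
         paste(names(dims)[dims < 1], collapse = ", "))
  }
  stopifnot(learning_rate > 0, distance_scale > 0, margin > 0)
  structure(list(vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
                 lookup_dim = as.integer(lookup_dim),
                 recurrent_units = as.integer(recurrent_units),
                 embedding_dim = as.integer(embedding_dim),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 distance_scale = distance_scale, loss = loss, margin = margin),
            class = "siamese_config")
}

# fast sigmoid; stats::plogis carries option overhead that dominates here
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

init_weights <- function(config) {
  U <- config$recurrent_units
  D <- config$lookup_dim
  b <- numeric(4L * U)
  b[U + seq_len(U)] <- 1              # forget-gate bias at 1, the usual LSTM start
  list(
    E  = matrix(stats::runif((config$vocab_size + 1L) * D, -0.05, 0.05),
                config$vocab_size + 1L, D),
    Wx = glorot_uniform(D, 4L * U),
    Wh = glorot_uniform(U, 4L * U),
    b  = b,
    Wd = glorot_uniform(config$max_len * U, config$embedding_dim),
    bd = numeric(config$embedding_dim)
  )
}

#' Build an (untrained) Siamese encoder
#'
#' @param config a [siamese_config()].
#' @return A `siamese_encoder` with deterministically seeded initial weights,
#'   an empty training history and no vocabulary attached yet.
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "siamese_config"))
  weights <- with_seed(config$seed, init_weights(config))
  structure(list(weights = weights, config = config, vocab = NULL,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      pair_accuracy = numeric())),
            class = "siamese_encoder")
}

# Shared-subnetwork forward pass. X: n x max_len integer matrix.
# Returns list(Z = n x embedding_dim embeddings, cache for backprop).
encoder_forward <- function(W, X, config, cache = FALSE) {
  n <- nrow(X)
  Tt <- config$max_len
  U <- config$recurrent_units
  iu <- seq_len(U); fu <- U + iu; gu <- 2L * U + iu; ou <- 3L * U + iu
  H <- C <- matrix(0, n, U)
  Fl <- matrix(0, n, Tt * U)
  cc <- if (cache) list(i = vector("list", Tt), f = vector("list", Tt),
                        g = vector("list", Tt), o = vector("list", Tt),
                        C = vector("list", Tt), Hprev = vector("list", Tt),
                        idx = vector("list", Tt))
  brow <- rep(W$b, each = n)
  for (t in seq_len(Tt)) {
    idx <- X[, t] + 1L
    Xe <- W$E[idx, , drop = FALSE]
    A <- Xe %*% W$Wx + H %*% W$Wh + brow
    i <- sigmoid(A[, iu, drop = FALSE])
    f <- sigmoid(A[, fu, drop = FALSE])
    g <- tanh(A[, gu, drop = FALSE])
    o <- sigmoid(A[, ou, drop = FALSE])
    Cn <- f * C + i * g
    Hn <- o * tanh(Cn)
    if (cache) {
      cc$i[[t]] <- i; cc$f[[t]] <- f; cc$g[[t]] <- g; cc$o[[t]] <- o
      cc$C[[t]] <- Cn; cc$Hprev[[t]] <- H; cc$idx[[t]] <- idx
    }
    C <- Cn; H <- Hn
    Fl[, (t - 1L) * U + iu] <- H
  }
  Z <- Fl %*% W$Wd + rep(W$bd, each = n)
  if (cache) { cc$Fl <- Fl; cc$Cprev0 <- matrix(0, n, U) }
  list(Z = Z, cache = cc)
}

# Backward pass for one twin; dZ is the gradient of the loss w.r.t. Z.
encoder_backward <- function(W, cache, dZ, config) {
  n <- nrow(dZ)
  Tt <- config$max_len
  U <- config$recurrent_units
  iu <- seq_len(U)
  dWd <- crossprod(cache$Fl, dZ)
  dbd <- colSums(dZ)
  dFl <- tcrossprod(dZ, W$Wd)
  dH <- dC <- matrix(0, n, U)
  dWx <- matrix(0, nrow(W$Wx), ncol(W$Wx))
  dWh <- matrix(0, nrow(W$Wh), ncol(W$Wh))
  db <- numeric(length(W$b))
  dXe_all <- vector("list", Tt)
  for (t in rev(seq_len(Tt))) {
    i <- cache$i[[t]]; f <- cache$f[[t]]; g <- cache$g[[t]]; o <- cache$o[[t]]
    Ct <- cache$C[[t]]
    Cprev <- if (t > 1L) cache$C[[t - 1L]] else cache$Cprev0
    tC <- tanh(Ct)
    dHt <- dFl[, (t - 1L) * U + iu, drop = FALSE] + dH
    do <- dHt * tC
    dCt <- dC + dHt * o * (1 - tC^2)
    di <- dCt * g
    dg <- dCt * i
    df <- dCt * Cprev
    dC <- dCt * f
    dA <- matrix(0, n, 4L * U)
    dA[, iu] <- di * i * (1 - i)
    dA[, U + iu] <- df * f * (1 - f)
    dA[, 2L * U + iu] <- dg * (1 - g^2)
    dA[, 3L * U + iu] <- do * o * (1 - o)
    Xe <- W$E[cache$idx[[t]], , drop = FALSE]
    dWx <- dWx + crossprod(Xe, dA)
    dWh <- dWh + crossprod(cache$Hprev[[t]], dA)
    db <- db + colSums(dA)
    dH <- tcrossprod(dA, W$Wh)
    dXe_all[[t]] <- tcrossprod(dA, W$Wx)
  }
  all_idx <- unlist(cache$idx, use.names = FALSE)
  agg <- rowsum(do.call(rbind, dXe_all), group = all_idx, reorder = FALSE)
  dE <- matrix(0, nrow(W$E), ncol(W$E))
  dE[as.integer(rownames(agg)), ] <- agg
  list(E = dE, Wx = dWx, Wh = dWh, b = db, Wd = dWd, bd = dbd)
}

# Head: distances, model outputs, loss and d(loss)/d(distance) for a batch.
siamese_head <- function(Za, Zb, target, config) {
  diff <- Za - Zb
  d <- sqrt(rowSums(diff^2) + 1e-12)
  s <- sigmoid(config$distance_scale * (d - 1))
  n <- length(d)
  if (config$loss == "bce") {
    sc <- pmin(pmax(s, 1e-12), 1 - 1e-12)
    loss <- -mean(target * log(sc) + (1 - target) * log(1 - sc))
    dd <- config$distance_scale * (s - target) / n
  } else {
    hinge <- pmax(0, config$margin - d)
    loss <- mean((1 - target) * d^2 + target * hinge^2)
    dd <- (2 * d * (1 - target) - 2 * hinge * target) / n
  }
  list(d = d, s = s, loss = loss, dd = dd, diff = diff,
       acc = mean((s >= 0.5) == (target == 1L)))
}

#' Train the Siamese encoder on labeled pairs
#'
#' Both twins share one parameter set: every gradient step updates the
#' single subnetwork with the summed gradients from both inputs. The
#' optimizer is Adam at `config$learning_rate`; pairs are reshuffled each
#' epoch under the config seed.
#'
#' @param pairs a [generate_pairs()] result containing both targets.
#' @param config a [siamese_config()].
#' @return A trained `siamese_encoder`; `$history` holds per-epoch mean loss
#'   and thresholded pair accuracy (s >= 0.5 predicts "different").
#' @export
train_siamese <- function(pairs, config) {
  stopifnot(inherits(pairs, "crf_pairs"), inherits(config, "siamese_config"))
  if (length(unique(pairs$target)) < 2L) {
    stop("training pairs must contain both same-class and different-class targets")
  }
  if (ncol(pairs$seq_a) != config$max_len) {
    stop("pair sequence length (", ncol(pairs$seq_a),
         ") does not match config$max_len (", config$max_len, ")")
  }
  W <- with_seed(config$seed, init_weights(config))
  m <- lapply(W, function(w) w * 0)
  v <- lapply(W, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  P <- length(pairs$target)
  history <- data.frame(epoch = integer(), loss = numeric(), pair_accuracy = numeric())
  with_seed(stage_seed(config$seed, 17L), {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(P)
      ep_loss <- 0; ep_correct <- 0
      starts <- seq(1L, P, by = config$batch_size)
      for (s0 in starts) {
        bi <- perm[s0:min(s0 + config$batch_size - 1L, P)]
        nb <- length(bi)
        tg <- pairs$target[bi]
        # both twins share one parameter set: stack them into a single
        # forward/backward pass, whose gradients sum over the stack exactly
        # as the twin-weight-sharing contract requires
        fw <- encoder_forward(W, rbind(pairs$seq_a[bi, , drop = FALSE],
                                       pairs$seq_b[bi, , drop = FALSE]),
                              config, cache = TRUE)
        Za <- fw$Z[seq_len(nb), , drop = FALSE]
        Zb <- fw$Z[nb + seq_len(nb), , drop = FALSE]
        head <- siamese_head(Za, Zb, tg, config)
        if (!is.finite(head$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        dZa <- head$diff * (head$dd / head$d)
        grads <- encoder_backward(W, fw$cache, rbind(dZa, -dZa), config)
        step <- step + 1L
        for (nm in names(W)) {
          gr <- grads[[nm]]
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gr
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gr^2
          mh <- m[[nm]] / (1 - beta1^step)
          vh <- v[[nm]] / (1 - beta2^step)
          W[[nm]] <- W[[nm]] - config$learning_rate * mh / (sqrt(vh) + eps)
        }
        ep_loss <- ep_loss + head$loss * nb
        ep_correct <- ep_correct + head$acc * nb
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / P,
                                           pair_accuracy = ep_correct / P))
    }
  })
  structure(list(weights = W, config = config, vocab = NULL, history = history),
            class = "siamese_encoder")
}

#' Embed encoded sequences
#'
#' Deterministic forward pass through the shared subnetwork only (the
#' distance head is not applied).
#'
#' @param encoder a `siamese_encoder`.
#' @param seqs integer vector of length `max_len`, or a matrix with
#'   `max_len` columns (one sequence per row).
#' @return numeric matrix, one `embedding_dim`-vector per row.
#' @export
embed_sequences <- function(encoder, seqs) {
  stopifnot(inherits(encoder, "siamese_encoder"))
  if (is.null(dim(seqs))) seqs <- matrix(seqs, nrow = 1L)
  if (ncol(seqs) != encoder$config$max_len) {
    stop("sequence length (", ncol(seqs), ") does not match config$max_len (",
         encoder$config$max_len, ")")
  }
  encoder_forward(encoder$weights, seqs, encoder$config)$Z
}

#' Euclidean distance between two embedding vectors
#'
#' The similarity metric of both the training head and the k-NN suggester:
#' sqrt of the sum of squared componentwise differences.
#'
#' @param a,b numeric vectors of equal length.
#' @return nonnegative real.
#' @export
pair_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("embedding dimension mismatch: ", length(a), " vs ", length(b))
  }
  sqrt(sum((a - b)^2))
}

#' Thresholded pair accuracy of a trained encoder
#'
#' Recomputes the head output s on every pair and scores s >= 0.5 as a
#' "different" prediction against the stored targets.
#'
#' @param encoder trained `siamese_encoder`.
#' @param pairs a `crf_pairs`.
#' @param chunk batch size for the forward passes.
#' @return fraction of pairs classified correctly.
#' @export
pair_accuracy <- function(encoder, pairs, chunk = 512L) {
  P <- length(pairs$target)
  correct <- 0
  for (s0 in seq(1L, P, by = chunk)) {
    bi <- s0:min(s0 + chunk - 1L, P)
    Za <- embed_sequences(encoder, pairs$seq_a[bi, , drop = FALSE])
    Zb <- embed_sequences(encoder, pairs$seq_b[bi, , drop = FALSE])
    d <- sqrt(rowSums((Za - Zb)^2))
    s <- sigmoid(encoder$config$distance_scale * (d - 1))
    correct <- correct + sum((s >= 0.5) == (pairs$target[bi] == 1L))
  }
  correct / P
}

ENCODER_FORMAT <- "crfmapr-encoder/1"

#' Save / load a trained encoder
#'
#' The archive is a directory holding the weights (R native serialization),
#' the vocabulary as JSON, the config as YAML and a schema-version stamp.
#' `load_encoder(save_encoder(e, path))` reproduces `embed_sequences()`
#' outputs exactly.
#'
#' @param encoder trained `siamese_encoder`.
#' @param path archive directory (created if needed).
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "siamese_encoder"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(ENCODER_FORMAT, file.path(path, "FORMAT"))
  saveRDS(encoder$weights, file.path(path, "weights.rds"))
  cfg <- unclass(encoder$config)
  yaml::write_yaml(cfg, file.path(path, "config.yaml"))
  if (!is.null(encoder$vocab)) {
    save_vocabulary(encoder$vocab, file.path(path, "vocabulary.json"))
  }
  utils::write.csv(encoder$history, file.path(path, "history.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  fmt_file <- file.path(path, "FORMAT")
  if (!file.exists(fmt_file)) stop("not an encoder archive (missing FORMAT stamp): ", path)
  fmt <- readLines(fmt_file, n = 1L)
  if (!identical(fmt, ENCODER_FORMAT)) {
    stop("encoder archive schema mismatch: found '", fmt, "', expected '",
         ENCODER_FORMAT, "'")
  }
  weights <- tryCatch(readRDS(file.path(path, "weights.rds")),
                      error = function(e) stop("corrupt encoder archive: ",
                                               conditionMessage(e)))
  cfg <- yaml::read_yaml(file.path(path, "config.yaml"))
  config <- do.call(siamese_config, cfg[setdiff(names(cfg), NULL)])
  vocab_file <- file.path(path, "vocabulary.json")
  vocab <- if (file.exists(vocab_file)) load_vocabulary(vocab_file)
  history <- utils::read.csv(file.path(path, "history.csv"))
  structure(list(weights = weights, config = config, vocab = vocab,
                 history = history),
            class = "siamese_encoder")
}

#' @export
print.siamese_encoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<siamese_encoder> vocab %d+OOV -> lookup %d -> LSTM %d -> dense %d\n",
              cfg$vocab_size, cfg$lookup_dim, cfg$recurrent_units, cfg$embedding_dim))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s); final loss %.4f, pair accuracy %.4f\n",
                last$epoch, last$loss, last$pair_accuracy))
  } else cat("  untrained\n")
  invisible(x)
}
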