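# Multilayer-perceptron predictor head over feature blocks.
#
# Trunk: 5 fully connected layers, each Linear -> batch-norm -> ReLU ->
# dropout(p = 0.1). Two output heads share the trunk: `carc` is a single
# linear unit on the log-potency scale, `mut` a single linear unit with a
# logistic link for mutagenicity probability. Training mode uses batch
# statistics and dropout; eval mode is deterministic (running statistics,
# dropout off), so eval predictions are batch-composition invariant.
#
# Implemented in base R matrix algebra with explicit reverse-mode gradients
# and an Adam optimizer; loss is mean squared error for the carcinogenicity
# head and binary cross-entropy (on logits) for the mutagenicity head.

.BN_EPS <- 1e-5

#' Construct a predictor model
#'
#' @param input_dim feature-block length the model accepts.
#' @param hidden widths of the 5 trunk layers.
#' @param dropout dropout probability applied at every trunk layer.
#' @param seed RNG seed for weight initialization.
#' @param feature_cfg optional list describing how inputs are featurized
#'   (fingerprint schemes, radius, bit widths, embedding dim); stored so a
#'   checkpointed model can reproduce its own inputs.
#' @return a `PredictorModel`.
#' @export
predictor_model <- function(input_dim, hidden = c(1024L, 512L, 256L, 128L, 64L),
                            dropout = 0.1, seed = 1L, feature_cfg = NULL) {
  stopifnot(length(hidden) == 5L, input_dim >= 1L,
            dropout >= 0, dropout < 1)
  set.seed(seed)
  dims <- c(input_dim, hidden)
  trunk <- lapply(seq_len(5L), function(i) {
    fan_in <- dims[i]
    list(
      W = matrix(stats::rnorm(hidden[i] * fan_in, sd = sqrt(2 / fan_in)),
                 hidden[i], fan_in),
      b = rep(0, hidden[i]),
      gamma = rep(1, hidden[i]),
      beta = rep(0, hidden[i]),
      run_mean = rep(0, hidden[i]),
      run_var = rep(1, hidden[i])
    )
  })
  head_init <- function(fan_in) {
    list(W = matrix(stats::rnorm(fan_in, sd = sqrt(1 / fan_in)), 1L, fan_in),
         b = 0)
  }
  structure(
    list(input_dim = input_dim, hidden = hidden, dropout = dropout,
         momentum = 0.1, trunk = trunk,
         heads = list(carc = head_init(hidden[5L]),
                      mut = head_init(hidden[5L])),
         feature_cfg = feature_cfg),
    class = "PredictorModel"
  )
}

#' Forward pass of the predictor
#'
#' @param model a `PredictorModel`.
#' @param X numeric matrix (batch x input_dim) of feature blocks.
#' @param head `"carc"` (unbounded log-potency) or `"mut"` (probability).
#' @param mode `"eval"` (deterministic) or `"train"` (batch statistics,
#'   dropout; uses the R RNG for dropout masks).
#' @return numeric vector of predictions, one per row of `X`. With
#'   `mode = "train"` the attribute `"model"` carries the model with updated
#'   batch-norm running statistics and `"cache"` the internals needed for
#'   backprop.
#' @export
mlp_forward <- function(model, X, head = c("carc", "mut"),
                        mode = c("eval", "train")) {
  head <- match.arg(head)
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop("feature width ", ncol(X), " does not match model input width ",
         model$input_dim)
  }
  n <- nrow(X)
  train <- mode == "train"
  cache <- if (train) list(layers = vector("list", 5L)) else NULL
  A <- X
  for (i in seq_len(5L)) {
    ly <- model$trunk[[i]]
    Z <- A %*% t(ly$W) + matrix(ly$b, n, length(ly$b), byrow = TRUE)
    if (train) {
      mu <- colMeans(Z)
      va <- colMeans(Z^2) - mu^2
      model$trunk[[i]]$run_mean <- (1 - model$momentum) * ly$run_mean +
        model$momentum * mu
      model$trunk[[i]]$run_var <- (1 - model$momentum) * ly$run_var +
        model$momentum * va
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
    }
    inv_sd <- 1 / sqrt(va + .BN_EPS)
    Zhat <- sweep(sweep(Z, 2L, mu, "-"), 2L, inv_sd, "*")
    Y <- sweep(sweep(Zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    H <- pmax(Y, 0)
    if (train && model$dropout > 0) {
      keep <- matrix(stats::rbinom(length(H), 1L, 1 - model$dropout),
                     nrow(H), ncol(H)) / (1 - model$dropout)
      Hd <- H * keep
    } else {
      keep <- NULL
      Hd <- H
    }
    if (train) {
      cache$layers[[i]] <- list(A_in = A, Zhat = Zhat, inv_sd = inv_sd,
                                Y = Y, keep = keep)
    }
    A <- Hd
  }
  hd <- model$heads[[head]]
  z <- as.numeric(A %*% t(hd$W) + hd$b)
  pred <- if (head == "mut") 1 / (1 + exp(-z)) else z
  if (train) {
    cache$A_out <- A
    cache$logit <- z
    attr(pred, "model") <- model
    attr(pred, "cache") <- cache
  }
  pred
}

# Loss and full parameter gradients for one training batch.
# Returns list(loss, grads, model) where model carries updated running stats.
.mlp_loss_grad <- function(model, X, y, head) {
  n <- nrow(X)
  pred <- mlp_forward(model, X, head = head, mode = "train")
  model <- attr(pred, "model")
  cache <- attr(pred, "cache")
  z <- cache$logit
  if (head == "carc") {
    loss <- mean((z - y)^2)
    dz <- 2 * (z - y) / n
  } else {
    p <- 1 / (1 + exp(-z))
    loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
    dz <- (p - y) / n
  }
  grads <- list(trunk = vector("list", 5L), heads = list())
  hd <- model$heads[[head]]
  grads$heads[[head]] <- list(
    W = matrix(colSums(dz * cache$A_out), 1L),
    b = sum(dz)
  )
  dA <- dz %*% hd$W   # n x w5
  for (i in 5:1) {
    ly <- model$trunk[[i]]
    cc <- cache$layers[[i]]
    if (!is.null(cc$keep)) dA <- dA * cc$keep
    dY <- dA * (cc$Y > 0)
    dgamma <- colSums(dY * cc$Zhat)
    dbeta <- colSums(dY)
    dZhat <- sweep(dY, 2L, ly$gamma, "*")
    m1 <- colMeans(dZhat)
    m2 <- colMeans(dZhat * cc$Zhat)
    dZ <- sweep(
      dZhat - matrix(m1, n, length(m1), byrow = TRUE) -
        cc$Zhat * matrix(m2, n, length(m2), byrow = TRUE),
      2L, cc$inv_sd, "*"
    )
    grads$trunk[[i]] <- list(
      W = t(dZ) %*% cc$A_in,
      b = colSums(dZ),
      gamma = dgamma,
      beta = dbeta
    )
    if (i > 1L) dA <- dZ %*% ly$W
  }
  list(loss = loss, grads = grads, model = model)
}

.adam_init <- function() {
  list(m = list(), v = list(), t = 0L)
}

# Flat-path Adam over the nested gradient list.
.adam_step <- function(model, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(path, param, grad) {
    key <- paste(path, collapse = ".")
    m <- state$m[[key]]; v <- state$v[[key]]
    if (is.null(m)) { m <- param * 0; v <- param * 0 }
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    state$m[[key]] <<- m
    state$v[[key]] <<- v
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    param - lr * mh / (sqrt(vh) + eps)
  }
  for (i in seq_len(5L)) {
    for (p in c("W", "b", "gamma", "beta")) {
      model$trunk[[i]][[p]] <- upd(c("trunk", i, p),
                                   model$trunk[[i]][[p]],
                                   grads$trunk[[i]][[p]])
    }
  }
  for (h in names(grads$heads)) {
    for (p in c("W", "b")) {
      model$heads[[h]][[p]] <- upd(c("head", h, p),
                                   model$heads[[h]][[p]],
                                   grads$heads[[h]][[p]])
    }
  }
  list(model = model, state = state)
}

#' Predict for a list of molecules
#'
#' Featurizes the molecules according to the model's stored feature
#' configuration, obtains graph embeddings from the supplied provider, and
#' runs a deterministic eval-mode forward pass. Output order follows input
#' order, and (eval-mode batch-norm) predictions do not depend on batch
#' composition.
#'
#' @param model a `PredictorModel` with a `feature_cfg`.
#' @param molecules list of `Molecule` objects.
#' @param encoder either an `EncoderParams` (embeddings computed on the fly),
#'   a provider function from [load_external_embeddings()], or `NULL` if the
#'   model uses no graph embedding.
#' @param head prediction head.
#' @return numeric vector of predictions named by molecule id.
#' @export
predict_batch <- function(model, molecules, encoder = NULL,
                          head = c("carc", "mut")) {
  head <- match.arg(head)
  stopifnot(inherits(model, "PredictorModel"), length(molecules) >= 1L)
  X <- featurize_molecules(molecules, model$feature_cfg, encoder)
  out <- mlp_forward(model, X, head = head, mode = "eval")
  names(out) <- vapply(molecules, function(m) m$id, "")
  out
}

#' Featurize molecules per a feature configuration
#'
#' @param molecules list of `Molecule`s.
#' @param feature_cfg list with `schemes` (subset of circular/path/
#'   structural_key), `radius`, `n_bits`, and `embedding_dim` (0 for none).
#' @param encoder `EncoderParams`, provider function, or `NULL`.
#' @return numeric feature matrix, one row per molecule.
#' @export
featurize_molecules <- function(molecules, feature_cfg, encoder = NULL) {
  cfg <- feature_cfg
  if (is.null(cfg)) {
    cfg <- list(schemes = c("circular", "path", "structural_key"),
                radius = 2L, n_bits = 2048L, embedding_dim = 0L)
  }
  parts <- lapply(cfg$schemes, function(sc) {
    fingerprint_matrix(molecules, sc, radius = cfg$radius,
                       n_bits = cfg$n_bits)
  })
  if (!is.null(cfg$embedding_dim) && cfg$embedding_dim > 0L) {
    if (is.null(encoder)) stop("model expects a graph embedding provider")
    E <- if (inherits(encoder, "EncoderParams")) {
      encode_molecules(molecules, encoder)
    } else {
      encoder(vapply(molecules, function(m) m$id, ""))
    }
    if (ncol(E) != cfg$embedding_dim) {
      stop("embedding dimension ", ncol(E), " does not match configured ",
           cfg$embedding_dim)
    }
    parts <- c(parts, list(E))
  }
  do.call(cbind, parts)
}
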