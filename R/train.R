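# Training engine: leakage-free splitting on canonical SMILES, early-stopped
# single-phase training, multi-round mutagenicity <-> carcinogenicity
# alternation, threefold-CV hyperparameter sweeps, and top-3 ensembling.

#' Training configuration
#'
#' @param rounds number of mutagenicity->carcinogenicity alternation cycles
#'   (default 3; performance gains saturate there).
#' @param patience early-stopping patience in epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs cap on epochs per phase.
#' @param seed RNG seed controlling shuffling and dropout.
#' @return a `TrainConfig` list.
#' @export
train_config <- function(rounds = 3L, patience = 10L, lr = 1e-3,
                         batch_size = 64L, max_epochs = 200L, seed = 1L) {
  stopifnot(rounds >= 0L, patience >= 1L, max_epochs >= 1L, batch_size >= 2L)
  structure(list(rounds = rounds, patience = patience, lr = lr,
                 batch_size = batch_size, max_epochs = max_epochs,
                 seed = seed),
            class = "TrainConfig")
}

#' Deduplicating cross-validation split
#'
#' Groups molecules by canonical SMILES so that duplicate spellings of one
#' structure always land in the same fold: no canonical SMILES ever appears
#' on both sides of a split. Groups are assigned to the currently smallest
#' fold after a seeded shuffle, keeping folds near-equal in molecule count.
#'
#' @param molecules list of `Molecule` objects.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return data.frame: `molecule_id`, `canonical`, `fold` (0-based).
#' @export
dedup_split <- function(molecules, k = 3L, seed = 1L) {
  stopifnot(k >= 2L, length(molecules) >= 1L)
  ids <- vapply(molecules, function(m) m$id, "")
  can <- vapply(molecules, function(m) m$canonical_smiles, "")
  groups <- split(seq_along(molecules), can)
  if (length(groups) < k) stop("fewer unique structures than folds")
  set.seed(seed)
  ord <- sample(length(groups))
  fold_of_group <- integer(length(groups))
  sizes <- integer(k)
  for (g in ord) {
    tgt <- which.min(sizes)
    fold_of_group[g] <- tgt - 1L
    sizes[tgt] <- sizes[tgt] + length(groups[[g]])
  }
  fold <- integer(length(molecules))
  for (g in seq_along(groups)) fold[groups[[g]]] <- fold_of_group[g]
  data.frame(molecule_id = ids, canonical = can, fold = fold,
             stringsAsFactors = FALSE)
}

.phase_loss <- function(model, X, y, objective) {
  pred <- mlp_forward(model, X, head = objective, mode = "eval")
  if (objective == "carc") {
    mean((pred - y)^2)
  } else {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

#' Single-objective training phase with early stopping
#'
#' Runs minibatch Adam on one objective, monitoring validation loss after
#' every epoch; stops when the validation loss has failed to improve for
#' `patience` consecutive epochs and returns the best-validation checkpoint.
#'
#' @param model a `PredictorModel`.
#' @param X,y training features and labels (labels 0/1 for `"mut"`).
#' @param objective `"carc"` (MSE on log-potency) or `"mut"` (binary
#'   cross-entropy).
#' @param cfg a `TrainConfig`.
#' @param Xval,yval validation set for early stopping.
#' @return list: `model` (best checkpoint), `history` (data.frame epoch,
#'   train_loss, val_loss), `best_epoch`.
#' @export
train_phase <- function(model, X, y, objective = c("carc", "mut"), cfg,
                        Xval, yval) {
  objective <- match.arg(objective)
  X <- as.matrix(X); Xval <- as.matrix(Xval)
  if (nrow(X) == 0L || length(y) == 0L) stop("empty training set")
  if (nrow(Xval) == 0L || length(yval) == 0L) stop("empty validation set")
  stopifnot(nrow(X) == length(y), nrow(Xval) == length(yval))
  set.seed(cfg$seed)
  state <- .adam_init()
  # the best checkpoint is chosen among post-epoch models: epoch 1 always
  # becomes the incumbent, so an untrained model is never returned
  best <- list(model = model, loss = Inf, epoch = 0L)
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  n <- nrow(X)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0; nb <- 0L
    for (s in starts) {
      b <- idx[s:min(s + cfg$batch_size - 1L, n)]
      if (length(b) < 2L) next  # batch-norm needs >= 2 rows
      lg <- .mlp_loss_grad(model, X[b, , drop = FALSE], y[b], objective)
      model <- lg$model
      stepped <- .adam_step(model, lg$grads, state, lr = cfg$lr)
      model <- stepped$model
      state <- stepped$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- .phase_loss(model, Xval, yval, objective)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(model = model, loss = vl, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  list(model = best$model, history = hist, best_epoch = best$epoch)
}

#' Multi-round mutagenicity/carcinogenicity pre-training
#'
#' Executes `cfg$rounds` cycles of (mutagenicity phase -> carcinogenicity
#' phase), each phase early-stopped on its own validation loss; model weights
#' carry across phase boundaries while the optimizer state is reset, which is
#' the essence of the alternation. With `rounds = 0` this reduces to plain
#' carcinogenicity training. The final phase is always carcinogenicity.
#'
#' @param model a `PredictorModel`.
#' @param mut_data,carc_data lists with `X`, `y`, `Xval`, `yval`.
#' @param cfg a `TrainConfig`.
#' @return list: `model`, `phases` (character vector of executed phases),
#'   `histories` (per-phase training histories).
#' @export
multi_round_pretrain <- function(model, mut_data, carc_data, cfg) {
  phases <- character(0)
  histories <- list()
  run <- function(data, objective, phase_idx) {
    pcfg <- cfg
    pcfg$seed <- cfg$seed + 1000L * phase_idx
    train_phase(model, data$X, data$y, objective, pcfg, data$Xval, data$yval)
  }
  if (cfg$rounds == 0L) {
    fit <- run(carc_data, "carc", 1L)
    return(list(model = fit$model, phases = "carc",
                histories = list(fit$history)))
  }
  k <- 0L
  for (r in seq_len(cfg$rounds)) {
    k <- k + 1L
    fit <- run(mut_data, "mut", k)
    model <- fit$model
    phases <- c(phases, "mut"); histories <- c(histories, list(fit$history))
    k <- k + 1L
    fit <- run(carc_data, "carc", k)
    model <- fit$model
    phases <- c(phases, "carc"); histories <- c(histories, list(fit$history))
  }
  list(model = model, phases = phases, histories = histories)
}

#' Hyperparameter sweep with threefold cross-validation
#'
#' Trains every configuration on each fold (validating on the held-out
#' fold) and ranks configurations by mean validation Pearson correlation on
#' the carcinogenicity objective.
#'
#' @param grid list of configurations; each element is a list with optional
#'   `hidden`, `lr`, `batch_size`, `max_epochs`, `patience`, `dropout`.
#' @param X,y features and continuous labels.
#' @param folds fold assignment vector (0-based, as from [dedup_split()]).
#' @param seed RNG seed (model init and training).
#' @return data.frame ranked by `mean_score` (descending) with per-fold
#'   scores; attribute `"configs"` holds the grid in ranked order.
#' @export
sweep_configs <- function(grid, X, y, folds, seed = 1L) {
  stopifnot(length(grid) >= 1L, nrow(X) == length(y),
            length(folds) == length(y))
  kf <- sort(unique(folds))
  res <- lapply(seq_along(grid), function(ci) {
    g <- grid[[ci]]
    scores <- vapply(kf, function(f) {
      tr <- folds != f
      cfg <- train_config(
        rounds = 0L,
        patience = g$patience %||% 5L,
        lr = g$lr %||% 1e-3,
        batch_size = g$batch_size %||% 64L,
        max_epochs = g$max_epochs %||% 50L,
        seed = seed + ci
      )
      mod <- predictor_model(ncol(X), hidden = g$hidden %||%
                               c(64L, 32L, 32L, 16L, 8L),
                             dropout = g$dropout %||% 0.1,
                             seed = seed + ci)
      fit <- train_phase(mod, X[tr, , drop = FALSE], y[tr], "carc", cfg,
                         X[!tr, , drop = FALSE], y[!tr])
      pred <- mlp_forward(fit$model, X[!tr, , drop = FALSE], "carc", "eval")
      if (stats::sd(pred) == 0) 0 else pearson(pred, y[!tr])
    }, numeric(1))
    c(config = ci, mean_score = mean(scores),
      stats::setNames(scores, paste0("fold", kf)))
  })
  df <- as.data.frame(do.call(rbind, res))
  ord <- order(-df$mean_score)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "configs") <- grid[df$config]
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-k ensemble from ranked sweep results
#'
#' Retrains the top `k` configurations on the supplied train/validation data
#' and averages their predictions.
#'
#' @param ranked output of [sweep_configs()] (needs >= k rows).
#' @param X,y,Xval,yval training and early-stopping data.
#' @param k ensemble size (default 3).
#' @param seed RNG seed.
#' @return an `EnsembleModel` (list of member `PredictorModel`s).
#' @export
build_ensemble <- function(ranked, X, y, Xval, yval, k = 3L, seed = 1L) {
  configs <- attr(ranked, "configs")
  if (!is.null(configs)) configs <- configs[seq_len(min(length(configs),
                                                        nrow(ranked)))]
  if (is.null(configs) || length(configs) < k) {
    stop("need at least ", k, " ranked configurations")
  }
  members <- lapply(seq_len(k), function(i) {
    g <- configs[[i]]
    cfg <- train_config(rounds = 0L, patience = g$patience %||% 5L,
                        lr = g$lr %||% 1e-3,
                        batch_size = g$batch_size %||% 64L,
                        max_epochs = g$max_epochs %||% 50L,
                        seed = seed + i)
    mod <- predictor_model(ncol(X),
                           hidden = g$hidden %||% c(64L, 32L, 32L, 16L, 8L),
                           dropout = g$dropout %||% 0.1, seed = seed + i)
    train_phase(mod, X, y, "carc", cfg, Xval, yval)$model
  })
  structure(list(members = members, k = k), class = "EnsembleModel")
}

#' Ensemble prediction (arithmetic mean of member predictions)
#'
#' @param ens an `EnsembleModel`.
#' @param X feature matrix.
#' @param head prediction head.
#' @return numeric vector of averaged predictions.
#' @export
ensemble_predict <- function(ens, X, head = "carc") {
  stopifnot(inherits(ens, "EnsembleModel"))
  preds <- vapply(ens$members,
                  function(m) mlp_forward(m, X, head = head, mode = "eval"),
                  numeric(nrow(as.matrix(X))))
  rowMeans(as.matrix(preds))
}
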