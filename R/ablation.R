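# Benchmark harness: featurize a synthetic bundle once, then train and
# evaluate predictor variants that differ in architecture input (fingerprint
# only vs fingerprint + graph embedding) and pre-training regime (none,
# single mutagenicity pre-training round, multi-round alternation).
#
# Problem sizes here are deliberately desk-scale: a 512-bit circular
# fingerprint, a 32-dimensional frozen graph embedding, and a narrow
# 5-layer trunk keep a full ablation (tens of seeded runs) tractable on one
# CPU while preserving the qualitative structure of the full-size model.

#' Featurize a synthetic bundle for benchmarking
#'
#' Parses all bundle molecules, computes circular fingerprints and frozen
#' graph-encoder embeddings, and carves the training set into
#' train/validation/holdout partitions with the leakage-free
#' canonical-SMILES split.
#'
#' @param bundle a `SyntheticBundle`.
#' @param n_bits circular fingerprint width.
#' @param radius circular fingerprint radius.
#' @param encoder `EncoderParams` for the frozen graph embedder.
#' @param split_seed seed for the dedup split.
#' @return a `BenchmarkFeatures` list: per-role fingerprint and embedding
#'   matrices, labels, and index vectors `idx_train`, `idx_val`,
#'   `idx_holdout` into the training arrays.
#' @export
benchmark_features <- function(bundle, n_bits = 512L, radius = 2L,
                               encoder = encoder_params(
                                 L = 2L, hidden_dim = 32L, d = 32L,
                                 n_heads = 4L, seed = 100L),
                               split_seed = 1L) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  parse_role <- function(role) {
    parse_molecule_set(role$molecules$smiles, role$molecules$id)
  }
  tr <- parse_role(bundle$train)
  mu <- parse_role(bundle$mut)
  te <- parse_role(bundle$test)
  fp <- function(mols) fingerprint_matrix(mols, "circular",
                                          radius = radius, n_bits = n_bits)
  emb <- function(mols) encode_molecules(mols, encoder)

  # embedding columns are standardized on the training set: raw atom
  # features span orders of magnitude (atomic mass), and unscaled random
  # projections would dominate the binary fingerprint block
  e_tr <- emb(tr)
  mu_e <- colMeans(e_tr)
  sd_e <- apply(e_tr, 2L, stats::sd)
  sd_e[sd_e == 0] <- 1
  scale_emb <- function(E) sweep(sweep(E, 2L, mu_e, "-"), 2L, sd_e, "/")

  plan <- dedup_split(tr, k = 5L, seed = split_seed)
  idx_train <- which(plan$fold <= 2L)
  idx_val <- which(plan$fold == 3L)
  idx_holdout <- which(plan$fold == 4L)

  mu_plan <- dedup_split(mu, k = 5L, seed = split_seed + 1L)
  mu_train <- which(mu_plan$fold <= 3L)
  mu_val <- which(mu_plan$fold == 4L)

  ord_tr <- match(vapply(tr, function(m) m$id, ""),
                  bundle$train$labels$molecule_id)
  ord_mu <- match(vapply(mu, function(m) m$id, ""),
                  bundle$mut$labels$molecule_id)
  ord_te <- match(vapply(te, function(m) m$id, ""),
                  bundle$test$labels$molecule_id)

  structure(
    list(
      fp_train = fp(tr), emb_train = scale_emb(e_tr),
      y_train = bundle$train$labels$y[ord_tr],
      sentinel_train = bundle$train$labels$is_sentinel[ord_tr],
      fp_mut = fp(mu), emb_mut = scale_emb(emb(mu)),
      y_mut = bundle$mut$labels$y[ord_mu],
      fp_test = fp(te), emb_test = scale_emb(emb(te)),
      y_test = bundle$test$labels$y[ord_te],
      idx_train = idx_train, idx_val = idx_val, idx_holdout = idx_holdout,
      mu_train = mu_train, mu_val = mu_val,
      encoder = encoder, emb_center = mu_e, emb_scale = sd_e
    ),
    class = "BenchmarkFeatures"
  )
}

.variant_uses_embedding <- function(variant) {
  variant != "fingerprint"
}

.variant_rounds <- function(variant) {
  switch(variant,
         fingerprint = 0L, fingerprint_encoder = 0L,
         single_pretrain = 1L, multi_round = 3L,
         stop("unknown variant: ", variant))
}

#' Train and evaluate one ablation variant
#'
#' Variants: `"fingerprint"` (fingerprint MLP, no pre-training),
#' `"fingerprint_encoder"` (adds the frozen graph embedding),
#' `"single_pretrain"` (one mutagenicity->carcinogenicity cycle) and
#' `"multi_round"` (three cycles).
#'
#' @param feats `BenchmarkFeatures`.
#' @param variant variant name.
#' @param seed training seed (model init, shuffling, dropout).
#' @param hidden trunk widths.
#' @param cfg optional `TrainConfig` template; `rounds` is overridden by the
#'   variant.
#' @return list: `model`, `pearson_holdout`, `mse_holdout`, `pred_holdout`,
#'   `pred_test`, `roc_auc_test`, `pr_auc_test`, `variant`, `seed`.
#' @export
run_ablation_variant <- function(feats, variant, seed = 1L,
                                 hidden = c(64L, 32L, 32L, 16L, 8L),
                                 cfg = NULL) {
  stopifnot(inherits(feats, "BenchmarkFeatures"))
  use_emb <- .variant_uses_embedding(variant)
  bind <- function(fp, emb) if (use_emb) cbind(fp, emb) else fp
  Xtr <- bind(feats$fp_train, feats$emb_train)
  Xmu <- bind(feats$fp_mut, feats$emb_mut)
  Xte <- bind(feats$fp_test, feats$emb_test)
  if (is.null(cfg)) {
    cfg <- train_config(rounds = .variant_rounds(variant), patience = 4L,
                        lr = 1e-3, batch_size = 256L, max_epochs = 25L,
                        seed = seed)
  } else {
    cfg$rounds <- .variant_rounds(variant)
    cfg$seed <- seed
  }
  model <- predictor_model(ncol(Xtr), hidden = hidden, dropout = 0.1,
                           seed = seed)
  carc <- list(X = Xtr[feats$idx_train, , drop = FALSE],
               y = feats$y_train[feats$idx_train],
               Xval = Xtr[feats$idx_val, , drop = FALSE],
               yval = feats$y_train[feats$idx_val])
  mut <- list(X = Xmu[feats$mu_train, , drop = FALSE],
              y = feats$y_mut[feats$mu_train],
              Xval = Xmu[feats$mu_val, , drop = FALSE],
              yval = feats$y_mut[feats$mu_val])
  fit <- multi_round_pretrain(model, mut, carc, cfg)
  ph <- mlp_forward(fit$model, Xtr[feats$idx_holdout, , drop = FALSE],
                    "carc", "eval")
  yh <- feats$y_train[feats$idx_holdout]
  pt <- mlp_forward(fit$model, Xte, "carc", "eval")
  list(model = fit$model,
       pearson_holdout = pearson(ph, yh),
       mse_holdout = mse(ph, yh),
       pred_holdout = ph,
       pred_test = pt,
       roc_auc_test = roc_auc(pt, feats$y_test),
       pr_auc_test = pr_auc(pt, feats$y_test),
       variant = variant, seed = seed)
}

#' Seed-averaged ablation experiment
#'
#' Runs every requested variant across `n_seeds` matched seeds and reports
#' the per-seed holdout Pearson correlations, mirroring a matched-seed
#' ablation table.
#'
#' @param feats `BenchmarkFeatures`.
#' @param variants character vector of variant names.
#' @param n_seeds number of matched seeds.
#' @param seed0 first seed.
#' @param ... passed to [run_ablation_variant()].
#' @return list: `pearson` (matrix seeds x variants), `mean` (named vector).
#' @export
ablation_experiment <- function(feats,
                                variants = c("fingerprint",
                                             "fingerprint_encoder",
                                             "single_pretrain",
                                             "multi_round"),
                                n_seeds = 20L, seed0 = 1L, ...) {
  P <- matrix(NA_real_, n_seeds, length(variants),
              dimnames = list(NULL, variants))
  for (s in seq_len(n_seeds)) {
    for (v in variants) {
      P[s, v] <- run_ablation_variant(feats, v, seed = seed0 + s - 1L,
                                      ...)$pearson_holdout
    }
  }
  list(pearson = P, mean = colMeans(P))
}
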