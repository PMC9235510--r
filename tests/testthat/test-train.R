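make_reg_data <- function(n = 120, p = 30, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  y <- 2 * X[, 1] - 1.5 * X[, 2] + rnorm(n, sd = 0.2)
  list(X = X, y = y)
}

test_that("dedup splits never place one structure in two folds", {
  smi <- c("CCO", "OCC", "C(O)C", "c1ccccc1", "C1=CC=CC=C1",
           "CCC", "CCCC", "CCN", "CCCN", "CC(C)C")
  mols <- parse_molecule_set(smi, paste0("m", seq_along(smi)))
  plan <- dedup_split(mols, k = 2, seed = 1)
  # all ethanol spellings in exactly one fold
  eth <- plan$fold[plan$canonical == plan$canonical[1]]
  expect_equal(length(unique(eth)), 1L)
  # zero canonical overlap between folds
  by_fold <- split(plan$canonical, plan$fold)
  expect_length(intersect(by_fold[[1]], by_fold[[2]]), 0L)
  # determinism in the seed
  expect_identical(plan, dedup_split(mols, k = 2, seed = 1))
  plans <- vapply(1:10, function(s) {
    paste(dedup_split(mols, k = 2, seed = s)$fold, collapse = "")
  }, "")
  expect_gt(length(unique(plans)), 1L)
  expect_error(dedup_split(mols[1:2], k = 5))
})

test_that("early stopping returns the best post-epoch checkpoint", {
  d <- make_reg_data()
  mod <- predictor_model(30, hidden = c(8, 8, 6, 4, 4), seed = 2)
  # diverging learning rate: validation loss cannot improve after epoch 1
  cfg <- train_config(rounds = 0, patience = 1, lr = 5,
                      batch_size = 32, max_epochs = 20, seed = 3)
  fit <- train_phase(mod, d$X[1:80, ], d$y[1:80], "carc", cfg,
                     d$X[81:120, ], d$y[81:120])
  expect_lte(nrow(fit$history), 1 + which.min(fit$history$val_loss))
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  expect_error(train_phase(mod, d$X[0, , drop = FALSE], numeric(0), "carc",
                           cfg, d$X, d$y))
})

test_that("training is seeded and converges on separable data", {
  d <- make_reg_data()
  mod <- predictor_model(30, hidden = c(8, 8, 6, 4, 4), seed = 2)
  cfg <- train_config(rounds = 0, patience = 5, lr = 3e-3,
                      batch_size = 32, max_epochs = 15, seed = 4)
  f1 <- train_phase(mod, d$X[1:80, ], d$y[1:80], "carc", cfg,
                    d$X[81:120, ], d$y[81:120])
  f2 <- train_phase(mod, d$X[1:80, ], d$y[1:80], "carc", cfg,
                    d$X[81:120, ], d$y[81:120])
  expect_identical(f1$history, f2$history)

  # linearly separable binary task reaches training accuracy 1
  set.seed(5)
  Xb <- matrix(rnorm(80 * 10), 80, 10)
  yb <- as.integer(Xb[, 1] > 0)
  Xb[, 1] <- Xb[, 1] * 3
  mb <- predictor_model(10, hidden = c(16, 8, 8, 4, 4), seed = 6)
  cb <- train_config(rounds = 0, patience = 20, lr = 5e-3,
                     batch_size = 16, max_epochs = 60, seed = 7)
  fb <- train_phase(mb, Xb, yb, "mut", cb, Xb, yb)
  acc <- mean((mlp_forward(fb$model, Xb, "mut", "eval") > 0.5) == yb)
  expect_equal(acc, 1.0)
})

test_that("multi-round alternation executes the documented phase schedule", {
  d <- make_reg_data(seed = 8)
  mut <- list(X = d$X[1:60, ], y = as.integer(d$y[1:60] > 0),
              Xval = d$X[61:90, ], yval = as.integer(d$y[61:90] > 0))
  carc <- list(X = d$X[1:60, ], y = d$y[1:60],
               Xval = d$X[61:90, ], yval = d$y[61:90])
  mod <- predictor_model(30, hidden = c(8, 8, 6, 4, 4), seed = 9)
  cfg0 <- train_config(rounds = 0, patience = 2, max_epochs = 3, seed = 10)
  fit0 <- multi_round_pretrain(mod, mut, carc, cfg0)
  expect_equal(fit0$phases, "carc")
  cfg3 <- train_config(rounds = 3, patience = 2, max_epochs = 3, seed = 10)
  fit3 <- multi_round_pretrain(mod, mut, carc, cfg3)
  expect_equal(fit3$phases, rep(c("mut", "carc"), 3))
  expect_length(fit3$histories, 6L)
})

test_that("sweeps rank a broken learning rate below a sane one", {
  d <- make_reg_data(n = 150, seed = 11)
  folds <- rep(0:2, each = 50)
  grid <- list(
    list(lr = 1e-3, hidden = c(8, 8, 6, 4, 4), max_epochs = 10,
         patience = 4),
    list(lr = 0, hidden = c(8, 8, 6, 4, 4), max_epochs = 10, patience = 4)
  )
  rk <- sweep_configs(grid, d$X, d$y, folds, seed = 12)
  expect_equal(nrow(rk), 2L)
  expect_equal(rk$config[1], 1)
  expect_gt(rk$mean_score[1], rk$mean_score[2])
  # the ranking key is the recomputed mean of the per-fold scores
  expect_equal(rk$mean_score,
               rowMeans(rk[, c("fold0", "fold1", "fold2")]))
  one <- sweep_configs(grid[1], d$X, d$y, folds, seed = 12)
  expect_equal(nrow(one), 1L)
})

test_that("ensembles average member predictions and never exceed worst MSE", {
  # hand-built members: zero trunks with head biases 1, 2, 3
  mk <- function(bias) {
    m <- predictor_model(4, hidden = c(4, 4, 3, 3, 2), seed = 1)
    for (i in 1:5) {
      m$trunk[[i]]$W[] <- 0; m$trunk[[i]]$b[] <- 0; m$trunk[[i]]$beta[] <- 0
    }
    m$heads$carc$W[] <- 0; m$heads$carc$b <- bias
    m
  }
  ens <- structure(list(members = list(mk(1), mk(2), mk(3)), k = 3),
                   class = "EnsembleModel")
  X <- matrix(rnorm(8), 2, 4)
  expect_equal(ensemble_predict(ens, X), c(2, 2))
  same <- structure(list(members = list(mk(2), mk(2), mk(2)), k = 3),
                    class = "EnsembleModel")
  expect_equal(ensemble_predict(same, X),
               mlp_forward(mk(2), X, "carc", "eval"))

  # averaging is convex: ensemble MSE <= max member MSE
  d <- make_reg_data(n = 90, seed = 13)
  folds <- rep(0:2, 30)
  grid <- list(list(lr = 1e-3, max_epochs = 6, patience = 3),
               list(lr = 2e-3, max_epochs = 6, patience = 3),
               list(lr = 5e-4, max_epochs = 6, patience = 3))
  rk <- sweep_configs(grid, d$X[1:60, ], d$y[1:60], folds[1:60], seed = 14)
  built <- build_ensemble(rk, d$X[1:60, ], d$y[1:60],
                          d$X[61:90, ], d$y[61:90], k = 3, seed = 15)
  pe <- ensemble_predict(built, d$X[61:90, ])
  me <- vapply(built$members,
               function(m) mse(mlp_forward(m, d$X[61:90, ], "carc", "eval"),
                               d$y[61:90]), 1)
  expect_lte(mse(pe, d$y[61:90]), max(me) + 1e-12)
  expect_error(build_ensemble(rk[1, ], d$X, d$y, d$X, d$y, k = 3))
})
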