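# Synthetic benchmark generator.
#
# Emulates the three dataset roles the training pipeline expects without any
# external downloads: a multi-experiment TD50 training table (CPDB-like), a
# larger binary mutagenicity pre-training set with limited concordance
# (Hansen-like, ~70%), and a binary external test set drawn from the potency
# extremes (CCRIS-like, expert-panel style). Carcinogenic potency is driven
# by planted toxicophore substructures: molecules are assembled from simple
# scaffolds (alkyl chains, cyclohexane, benzene) and, with probability f, a
# toxicophore fragment (nitroso or aromatic nitro by default) is grafted at
# a valence-legal site, raising the latent log-potency by its effect weight.

.TOX_FRAGMENTS <- list(
  nitroso = list(fragment = "N=O", needs_aromatic = FALSE),
  aromatic_nitro = list(fragment = "[N+](=O)[O-]", needs_aromatic = TRUE)
)

.DECORATIONS <- c("C", "CC", "O", "F", "")

#' Synthetic benchmark configuration
#'
#' @param n_train,n_mut,n_test sizes of the continuous training set, the
#'   binary mutagenicity pre-training set, and the binary external test set.
#' @param planted_fraction probability a molecule carries a toxicophore.
#' @param weights named effect weights (log10-potency units) per planted
#'   toxicophore.
#' @param baseline_mean,baseline_sd latent log-potency baseline distribution.
#' @param noise_sd per-experiment log10-TD50 noise SD.
#' @param exp_probs distribution of experiments per molecule (1..4).
#' @param concordance mutagenicity/carcinogenicity concordance target c.
#' @param nc_mid,nc_scale logistic parameters of the per-experiment
#'   no-tumor-response probability `plogis((nc_mid - z) / nc_scale)`.
#' @param sentinel sentinel log-potency for non-carcinogenic molecules.
#' @param seed master RNG seed.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_train = 1500L, n_mut = 3000L, n_test = 400L,
                             planted_fraction = 0.35,
                             weights = c(nitroso = 2, aromatic_nitro = 2),
                             baseline_mean = -1.2, baseline_sd = 0.4,
                             noise_sd = 0.3,
                             exp_probs = c(0.5, 0.3, 0.15, 0.05),
                             concordance = 0.70,
                             nc_mid = -0.8, nc_scale = 0.4,
                             sentinel = -1.62, seed = 1L) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            noise_sd > 0, concordance > 0.5, concordance <= 1,
            all(names(weights) %in% names(.TOX_FRAGMENTS)))
  structure(
    list(n_train = n_train, n_mut = n_mut, n_test = n_test,
         planted_fraction = planted_fraction, weights = weights,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         noise_sd = noise_sd, exp_probs = exp_probs,
         concordance = concordance, nc_mid = nc_mid, nc_scale = nc_scale,
         sentinel = sentinel, seed = seed),
    class = "SyntheticConfig"
  )
}

# A random acyclic backbone assembled from small valence-safe segments
# (alkyl runs, methyl/hydroxy branch points, ether links, alkene units).
.CHAIN_SEGMENTS <- c("C", "CC", "CCC", "C(C)C", "C(O)C", "C(C)(C)C",
                     "CC=CC", "COC")

.rand_chain <- function(k_min = 1L, k_max = 4L) {
  k <- sample(k_min:k_max, 1L)
  paste(sample(.CHAIN_SEGMENTS, k, replace = TRUE), collapse = "")
}

.RING_TEMPLATES <- c(
  "c1ccc({R})cc1", "c1cc({R})ccc1C", "c1cc({R})cc(C)c1", "c1cc({R})ccc1CC",
  "c1cc({R})ncc1", "c1ccnc({R})c1", "c1cc({R})cnc1", "c1ccc2cc({R})ccc2c1",
  "c1ccc({R})c(C)c1", "c1cc(C)cc({R})c1"
)

# One random scaffold template with a "{R}" substitution slot.
.rand_scaffold <- function(need_aromatic = FALSE) {
  aromatic <- need_aromatic || stats::runif(1) < 0.5
  if (aromatic) {
    chain <- if (stats::runif(1) < 0.4) "" else .rand_chain(1L, 3L)
    paste0(chain, sample(.RING_TEMPLATES, 1L))
  } else {
    chain <- .rand_chain(1L, 4L)
    pre <- sample(c("", "C1CCCCC1", "C1CCCC1", "OC"), 1L,
                  prob = c(0.6, 0.15, 0.1, 0.15))
    paste0(pre, chain, "{R}")
  }
}

.fill_slot <- function(template, filler) {
  if (nzchar(filler)) {
    sub("{R}", filler, template, fixed = TRUE)
  } else {
    sub("{R}", "", sub("({R})", "", template, fixed = TRUE), fixed = TRUE)
  }
}

#' Generate synthetic molecules with planted toxicophores
#'
#' @param cfg a `SyntheticConfig`.
#' @param n number of molecules (defaults to `cfg$n_train`).
#' @param seed RNG seed.
#' @param id_prefix identifier prefix.
#' @return data.frame: `id`, `smiles`, `canonical`, `planted` (logical),
#'   `planted_def` (toxicophore name or `NA`).
#' @export
generate_molecules <- function(cfg, n = cfg$n_train, seed = cfg$seed,
                               id_prefix = "syn") {
  set.seed(seed)
  defs <- names(cfg$weights)
  rows <- lapply(seq_len(n), function(i) {
    planted <- stats::runif(1) < cfg$planted_fraction
    if (planted) {
      def <- sample(defs, 1L)
      frag <- .TOX_FRAGMENTS[[def]]
      tpl <- .rand_scaffold(frag$needs_aromatic)
      smi <- .fill_slot(tpl, frag$fragment)
    } else {
      def <- NA_character_
      tpl <- .rand_scaffold(FALSE)
      smi <- .fill_slot(tpl, sample(.DECORATIONS, 1L))
    }
    data.frame(id = sprintf("%s%05d", id_prefix, i), smiles = smi,
               planted = planted, planted_def = def,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$canonical <- canonical_smiles_batch(df$smiles)
  stopifnot(!anyNA(df$canonical))
  df
}

#' Simulate multi-experiment TD50 records
#'
#' Latent log-potency `z = baseline + sum(w * planted) + N(0, baseline_sd)`;
#' each experiment is non-carcinogenic (the beta = 0 case: no dose-tumor
#' relationship) with probability `plogis((nc_mid - z) / nc_scale)`, and
#' otherwise reports `TD50 = 10^-(z + noise)`.
#'
#' @param molecules data.frame from [generate_molecules()].
#' @param cfg a `SyntheticConfig`.
#' @param seed RNG seed.
#' @return list: `records` (molecule_id, experiment_id, td50 with `NA` for
#'   non-carcinogenic experiments) and `truth` (molecule_id, z, planted,
#'   planted_def, carc_true).
#' @export
simulate_potency <- function(molecules, cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- nrow(molecules)
  w <- ifelse(molecules$planted, cfg$weights[molecules$planted_def], 0)
  z <- cfg$baseline_mean + w + stats::rnorm(n, sd = cfg$baseline_sd)
  n_exp <- sample(seq_along(cfg$exp_probs), n, replace = TRUE,
                  prob = cfg$exp_probs)
  recs <- lapply(seq_len(n), function(i) {
    k <- n_exp[i]
    p_nc <- stats::plogis((cfg$nc_mid - z[i]) / cfg$nc_scale)
    nc <- stats::runif(k) < p_nc
    td50 <- ifelse(nc, NA_real_,
                   10^-(z[i] + stats::rnorm(k, sd = cfg$noise_sd)))
    data.frame(molecule_id = molecules$id[i],
               experiment_id = paste0(molecules$id[i], "_e", seq_len(k)),
               td50 = td50, stringsAsFactors = FALSE)
  })
  truth <- data.frame(molecule_id = molecules$id, z = z,
                      planted = molecules$planted,
                      planted_def = molecules$planted_def,
                      carc_true = as.integer(z > cfg$nc_mid),
                      stringsAsFactors = FALSE)
  list(records = do.call(rbind, recs), truth = truth)
}

#' Simulate binary mutagenicity labels at a target concordance
#'
#' Flips the binarized carcinogenicity ground truth independently with
#' probability `1 - c`, emulating the limited (~70%) concordance between
#' mutagenicity assays and animal carcinogenicity.
#'
#' @param carc_true integer 0/1 ground-truth carcinogenicity indicators.
#' @param cfg a `SyntheticConfig` (uses `concordance`).
#' @param seed RNG seed.
#' @return integer 0/1 mutagenicity labels.
#' @export
simulate_mutagenicity <- function(carc_true, cfg, seed = cfg$seed) {
  set.seed(seed)
  flip <- stats::runif(length(carc_true)) > cfg$concordance
  as.integer(ifelse(flip, 1L - carc_true, carc_true))
}

#' Simulate a proportional-hazards bioassay
#'
#' Dose-response tumor counts under `lambda(t, d) = (1 + beta d) lambda0(t)`
#' with the cumulative baseline hazard normalized to 1 at the experiment
#' horizon: the probability of tumor by the end of the assay at dose-rate d
#' is `1 - exp(-(1 + beta d))`.
#'
#' @param beta hazard coefficient (per mg/kg/day).
#' @param doses dose-rate grid (mg/kg/day), typically including 0.
#' @param n_per_dose animals per dose group.
#' @param seed RNG seed.
#' @return data.frame: `dose`, `n`, `tumors`.
#' @export
simulate_hazard_assay <- function(beta, doses, n_per_dose = 50L, seed = 1L) {
  set.seed(seed)
  p <- 1 - exp(-(1 + beta * doses))
  data.frame(dose = doses, n = n_per_dose,
             tumors = stats::rbinom(length(doses), n_per_dose, p))
}

#' Maximum-likelihood TD50 from bioassay counts
#'
#' Fits `beta` (and the cumulative baseline hazard) of the proportional-
#' hazards dose model to binomial tumor counts and returns
#' `TD50 = log(2) / beta_hat`, the dose-rate at which the probability of
#' remaining tumor-free is halved relative to baseline.
#'
#' @param assay data.frame from [simulate_hazard_assay()] (columns `dose`,
#'   `n`, `tumors`).
#' @return list: `beta_hat`, `lambda0_hat`, `td50`.
#' @export
estimate_td50_hazard <- function(assay) {
  nll <- function(par) {
    lam <- exp(par[1L]); beta <- exp(par[2L])
    p <- 1 - exp(-lam * (1 + beta * assay$dose))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(assay$tumors, assay$n, p, log = TRUE))
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead")
  beta_hat <- exp(fit$par[2L])
  lambda0_hat <- exp(fit$par[1L])
  list(beta_hat = beta_hat, lambda0_hat = lambda0_hat,
       td50 = log(2) / (lambda0_hat * beta_hat))
}

#' Compose the full synthetic benchmark bundle
#'
#' Builds the three dataset roles with disjoint molecule ids: a continuous
#' training set with multi-experiment TD50 records and log-potency labels, a
#' binary mutagenicity pre-training set, and an external-style binary test
#' set drawn from the extremes of the latent potency spectrum, deduplicated
#' against the training set by canonical SMILES.
#'
#' @param cfg a `SyntheticConfig`.
#' @return a `SyntheticBundle`: lists `train` (molecules, records, labels),
#'   `mut` (molecules, labels), `test` (molecules, labels), each with a
#'   `truth` data.frame, plus the `config`.
#' @export
make_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  tr_mols <- generate_molecules(cfg, cfg$n_train, cfg$seed, "trn")
  tr_sim <- simulate_potency(tr_mols, cfg, cfg$seed + 1L)
  tr_labels <- potency_labels(tr_sim$records, sentinel = cfg$sentinel)
  tr_labels <- tr_labels[match(tr_mols$id, tr_labels$molecule_id), ]

  mut_mols <- generate_molecules(cfg, cfg$n_mut, cfg$seed + 2L, "mut")
  mut_sim <- simulate_potency(mut_mols, cfg, cfg$seed + 3L)
  mut_y <- simulate_mutagenicity(mut_sim$truth$carc_true, cfg, cfg$seed + 4L)

  # the external set holds unique structures only: the pool is deduplicated
  # by canonical SMILES (an expert panel labels a compound once) and against
  # the training set, then the latent-potency extremes are selected
  pool <- generate_molecules(cfg, 5L * cfg$n_test, cfg$seed + 5L, "tst")
  pool_sim <- simulate_potency(pool, cfg, cfg$seed + 6L)
  keep <- !(pool$canonical %in% tr_mols$canonical) &
    !duplicated(pool$canonical)
  if (sum(keep) < cfg$n_test) stop("synthetic pool too small for n_test")
  pool <- pool[keep, ]
  pz <- pool_sim$truth$z[keep]
  ord <- order(pz)
  lo <- head(ord, cfg$n_test %/% 2L)
  hi <- tail(ord, cfg$n_test %/% 2L)
  test_mols <- pool[c(lo, hi), ]
  test_y <- c(rep(0L, length(lo)), rep(1L, length(hi)))
  test_truth <- pool_sim$truth[keep, ][c(lo, hi), ]

  structure(
    list(
      train = list(molecules = tr_mols, records = tr_sim$records,
                   labels = tr_labels, truth = tr_sim$truth),
      mut = list(molecules = mut_mols,
                 labels = data.frame(molecule_id = mut_mols$id, y = mut_y),
                 truth = mut_sim$truth),
      test = list(molecules = test_mols,
                  labels = data.frame(molecule_id = test_mols$id,
                                      y = test_y),
                  truth = test_truth),
      config = cfg
    ),
    class = "SyntheticBundle"
  )
}
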