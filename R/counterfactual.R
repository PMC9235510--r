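# Counterfactual interpretability: local chemical-subspace sampling by
# random string mutation of the molecule, counterfactual selection by
# prediction-threshold crossing, and toxicophore enrichment statistics.
#
# The subspace sampler tokenizes the (canonical) SMILES string and applies
# 1..k random edits per sample - atom substitutions, substituent-branch
# insertions (including toxicophore-bearing fragments), and branch/terminal
# deletions - then keeps only candidates that survive parsing, the valence
# audit, and canonical-form deduplication. Validity filtering plays the role
# a robust string encoding plays elsewhere: every retained sample is a real,
# distinct molecule at a measurable Tanimoto distance from the base.

.SMILES_TOKEN_RE <- paste0(
  "\\[[^]]+\\]|Cl|Br|%\\d\\d|[BCNOPSFIbcnops]|[-=#/\\\\]|\\d|[().]"
)

.tokenize_smiles <- function(s) {
  regmatches(s, gregexpr(.SMILES_TOKEN_RE, s))[[1L]]
}

.INSERT_FRAGMENTS <- c(
  "C", "CC", "O", "N", "Cl", "Br", "I",
  "N=O", "[N+](=O)[O-]", "NN", "OO", "ON", "NO",
  "C9CO9", "C9C[NH]9", "C9CS9", "N=NC"
)

.SUBST_SETS <- list(
  aliphatic = c("C", "N", "O", "S"),
  aromatic = c("c", "n"),
  halogen = c("F", "Cl", "Br", "I")
)

.mutate_once <- function(toks) {
  n <- length(toks)
  is_atom <- toks %in% unlist(.SUBST_SETS) | grepl("^\\[", toks)
  op <- sample(c("subst", "insert", "delete"), 1L, prob = c(0.4, 0.4, 0.2))
  if (op == "subst") {
    cand <- which(toks %in% unlist(.SUBST_SETS))
    if (!length(cand)) return(toks)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    pool <- if (toks[i] %in% .SUBST_SETS$aromatic) {
      .SUBST_SETS$aromatic
    } else {
      c(.SUBST_SETS$aliphatic, .SUBST_SETS$halogen)
    }
    pool <- setdiff(pool, toks[i])
    toks[i] <- sample(pool, 1L)
    toks
  } else if (op == "insert") {
    cand <- which(is_atom)
    if (!length(cand)) return(toks)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    # skip past ring-closure digits so "c1" stays intact
    while (i < n && grepl("^(\\d|%\\d\\d)$", toks[i + 1L])) i <- i + 1L
    frag <- sample(.INSERT_FRAGMENTS, 1L)
    append(toks, c("(", .tokenize_smiles(frag), ")"), after = i)
  } else {
    s <- paste(toks, collapse = "")
    # removable substrings: short parenthesized branches or a terminal atom
    branches <- gregexpr("\\([^()]{1,12}\\)", s)[[1L]]
    choices <- list()
    if (branches[1L] != -1L) {
      lens <- attr(branches, "match.length")
      for (k in seq_along(branches)) {
        choices[[length(choices) + 1L]] <- c(branches[k], lens[k])
      }
    }
    tail_at <- regexpr("(Cl|Br|[CNOSFI])$", s)
    if (tail_at != -1L && nchar(s) > attr(tail_at, "match.length")) {
      choices[[length(choices) + 1L]] <-
        c(tail_at, attr(tail_at, "match.length"))
    }
    if (!length(choices)) return(toks)
    pick <- choices[[sample.int(length(choices), 1L)]]
    s2 <- paste0(substr(s, 1L, pick[1L] - 1L),
                 substr(s, pick[1L] + pick[2L], nchar(s)))
    .tokenize_smiles(s2)
  }
}

#' Sample the local chemical subspace of a molecule
#'
#' Applies `n_samples` independent random mutation chains (1..`max_mutations`
#' string edits each) to the base molecule and retains the candidates that
#' parse, pass the valence audit, and are canonically distinct from the base
#' and from each other. Aggressive filtering can return fewer rows than
#' `n_samples`; the attrition is reported in the `"n_attempted"` attribute.
#'
#' @param base a `Molecule`.
#' @param n_samples number of mutation attempts (default 2000).
#' @param max_mutations maximum edits per sample (mutation count is drawn
#'   uniformly from 1..max_mutations).
#' @param seed RNG seed.
#' @return data.frame: `smiles`, `canonical`, `tanimoto_distance` (1 - T to
#'   the base molecule, circular fingerprints); attribute `"molecules"`
#'   holds the parsed `Molecule` list in row order.
#' @export
sample_subspace <- function(base, n_samples = 2000L, max_mutations = 3L,
                            seed = 1L) {
  stopifnot(inherits(base, "Molecule"), n_samples >= 1L, max_mutations >= 1L)
  set.seed(seed)
  toks0 <- .tokenize_smiles(base$canonical_smiles)
  cand <- character(n_samples)
  for (i in seq_len(n_samples)) {
    toks <- toks0
    for (k in seq_len(sample.int(max_mutations, 1L))) {
      toks <- .mutate_once(toks)
    }
    cand[i] <- paste(toks, collapse = "")
  }
  cand <- unique(cand[nzchar(cand)])
  can <- canonical_smiles_batch(cand)
  ok <- !is.na(can) & can != base$canonical_smiles & !duplicated(can)
  cand <- cand[ok]; can <- can[ok]
  if (!length(cand)) {
    out <- data.frame(smiles = character(0), canonical = character(0),
                      tanimoto_distance = numeric(0))
    attr(out, "molecules") <- list()
    attr(out, "n_attempted") <- n_samples
    return(out)
  }
  mols <- parse_molecule_set(cand, paste0(base$id, "_cf", seq_along(cand)))
  kept_can <- vapply(mols, function(m) m$canonical_smiles, "")
  kept_smi <- vapply(mols, function(m) m$smiles, "")
  fps <- fingerprint_matrix(c(list(base), mols), "circular")
  dist <- 1 - as.numeric(.tanimoto_cross(fps[1L, , drop = FALSE],
                                         fps[-1L, , drop = FALSE]))
  out <- data.frame(smiles = kept_smi, canonical = kept_can,
                    tanimoto_distance = dist, stringsAsFactors = FALSE)
  attr(out, "molecules") <- mols
  attr(out, "n_attempted") <- n_samples
  out
}

#' Select the counterfactual pair from a scored subspace
#'
#' A positive counterfactual is the minimal-distance sample whose prediction
#' reaches the upper threshold; a negative counterfactual the
#' minimal-distance sample at or below the lower threshold. Either can be
#' absent (`NULL`) when no sample qualifies.
#'
#' @param base_pred model prediction for the base molecule; must satisfy
#'   `lower < base_pred < upper`.
#' @param samples data.frame with columns `tanimoto_distance` and
#'   `prediction` (plus any identifying columns, carried through).
#' @param upper,lower prediction thresholds.
#' @return a `CounterfactualPair`: list with `positive` and `negative`
#'   (single-row data.frames or `NULL`).
#' @export
select_counterfactuals <- function(base_pred, samples, upper, lower) {
  if (!(upper > base_pred && base_pred > lower)) {
    stop("thresholds must satisfy lower < base prediction < upper")
  }
  stopifnot(all(c("tanimoto_distance", "prediction") %in% names(samples)))
  pick <- function(idx) {
    if (!length(idx)) return(NULL)
    idx <- idx[order(samples$tanimoto_distance[idx])]
    samples[idx[1L], , drop = FALSE]
  }
  structure(
    list(positive = pick(which(samples$prediction >= upper)),
         negative = pick(which(samples$prediction <= lower))),
    class = "CounterfactualPair"
  )
}

#' Load a toxicophore catalogue
#'
#' Reads a TSV with columns `name` and `smarts` (comma-separated SMARTS
#' alternatives per toxicophore; a molecule matches a definition when any of
#' its patterns matches). Every pattern is validated at load time.
#'
#' @param path catalogue file; defaults to the packaged catalogue of seven
#'   classical toxicophores (nitroso, aliphatic halide, aromatic nitro,
#'   aromatic amine, three-membered heterocycles, azo,
#'   heteroatom-heteroatom).
#' @return named list of `ToxicophoreDef` (`name`, `patterns`).
#' @export
load_toxicophores <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toxicophores.tsv", package = "carcipred")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "toxicophores.tsv")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  probe <- ChemmineOB::forEachMol("SMILES", "c1ccccc1", function(x) x)
  defs <- lapply(seq_len(nrow(df)), function(i) {
    pats <- gsub(" ", "", strsplit(df$smarts[i], ",")[[1L]], fixed = TRUE)
    for (p in pats) {
      ok <- tryCatch({
        ChemmineOB::smartsSearch_OB(probe, p); TRUE
      }, error = function(e) FALSE)
      if (!ok) stop("invalid SMARTS in catalogue (", df$name[i], "): ", p)
    }
    structure(list(name = df$name[i], patterns = pats),
              class = "ToxicophoreDef")
  })
  names(defs) <- df$name
  defs
}

# Match matrix: molecules x toxicophore definitions (any-pattern per def).
.match_defs <- function(mols, defs) {
  can <- vapply(mols, function(m) m$canonical_smiles, "")
  refs <- ChemmineOB::forEachMol("SMILES", paste(can, collapse = "\n"),
                                 function(x) x)
  out <- matrix(FALSE, length(mols), length(defs),
                dimnames = list(vapply(mols, function(m) m$id, ""),
                                vapply(defs, function(d) d$name, "")))
  for (j in seq_along(defs)) {
    hit <- rep(FALSE, length(mols))
    for (p in defs[[j]]$patterns) {
      hit <- hit | (unlist(ChemmineOB::smartsSearch_OB(refs, p)) > 0)
    }
    out[, j] <- hit
  }
  out
}

#' Match a molecule against toxicophore definitions
#'
#' @param m a `Molecule`.
#' @param defs catalogue from [load_toxicophores()].
#' @return named logical vector, one entry per definition (TRUE when any of
#'   the definition's SMARTS patterns matches as a substructure).
#' @export
match_toxicophores <- function(m, defs) {
  stopifnot(inherits(m, "Molecule"))
  .match_defs(list(m), defs)[1L, ]
}

#' Toxicophore enrichment table across counterfactual groups
#'
#' For every toxicophore definition, counts matches among the original
#' molecules and their positive/negative counterfactuals, reports
#' frequencies (%), frequency ratios relative to the originals (the printed
#' "odds ratio relative to the % in originals" convention), cross-product
#' odds ratios, two-sided Fisher exact p-values for each counterfactual
#' group against the originals, and Benjamini-Hochberg adjusted q-values
#' across definitions within each group.
#'
#' @param originals,positives,negatives lists of `Molecule` objects.
#' @param defs catalogue from [load_toxicophores()].
#' @return data.frame, one row per toxicophore definition.
#' @export
enrichment_table <- function(originals, positives, negatives, defs) {
  stopifnot(length(originals) >= 1L, length(positives) >= 1L,
            length(negatives) >= 1L)
  mo <- .match_defs(originals, defs)
  mp <- .match_defs(positives, defs)
  mn <- .match_defs(negatives, defs)
  n_o <- nrow(mo); n_p <- nrow(mp); n_n <- nrow(mn)
  rows <- lapply(seq_along(defs), function(j) {
    co <- sum(mo[, j]); cp <- sum(mp[, j]); cn <- sum(mn[, j])
    fo <- 100 * co / n_o; fp <- 100 * cp / n_p; fn_ <- 100 * cn / n_n
    fish <- function(cg, ng) {
      stats::fisher.test(matrix(c(cg, ng - cg, co, n_o - co), 2L,
                                byrow = TRUE))$p.value
    }
    odds <- function(cg, ng) {
      num <- cg * (n_o - co); den <- (ng - cg) * co
      if (den == 0) NA_real_ else num / den
    }
    data.frame(
      toxicophore = defs[[j]]$name,
      count_negative = cn, count_original = co, count_positive = cp,
      freq_negative = fn_, freq_original = fo, freq_positive = fp,
      ratio_negative = frequency_ratio(fn_, fo),
      ratio_positive = frequency_ratio(fp, fo),
      odds_negative = odds(cn, n_n), odds_positive = odds(cp, n_p),
      p_negative = fish(cn, n_n), p_positive = fish(cp, n_p),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_negative <- stats::p.adjust(out$p_negative, method = "BH")
  out$q_positive <- stats::p.adjust(out$p_positive, method = "BH")
  out
}

#' Frequency ratio relative to the originals group
#'
#' The ratio printed alongside enrichment percentages: group frequency
#' divided by the originals' frequency, undefined (`NA`) when the originals'
#' frequency is zero.
#'
#' @param freq_group,freq_originals frequencies in percent.
#' @return the ratio, or `NA` if `freq_originals` is zero.
#' @export
frequency_ratio <- function(freq_group, freq_originals) {
  if (freq_originals == 0) return(NA_real_)
  freq_group / freq_originals
}

#' Counterfactual thresholds from the training prediction spread
#'
#' Default rule: upper/lower thresholds at the base prediction plus/minus
#' one standard deviation of the model's training-set predictions.
#'
#' @param base_pred prediction for the base molecule.
#' @param train_preds model predictions over the training set.
#' @param k width in SDs (default 1).
#' @return list with `upper` and `lower`.
#' @export
counterfactual_thresholds <- function(base_pred, train_preds, k = 1) {
  s <- stats::sd(train_preds)
  list(upper = base_pred + k * s, lower = base_pred - k * s)
}
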