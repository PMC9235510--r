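test_that("toxicophore catalogue loads and matches reference structures", {
  defs <- load_toxicophores()
  expect_length(defs, 7L)
  m <- fixture_mol("CN=O", "nitroso")
  hits <- match_toxicophores(m, defs)
  expect_true(hits[["Nitroso"]])
  expect_false(any(hits[names(hits) != "Nitroso"]))

  # ethanol matches none of the seven definitions
  expect_false(any(match_toxicophores(fixture_mol("CCO", "ethanol"), defs)))
  # chlorine on an aliphatic carbon is an aliphatic halide...
  expect_true(match_toxicophores(fixture_mol("CCl", "cme"),
                                 defs)[["Aliphatic halide"]])
  # ...but on an aromatic ring it is not
  expect_false(match_toxicophores(fixture_mol("Clc1ccccc1", "clbz"),
                                  defs)[["Aliphatic halide"]])
  expect_true(match_toxicophores(fixture_mol("Nc1ccccc1", "aniline"),
                                 defs)[["Aromatic amine"]])
  expect_true(match_toxicophores(fixture_mol("C1CO1", "epox"),
                                 defs)[["Three-membered heterocycle"]])
  expect_true(match_toxicophores(fixture_mol("O=[N+]([O-])c1ccccc1", "nb"),
                                 defs)[["Aromatic nitro"]])
  expect_true(match_toxicophores(fixture_mol("NN", "hydrazine"),
                                 defs)[["Unsubstituted heteroatom-bonded heteroatom"]])

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tsmarts", "broken\t[[bad"), bad)
  expect_error(load_toxicophores(bad), "invalid SMARTS")
})

test_that("subspace sampling yields distinct valid neighbors, seeded", {
  base <- fixture_mol("CCCCc1ccc(CC)cc1", "base")
  s1 <- sample_subspace(base, n_samples = 300, seed = 5)
  expect_gt(nrow(s1), 20)
  expect_false(base$canonical_smiles %in% s1$canonical)
  expect_equal(anyDuplicated(s1$canonical), 0L)
  expect_true(all(s1$tanimoto_distance > 0 & s1$tanimoto_distance <= 1))
  s2 <- sample_subspace(base, n_samples = 300, seed = 5)
  expect_identical(s1$canonical, s2$canonical)
  mols <- attr(s1, "molecules")
  expect_equal(vapply(mols, function(m) m$canonical_smiles, ""),
               s1$canonical)
})

test_that("counterfactual selection picks minimal-distance threshold crossers", {
  samples <- data.frame(
    smiles = paste0("s", 1:5),
    tanimoto_distance = c(0.2, 0.4, 0.1, 0.5, 0.3),
    prediction = c(0.95, 0.99, 0.5, 0.01, 0.02)
  )
  pair <- select_counterfactuals(0.5, samples, upper = 0.9, lower = 0.1)
  expect_equal(pair$positive$smiles, "s1")   # 0.2 < 0.4 among preds >= 0.9
  expect_equal(pair$negative$smiles, "s5")   # 0.3 < 0.5 among preds <= 0.1

  # exhaustive-search oracle over random sample sets
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    df <- data.frame(smiles = paste0("x", 1:n),
                     tanimoto_distance = runif(n),
                     prediction = runif(n))
    pr <- select_counterfactuals(0.5, df, 0.8, 0.2)
    hi <- df[df$prediction >= 0.8, ]
    lo <- df[df$prediction <= 0.2, ]
    if (nrow(hi)) {
      expect_equal(pr$positive$tanimoto_distance,
                   min(hi$tanimoto_distance))
    } else expect_null(pr$positive)
    if (nrow(lo)) {
      expect_equal(pr$negative$tanimoto_distance,
                   min(lo$tanimoto_distance))
    } else expect_null(pr$negative)
  }

  none <- select_counterfactuals(0.5, samples[3, ], 0.9, 0.1)
  expect_null(none$positive); expect_null(none$negative)
  expect_error(select_counterfactuals(0.95, samples, 0.9, 0.1), "thresholds")
})

test_that("enrichment statistics match hand arithmetic and brute-force BH", {
  defs <- load_toxicophores()
  orig <- lapply(c("CN=O", "CCO", "CCl", "c1ccccc1"), parse_smiles)
  pos <- lapply(c("CN=O", "CCN=O", "CCl", "NN"), parse_smiles)
  neg <- lapply(c("CCO", "CCC", "c1ccccc1", "CCCC"), parse_smiles)
  tab <- enrichment_table(orig, pos, neg, defs)
  expect_equal(nrow(tab), 7L)
  nitro <- tab[tab$toxicophore == "Nitroso", ]
  expect_equal(nitro$freq_original, 25)
  expect_equal(nitro$freq_positive, 50)
  expect_equal(nitro$ratio_positive, 2)
  expect_equal(nitro$ratio_negative, 0)
  expect_true(all(tab$p_positive >= 0 & tab$p_positive <= 1))
  expect_true(all(tab$freq_positive >= 0 & tab$freq_positive <= 100))

  # identical groups: all ratios 1 (where defined), all p-values 1
  same <- enrichment_table(orig, orig, orig, defs)
  def_rows <- same$count_original > 0
  expect_true(all(same$ratio_positive[def_rows] == 1))
  expect_true(all(same$p_positive == 1 & same$p_negative == 1))

  # Fisher p for [[8,2],[2,8]] equals hypergeometric enumeration
  p_fisher <- fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value
  # enumerate all tables with margins (10, 10) x (10, 10)
  probs <- dhyper(0:10, 10, 10, 10)
  p_enum <- sum(probs[probs <= dhyper(8, 10, 10, 10) + 1e-12])
  expect_equal(p_fisher, p_enum, tolerance = 1e-12)

  # BH equals the brute-force step-up definition for m <= 20
  set.seed(10)
  for (i in 1:10) {
    m <- sample(3:20, 1)
    p <- runif(m)
    bh <- p.adjust(p, "BH")
    o <- order(p)
    stepup <- numeric(m)
    q <- p[o] * m / seq_len(m)
    for (k in m:1) stepup[k] <- if (k == m) q[k] else min(q[k], stepup[k + 1])
    stepup <- pmin(stepup, 1)
    expect_equal(bh[o], stepup, tolerance = 1e-12)
  }
})

test_that("frequency ratios reproduce printed enrichment parentheticals", {
  expect_equal(round(frequency_ratio(32.17, 21.95), 2), 1.47)
  expect_equal(round(frequency_ratio(18.26, 13.82), 2), 1.32)
  expect_equal(round(frequency_ratio(2.75, 21.95), 2), 0.13)
  expect_true(is.na(frequency_ratio(6.96, 0)))
})

test_that("an oracle model produces toxicophore-enriched counterfactuals", {
  defs <- load_toxicophores()
  cfg <- synthetic_config(seed = 31, planted_fraction = 0.3)
  df <- generate_molecules(cfg, 25, seed = 31, id_prefix = "cf")
  originals <- parse_molecule_set(df$smiles, df$id)
  oracle <- function(mols) {
    as.numeric(carcipred:::.match_defs(mols, defs["Nitroso"])[, 1])
  }
  pos <- list(); neg <- list()
  for (b in originals) {
    ss <- sample_subspace(b, n_samples = 150, seed = 7)
    if (!nrow(ss)) next
    mols <- attr(ss, "molecules")
    ss$prediction <- oracle(mols)
    base_pred <- 0.5
    pair <- select_counterfactuals(base_pred, ss, upper = 0.9, lower = 0.1)
    if (!is.null(pair$positive)) {
      pos[[length(pos) + 1]] <- mols[[match(pair$positive$canonical,
                                            ss$canonical)]]
    }
    if (!is.null(pair$negative)) {
      neg[[length(neg) + 1]] <- mols[[match(pair$negative$canonical,
                                            ss$canonical)]]
    }
  }
  expect_gt(length(pos), 5)
  expect_gt(length(neg), 5)
  tab <- enrichment_table(originals, pos, neg, defs)
  nitro <- tab[tab$toxicophore == "Nitroso", ]
  expect_gt(nitro$ratio_positive, 1)
  expect_lt(nitro$ratio_negative, 1)
})
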