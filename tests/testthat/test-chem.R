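test_that("SMILES parsing yields valence-valid molecules with canonical forms", {
  m <- fixture_mol("CCO", "ethanol")
  expect_s3_class(m, "Molecule")
  expect_equal(m$graph$n_nodes, 3L)
  expect_true(nzchar(m$canonical_smiles))

  # alternative spellings of one structure canonicalize identically
  expect_equal(parse_smiles("C(O)C")$canonical_smiles, m$canonical_smiles)
  expect_equal(parse_smiles("OCC")$canonical_smiles, m$canonical_smiles)
  expect_equal(parse_smiles("c1ccccc1")$canonical_smiles,
               parse_smiles("C1=CC=CC=C1")$canonical_smiles)

  expect_error(parse_smiles("C(C)(C)(C)(C)C"),
               class = "carcipred_invalid_molecule")
  expect_error(parse_smiles(""), class = "carcipred_invalid_molecule")
  expect_error(parse_smiles("notasmiles!!"),
               class = "carcipred_invalid_molecule")
})

test_that("canonicalization is idempotent and atom-order invariant", {
  for (smi in c("CC(C)CO", "CCc1ccc(CC(C)O)cc1", "ClCCCN")) {
    m <- fixture_mol(smi)
    expect_equal(parse_smiles(m$canonical_smiles)$canonical_smiles,
                 m$canonical_smiles)
    # 100 random atom relabelings all map back to one canonical string
    set.seed(7)
    cans <- vapply(seq_len(100), function(i) {
      g <- permute_graph(m$graph, sample(m$graph$n_nodes))
      sdf_to_canonical(graph_to_sdf_text(g))
    }, "")
    expect_equal(length(unique(cans)), 1L)
    expect_equal(unique(cans), m$canonical_smiles)
  }
})

test_that("skip-and-log loading drops invalid structures, strict mode fails", {
  res <- parse_molecule_set(c("CCO", "C1CC", "CCC", "C(C)(C)(C)(C)C"),
                            c("a", "b", "c", "d"))
  expect_length(res, 2L)
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$id, c("b", "d"))
  expect_error(
    parse_molecule_set(c("CCO", "C1CC"), c("a", "b"), strict = TRUE),
    class = "carcipred_invalid_molecule"
  )
})

test_that("molecular graphs carry the expected topology and features", {
  eth <- fixture_mol("CCO", "ethanol")$graph
  expect_equal(eth$n_nodes, 3L)
  expect_equal(nrow(eth$edges), 4L)  # 2 undirected bonds, both directions
  expect_true(all(eth$edges$i != eth$edges$j))

  benz <- fixture_mol("c1ccccc1", "benzene")$graph
  expect_equal(benz$n_nodes, 6L)
  expect_equal(nrow(benz$edges) / 2, 6)
  expect_true(all(benz$nodes[, "aromatic"] == 1))
  expect_true(all(benz$nodes[, "in_ring"] == 1))
  expect_true(all(benz$edges$aromatic == 1))

  # edges are symmetric: every (i, j) has its (j, i) mirror
  key <- paste(eth$edges$i, eth$edges$j)
  rkey <- paste(eth$edges$j, eth$edges$i)
  expect_setequal(key, rkey)

  # node permutation produces an isomorphic graph (degree/feature multiset)
  set.seed(1)
  g2 <- permute_graph(benz, sample(6))
  expect_equal(sort(g2$nodes[, "degree"]), sort(benz$nodes[, "degree"]))
  expect_equal(sdf_to_canonical(graph_to_sdf_text(g2)),
               fixture_mol("c1ccccc1", "benzene")$canonical_smiles)
})

test_that("fingerprint schemes are deterministic with documented sizes", {
  m <- fixture_mol("CCO", "ethanol")
  fc1 <- circular_fingerprint(m); fc2 <- circular_fingerprint(m)
  expect_identical(fc1$bits, fc2$bits)
  expect_equal(fc1$n_bits, 2048L)
  expect_true(all(fc1$bits %in% c(0L, 1L)))

  fp <- path_fingerprint(m)
  expect_equal(fp$n_bits, 2048L)
  expect_identical(fp$bits, path_fingerprint(m)$bits)

  fk <- structural_key_fingerprint(m)
  expect_equal(fk$n_bits, 167L)

  # a nonempty molecule sets at least the atom-environment bit
  expect_gte(sum(circular_fingerprint(fixture_mol("C", "methane"))$bits), 1)
  # a single-atom graph has no bond paths: at most a handful of path bits
  expect_lte(sum(path_fingerprint(fixture_mol("C", "methane"))$bits), 5)

  # distinct environments give Tanimoto < 1
  fb <- circular_fingerprint(fixture_mol("c1ccccc1", "benzene"))
  expect_lt(tanimoto(fc1$bits, fb$bits), 1)

  # benzene sets the aromatic-ring structural key; ethane does not
  kb <- structural_key_fingerprint(fixture_mol("c1ccccc1", "benzene"))
  ke <- structural_key_fingerprint(fixture_mol("CC", "ethane"))
  expect_equal(kb$bits[162], 1L)
  expect_equal(ke$bits[162], 0L)

  # fingerprints depend only on the canonical structure
  expect_identical(circular_fingerprint(parse_smiles("OCC"))$bits, fc1$bits)
})

test_that("feature blocks lay out all segments exactly once", {
  m <- fixture_mol("CCO", "ethanol")
  emb <- c(0.5, -1, 2)
  blk <- build_feature_block(m, emb)
  expect_equal(length(blk$vector), 2048L + 2048L + 167L + 3L)
  offs <- vapply(blk$layout, function(x) x[["offset"]], 1L)
  lens <- vapply(blk$layout, function(x) x[["length"]], 1L)
  # offsets partition the vector exactly: contiguous, exhaustive, disjoint
  expect_equal(unname(offs), cumsum(c(1L, unname(lens)[-4])))
  expect_equal(sum(lens), length(blk$vector))
  eo <- blk$layout$graph_embedding
  expect_equal(blk$vector[eo[["offset"]] + 0:2], emb)

  # zero embedding zeroes only that segment and keeps fingerprints intact
  blk0 <- build_feature_block(m, c(0, 0, 0))
  expect_equal(blk0$vector[eo[["offset"]] + 0:2], c(0, 0, 0))
  expect_equal(blk0$vector[1:2048], blk$vector[1:2048])

  # per-row independence: blocks of two molecules are each molecule's own
  m2 <- fixture_mol("c1ccccc1", "benzene")
  expect_equal(build_feature_block(m2, emb)$vector,
               build_feature_block(m2, emb)$vector)
})

test_that("batch fingerprint matrices agree with per-molecule calls", {
  mols <- list(fixture_mol("CCO", "ethanol"),
               fixture_mol("c1ccccc1", "benzene"),
               fixture_mol("CCl", "chloro"))
  M <- fingerprint_matrix(mols, "circular", n_bits = 1024L)
  expect_equal(dim(M), c(3L, 1024L))
  expect_equal(M[2, ],
               circular_fingerprint(mols[[2]], n_bits = 1024L)$bits,
               ignore_attr = TRUE)
  K <- fingerprint_matrix(mols, "structural_key")
  expect_equal(K[1, ], structural_key_fingerprint(mols[[1]])$bits,
               ignore_attr = TRUE)
  P <- fingerprint_matrix(mols, "path")
  expect_equal(P[3, ], path_fingerprint(mols[[3]])$bits,
               ignore_attr = TRUE)
})
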