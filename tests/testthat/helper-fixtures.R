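# Shared fixtures: parsed molecules are cached per test run, and a minimal
# V2000 writer lets tests feed atom-order permutations of a structure back
# through the canonicalizer.

.fixture_env <- new.env(parent = emptyenv())

fixture_mol <- function(smiles, id = smiles) {
  key <- paste0(id, "|", smiles)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- parse_smiles(smiles, id)
  }
  .fixture_env[[key]]
}

# Write a MolGraph as V2000 molfile text (coordinates zeroed; neutral atoms).
graph_to_sdf_text <- function(graph) {
  n <- graph$n_nodes
  half <- nrow(graph$edges) / 2
  lines <- c("perm", " tests", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, half))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, graph$symbols[i]))
  }
  if (half > 0) {
    for (k in seq_len(half)) {
      ord <- graph$edges$order[k]
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                graph$edges$i[k], graph$edges$j[k],
                                as.integer(ord)))
    }
  }
  c(lines, "M  END", "$$$$")
}

# Random atom-order permutation of a MolGraph.
permute_graph <- function(graph, perm) {
  g <- graph
  g$nodes <- g$nodes[perm, , drop = FALSE]
  g$symbols <- g$symbols[perm]
  g$edges$i <- match(g$edges$i, perm)
  g$edges$j <- match(g$edges$j, perm)
  g
}

# Canonical SMILES of an SDF text block via obabel.
sdf_to_canonical <- function(sdf_lines) {
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)))
  writeLines(sdf_lines, fin)
  suppressWarnings(system2("obabel", c("-isdf", fin, "-ocan", "-O", fout),
                           stdout = FALSE, stderr = FALSE))
  out <- readLines(fout, warn = FALSE)
  sub("\t.*$", "", out[1L])
}

# Small synthetic molecule list shared across property tests.
fixture_synthetic_mols <- function(n = 60, seed = 99) {
  key <- sprintf("synmols|%d|%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(seed = seed)
    df <- generate_molecules(cfg, n, seed = seed, id_prefix = "fx")
    .fixture_env[[key]] <- parse_molecule_set(df$smiles, df$id)
  }
  .fixture_env[[key]]
}
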