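# Molecule parsing, canonicalization and featurization.
#
# SMILES handling is delegated to OpenBabel (via ChemmineR/ChemmineOB and the
# obabel CLI for batch work). OpenBabel is permissive about valence, so an
# explicit valence audit over the parsed bond orders is applied on top.

.ATOM_TABLE <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  number = c(1L, 5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L, 35L, 53L),
  mass   = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974,
             32.065, 35.453, 79.904, 126.904),
  # maximum explicit valence for the neutral atom; charges adjust (see below)
  max_valence = c(1, 3, 4, 3, 2, 1, 4, 5, 6, 1, 1, 1),
  stringsAsFactors = FALSE
)

.condition_stop <- function(class, msg) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Canonicalize a batch of SMILES strings
#'
#' Runs every SMILES through OpenBabel's canonical SMILES writer in a single
#' batch call. Strings that fail to parse come back as `NA` rather than
#' aborting the batch, which is what dataset loaders need for
#' skip-and-log behavior.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles_batch <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  tags <- paste0("q", seq_along(smiles))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, tags), fin)
  suppressWarnings(
    system2("obabel", c("-ismi", fin, "-ocan", "-O", fout, "-e"),
            stdout = FALSE, stderr = FALSE)
  )
  out <- rep(NA_character_, length(smiles))
  if (file.exists(fout)) {
    lines <- readLines(fout, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      can <- vapply(parts, `[[`, "", 1L)
      tag <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", ""))
      hit <- match(tag, tags)
      ok <- !is.na(hit) & nzchar(can)
      out[hit[ok]] <- can[ok]
    }
  }
  # empty canonical string means the parser emitted nothing useful
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

.charge_from_code <- function(code) {
  # MDL V2000 charge column codes
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  unname(map[as.character(code)])
}

.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  symbols <- sub("_.*$", "", rownames(ab))
  charge_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charges <- .charge_from_code(charge_col)
  idx <- match(symbols, .ATOM_TABLE$symbol)
  if (anyNA(idx)) {
    .condition_stop("carcipred_invalid_molecule",
                    paste0("unsupported element(s): ",
                           paste(unique(symbols[is.na(idx)]), collapse = ", ")))
  }
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    ei <- integer(0); ej <- integer(0); order <- numeric(0)
  } else {
    ei <- as.integer(bb[, 1L]); ej <- as.integer(bb[, 2L])
    order <- as.numeric(bb[, 3L])
  }
  degree <- tabulate(c(ei, ej), nbins = n)

  # ring membership and aromaticity from ring perception; acyclic fast path
  in_ring <- rep(FALSE, n); arom_atom <- rep(FALSE, n)
  arom_bond <- rep(FALSE, length(ei))
  if (length(ei) >= n && n >= 3L) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rg) && length(rg$RINGS)) {
      ring_ids <- lapply(rg$RINGS, function(r) as.integer(sub("^.*_", "", r)))
      for (k in seq_along(ring_ids)) {
        ids <- ring_ids[[k]]
        in_ring[ids] <- TRUE
        if (isTRUE(rg$AROMATIC[[k]])) arom_atom[ids] <- TRUE
      }
      both_in <- function(flag) flag[ei] & flag[ej]
      # a bond is flagged per ring so that only true ring bonds inherit flags
      ring_bond <- rep(FALSE, length(ei))
      for (k in seq_along(ring_ids)) {
        ids <- ring_ids[[k]]
        memb <- ei %in% ids & ej %in% ids
        ring_bond <- ring_bond | memb
        if (isTRUE(rg$AROMATIC[[k]])) arom_bond <- arom_bond | memb
      }
    } else ring_bond <- rep(FALSE, length(ei))
  } else ring_bond <- rep(FALSE, length(ei))

  nodes <- cbind(
    atomic_number = .ATOM_TABLE$number[idx],
    atomic_mass   = .ATOM_TABLE$mass[idx],
    formal_charge = charges,
    degree        = degree,
    aromatic      = as.numeric(arom_atom),
    in_ring       = as.numeric(in_ring)
  )
  rownames(nodes) <- NULL
  edges <- data.frame(
    i = c(ei, ej), j = c(ej, ei),
    order = c(order, order),
    aromatic = as.numeric(c(arom_bond, arom_bond)),
    ring = as.numeric(c(ring_bond, ring_bond))
  )
  structure(
    list(nodes = nodes, symbols = symbols, edges = edges, n_nodes = n),
    class = "MolGraph"
  )
}

.is_single_atom <- function(can) {
  grepl("^(\\[[A-Z][a-z]?H?\\d*[+-]?\\d*\\]|Cl|Br|[BCNOPSFI])$", can)
}

.single_atom_graph <- function(can) {
  inner <- gsub("^\\[|\\]$", "", can)
  sym <- regmatches(inner, regexpr("^[A-Z][a-z]?", inner))
  chg <- 0L
  cm <- regmatches(inner, regexpr("[+-]\\d*$", inner))
  if (length(cm) && nzchar(cm)) {
    sgn <- if (substr(cm, 1, 1) == "+") 1L else -1L
    num <- sub("^[+-]", "", cm)
    chg <- sgn * if (nzchar(num)) as.integer(num) else 1L
  }
  idx <- match(sym, .ATOM_TABLE$symbol)
  if (is.na(idx)) {
    .condition_stop("carcipred_invalid_molecule",
                    paste0("unsupported element: ", sym))
  }
  nodes <- cbind(atomic_number = .ATOM_TABLE$number[idx],
                 atomic_mass = .ATOM_TABLE$mass[idx],
                 formal_charge = chg, degree = 0, aromatic = 0, in_ring = 0)
  structure(
    list(nodes = nodes, symbols = sym,
         edges = data.frame(i = integer(0), j = integer(0),
                            order = numeric(0), aromatic = numeric(0),
                            ring = numeric(0)),
         n_nodes = 1L),
    class = "MolGraph"
  )
}

.check_valence <- function(graph) {
  n <- graph$n_nodes
  ei <- graph$edges$i[seq_len(nrow(graph$edges) / 2)]
  order <- graph$edges$order[seq_len(nrow(graph$edges) / 2)]
  ej <- graph$edges$j[seq_len(nrow(graph$edges) / 2)]
  # treat order-4 (aromatic SDF convention) as 1.5
  ord <- ifelse(order == 4, 1.5, order)
  val <- rep(0, n)
  for (k in seq_along(ei)) {
    val[ei[k]] <- val[ei[k]] + ord[k]
    val[ej[k]] <- val[ej[k]] + ord[k]
  }
  idx <- match(graph$symbols, .ATOM_TABLE$symbol)
  maxv <- .ATOM_TABLE$max_valence[idx]
  chg <- graph$nodes[, "formal_charge"]
  # positive charge on N/O/S/P raises capacity, negative lowers it
  adj <- ifelse(graph$symbols %in% c("N", "O", "S", "P"), chg, 0)
  allowed <- maxv + adj
  bad <- which(val > allowed + 1e-9)
  if (length(bad)) {
    .condition_stop(
      "carcipred_invalid_molecule",
      paste0("valence violation at atom(s) ",
             paste(graph$symbols[bad], bad, sep = "", collapse = ", "))
    )
  }
  invisible(TRUE)
}

#' Parse a set of SMILES strings into Molecule objects
#'
#' Batch loader with the skip-and-log policy: strings that fail OpenBabel
#' parsing or the valence audit are dropped and reported in the `skipped`
#' attribute; with `strict = TRUE` the first failure raises an
#' invalid-molecule error instead.
#'
#' @param smiles character vector of SMILES.
#' @param ids character vector of identifiers (same length).
#' @param strict fail on first invalid structure instead of skipping.
#' @return list of `Molecule` objects with attribute `skipped`
#'   (data.frame id, smiles, reason).
#' @export
parse_molecule_set <- function(smiles, ids = NULL, strict = FALSE) {
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  stopifnot(length(smiles) == length(ids))
  can <- canonical_smiles_batch(smiles)
  skipped <- data.frame(id = character(0), smiles = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  bad <- which(is.na(can))
  if (length(bad)) {
    if (strict) {
      .condition_stop("carcipred_invalid_molecule",
                      paste0("unparsable SMILES: ", smiles[bad[1L]]))
    }
    skipped <- rbind(skipped, data.frame(id = ids[bad], smiles = smiles[bad],
                                         reason = "unparsable",
                                         stringsAsFactors = FALSE))
  }
  keep <- which(!is.na(can))
  mols <- vector("list", 0L)
  if (length(keep)) {
    v <- can[keep]
    names(v) <- ids[keep]
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(v))
    for (t in seq_along(keep)) {
      i <- keep[t]
      m <- tryCatch({
        g <- if (.is_single_atom(can[i])) .single_atom_graph(can[i])
             else .graph_from_sdf(sdfset[[t]])
        .check_valence(g)
        structure(
          list(id = ids[i], smiles = smiles[i], canonical_smiles = can[i],
               graph = g),
          class = "Molecule"
        )
      }, carcipred_invalid_molecule = function(e) e)
      if (inherits(m, "condition")) {
        if (strict) stop(m)
        skipped <- rbind(skipped, data.frame(
          id = ids[i], smiles = smiles[i],
          reason = conditionMessage(m), stringsAsFactors = FALSE))
      } else {
        mols[[length(mols) + 1L]] <- m
      }
    }
  }
  attr(mols, "skipped") <- skipped
  mols
}

#' Parse a single SMILES string
#'
#' @param s SMILES string (non-empty).
#' @param id molecule identifier.
#' @return a `Molecule` object: fields `id`, `smiles`, `canonical_smiles`,
#'   and the parsed `graph`.
#' @examples
#' \dontrun{
#' m <- parse_smiles("CCO", "ethanol")
#' m$canonical_smiles
#' }
#' @export
parse_smiles <- function(s, id = "mol") {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    .condition_stop("carcipred_invalid_molecule", "empty or non-scalar SMILES")
  }
  out <- parse_molecule_set(s, id, strict = TRUE)
  out[[1L]]
}

#' Canonical SMILES of a parsed molecule
#'
#' Deterministic within a run; equal structures map to equal strings.
#' Canonical strings are implementation-defined (OpenBabel's algorithm);
#' cross-toolkit equality is not promised.
#'
#' @param m a `Molecule`.
#' @return canonical SMILES string.
#' @export
canonicalize <- function(m) {
  stopifnot(inherits(m, "Molecule"))
  m$canonical_smiles
}

#' Molecular graph of a parsed molecule
#'
#' Returns the node/edge representation used by the graph encoder: one node
#' per heavy atom with features (atomic number, atomic mass, formal charge,
#' degree, aromatic flag, ring flag) and one directed edge pair per bond with
#' features (bond order, aromatic flag, ring flag).
#'
#' @param m a `Molecule`.
#' @return a `MolGraph`: `nodes` (matrix n x 6), `symbols`, `edges`
#'   (data.frame i, j, order, aromatic, ring; both directions), `n_nodes`.
#' @export
mol_to_graph <- function(m) {
  stopifnot(inherits(m, "Molecule"))
  m$graph
}

.fold_bits <- function(bits, n_bits) {
  len <- length(bits)
  if (n_bits >= len) {
    return(as.integer(c(bits, rep(0L, n_bits - len))))
  }
  pad <- (n_bits - len %% n_bits) %% n_bits
  mat <- matrix(c(bits, rep(0, pad)), nrow = n_bits)
  as.integer(rowSums(mat) > 0)
}

.new_fp <- function(bits, scheme) {
  structure(list(bits = as.integer(bits), scheme = scheme,
                 n_bits = length(bits)), class = "FingerprintVector")
}

# Batch fingerprints through the obabel CLI (FPS interchange format).
# Bit i (0-based) of the fingerprint lives in byte i %/% 8, position i %% 8
# counted from the least significant bit of the byte.
.ob_fp_batch <- function(smiles, type) {
  stopifnot(length(smiles) >= 1L)
  tags <- paste0("q", seq_along(smiles))
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".fps")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, tags), fin)
  suppressWarnings(
    system2("obabel", c("-ismi", fin, "-ofps", paste0("-xf", type),
                        "-O", fout, "-e"),
            stdout = FALSE, stderr = FALSE)
  )
  lines <- readLines(fout, warn = FALSE)
  nb_line <- grep("^#num_bits=", lines, value = TRUE)
  num_bits <- as.integer(sub("^#num_bits=", "", nb_line[1L]))
  rec <- lines[!startsWith(lines, "#")]
  rec <- rec[nzchar(rec)]
  parts <- strsplit(rec, "\t", fixed = TRUE)
  hex <- vapply(parts, `[[`, "", 1L)
  tag <- vapply(parts, `[[`, "", 2L)
  hit <- match(tags, tag)
  if (anyNA(hit)) {
    .condition_stop("carcipred_invalid_molecule",
                    paste0("fingerprinting failed for: ",
                           paste(smiles[is.na(hit)], collapse = ", ")))
  }
  hex <- hex[hit]
  nbytes <- nchar(hex[1L]) / 2L
  bytes <- matrix(0L, length(hex), nbytes)
  for (b in seq_len(nbytes)) {
    bytes[, b] <- strtoi(substring(hex, 2L * b - 1L, 2L * b), 16L)
  }
  bits <- matrix(0L, length(hex), 8L * nbytes)
  for (k in 0:7) {
    bits[, seq(k + 1L, 8L * nbytes, by = 8L)] <-
      bitwAnd(bitwShiftR(bytes, k), 1L)
  }
  bits[, seq_len(num_bits), drop = FALSE]
}

#' Circular (Morgan/ECFP) fingerprint
#'
#' Extended-connectivity fingerprint of the requested radius (radius 2 is the
#' ECFP4-equivalent default), computed by OpenBabel and folded down to
#' `n_bits` positions by OR.
#'
#' @param m a `Molecule`.
#' @param radius neighborhood radius (>= 1).
#' @param n_bits fingerprint length (default 2048).
#' @return `FingerprintVector` with scheme `"circular"`.
#' @export
circular_fingerprint <- function(m, radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(m, "Molecule"), radius >= 1L, n_bits >= 1L)
  raw <- .ob_fp_batch(m$canonical_smiles, paste0("ECFP", 2L * radius))[1L, ]
  .new_fp(.fold_bits(raw, n_bits), "circular")
}

.path_strings <- function(graph, max_bonds = 7L) {
  n <- graph$n_nodes
  half <- nrow(graph$edges) / 2
  if (half == 0L) return(character(0))
  adj <- vector("list", n)
  ei <- graph$edges$i; ej <- graph$edges$j; eo <- graph$edges$order
  earom <- graph$edges$aromatic
  for (k in seq_len(nrow(graph$edges))) {
    adj[[ei[k]]] <- rbind(adj[[ei[k]]], c(ej[k], eo[k], earom[k]))
  }
  sym <- ifelse(graph$nodes[, "aromatic"] > 0,
                tolower(graph$symbols), graph$symbols)
  bond_tok <- function(order, arom) if (arom > 0) "a" else as.character(order)
  acc <- new.env(parent = emptyenv())
  walk <- function(path_atoms, toks) {
    last <- path_atoms[length(path_atoms)]
    nb <- adj[[last]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1L]
      if (nxt %in% path_atoms) next
      t2 <- c(toks, bond_tok(nb[r, 2L], nb[r, 3L]), sym[nxt])
      fwd <- paste(t2, collapse = "")
      rev_ <- paste(rev(t2), collapse = "")
      key <- if (fwd <= rev_) fwd else rev_
      assign(key, TRUE, envir = acc)
      if ((length(t2) - 1L) / 2L < max_bonds) walk(c(path_atoms, nxt), t2)
    }
  }
  for (s in seq_len(n)) walk(s, sym[s])
  ls(acc)
}

.hash_string <- function(s, n_bits) {
  codes <- utf8ToInt(s)
  h <- 7
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  (h %% n_bits) + 1L
}

#' Path-based (linear substructure) fingerprint
#'
#' Enumerates all simple bond paths of length 1-7, canonicalizes each path
#' string over its two reading directions, and hashes it into `n_bits`
#' positions.
#'
#' @param m a `Molecule`.
#' @param n_bits fingerprint length (default 2048).
#' @param max_bonds longest path length in bonds.
#' @return `FingerprintVector` with scheme `"path"`.
#' @export
path_fingerprint <- function(m, n_bits = 2048L, max_bonds = 7L) {
  stopifnot(inherits(m, "Molecule"), n_bits >= 1L)
  paths <- .path_strings(m$graph, max_bonds)
  bits <- integer(n_bits)
  for (p in paths) bits[.hash_string(p, n_bits)] <- 1L
  .new_fp(bits, "path")
}

#' Structural-key (MACCS) fingerprint
#'
#' The published 166-key structural catalogue as computed by OpenBabel, plus
#' one trailing padding bit, giving 167 bits.
#'
#' @param m a `Molecule`.
#' @return `FingerprintVector` with scheme `"structural_key"`, length 167.
#' @export
structural_key_fingerprint <- function(m) {
  stopifnot(inherits(m, "Molecule"))
  raw <- .ob_fp_batch(m$canonical_smiles, "MACCS")[1L, ]
  .new_fp(c(raw, 0L), "structural_key")
}

#' Fingerprint matrix for a set of molecules
#'
#' Batch featurization: one row per molecule, columns are fingerprint bits of
#' the requested scheme. Much faster than per-molecule calls for large sets.
#'
#' @param mols list of `Molecule` objects.
#' @param scheme one of `"circular"`, `"path"`, `"structural_key"`.
#' @param radius circular-fingerprint radius.
#' @param n_bits fingerprint length for circular/path schemes.
#' @return integer matrix (n molecules x n_bits), rownames = molecule ids.
#' @export
fingerprint_matrix <- function(mols, scheme = c("circular", "path",
                                                "structural_key"),
                               radius = 2L, n_bits = 2048L) {
  scheme <- match.arg(scheme)
  stopifnot(length(mols) >= 1L)
  can <- vapply(mols, function(m) m$canonical_smiles, "")
  out <- switch(scheme,
    circular = {
      raw <- .ob_fp_batch(can, paste0("ECFP", 2L * radius))
      t(apply(raw, 1L, .fold_bits, n_bits = n_bits))
    },
    structural_key = {
      raw <- .ob_fp_batch(can, "MACCS")
      cbind(raw, 0L)
    },
    path = {
      m <- matrix(0L, length(mols), n_bits)
      for (i in seq_along(mols)) {
        m[i, ] <- path_fingerprint(mols[[i]], n_bits)$bits
      }
      m
    })
  rownames(out) <- vapply(mols, function(m) m$id, "")
  storage.mode(out) <- "integer"
  out
}

#' Concatenated model-input feature block
#'
#' Lays out `[circular | path | structural_key | graph_embedding]` with named
#' offsets; total length 2048 + 2048 + 167 + `length(graph_embedding)` at the
#' defaults.
#'
#' @param m a `Molecule`.
#' @param graph_embedding numeric vector (possibly length 0) from the graph
#'   encoder or an external embedding table.
#' @param radius,n_bits passed to the circular/path fingerprints.
#' @return a `FeatureBlock`: `vector` plus `layout` (list of
#'   `c(offset, length)` per segment, 1-based offsets).
#' @export
build_feature_block <- function(m, graph_embedding = numeric(0),
                                radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(m, "Molecule"), is.numeric(graph_embedding))
  fc <- circular_fingerprint(m, radius, n_bits)
  fp <- path_fingerprint(m, n_bits)
  fk <- structural_key_fingerprint(m)
  segs <- list(circular = fc$bits, path = fp$bits,
               structural_key = fk$bits, graph_embedding = graph_embedding)
  lens <- vapply(segs, length, 1L)
  offs <- cumsum(c(1L, lens[-length(lens)]))
  layout <- Map(function(o, l) c(offset = o, length = l), offs, lens)
  names(layout) <- names(segs)
  structure(list(vector = as.numeric(unlist(segs, use.names = FALSE)),
                 layout = layout),
            class = "FeatureBlock")
}

#' Read a molecule table from CSV/TSV
#'
#' Expects a header with at least `id` and `smiles` columns (case
#' insensitive); extra columns are preserved.
#'
#' @param path file path; tab or comma delimited (sniffed from the header).
#' @return data.frame with columns `id`, `smiles`, plus extras.
#' @export
read_molecule_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  names(df) <- tolower(names(df))
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("molecule table needs 'id' and 'smiles' columns")
  }
  df
}
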