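#' Atom featurizer configuration
#'
#' Fixes the vocabulary used to turn a parsed atom into a fixed-length
#' numeric feature vector. The encoding is one-hot over element (with a
#' reserved "other" slot), degree, hybridization and total hydrogen count,
#' plus scalar formal charge and aromatic/ring indicator flags. Freezing
#' this vocabulary fixes `d_atom`, the shared node-feature width of every
#' molecular graph in a dataset.
#'
#' @param elements character vector of explicit element symbols; anything
#'   else maps to the reserved "other" slot.
#' @param max_degree largest heavy-atom degree encoded explicitly (one-hot
#'   over 0..max_degree; larger degrees clamp to the last slot).
#' @param max_h largest total (implicit) hydrogen count encoded explicitly.
#' @param hybridizations hybridization levels encoded one-hot.
#' @return an object of class `atom_featurizer_config` with a `d_atom` field.
#' @export
#' @examples
#' cfg <- atom_featurizer_config()
#' cfg$d_atom
atom_featurizer_config <- function(elements = c("C", "N", "O", "S", "F",
                                                "Cl", "Br", "I", "P"),
                                   max_degree = 5L,
                                   max_h = 4L,
                                   hybridizations = c("sp", "sp2", "sp3",
                                                      "other")) {
  cfg <- list(
    elements = elements,
    max_degree = as.integer(max_degree),
    max_h = as.integer(max_h),
    hybridizations = hybridizations
  )
  cfg$d_atom <- (length(elements) + 1L) + (cfg$max_degree + 1L) + 1L + 1L +
    1L + length(hybridizations) + (cfg$max_h + 1L)
  class(cfg) <- "atom_featurizer_config"
  cfg
}

#' Encode one atom descriptor as a numeric feature vector
#'
#' Total function over parsed atoms: out-of-vocabulary elements fall into
#' the reserved "other" element slot and degrees/H-counts clamp to the last
#' one-hot slot. Identical descriptors always yield identical vectors.
#'
#' @param atom a list with fields `element`, `degree`, `formal_charge`,
#'   `hybridization`, `aromatic`, `in_ring`, `n_h`.
#' @param config an [atom_featurizer_config()].
#' @return numeric vector of length `config$d_atom`.
#' @export
atom_feature_vector <- function(atom, config = atom_featurizer_config()) {
  one_hot <- function(idx, n) {
    v <- numeric(n)
    v[idx] <- 1
    v
  }
  n_el <- length(config$elements)
  el_idx <- match(atom$element, config$elements)
  el <- one_hot(if (is.na(el_idx)) n_el + 1L else el_idx, n_el + 1L)
  deg <- one_hot(min(atom$degree, config$max_degree) + 1L,
                 config$max_degree + 1L)
  hyb_idx <- match(atom$hybridization, config$hybridizations)
  hyb <- one_hot(if (is.na(hyb_idx)) length(config$hybridizations) else hyb_idx,
                 length(config$hybridizations))
  hs <- one_hot(min(atom$n_h, config$max_h) + 1L, config$max_h + 1L)
  c(el, deg, as.numeric(atom$formal_charge), as.numeric(isTRUE(atom$aromatic)),
    as.numeric(isTRUE(atom$in_ring)), hyb, hs)
}

# SDF V2000 charge-code column -> formal charge
.sdf_charge_map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                     `6` = -2, `7` = -3)

.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3)

.implicit_h <- function(element, charge, bond_order_sum) {
  v <- .default_valence[element]
  if (is.na(v)) return(0L)
  # accepting-lone-pair elements gain capacity with positive charge
  v <- if (element %in% c("N", "P", "O", "S")) v + charge else v - abs(charge)
  as.integer(max(0, v - bond_order_sum))
}

# Parse the atom lines of a V2000 molfile produced by OpenBabel; used only
# for zero-bond molecules, which ChemmineR's SDF container cannot hold.
.parse_v2000_atoms <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts <- grep("V2000", lines, fixed = TRUE)[1]
  if (is.na(counts)) return(NULL)
  n_atoms <- as.integer(substr(lines[counts], 1, 3))
  if (is.na(n_atoms) || n_atoms < 1) return(NULL)
  at <- lines[(counts + 1):(counts + n_atoms)]
  data.frame(
    element = trimws(substr(at, 32, 34)),
    charge_code = as.integer(substr(at, 37, 39)),
    stringsAsFactors = FALSE
  )
}

# Parse one SMILES into atoms (descriptor data.frame) and bonds (i, j, order)
.parse_smiles <- function(smiles) {
  check_that(is.character(smiles) && length(smiles) == 1 && nzchar(trimws(smiles)),
             "cannot parse empty SMILES string")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "q"))),
    error = function(e) NULL
  )
  valid <- !is.null(sdf) && length(sdf) == 1 && ChemmineR::validSDF(sdf)[1]
  if (!valid) {
    # zero-bond molecules (one heavy atom) are valid chemistry that the SDF
    # container rejects; read the molfile atom block directly
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
      error = function(e) ""
    )
    atoms <- if (nzchar(txt)) .parse_v2000_atoms(txt) else NULL
    if (is.null(atoms)) abort("unparsable SMILES: '%s'", smiles)
    atoms$charge <- unname(.sdf_charge_map[as.character(atoms$charge_code)])
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "order")))
    ring_atoms <- arom_atoms <- integer(0)
  } else {
    mol <- sdf[[1]]
    ab <- ChemmineR::atomblock(mol)
    atoms <- data.frame(
      element = sub("_[0-9]+$", "", rownames(ab)),
      charge = unname(.sdf_charge_map[as.character(ab[, "C5"])]),
      stringsAsFactors = FALSE
    )
    bb <- ChemmineR::bondblock(mol)
    bonds <- cbind(i = as.integer(bb[, "C1"]), j = as.integer(bb[, "C2"]),
                   order = as.integer(bb[, "C3"]))
    ring_info <- tryCatch(
      ChemmineR::rings(mol, type = "all", arom = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_idx <- function(rings) {
      unique(as.integer(sub(".*_", "", unlist(rings, use.names = FALSE))))
    }
    ring_atoms <- ring_idx(ring_info$RINGS %||% list())
    arom_flags <- ring_info$AROMATIC %||% logical(0)
    arom_atoms <- ring_idx((ring_info$RINGS %||% list())[which(arom_flags)])
  }
  atoms$charge[is.na(atoms$charge)] <- 0
  n <- nrow(atoms)
  if (n == 0) abort("unparsable SMILES: '%s'", smiles)
  deg <- integer(n)
  order_sum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      for (a in bonds[k, c("i", "j")]) {
        deg[a] <- deg[a] + 1L
        order_sum[a] <- order_sum[a] + bonds[k, "order"]
        if (bonds[k, "order"] == 2) n_double[a] <- n_double[a] + 1L
        if (bonds[k, "order"] == 3) n_triple[a] <- n_triple[a] + 1L
      }
    }
  }
  atoms$degree <- deg
  atoms$aromatic <- seq_len(n) %in% arom_atoms
  atoms$in_ring <- seq_len(n) %in% ring_atoms
  atoms$hybridization <- vapply(seq_len(n), function(a) {
    if (!atoms$element[a] %in% names(.default_valence)) return("other")
    if (n_triple[a] > 0 || n_double[a] >= 2) return("sp")
    if (n_double[a] > 0 || atoms$aromatic[a]) return("sp2")
    "sp3"
  }, character(1))
  atoms$n_h <- vapply(seq_len(n), function(a) {
    .implicit_h(atoms$element[a], atoms$charge[a], order_sum[a])
  }, integer(1))
  list(atoms = atoms, bonds = bonds)
}

#' Convert a SMILES string into a bidirected molecular graph
#'
#' Parses a SMILES string (heavy atoms only; hydrogens stay implicit) and
#' returns the graph consumed by the attention encoder: a per-atom feature
#' matrix plus a directed edge list in which every bond appears in both
#' directions and, after augmentation, every atom carries exactly one
#' self-loop. Self-loops guarantee every node has a non-empty neighborhood
#' so the attention softmax is always defined.
#'
#' @param smiles a single SMILES string.
#' @param config an [atom_featurizer_config()].
#' @param drug_id optional identifier stored on the graph.
#' @param self_loops add one self-loop per atom (default TRUE).
#' @return an object of class `molecular_graph`: list with `node_features`
#'   (n_atoms x d_atom), `edges` (m x 2, 0-based source/destination),
#'   `n_atoms`, `n_bond_edges`, `drug_id`, `atoms`, `bonds`.
#' @export
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms        # 3
#' g$n_bond_edges   # 4: two bonds, both directions
smiles_to_graph <- function(smiles, config = atom_featurizer_config(),
                            drug_id = NULL, self_loops = TRUE) {
  parsed <- .parse_smiles(smiles)
  atoms <- parsed$atoms
  n <- nrow(atoms)
  feats <- t(vapply(seq_len(n), function(a) {
    atom_feature_vector(
      list(element = atoms$element[a], degree = atoms$degree[a],
           formal_charge = atoms$charge[a],
           hybridization = atoms$hybridization[a],
           aromatic = atoms$aromatic[a], in_ring = atoms$in_ring[a],
           n_h = atoms$n_h[a]),
      config
    )
  }, numeric(config$d_atom)))
  bond_edges <- if (nrow(parsed$bonds) > 0) {
    rbind(cbind(parsed$bonds[, "i"], parsed$bonds[, "j"]),
          cbind(parsed$bonds[, "j"], parsed$bonds[, "i"])) - 1L
  } else {
    matrix(integer(0), ncol = 2)
  }
  edges <- bond_edges
  if (self_loops) edges <- rbind(edges, cbind(seq_len(n), seq_len(n)) - 1L)
  g <- list(
    node_features = feats,
    edges = edges,
    n_atoms = n,
    n_bond_edges = nrow(bond_edges),
    drug_id = drug_id,
    atoms = atoms,
    bonds = parsed$bonds
  )
  class(g) <- "molecular_graph"
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph%s: %d atoms, %d directed bond edges, d_atom=%d>\n",
              if (is.null(x$drug_id)) "" else paste0(" ", x$drug_id),
              x$n_atoms, x$n_bond_edges, ncol(x$node_features)))
  invisible(x)
}

# Deterministic integer hash of an integer vector (stays within 2^31)
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (as.numeric(x) %% 2147483647)) %% 2147483647
  h
}

#' Circular (Morgan/ECFP-style) fingerprint of a molecular graph
#'
#' Iterative neighborhood hashing: each atom starts from a hash of its
#' descriptor tuple, then for `radius` rounds absorbs the sorted
#' (bond order, neighbor invariant) multiset of its neighbors. Every
#' invariant produced at every round sets one bit (invariant mod `n_bits`).
#' Radius 2 corresponds to ECFP4-diameter substructures.
#'
#' @param graph a [smiles_to_graph()] result.
#' @param radius neighborhood radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return sorted integer vector of set-bit indices (0-based), possibly empty.
#' @export
morgan_fingerprint <- function(graph, radius = 2L, n_bits = 2048L) {
  atoms <- graph$atoms
  n <- nrow(atoms)
  if (n == 0) return(integer(0))
  inv <- vapply(seq_len(n), function(a) {
    .hash_ints(c(match(atoms$element[a], c(names(.default_valence), "X"),
                       nomatch = 99L),
                 atoms$degree[a], round(atoms$charge[a]), atoms$n_h[a],
                 as.integer(atoms$aromatic[a]), as.integer(atoms$in_ring[a])))
  }, numeric(1))
  nbrs <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[k, "i"]; j <- graph$bonds[k, "j"]
      o <- graph$bonds[k, "order"]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  all_inv <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(a) {
      nb <- nbrs[[a]]
      if (is.null(nb)) return(.hash_ints(c(r, inv[a])))
      pieces <- cbind(nb[, 2], inv[nb[, 1]])
      pieces <- pieces[order(pieces[, 1], pieces[, 2]), , drop = FALSE]
      .hash_ints(c(r, inv[a], as.numeric(t(pieces))))
    }, numeric(1))
    all_inv <- c(all_inv, inv)
  }
  sort(unique(as.integer(all_inv %% n_bits)))
}

#' Fingerprints for a vector of SMILES strings
#'
#' @param smiles character vector (optionally named by drug id).
#' @param radius,n_bits passed to [morgan_fingerprint()].
#' @param config atom featurizer configuration used during parsing.
#' @return named list of set-bit index vectors.
#' @export
fingerprints_from_smiles <- function(smiles, radius = 2L, n_bits = 2048L,
                                     config = atom_featurizer_config()) {
  out <- lapply(smiles, function(s) {
    morgan_fingerprint(smiles_to_graph(s, config), radius, n_bits)
  })
  names(out) <- names(smiles)
  out
}

#' Serialize a molecular graph to JSON (fixture caching)
#' @param graph a `molecular_graph`.
#' @param path output file.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(drug_id = graph$drug_id, n_atoms = graph$n_atoms,
         n_bond_edges = graph$n_bond_edges,
         node_features = graph$node_features, edges = graph$edges),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
}

#' Read a molecular graph serialized with [write_graph_json()]
#' @param path JSON file.
#' @return a `molecular_graph` (without atom/bond descriptor tables).
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- list(
    node_features = matrix(as.numeric(x$node_features),
                           nrow = x$n_atoms, byrow = FALSE),
    edges = matrix(as.integer(x$edges), ncol = 2),
    n_atoms = as.integer(x$n_atoms),
    n_bond_edges = as.integer(x$n_bond_edges),
    drug_id = x$drug_id, atoms = NULL, bonds = NULL
  )
  class(g) <- "molecular_graph"
  g
}
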