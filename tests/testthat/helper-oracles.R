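# Independent oracles used to check the implementation, plus shared small
# fixtures. Each oracle is a direct textbook computation that never calls
# the code path it verifies.

# Affine-gap Needleman-Wunsch (Gotoh) global alignment score: a gap of
# length L costs open + L * ext. Plain dynamic programming over three
# state matrices.
nw_oracle_score <- function(a, b, submat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e18
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# brute-force Tanimoto on two bit sets
tanimoto_oracle <- function(f1, f2) {
  u <- length(union(f1, f2))
  if (u == 0) return(0)
  length(intersect(f1, f2)) / u
}

# 50 SMILES with heavy-atom and bond counts frozen from an independent
# cheminformatics parser (RDKit 2024.09)
smiles_fixture <- function() {
  txt <- "
C 1 0; CC 2 1; CCO 3 2; CCC 3 2; CCCC 4 3; CCN 3 2; CCCO 4 3; CC(C)C 4 3
CC(C)O 4 3; CCCCC 5 4; c1ccccc1 6 6; Cc1ccccc1 7 7; Oc1ccccc1 7 7
Nc1ccccc1 7 7; Clc1ccccc1 7 7; Cc1ccc(O)cc1 8 8; Cc1ccc(N)cc1 8 8
Fc1ccccc1 7 7; CCc1ccccc1 8 8; COc1ccccc1 8 8; CCOCC 5 4; CCOC(=O)C 6 5
COC(=O)CC 6 5; CCOC(=O)CC 7 6; COC 3 2; CCOCCO 6 5; CC(=O)OC 5 4
CCCOC 5 4; COCCOC 6 5; CC(=O)OCC 6 5; CCNCC 5 4; CCNC(=O)C 6 5
CN(C)CC 5 4; CNC 3 2; CCNC(=O)CC 7 6; CN(C)C 4 3; CCCNC 5 4; CNC(=O)C 5 4
CCN(CC)CC 7 6; CNCC 4 3; C#N 2 1; C#CC 3 2; CC=O 3 2; C=C 2 1
CC(=O)O 4 3; C1CCCCC1 6 6; C1CCNCC1 6 6; c1ccncc1 6 6; CC(N)C(=O)O 6 5
[NH4+] 1 0"
  rows <- strsplit(trimws(unlist(strsplit(gsub("\n", ";", txt), ";"))), " ")
  rows <- rows[lengths(rows) == 3]
  data.frame(
    smiles = vapply(rows, `[`, character(1), 1),
    n_heavy = as.integer(vapply(rows, `[`, character(1), 2)),
    n_bonds = as.integer(vapply(rows, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
}

# two well-separated Gaussian blobs embedded in d dimensions
make_blobs <- function(n_per_class = 150, d = 16, sep = 6, seed = 7) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(rep(sep, 2), rep(0, d - 2)))
  X <- rbind(
    matrix(stats::rnorm(n_per_class * d), n_per_class, d) +
      matrix(centers[1, ], n_per_class, d, byrow = TRUE),
    matrix(stats::rnorm(n_per_class * d), n_per_class, d) +
      matrix(centers[2, ], n_per_class, d, byrow = TRUE)
  )
  colnames(X) <- paste0("x", seq_len(d))
  list(X = X, y = rep(0:1, each = n_per_class))
}
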