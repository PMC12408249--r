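#' Tanimoto similarity matrix from fingerprint bit sets
#'
#' Entry (i, j) is |F_i intersect F_j| / |F_i union F_j| on set-bit indices.
#' A pair in which either fingerprint is empty scores 0, including the
#' diagonal of an empty-fingerprint drug: an empty fingerprint carries no
#' evidence of similarity, not evidence of identity.
#'
#' @param fingerprints list of integer vectors of set-bit indices, named by
#'   drug id.
#' @return a `similarity_matrix`: symmetric numeric matrix in \[0, 1\] with
#'   an `ids` attribute.
#' @export
tanimoto_similarity <- function(fingerprints) {
  n <- length(fingerprints)
  ids <- names(fingerprints) %||% as.character(seq_len(n))
  fps <- lapply(fingerprints, function(f) sort(unique(as.integer(f))))
  sizes <- lengths(fps)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (sizes[i] == 0) next
    m[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      if (sizes[j] == 0) next
      inter <- length(intersect(fps[[i]], fps[[j]]))
      m[i, j] <- m[j, i] <- inter / (sizes[i] + sizes[j] - inter)
    }
  }
  new_similarity_matrix(m, ids)
}

new_similarity_matrix <- function(values, ids) {
  dimnames(values) <- list(ids, ids)
  structure(values, ids = ids, class = c("similarity_matrix", "matrix", "array"))
}

#' Cosine similarity between the rows of a binary interaction matrix
#'
#' Used to derive drug-drug similarity from drug-target interaction
#' profiles: entry (i, j) is the cosine of rows i and j. Any pair involving
#' an all-zero row (a drug with no recorded targets) scores 0, including
#' that drug's diagonal entry.
#'
#' @param M binary matrix (drugs x targets), rownames are drug ids.
#' @return a `similarity_matrix` over the row ids of `M`.
#' @export
interaction_cosine <- function(M) {
  M <- as.matrix(M)
  check_that(all(M %in% c(0, 1)), "interaction matrix entries must be 0/1")
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  norms <- sqrt(rowSums(M^2))
  dot <- M %*% t(M)
  denom <- outer(norms, norms)
  s <- ifelse(denom > 0, dot / denom, 0)
  s <- pmin(pmax((s + t(s)) / 2, 0), 1)   # symmetrize against fp noise
  diag(s) <- ifelse(norms > 0, 1, 0)
  new_similarity_matrix(s, ids)
}

# affine-gap global alignment score via Biostrings, BLOSUM62 / open 10 / ext 1
.nw_score <- function(a, b, submat, gap_open, gap_ext) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_ext, type = "global", scoreOnly = TRUE
  )
}

#' Global-alignment similarity matrix for amino-acid sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps
#' (opening 10, extension 1). Raw scores are normalized symmetrically as
#' score(i, j) / sqrt(score(i, i) * score(j, j)) and clipped to \[0, 1\], so
#' self-similarity is exactly 1 for non-empty sequences. Multi-chain drugs
#' should be passed as their concatenated chains.
#'
#' @param sequences character vector of amino-acid strings (20-letter
#'   alphabet plus X), named by drug id.
#' @param gap_open,gap_ext affine gap penalties (non-negative costs).
#' @return a `similarity_matrix`.
#' @export
global_alignment_similarity <- function(sequences, gap_open = 10,
                                        gap_ext = 1) {
  n <- length(sequences)
  ids <- names(sequences) %||% as.character(seq_len(n))
  empty <- !nzchar(sequences)
  if (any(empty)) {
    abort("empty sequence for drug(s): %s",
          paste(ids[empty], collapse = ", "))
  }
  submat <- .blosum62()
  self <- vapply(sequences, function(s) .nw_score(s, s, submat,
                                                  gap_open, gap_ext),
                 numeric(1))
  m <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      sc <- .nw_score(sequences[[i]], sequences[[j]], submat,
                      gap_open, gap_ext)
      denom <- sqrt(self[i] * self[j])
      v <- if (is.finite(denom) && denom > 0) sc / denom else 0
      m[i, j] <- m[j, i] <- min(max(v, 0), 1)
    }
  }
  new_similarity_matrix(m, ids)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Build a binary interaction matrix from an edge list
#'
#' @param edges data.frame with two identifier columns (first = row entity,
#'   second = column entity); extra columns ignored.
#' @param row_ids,col_ids full identifier rosters; rows/columns appear even
#'   when a drug has no edges (all-zero row).
#' @param symmetric if TRUE, row and column rosters must match and each
#'   edge sets both (i, j) and (j, i); diagonal forced to 0.
#' @return binary matrix with id dimnames.
#' @export
interaction_matrix <- function(edges, row_ids, col_ids = row_ids,
                               symmetric = FALSE) {
  m <- matrix(0, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(edges) > 0) {
    a <- as.character(edges[[1]])
    b <- as.character(edges[[2]])
    bad <- c(setdiff(a, row_ids), setdiff(b, col_ids))
    if (length(bad) > 0) {
      abort("edge list references unknown identifier(s): %s",
            paste(utils::head(unique(bad), 10), collapse = ", "))
    }
    m[cbind(a, b)] <- 1
    if (symmetric) {
      check_that(identical(row_ids, col_ids),
                 "symmetric interaction matrix needs one shared roster")
      m[cbind(b, a)] <- 1
      diag(m) <- 0
    }
  }
  m
}

#' Fuse an interaction matrix with two similarity matrices
#'
#' The fused feature block is the plain elementwise sum of the drug-drug
#' interaction matrix and the two similarity matrices (structure/sequence
#' derived and target-profile derived), with no rescaling, so entries lie
#' in \[0, 3\].
#'
#' @param I binary drug-drug interaction matrix.
#' @param T_ target-profile similarity matrix.
#' @param S structure or sequence similarity matrix.
#' @return numeric matrix `I + T_ + S` with the shared dimnames.
#' @export
fuse_feature_block <- function(I, T_, S) {
  dims <- list(dim(I), dim(T_), dim(S))
  check_that(length(unique(vapply(dims, paste, character(1),
                                  collapse = "x"))) == 1,
             "fuse: matrices must share one shape")
  ids <- list(rownames(I), rownames(T_), rownames(S))
  ids <- ids[!vapply(ids, is.null, logical(1))]
  if (length(ids) > 1) {
    check_that(all(vapply(ids[-1], identical, logical(1), ids[[1]])),
               "fuse: matrices must share one id order")
  }
  out <- unclass(I) + unclass(T_) + unclass(S)
  attr(out, "ids") <- NULL
  out
}
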