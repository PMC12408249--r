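#' A biotech drug with one or more amino-acid chains
#'
#' @param drug_id identifier.
#' @param chains character vector of non-empty amino-acid strings.
#' @return object of class `protein_record`.
#' @export
protein_record <- function(drug_id, chains) {
  chains <- as.character(chains)
  check_that(length(chains) >= 1, "protein record '%s' needs at least one chain",
             drug_id)
  if (any(!nzchar(chains))) {
    abort("protein record '%s' has an empty chain", drug_id)
  }
  structure(list(drug_id = drug_id, chains = chains),
            class = "protein_record")
}

#' Deterministic k-mer composition sequence embedder
#'
#' An offline stand-in for a pretrained protein language model, exposing
#' the same interface and output width (default 1024). Each chain is mapped
#' to its k-mer (k = 3) composition, hashed into `d_emb` buckets with
#' seed-salted signs, and L2-normalized, so identical sequences always give
#' identical unit-norm vectors and composition differences move the
#' embedding. It captures none of the contextual structure a trained
#' language model learns; it exists so every downstream tensor shape and
#' contract can be exercised without model downloads.
#'
#' @param d_emb embedding width (default 1024).
#' @param k k-mer length (default 3).
#' @param seed salt for the hashing (default 0).
#' @return object of class `sequence_embedder` with fields `embed`
#'   (function(chain) -> numeric(d_emb)) and `d_emb`.
#' @export
stub_embedder <- function(d_emb = 1024L, k = 3L, seed = 0L) {
  d_emb <- as.integer(d_emb)
  force(k); force(seed)
  embed <- function(chain) {
    check_that(is.character(chain) && length(chain) == 1 && nzchar(chain),
               "embedder requires one non-empty sequence")
    codes <- utf8ToInt(toupper(chain)) - 64L  # A=1 .. Z=26
    codes[codes < 1 | codes > 26] <- 24L      # fold unknowns onto X
    v <- numeric(d_emb)
    n_kmers <- length(codes) - k + 1L
    if (n_kmers < 1) {
      idx <- .hash_ints(c(seed, codes)) %% d_emb + 1
      v[idx] <- 1
      return(v)
    }
    for (s in seq_len(n_kmers)) {
      h <- .hash_ints(c(seed, codes[s:(s + k - 1L)]))
      idx <- (h %% d_emb) + 1
      sign <- if ((h %/% d_emb) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sign
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  structure(list(embed = embed, d_emb = d_emb, kind = "kmer_stub"),
            class = "sequence_embedder")
}

#' Embed a protein record by averaging its per-chain embeddings
#'
#' Each chain is embedded independently and the unweighted arithmetic mean
#' is returned, so single-chain drugs pass through unchanged and chain
#' order never matters.
#'
#' @param record a [protein_record()].
#' @param embedder a `sequence_embedder` (e.g. [stub_embedder()]).
#' @return numeric vector of length `embedder$d_emb`.
#' @export
embed_record <- function(record, embedder) {
  vecs <- lapply(seq_along(record$chains), function(i) {
    v <- tryCatch(embedder$embed(record$chains[[i]]), error = function(e) {
      abort("embedding failed for drug '%s' chain %d: %s",
            record$drug_id, i, conditionMessage(e))
    })
    check_that(length(v) == embedder$d_emb,
               "embedder returned wrong width for drug '%s' chain %d",
               record$drug_id, i)
    v
  })
  Reduce(`+`, vecs) / length(vecs)
}

#' Embedding matrix for a list of protein records
#'
#' @param records list of [protein_record()]s.
#' @param embedder a `sequence_embedder`.
#' @return matrix (n_records x d_emb) with drug ids as rownames.
#' @export
embed_records <- function(records, embedder = stub_embedder()) {
  out <- t(vapply(records, embed_record, numeric(embedder$d_emb),
                  embedder = embedder))
  rownames(out) <- vapply(records, `[[`, character(1), "drug_id")
  out
}
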