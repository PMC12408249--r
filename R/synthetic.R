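# Synthetic corpus generator: a download-free stand-in for a curated
# drug-interaction corpus with a planted, cluster-determined label rule.

#' Synthetic corpus configuration
#'
#' Defines two drug populations partitioned into latent clusters. Small
#' molecules are drawn per cluster from one chemical scaffold family with
#' enumerated substituent edits; biotech drugs carry 1-3 amino-acid chains
#' built from per-cluster sequence motifs. Drug-target edges concentrate
#' inside cluster-specific target blocks, drug-drug interaction edges
#' concentrate within clusters, and the pair label is a deterministic
#' function of the (small-molecule cluster, biotech cluster) combination -
#' optionally flipped with probability `label_noise` - so every feature
#' block carries recoverable signal.
#'
#' @param n_small number of small-molecule drugs.
#' @param n_biotech number of biotech drugs.
#' @param n_targets total target roster, split 3:1 between the
#'   small-molecule and biotech target universes.
#' @param n_classes number of interaction classes including the negative
#'   class at index 0.
#' @param n_clusters latent cluster count per population (max 4: one per
#'   scaffold/motif family).
#' @param label_noise probability of flipping a pair label to a random
#'   other class.
#' @param negative_fraction approximate fraction of cluster combinations
#'   mapped to the negative (non-interacting) class.
#' @param seed RNG seed; the corpus is fully reproducible from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_small = 120L, n_biotech = 30L,
                             n_targets = 64L, n_classes = 8L,
                             n_clusters = 4L, label_noise = 0.05,
                             negative_fraction = 0.2, seed = 1L) {
  check_that(n_classes >= 2, "need at least two classes")
  check_that(label_noise >= 0 && label_noise < 0.5,
             "label_noise must be in [0, 0.5)")
  check_that(n_small > 0 && n_biotech > 0 && n_targets > 0,
             "all counts must be positive")
  check_that(n_clusters >= 2 && n_clusters <= 4,
             "n_clusters must be between 2 and 4 (one scaffold family each)")
  if (n_clusters > n_small || n_clusters > n_biotech) {
    abort("more clusters (%d) than drugs in a population", n_clusters)
  }
  structure(list(n_small = as.integer(n_small),
                 n_biotech = as.integer(n_biotech),
                 n_targets = as.integer(n_targets),
                 n_classes = as.integer(n_classes),
                 n_clusters = as.integer(n_clusters),
                 label_noise = label_noise,
                 negative_fraction = negative_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# scaffold families: each returns a deterministic pool of valid SMILES
.smiles_pools <- function() {
  aliphatic <- as.vector(outer(
    vapply(3:8, function(l) strrep("C", l), character(1)),
    c("", "O", "N", "C(C)C", "CO"), paste0))
  subs <- c("C", "O", "N", "Cl", "F", "CC", "OC")
  aromatic <- as.vector(outer(subs, subs, function(a, b) {
    paste0(a, "c1ccc(", b, ")cc1")
  }))
  ethers <- as.vector(outer(
    c("C", "CC", "CCC", "CC(C)", "CCCC"),
    c("OC", "OCC", "OC(=O)C", "OC(=O)CC", "COC", "OCCO"), paste0))
  amines <- as.vector(outer(
    c("C", "CC", "CCC", "CN(C)", "CCCC"),
    c("NC", "NCC", "NC(=O)C", "NC(=O)CC", "N(C)C", "NCCN"), paste0))
  list(aliphatic = aliphatic, aromatic = aromatic, ethers = ethers,
       amines = amines)
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_aa <- function(n) paste(sample(.aa_alphabet, n, replace = TRUE),
                                collapse = "")

.mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(.aa_alphabet, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

# deterministic map (sm cluster, bt cluster) -> class, long-tailed:
# the first ceil(negative_fraction * n_combos) combos are negative, the
# rest are dealt to positive classes with geometrically shrinking shares.
.combo_label_map <- function(n_clusters, n_classes, negative_fraction) {
  n_combos <- n_clusters^2
  n_neg <- min(max(round(negative_fraction * n_combos), 0L), n_combos - 1L)
  n_pos_combos <- n_combos - n_neg
  n_pos_classes <- min(n_classes - 1L, n_pos_combos)
  # shares ~ 2^{-(i-1)}, at least one combo per class
  w <- 2^(-(seq_len(n_pos_classes) - 1))
  alloc <- pmax(1L, round(w / sum(w) * n_pos_combos))
  while (sum(alloc) > n_pos_combos) alloc[which.max(alloc)] <-
    alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_pos_combos) alloc[1L] <- alloc[1L] + 1L
  map <- c(rep(0L, n_neg), rep(seq_len(n_pos_classes), alloc))
  matrix(map, n_clusters, n_clusters)
}

#' Generate a synthetic corpus
#'
#' @param cfg a [synthetic_config()].
#' @return a corpus list consumable by [assemble_dataset()] and
#'   [write_corpus()]: `smiles` (named vector), `proteins` (list of
#'   [protein_record()]), `ssi_edges`, `bbi_edges`, `sti_edges`,
#'   `bti_edges`, `pairs`, `label_vocab`, `sm_targets`, `bt_targets`,
#'   `clusters` (ground-truth latent assignments), `config`.
#' @export
generate_corpus <- function(cfg = synthetic_config()) {
  with_rng(cfg$seed, {
    nc <- cfg$n_clusters
    sm_ids <- sprintf("SM%04d", seq_len(cfg$n_small))
    bt_ids <- sprintf("BT%04d", seq_len(cfg$n_biotech))
    sm_cluster <- rep_len(seq_len(nc), cfg$n_small)
    bt_cluster <- rep_len(seq_len(nc), cfg$n_biotech)

    pools <- .smiles_pools()[seq_len(nc)]
    smiles <- character(cfg$n_small)
    for (c_ in seq_len(nc)) {
      members <- which(sm_cluster == c_)
      pool <- pools[[c_]][sample.int(length(pools[[c_]]))]
      smiles[members] <- pool[((seq_along(members) - 1L) %% length(pool)) + 1L]
    }
    names(smiles) <- sm_ids

    # per-cluster motif profiles; chains share motifs within a cluster
    motifs <- lapply(seq_len(nc), function(c_) {
      vapply(1:3, function(i) .random_aa(12L), character(1))
    })
    proteins <- lapply(seq_len(cfg$n_biotech), function(i) {
      c_ <- bt_cluster[i]
      n_chains <- sample(1:3, 1)
      chains <- vapply(seq_len(n_chains), function(ch) {
        base <- paste0(motifs[[c_]][1], .random_aa(8L), motifs[[c_]][2],
                       .random_aa(8L), motifs[[c_]][3])
        .mutate_seq(base, 0.1)
      }, character(1))
      protein_record(bt_ids[i], chains)
    })

    n_sm_t <- max(nc, round(cfg$n_targets * 3 / 4))
    n_bt_t <- max(nc, cfg$n_targets - n_sm_t)
    sm_targets <- sprintf("TS%04d", seq_len(n_sm_t))
    bt_targets <- sprintf("TB%04d", seq_len(n_bt_t))
    target_block <- function(targets) rep_len(seq_len(nc), length(targets))
    draw_dti <- function(ids, clusters, targets, p_in = 0.6, p_out = 0.05) {
      tb <- target_block(targets)
      do.call(rbind, lapply(seq_along(ids), function(i) {
        p <- ifelse(tb == clusters[i], p_in, p_out)
        hit <- stats::runif(length(targets)) < p
        if (!any(hit)) return(NULL)
        data.frame(drug_id = ids[i], target_id = targets[hit],
                   stringsAsFactors = FALSE)
      }))
    }
    sti_edges <- draw_dti(sm_ids, sm_cluster, sm_targets)
    bti_edges <- draw_dti(bt_ids, bt_cluster, bt_targets)

    draw_ddi <- function(ids, clusters, p_in = 0.3, p_out = 0.02) {
      n <- length(ids)
      pr <- utils::combn(n, 2)
      same <- clusters[pr[1, ]] == clusters[pr[2, ]]
      hit <- stats::runif(ncol(pr)) < ifelse(same, p_in, p_out)
      data.frame(drug_id_a = ids[pr[1, hit]], drug_id_b = ids[pr[2, hit]],
                 stringsAsFactors = FALSE)
    }
    ssi_edges <- draw_ddi(sm_ids, sm_cluster)
    bbi_edges <- draw_ddi(bt_ids, bt_cluster)

    map <- .combo_label_map(nc, cfg$n_classes, cfg$negative_fraction)
    label_vocab <- c("no_interaction",
                     sprintf("interaction_type_%02d",
                             seq_len(cfg$n_classes - 1L)))
    pairs <- expand.grid(sm = seq_len(cfg$n_small),
                         bt = seq_len(cfg$n_biotech))
    label0 <- map[cbind(sm_cluster[pairs$sm], bt_cluster[pairs$bt])]
    if (cfg$label_noise > 0) {
      flip <- stats::runif(nrow(pairs)) < cfg$label_noise
      label0[flip] <- (label0[flip] +
                         sample.int(cfg$n_classes - 1L, sum(flip),
                                    replace = TRUE)) %% cfg$n_classes
    }
    pairs_df <- data.frame(sm_id = sm_ids[pairs$sm], bt_id = bt_ids[pairs$bt],
                           label = label_vocab[label0 + 1L],
                           stringsAsFactors = FALSE)

    list(
      smiles = smiles, proteins = proteins,
      ssi_edges = ssi_edges, bbi_edges = bbi_edges,
      sti_edges = sti_edges, bti_edges = bti_edges,
      pairs = pairs_df, label_vocab = label_vocab,
      sm_targets = sm_targets, bt_targets = bt_targets,
      clusters = list(
        small = stats::setNames(sm_cluster, sm_ids),
        biotech = stats::setNames(bt_cluster, bt_ids),
        combo_label = map
      ),
      config = cfg
    )
  })
}
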