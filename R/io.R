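# On-disk formats: SMILES table (CSV), chain FASTA, edge-list CSVs, label
# vocabulary JSON, dense matrix CSV with id sidecars, metrics JSON,
# checkpoint archive.

#' Write a corpus to a directory of plain-text files
#'
#' Produces exactly the formats [load_corpus()] consumes: `smiles.csv`
#' (drug_id, smiles), `biotech.fasta` (records named `drugID_chainN`),
#' `ssi.csv`/`bbi.csv` (drug_id_a, drug_id_b), `sti.csv`/`bti.csv`
#' (drug_id, target_id), `pairs.csv` (sm_id, bt_id, label),
#' `labels.json` (frozen vocabulary, negative class first),
#' `targets.json` (both target rosters), and - for synthetic corpora -
#' `clusters.csv` with the ground-truth latent assignments plus a
#' `config.json` echo.
#'
#' @param corpus a corpus list ([generate_corpus()] output or equivalent).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(data.frame(drug_id = names(corpus$smiles),
                              smiles = unname(corpus$smiles)),
                   p("smiles.csv"), row.names = FALSE)
  fasta <- unlist(lapply(corpus$proteins, function(pr) {
    unlist(lapply(seq_along(pr$chains), function(i) {
      c(sprintf(">%s_chain%d", pr$drug_id, i), pr$chains[i])
    }))
  }))
  writeLines(fasta, p("biotech.fasta"))
  utils::write.csv(corpus$ssi_edges, p("ssi.csv"), row.names = FALSE)
  utils::write.csv(corpus$bbi_edges, p("bbi.csv"), row.names = FALSE)
  utils::write.csv(corpus$sti_edges, p("sti.csv"), row.names = FALSE)
  utils::write.csv(corpus$bti_edges, p("bti.csv"), row.names = FALSE)
  utils::write.csv(corpus$pairs, p("pairs.csv"), row.names = FALSE)
  jsonlite::write_json(corpus$label_vocab, p("labels.json"))
  jsonlite::write_json(list(sm_targets = corpus$sm_targets,
                            bt_targets = corpus$bt_targets),
                       p("targets.json"))
  if (!is.null(corpus$clusters)) {
    cl <- rbind(
      data.frame(drug_id = names(corpus$clusters$small),
                 population = "small",
                 cluster = unname(corpus$clusters$small)),
      data.frame(drug_id = names(corpus$clusters$biotech),
                 population = "biotech",
                 cluster = unname(corpus$clusters$biotech))
    )
    utils::write.csv(cl, p("clusters.csv"), row.names = FALSE)
  }
  if (!is.null(corpus$config)) {
    jsonlite::write_json(unclass(corpus$config), p("config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

.read_edges <- function(path, what) {
  check_that(file.exists(path), "missing input file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(ncol(df) >= 2, "%s: expected two identifier columns", path)
  dup <- duplicated(df[, 1:2])
  if (any(dup)) {
    message(sprintf("%s: deduplicated %d duplicate edge(s)", what, sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Load and cross-validate a corpus from a directory
#'
#' Reads the file layout of [write_corpus()], deduplicates edge lists
#' (logging the count), verifies that every edge endpoint and pair member
#' resolves to a declared drug or target, and freezes the label vocabulary:
#' sorted label strings with the negative class pinned to index 0.
#'
#' @param dir corpus directory.
#' @param negative_label label string treated as the negative class
#'   (default `"no_interaction"`).
#' @param label_vocab optional frozen vocabulary; unknown labels then error.
#' @return a corpus list (same shape as [generate_corpus()] output).
#' @export
load_corpus <- function(dir, negative_label = "no_interaction",
                        label_vocab = NULL) {
  p <- function(f) file.path(dir, f)
  for (f in c("smiles.csv", "biotech.fasta", "pairs.csv")) {
    check_that(file.exists(p(f)), "missing input file: %s", p(f))
  }
  sm <- utils::read.csv(p("smiles.csv"), stringsAsFactors = FALSE)
  check_that(all(c("drug_id", "smiles") %in% names(sm)),
             "smiles.csv needs drug_id and smiles columns")
  smiles <- stats::setNames(sm$smiles, sm$drug_id)
  fa <- Biostrings::readAAStringSet(p("biotech.fasta"))
  chain_names <- names(fa)
  bt_of <- sub("_chain[0-9]+$", "", chain_names)
  chain_no <- as.integer(sub(".*_chain", "", chain_names))
  proteins <- lapply(unique(bt_of), function(id) {
    sel <- which(bt_of == id)
    sel <- sel[order(chain_no[sel])]
    protein_record(id, as.character(fa[sel]))
  })
  bt_ids <- unique(bt_of)

  ssi <- .read_edges(p("ssi.csv"), "ssi")
  bbi <- .read_edges(p("bbi.csv"), "bbi")
  sti <- .read_edges(p("sti.csv"), "sti")
  bti <- .read_edges(p("bti.csv"), "bti")
  pairs <- utils::read.csv(p("pairs.csv"), stringsAsFactors = FALSE)
  check_that(all(c("sm_id", "bt_id", "label") %in% names(pairs)),
             "pairs.csv needs sm_id, bt_id, label columns")

  if (file.exists(p("targets.json"))) {
    tj <- jsonlite::read_json(p("targets.json"), simplifyVector = TRUE)
    sm_targets <- tj$sm_targets
    bt_targets <- tj$bt_targets
  } else {
    sm_targets <- sort(unique(sti[[2]]))
    bt_targets <- sort(unique(bti[[2]]))
  }

  dangling <- c(
    setdiff(c(ssi[[1]], ssi[[2]], sti[[1]], pairs$sm_id), names(smiles)),
    setdiff(c(bbi[[1]], bbi[[2]], bti[[1]], pairs$bt_id), bt_ids),
    setdiff(sti[[2]], sm_targets), setdiff(bti[[2]], bt_targets)
  )
  if (length(dangling) > 0) {
    abort("dangling identifier(s): %s",
          paste(utils::head(unique(dangling), 10), collapse = ", "))
  }

  if (file.exists(p("labels.json")) && is.null(label_vocab)) {
    label_vocab <- unlist(jsonlite::read_json(p("labels.json"),
                                              simplifyVector = TRUE))
  }
  if (is.null(label_vocab)) {
    pos <- sort(setdiff(unique(pairs$label), negative_label))
    label_vocab <- c(negative_label, pos)
  }
  unknown <- setdiff(unique(pairs$label), label_vocab)
  if (length(unknown) > 0) {
    abort("label(s) outside the frozen vocabulary: %s",
          paste(utils::head(unknown, 10), collapse = ", "))
  }
  check_that(label_vocab[1] == negative_label,
             "the negative class must sit at vocabulary index 0")

  out <- list(smiles = smiles, proteins = proteins,
              ssi_edges = ssi[, 1:2], bbi_edges = bbi[, 1:2],
              sti_edges = sti[, 1:2], bti_edges = bti[, 1:2],
              pairs = pairs[, c("sm_id", "bt_id", "label")],
              label_vocab = label_vocab,
              sm_targets = sm_targets, bt_targets = bt_targets)
  if (file.exists(p("clusters.csv"))) {
    cl <- utils::read.csv(p("clusters.csv"), stringsAsFactors = FALSE)
    out$clusters <- list(
      small = stats::setNames(cl$cluster[cl$population == "small"],
                              cl$drug_id[cl$population == "small"]),
      biotech = stats::setNames(cl$cluster[cl$population == "biotech"],
                                cl$drug_id[cl$population == "biotech"])
    )
  }
  out
}

#' Write a dense matrix as CSV with an id sidecar
#' @param m matrix with rownames.
#' @param path CSV path; ids go to `<path>.ids`.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = FALSE)
  writeLines(rownames(m) %||% character(0), paste0(path, ".ids"))
  invisible(path)
}

#' Read a matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return matrix with ids restored as rownames.
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  idp <- paste0(path, ".ids")
  if (file.exists(idp)) rownames(m) <- readLines(idp)
  m
}

#' Save a trained model as a flat named-tensor archive + config echo
#'
#' @param model a `bsinet_model`.
#' @param path checkpoint path (RDS of a flat named list of arrays); the
#'   configuration echo goes to `<path>.json`.
#' @export
save_checkpoint <- function(model, path) {
  flat <- list()
  walk <- function(p, prefix) {
    if (is.list(p)) {
      for (nm in names(p)) walk(p[[nm]], paste0(prefix, nm, "."))
    } else if (is.numeric(p)) {
      flat[[substr(prefix, 1, nchar(prefix) - 1)]] <<- p
    }
  }
  walk(model$params, "")
  saveRDS(list(tensors = flat, d_atom = model$d_atom), path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return a `bsinet_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg_raw <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(bsinet_config,
                 cfg_raw[intersect(names(cfg_raw),
                                   names(formals(bsinet_config)))])
  model <- bsinet_init(cfg, ck$d_atom, seed = 1L)
  assign_flat <- function(p, prefix) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- assign_flat(p[[nm]],
                                                  paste0(prefix, nm, "."))
      return(p)
    }
    if (!is.numeric(p)) return(p)
    key <- substr(prefix, 1, nchar(prefix) - 1)
    check_that(key %in% names(ck$tensors), "checkpoint missing tensor '%s'",
               key)
    v <- ck$tensors[[key]]
    check_that(length(v) == length(p), "checkpoint tensor '%s' has wrong size",
               key)
    if (is.matrix(p)) matrix(v, nrow(p), ncol(p)) else as.numeric(v)
  }
  params <- model$params
  for (nm in names(params)) {
    params[[nm]] <- assign_flat(params[[nm]], paste0(nm, "."))
  }
  model$params <- params
  model
}
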