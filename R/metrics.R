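# Multiclass evaluation: micro / macro / support-weighted regimes.

#' Confusion matrix with a fixed class count
#'
#' @param y_true,y_pred 0-based class index vectors.
#' @param n_classes total class count C.
#' @return C x C count matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  check_that(length(y_true) == length(y_pred),
             "confusion_matrix: length mismatch")
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  dimnames(m) <- list(true = seq_len(n_classes) - 1L,
                      pred = seq_len(n_classes) - 1L)
  m
}

#' Multiclass Matthews correlation coefficient of a confusion matrix
#'
#' The generalized correlation coefficient
#' (c*s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2)) over the
#' pooled confusion matrix; reduces to binary MCC for two classes. Returns
#' 0 when a marginal is degenerate.
#'
#' @param cm confusion matrix (true x predicted counts).
#' @return scalar in \[-1, 1\].
#' @export
multiclass_mcc <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)   # true counts
  p_k <- colSums(cm)   # predicted counts
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

# one-vs-rest precision/recall/F1 per class from a confusion matrix
.per_class_prf <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(class = seq_len(nrow(cm)) - 1L, support = rowSums(cm),
             precision = prec, recall = rec, f1 = f1)
}

#' Area under the ROC curve for a binary indicator and scores
#'
#' Mann-Whitney formulation with midranks, so ties are handled exactly.
#'
#' @param truth 0/1 indicator vector.
#' @param score numeric score vector.
#' @return AUROC in \[0, 1\], or NA if only one class is present.
#' @export
binary_auroc <- function(truth, score) {
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sum over score-descending positives of
#' precision at each recall increment, with ties processed as blocks.
#'
#' @param truth 0/1 indicator vector.
#' @param score numeric score vector.
#' @return AUPR in \[0, 1\], or NA if no positives.
#' @export
binary_aupr <- function(truth, score) {
  n_pos <- sum(truth == 1)
  if (n_pos == 0 || n_pos == length(truth)) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]
  score <- score[o]
  tp <- cumsum(truth)
  n_seen <- seq_along(truth)
  keep <- c(score[-1] != score[-length(score)], TRUE)  # block ends of ties
  tp_k <- tp[keep]
  n_k <- n_seen[keep]
  prec <- tp_k / n_k
  rec <- tp_k / n_pos
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

.ovr_ranking <- function(y_true, prob, classes, fun) {
  vapply(classes, function(k) {
    fun(as.integer(y_true == k), prob[, k + 1L])
  }, numeric(1))
}

#' Multiclass metrics for one averaging regime
#'
#' * micro: metrics on the pooled confusion matrix; precision, recall, F1
#'   all equal accuracy, MCC is the multiclass coefficient, and AUROC/AUPR
#'   flatten every one-vs-rest (indicator, score) pair into one curve.
#' * macro: unweighted mean of per-class one-vs-rest metrics.
#' * weighted: support-weighted mean of the same per-class metrics.
#'
#' Classes absent from `y_true` are skipped (with a warning) in macro and
#' weighted ranking metrics, since their one-vs-rest curves are undefined.
#'
#' @param y_true,y_pred 0-based class index vectors.
#' @param prob_matrix probability matrix (rows sum to 1), one column per
#'   class; optional (ranking metrics become NA without it).
#' @param regime `"micro"`, `"macro"` or `"weighted"`.
#' @param n_classes total class count (default: inferred).
#' @return named list: precision, recall, f1, accuracy, mcc (micro only),
#'   auroc, aupr, confusion, per_class.
#' @export
evaluate <- function(y_true, y_pred, prob_matrix = NULL,
                     regime = c("micro", "macro", "weighted"),
                     n_classes = NULL) {
  regime <- match.arg(regime)
  check_that(length(y_true) == length(y_pred), "evaluate: length mismatch")
  if (is.null(n_classes)) {
    n_classes <- max(c(y_true, y_pred,
                       if (!is.null(prob_matrix)) ncol(prob_matrix) - 1L)) + 1L
  }
  if (!is.null(prob_matrix)) {
    check_that(ncol(prob_matrix) == n_classes,
               "evaluate: prob matrix has %d columns for %d classes",
               ncol(prob_matrix), n_classes)
  }
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  pc <- .per_class_prf(cm)
  acc <- sum(diag(cm)) / sum(cm)
  present <- which(pc$support > 0) - 1L
  if (length(present) < n_classes && regime != "micro") {
    warning(sprintf("%d class(es) absent from y_true; skipped in %s ranking metrics",
                    n_classes - length(present), regime), call. = FALSE)
  }
  out <- switch(regime,
    micro = {
      auroc <- aupr <- NA_real_
      if (!is.null(prob_matrix)) {
        truth_flat <- as.integer(
          outer(y_true, seq_len(n_classes) - 1L, `==`))
        score_flat <- as.vector(prob_matrix)
        auroc <- binary_auroc(truth_flat, score_flat)
        aupr <- binary_aupr(truth_flat, score_flat)
      }
      list(precision = acc, recall = acc, f1 = acc, accuracy = acc,
           mcc = multiclass_mcc(cm), auroc = auroc, aupr = aupr)
    },
    macro = {
      auroc <- aupr <- NA_real_
      if (!is.null(prob_matrix)) {
        auroc <- mean(.ovr_ranking(y_true, prob_matrix, present, binary_auroc),
                      na.rm = TRUE)
        aupr <- mean(.ovr_ranking(y_true, prob_matrix, present, binary_aupr),
                     na.rm = TRUE)
      }
      list(precision = mean(pc$precision[present + 1L]),
           recall = mean(pc$recall[present + 1L]),
           f1 = mean(pc$f1[present + 1L]), accuracy = acc,
           mcc = NA_real_, auroc = auroc, aupr = aupr)
    },
    weighted = {
      w <- pc$support[present + 1L] / sum(pc$support[present + 1L])
      auroc <- aupr <- NA_real_
      if (!is.null(prob_matrix)) {
        auroc <- sum(w * .ovr_ranking(y_true, prob_matrix, present,
                                      binary_auroc))
        aupr <- sum(w * .ovr_ranking(y_true, prob_matrix, present,
                                     binary_aupr))
      }
      list(precision = sum(w * pc$precision[present + 1L]),
           recall = sum(w * pc$recall[present + 1L]),
           f1 = sum(w * pc$f1[present + 1L]), accuracy = acc,
           mcc = NA_real_, auroc = auroc, aupr = aupr)
    }
  )
  out$confusion <- cm
  out$per_class <- pc
  out$regime <- regime
  out
}

#' Full metrics report over all three regimes
#'
#' @inheritParams evaluate
#' @return list with `micro`, `macro`, `weighted` metric lists and the
#'   shared confusion matrix.
#' @export
metrics_report <- function(y_true, y_pred, prob_matrix = NULL,
                           n_classes = NULL) {
  out <- lapply(c(micro = "micro", macro = "macro", weighted = "weighted"),
                function(r) {
                  evaluate(y_true, y_pred, prob_matrix, r, n_classes)
                })
  out$confusion <- out$micro$confusion
  out
}
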