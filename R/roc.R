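# ROC machinery: Mann-Whitney AUC with DeLong variance, the paired
# DeLong test, and the Youden-index cutoff.

# DeLong placement values: for each positive the fraction of negatives
# it beats (ties = 1/2), and vice versa.
.placements <- function(pos, neg) {
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC with rank-sum p-value and DeLong confidence interval
#'
#' The c-statistic (Mann-Whitney AUC, ties counted 1/2), a two-sided
#' p-value from the normal-approximated rank-sum test with tie
#' correction, and a 95% CI from the DeLong variance (clipped to
#' [0, 1]). When every value is tied the AUC is 0.5 and p = 1.
#'
#' @param values numeric scores, higher = more responder-like.
#' @param labels logical/0-1 responder flags, same length.
#' @return list with `auc`, `p_value`, `ci95` (low, high),
#'   `auc_flipped` (= max(auc, 1 - auc), the flipped-orientation AUC),
#'   `n_pos`, `n_neg`.
#' @export
aucWithP <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  pos <- values[labels]
  neg <- values[!labels]
  if (!length(pos) || !length(neg))
    stop("need at least one case in each class")
  pl <- .placements(pos, neg)
  auc <- pl$auc
  if (length(unique(values)) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(pos, neg, exact = FALSE, correct = FALSE)$p.value)
    if (!is.finite(p)) p <- 1
  }
  se <- sqrt(var(pl$v10) / length(pos) + var(pl$v01) / length(neg))
  if (!is.finite(se)) se <- 0
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  list(auc = auc, p_value = p, ci95 = ci, auc_flipped = max(auc, 1 - auc),
       n_pos = length(pos), n_neg = length(neg))
}

#' Evaluate the ROC of model scores
#'
#' Thin wrapper over [aucWithP()] for prediction scores.
#'
#' @param scores numeric scores in [0, 1].
#' @param labels responder flags.
#' @return as [aucWithP()].
#' @export
evaluateRoc <- function(scores, labels) aucWithP(scores, labels)

#' DeLong's test for two correlated AUCs
#'
#' Two-sided p-value for the difference of the AUCs of two score
#' vectors on the same cases, using the paired DeLong variance. If the
#' two scorers rank the cases identically the variance of the
#' difference is zero and p = 1 by convention (logged).
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels responder flags.
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delongCompare <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- .placements(scores_a[labels], scores_a[!labels])
  pb <- .placements(scores_b[labels], scores_b[!labels])
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- var(cbind(pa$v10, pb$v10))
  s01 <- var(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc
  if (!is.finite(v) || v <= .Machine$double.eps) {
    message("DeLong: zero variance of the AUC difference; p = 1 by convention")
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                z = 0, p_value = 1))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Youden-index optimal cutoff
#'
#' Scans the midpoints between consecutive unique observed scores,
#' maximizes `J = sensitivity + specificity - 1` with the orientation
#' "score >= threshold predicts responder", breaks ties toward higher
#' sensitivity (then the lower threshold), and reports accuracy,
#' sensitivity and specificity at the chosen threshold. With all
#' scores identical J = 0 and the metrics are degenerate (warned).
#'
#' @param scores numeric prediction scores.
#' @param labels responder flags.
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
youdenCutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(any(labels), any(!labels))
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("all scores identical; Youden index is 0 and the cutoff degenerate")
    thr <- u
  } else {
    thr <- (u[-1] + u[-length(u)]) / 2
  }
  stats <- vapply(thr, function(t) {
    pred <- scores >= t
    sens <- mean(pred[labels])
    spec <- mean(!pred[!labels])
    c(sens = sens, spec = spec, J = sens + spec - 1)
  }, numeric(3))
  best_j <- max(stats["J", ])
  cand <- which(stats["J", ] >= best_j - 1e-12)
  cand <- cand[order(-stats["sens", cand], thr[cand])][1]
  t_star <- thr[cand]
  pred <- scores >= t_star
  list(threshold = t_star,
       J = unname(stats["J", cand]),
       sensitivity = unname(stats["sens", cand]),
       specificity = unname(stats["spec", cand]),
       accuracy = mean(pred == labels))
}

#' Classification metrics at a fixed cutoff
#'
#' @param scores numeric scores.
#' @param labels responder flags.
#' @param threshold cutoff; score >= threshold predicts responder.
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
cutoffMetrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  list(accuracy = mean(pred == labels),
       sensitivity = mean(pred[labels]),
       specificity = mean(!pred[!labels]))
}
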