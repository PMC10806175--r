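# Discovery-phase feature selection: per-feature ROC screening, then
# Pearson-correlation redundancy grouping with highest-AUC
# representatives.

#' Screen features by per-feature AUC
#'
#' Computes the c-statistic of every feature against the response label
#' and keeps features with `auc >= auc_threshold` and rank-sum
#' `p < alpha`, sorted by descending AUC (ties broken by feature id).
#' Screening uses the raw, unflipped AUC — features predictive in the
#' negative direction are excluded by design (set
#' `two_sided = TRUE` to screen on max(auc, 1 - auc)). Features with
#' any missing value are dropped with a warning.
#'
#' @param table numeric matrix, features x cases (as the `features`
#'   assay of [extractCohort()]), or a SummarizedExperiment.
#' @param labels responder flags per case.
#' @param auc_threshold minimum AUC, default 0.7.
#' @param alpha significance level, default 0.05.
#' @param two_sided screen on the flipped AUC as well (default FALSE).
#' @return data.frame with columns `feature`, `auc`, `p`, `ci_low`,
#'   `ci_high`, sorted by descending AUC; zero rows allowed.
#' @export
screenFeatures <- function(table, labels, auc_threshold = 0.7,
                           alpha = 0.05, two_sided = FALSE) {
  m <- .asFeatureMatrix(table)
  stopifnot(ncol(m) == length(labels),
            auc_threshold > 0, auc_threshold < 1, alpha > 0, alpha < 1)
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    warning(sum(bad), " feature(s) with missing values dropped from screening")
    m <- m[!bad, , drop = FALSE]
  }
  res <- lapply(rownames(m), function(f) {
    r <- aucWithP(m[f, ], labels)
    data.frame(feature = f,
               auc = if (two_sided) r$auc_flipped else r$auc,
               p = r$p_value, ci_low = r$ci95[1], ci_high = r$ci95[2])
  })
  res <- do.call(rbind, res)
  keep <- res$auc >= auc_threshold & res$p < alpha
  out <- res[keep, , drop = FALSE]
  out <- out[order(-out$auc, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) message("no feature passed the AUC screen")
  out
}

#' Group correlated candidates and pick highest-AUC representatives
#'
#' Greedy, AUC-seeded grouping: candidates are walked in descending-AUC
#' order; a feature joins the first existing group whose representative
#' satisfies `|Pearson r| >= r_threshold` with `p < alpha`, otherwise it
#' founds a new group as its representative. Because the walk is in AUC
#' order, every representative has the maximum AUC of its group. A
#' zero-variance candidate (correlation undefined) founds its own group
#' with a warning. `method = "components"` instead merges by connected
#' components of the |r| >= threshold graph (representative = member
#' with max AUC).
#'
#' @param table features x cases matrix or SummarizedExperiment.
#' @param screening the data.frame from [screenFeatures()] (candidates,
#'   sorted by descending AUC).
#' @param r_threshold absolute Pearson correlation threshold, default 0.7.
#' @param alpha correlation-test significance level, default 0.05.
#' @param method "greedy" (default) or "components".
#' @return list of groups, each a list with `representative`,
#'   `representative_auc`, `members`.
#' @export
correlationGroup <- function(table, screening, r_threshold = 0.7,
                             alpha = 0.05,
                             method = c("greedy", "components")) {
  method <- match.arg(method)
  m <- .asFeatureMatrix(table)
  stopifnot(r_threshold > 0, r_threshold < 1)
  cand <- screening$feature
  aucs <- setNames(screening$auc, cand)
  if (!length(cand)) return(list())
  ord <- cand[order(-aucs[cand], cand)]

  correlated <- function(f, g) {
    x <- m[f, ]; y <- m[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA)
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    abs(ct$estimate) >= r_threshold && ct$p.value < alpha
  }

  if (method == "greedy") {
    groups <- list()
    for (f in ord) {
      if (sd(m[f, ]) == 0) {
        warning("constant feature ", f, " forms its own group")
        groups[[length(groups) + 1L]] <-
          list(representative = f, representative_auc = unname(aucs[f]),
               members = f)
        next
      }
      placed <- FALSE
      for (gi in seq_along(groups)) {
        hit <- correlated(f, groups[[gi]]$representative)
        if (isTRUE(hit)) {
          groups[[gi]]$members <- c(groups[[gi]]$members, f)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        groups[[length(groups) + 1L]] <-
          list(representative = f, representative_auc = unname(aucs[f]),
               members = f)
    }
  } else {
    n <- length(ord)
    uf <- .unionFind(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (isTRUE(correlated(ord[i], ord[j]))) uf$union(i, j)
    roots <- uf$roots()
    groups <- lapply(split(ord, roots), function(mem) {
      rep <- mem[order(-aucs[mem], mem)][1]
      list(representative = rep, representative_auc = unname(aucs[rep]),
           members = mem)
    })
    groups <- unname(groups[order(-vapply(groups, `[[`, numeric(1),
                                          "representative_auc"))])
  }
  groups
}

#' Representatives of a grouping
#'
#' @param groups the list from [correlationGroup()].
#' @return character vector of representative feature ids.
#' @export
selectedFeatures <- function(groups)
  vapply(groups, `[[`, character(1), "representative")

.asFeatureMatrix <- function(table) {
  if (is(table, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(table, "features"))
  stopifnot(is.matrix(table), !is.null(rownames(table)))
  table
}

#' Write selection artifacts
#'
#' Emits `screening.csv`, `groups.json` and `selected_features.txt`.
#'
#' @param screening data.frame from [screenFeatures()].
#' @param groups list from [correlationGroup()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeSelection <- function(screening, groups, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "screening.csv")
  write.csv(screening, p1, row.names = FALSE)
  p2 <- file.path(dir, "groups.json")
  jsonlite::write_json(
    setNames(lapply(groups, `[[`, "members"),
             selectedFeatures(groups)), p2, digits = NA)
  p3 <- file.path(dir, "selected_features.txt")
  writeLines(selectedFeatures(groups), p3)
  invisible(c(p1, p2, p3))
}
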