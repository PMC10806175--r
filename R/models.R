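# The five response classifiers. All produce a probability-like score
# in [0, 1] ("prediction score"); a higher score means more
# responder-like. RF additionally exposes out-of-bag scores for
# training-cohort cases, which downstream survival stratification uses
# by default.

#' Train a CRT-response classifier
#'
#' Supported algorithms and score definitions:
#' * `RF` — random forest (500 trees, sqrt(p) candidate features per
#'   split); score = fraction of trees voting responder.
#' * `NB` — Gaussian naive Bayes posterior.
#' * `RR` — L2-penalized (ridge) logistic regression; the penalty is
#'   chosen on a small internal cross-validated grid with seed-fixed
#'   folds.
#' * `ANN` — single-hidden-layer network (8 units, sigmoid output,
#'   weight decay 0.01).
#' * `SVM` — RBF support vector machine with Platt-scaled
#'   probabilities.
#'
#' Features are z-scored with training-cohort statistics for RR, ANN
#' and SVM; RF and NB see raw features. The same seed with the same
#' data reproduces the model exactly.
#'
#' @param algorithm one of "RF", "NB", "RR", "ANN", "SVM".
#' @param table features x cases matrix (or SummarizedExperiment);
#'   rows = the selected feature ids.
#' @param labels responder flags per case.
#' @param feature_ids features to train on (default: all rows).
#' @param seed integer seed.
#' @return a [ResponseModel-class].
#' @export
trainModel <- function(algorithm = c("RF", "NB", "RR", "ANN", "SVM"),
                       table, labels, feature_ids = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  m <- .asFeatureMatrix(table)
  if (is.null(feature_ids)) feature_ids <- rownames(m)
  stopifnot(all(feature_ids %in% rownames(m)))
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 cases per class")
  x <- t(m[feature_ids, , drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  standardize <- algorithm %in% c("RR", "ANN", "SVM")
  xs <- if (standardize) scale(x, ctr, scl) else x
  yf <- factor(y, levels = c(0, 1))
  set.seed(as.integer(seed))
  fit <- switch(algorithm,
    RF = randomForest::randomForest(x, yf, ntree = 500,
                                    mtry = max(1, floor(sqrt(ncol(x))))),
    NB = e1071::naiveBayes(x, yf),
    RR = {
      foldid <- sample(rep_len(1:5, nrow(xs)))
      cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 0,
                              foldid = foldid, nfolds = 5,
                              lambda = 10^seq(2, -4, length.out = 40))
      cv
    },
    ANN = nnet::nnet(xs, y, size = 8, decay = 0.01, maxit = 500,
                     entropy = TRUE, trace = FALSE),
    SVM = e1071::svm(xs, yf, kernel = "radial", probability = TRUE))
  new("ResponseModel", algorithm = algorithm, fit = fit,
      featureIds = feature_ids,
      center = if (standardize) ctr else setNames(rep(0, ncol(x)),
                                                  colnames(x)),
      scale = if (standardize) scl else setNames(rep(1, ncol(x)),
                                                 colnames(x)),
      seed = as.integer(seed))
}

#' Score cases with a trained model
#'
#' Scores lie in [0, 1]. For an RF model, `source = "out_of_bag"`
#' returns out-of-bag vote fractions for the training cases (only trees
#' that did not see a case vote on it); `"resubstitution"` re-predicts
#' the training data with the full forest; `"held_out"` (any new data)
#' uses the full model. Non-RF algorithms ignore the OOB request.
#'
#' @param model a [ResponseModel-class].
#' @param table features x cases matrix or SummarizedExperiment; must
#'   contain every trained feature id.
#' @param source one of "held_out", "resubstitution", "out_of_bag".
#' @return data.frame with `case_id`, `score`, `source`.
#' @export
scoreCases <- function(model, table,
                       source = c("held_out", "resubstitution",
                                  "out_of_bag")) {
  source <- match.arg(source)
  m <- .asFeatureMatrix(table)
  missing <- setdiff(model@featureIds, rownames(m))
  if (length(missing))
    stop("unseen feature id(s): ", paste(missing, collapse = ", "))
  x <- t(m[model@featureIds, , drop = FALSE])
  xs <- scale(x, model@center[colnames(x)], model@scale[colnames(x)])
  sc <- switch(model@algorithm,
    RF = {
      if (source == "out_of_bag")
        predict(model@fit, type = "prob")[, "1"]  # OOB votes on training data
      else
        predict(model@fit, newdata = x, type = "prob")[, "1"]
    },
    NB = predict(model@fit, newdata = x, type = "raw")[, "1"],
    RR = as.numeric(predict(model@fit, newx = xs, s = "lambda.min",
                            type = "response")),
    ANN = as.numeric(predict(model@fit, newdata = xs)),
    SVM = {
      pr <- predict(model@fit, newdata = xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  sc <- pmin(pmax(as.numeric(sc), 0), 1)
  data.frame(case_id = rownames(x), score = sc,
             source = if (model@algorithm == "RF") source else
               if (source == "out_of_bag") "resubstitution" else source,
             row.names = NULL)
}

#' Train all five models
#'
#' @param table features x cases matrix or SummarizedExperiment.
#' @param labels responder flags.
#' @param feature_ids selected feature ids.
#' @param seed base seed; each algorithm gets a deterministic sub-seed.
#' @return named list of [ResponseModel-class] (RF, NB, RR, ANN, SVM).
#' @export
trainAllModels <- function(table, labels, feature_ids = NULL, seed = 1L) {
  algs <- c("RF", "NB", "RR", "ANN", "SVM")
  setNames(lapply(seq_along(algs), function(k)
    trainModel(algs[k], table, labels, feature_ids,
               seed = as.integer(.subSeed(seed, 7000 + k)))), algs)
}
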