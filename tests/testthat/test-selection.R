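test_that("AUC matches pair enumeration and handles ties", {
  # perfect separation
  r <- aucWithP(c(2, 3, 0, 1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)

  # pure ties
  r <- aucWithP(rep(5, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(r$auc, 0.5)
  expect_equal(r$p_value, 1)

  # 4 pairs, 3 concordant
  r <- aucWithP(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, oracleAUC(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)))

  # random data: exhaustive pair enumeration agrees, CI brackets AUC
  set.seed(12)
  for (k in 1:10) {
    v <- sample(1:8, 20, replace = TRUE)  # deliberate ties
    l <- rbinom(20, 1, 0.4)
    if (sum(l) == 0 || sum(l) == 20) next
    r <- aucWithP(v, l)
    expect_equal(r$auc, oracleAUC(v, l))
    expect_lte(r$ci95[1], r$auc)
    expect_gte(r$ci95[2], r$auc)
  }

  expect_error(aucWithP(1:5, rep(1, 5)), "each class")
})

test_that("DeLong variance agrees with an independent implementation", {
  set.seed(44)
  l <- rep(c(1, 0), times = c(10, 15))
  a <- rnorm(25) + l
  b <- rnorm(25) + 0.5 * l
  d <- delongCompare(a, b, l)
  ref <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE, direction = "<"),
                        pROC::roc(l, b, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(d$p_value, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(d$auc_a, as.numeric(pROC::auc(l, a, quiet = TRUE,
                                             direction = "<")))
})

test_that("screening applies the AUC and significance thresholds", {
  # a feature equal to the label is always included with auc 1
  toy <- toyFeatureMatrix(5, n_features = 20, effect = 0)
  toy$m["f001", ] <- toy$labels
  sc <- screenFeatures(toy$m, toy$labels)
  expect_true("f001" %in% sc$feature)
  expect_equal(sc$auc[sc$feature == "f001"], 1.0)
  expect_equal(sc$feature[1], "f001")  # sorted by descending AUC

  # impossible threshold empties the list
  expect_equal(nrow(screenFeatures(toy$m, toy$labels,
                                   auc_threshold = 0.999)), 1)
  toy$m["f001", ] <- rnorm(ncol(toy$m))
  expect_equal(nrow(suppressMessages(
    screenFeatures(toy$m, toy$labels, auc_threshold = 0.9999))), 0)

  # null features pass only rarely (476 features, n = 27): far fewer
  # than the with-effect regime would admit
  counts <- vapply(1:20, function(s) {
    toy <- toyFeatureMatrix(1000 + s, n_features = 476, effect = 0,
                            n_informative = 0)
    nrow(screenFeatures(toy$m, toy$labels))
  }, numeric(1))
  expect_lt(mean(counts), 50)

  # missing-value features are dropped with a warning
  toy <- toyFeatureMatrix(6, n_features = 10, effect = 2)
  toy$m[3, 5] <- NA
  expect_warning(screenFeatures(toy$m, toy$labels), "missing")
})

test_that("correlation grouping is greedy, AUC-seeded and deterministic", {
  set.seed(77)
  n <- 40
  base <- rnorm(n)
  labels <- rep(c(1, 0), times = c(12, 28))
  sig <- labels + rnorm(n, 0, 0.4)
  m <- rbind(f1 = sig, f2 = sig, f3 = rnorm(n))
  m["f1", ] <- m["f1", ] + rnorm(n, 0, 1e-6)  # identical up to jitter
  sc <- data.frame(feature = c("f1", "f2", "f3"),
                   auc = c(0.9, 0.8, 0.75), p = 0.01,
                   ci_low = 0, ci_high = 1)
  g <- correlationGroup(m, sc)
  expect_equal(length(g), 2)
  expect_equal(g[[1]]$representative, "f1")
  expect_setequal(g[[1]]$members, c("f1", "f2"))
  expect_equal(g[[2]]$members, "f3")
  expect_equal(selectedFeatures(g), c("f1", "f3"))

  # representative AUC >= every member AUC by construction
  toy <- toyFeatureMatrix(9, n_features = 60, effect = 1.5,
                          n_informative = 30)
  sct <- screenFeatures(toy$m, toy$labels)
  g <- correlationGroup(toy$m, sct)
  aucs <- setNames(sct$auc, sct$feature)
  for (gr in g)
    expect_true(all(aucs[gr$representative] >= aucs[gr$members]))

  # all mutually correlated -> one group; all independent -> all singletons
  mm <- rbind(a = base, b = 2 * base + 1, c = -base)
  scm <- data.frame(feature = c("a", "b", "c"), auc = c(0.8, 0.75, 0.72),
                    p = 0.01, ci_low = 0, ci_high = 1)
  expect_equal(length(correlationGroup(mm, scm)), 1)
  set.seed(3)
  mi <- rbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(length(correlationGroup(mi, scm)), 3)

  # constant feature founds its own group with a warning
  mc <- rbind(a = base, b = rep(1, n))
  scc <- data.frame(feature = c("a", "b"), auc = c(0.8, 0.75), p = 0.01,
                    ci_low = 0, ci_high = 1)
  expect_warning(gc <- correlationGroup(mc, scc), "constant")
  expect_equal(length(gc), 2)

  # column-order invariance given distinct AUCs
  g1 <- correlationGroup(m, sc)
  g2 <- correlationGroup(m[c(3, 1, 2), ], sc)
  expect_identical(selectedFeatures(g1), selectedFeatures(g2))

  # connected-components variant agrees here
  g3 <- correlationGroup(m, sc, method = "components")
  expect_setequal(selectedFeatures(g3), selectedFeatures(g1))
})
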