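test_that("negative sampling enumerates the complement exactly", {
  g <- assemble_man(edge_df("drug:d1", "protein:p1", "drug-target"))
  g <- assemble_man(list(g$edges,
                         edge_df("drug:d2", "protein:p2", "drug-target")))
  # 2 drugs x 2 proteins with 2 edges: exactly 2 non-edges
  neg <- sample_negatives(g, 2L, seed = 5L)
  expect_setequal(paste(neg$drug, neg$protein),
                  c("drug:d1 protein:p2", "drug:d2 protein:p1"))
  # infeasible requests fail
  expect_error(sample_negatives(g, 3L, seed = 5L), "non-edges")
  # seeded reproducibility
  expect_identical(sample_negatives(g, 1L, seed = 9L),
                   sample_negatives(g, 1L, seed = 9L))
})

test_that("sampled negatives never collide with positives", {
  man <- generate_man(synth_config(
    n_per_type = c(drug = 20, protein = 20, disease = 5, lncRNA = 5,
                   miRNA = 5),
    p_in = 0.5, p_out = 0.05, seed = 3))
  g <- man$graph
  dti <- g$edges[g$edges$relation == "drug-target", ]
  pos_key <- paste(pmin(dti$u, dti$v), pmax(dti$u, dti$v))
  neg <- sample_negatives(g, 100L, seed = 2L)
  neg_key <- paste(pmin(neg$drug, neg$protein), pmax(neg$drug, neg$protein))
  expect_equal(anyDuplicated(neg_key), 0L)
  expect_length(intersect(neg_key, pos_key), 0L)
})

test_that("fold plans stratify both classes to within one row", {
  plan <- make_fold_plan(rep(c(0L, 1L), each = 10L), k = 5L, seed = 1L)
  tab <- table(plan, rep(c(0L, 1L), each = 10L))
  expect_true(all(tab == 2L))
  # 22,214 balanced rows: exact stratification gives 4443 x 4 + 4442
  labels <- rep(c(0L, 1L), each = 11107L)
  plan2 <- make_fold_plan(labels, k = 5L, seed = 2L)
  sizes <- sort(as.integer(table(plan2)), decreasing = TRUE)
  expect_equal(sizes, c(4443L, 4443L, 4443L, 4443L, 4442L))
  expect_equal(length(plan2), 22214L)
  # folds partition the rows
  expect_true(all(plan2 %in% 1:5))
  expect_error(make_fold_plan(c(0L, 1L), k = 5L), "at least")
})

test_that("confusion counts match an independent loop oracle", {
  expect_equal(confusion(c(1, 0), c(1, 0)),
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(confusion(c(1, 0), c(0, 1)),
               list(TP = 0L, FP = 1L, TN = 0L, FN = 1L))
  expect_error(confusion(c(1, 0), c(1)), "length")
  set.seed(44)
  labels <- sample(0:1, 1000L, replace = TRUE)
  pred <- sample(0:1, 1000L, replace = TRUE)
  expect_equal(confusion(labels, pred), confusion_oracle(labels, pred))
})

test_that("threshold metrics evaluate the published formulas", {
  perfect <- classification_metrics(list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(unname(perfect), rep(1, 5L))
  inverted <- classification_metrics(list(TP = 0L, FP = 1L, TN = 0L, FN = 1L))
  expect_equal(inverted[["Acc"]], 0)
  expect_equal(inverted[["MCC"]], -1)
  m <- classification_metrics(list(TP = 60L, FP = 20L, TN = 80L, FN = 40L))
  expect_equal(m[["Acc"]], 0.70)
  expect_equal(m[["TPR"]], 0.60)
  expect_equal(m[["TNR"]], 0.80)
  expect_equal(m[["PPV"]], 0.75)
  expect_equal(m[["MCC"]], (60 * 80 - 20 * 40) /
                 sqrt(100 * 100 * 80 * 120))
  # zero denominators are undefined, not zero
  m0 <- classification_metrics(list(TP = 0L, FP = 0L, TN = 5L, FN = 0L))
  expect_true(is.na(m0[["TPR"]]))
  expect_true(is.na(m0[["PPV"]]))
  expect_true(is.na(m0[["MCC"]]))
  expect_equal(m0[["Acc"]], 1)
})

test_that("metrics agree with brute-force formula evaluation on random tables", {
  set.seed(99)
  for (rep in 1:1000) {
    cc <- as.list(stats::setNames(sample(0:40, 4L, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    if (sum(unlist(cc)) == 0L) next
    m <- classification_metrics(cc)
    with(cc, {
      expect_equal(m[["Acc"]], (TP + TN) / (TP + FP + TN + FN),
                   tolerance = 1e-12)
      if (TP + FN > 0) expect_equal(m[["TPR"]], TP / (TP + FN),
                                    tolerance = 1e-12)
      if (FP + TN > 0) expect_equal(m[["TNR"]], TN / (FP + TN),
                                    tolerance = 1e-12)
      if (FP + TP > 0) expect_equal(m[["PPV"]], TP / (FP + TP),
                                    tolerance = 1e-12)
      den <- sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TP + FP) * sqrt(TN + FN)
      if (den > 0) expect_equal(m[["MCC"]], (TP * TN - FP * FN) / den,
                                tolerance = 1e-12)
    })
  }
})

test_that("MCC magnitude is invariant under swapping the class convention", {
  set.seed(7)
  for (rep in 1:200) {
    cc <- as.list(stats::setNames(sample(1:30, 4L, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    swapped <- list(TP = cc$TN, FP = cc$FN, TN = cc$TP, FN = cc$FP)
    expect_equal(classification_metrics(cc)[["MCC"]],
                 classification_metrics(swapped)[["MCC"]],
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise Mann-Whitney oracle, ties counted half", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.3, 4L))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  set.seed(17)
  for (rep in 1:50) {
    n <- 200L
    labels <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    scores <- round(stats::runif(n), 2L)  # rounding forces ties
    expect_equal(roc_auc(labels, scores)$auc, auc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC point list is monotone from (0,0) to (1,1)", {
  set.seed(23)
  labels <- sample(0:1, 100L, replace = TRUE)
  scores <- round(stats::runif(100L), 1L)
  pts <- roc_auc(labels, scores)$points
  expect_equal(pts$fpr[1L], 0); expect_equal(pts$tpr[1L], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  # trapezoid over the point list reproduces the rank-form AUC
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                                 utils::tail(pts$tpr, -1L)) / 2)
  expect_equal(trap, roc_auc(labels, scores)$auc, tolerance = 1e-12)
})

test_that("AUC against pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(27)
  labels <- sample(0:1, 300L, replace = TRUE)
  scores <- stats::runif(300L)
  ours <- roc_auc(labels, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cross-validation conserves rows and nails separable data", {
  set.seed(50)
  n <- 100L
  labels <- rep(c(0L, 1L), each = n / 2L)
  x <- matrix(rnorm(n * 4L), ncol = 4L)
  x[labels == 1L, 1L] <- x[labels == 1L, 1L] + 10  # perfectly separable
  pairs <- data.frame(drug = sprintf("drug:d%d", seq_len(n)),
                      protein = sprintf("protein:p%d", seq_len(n)),
                      label = labels)
  ds <- structure(list(pairs = pairs, features = x, tag = "attribute",
                       n_dropped = 0L), class = "pair_dataset")
  plan <- make_fold_plan(labels, k = 5L, seed = 3L)
  rep_rf <- run_cv(ds, plan, classifier_random_forest(), seed = 8L)
  expect_equal(sum(rep_rf$per_fold$TP + rep_rf$per_fold$FP +
                     rep_rf$per_fold$TN + rep_rf$per_fold$FN), n)
  expect_equal(unname(rep_rf$mean[["Acc"]]), 1)
  expect_equal(unname(rep_rf$mean[["AUC"]]), 1)
})

test_that("label-independent features give chance-level AUC", {
  aucs <- vapply(1:3, function(s) {
    set.seed(100 + s)
    n <- 300L
    labels <- rep(c(0L, 1L), each = n / 2L)
    x <- matrix(rnorm(n * 6L), ncol = 6L)
    pairs <- data.frame(drug = sprintf("drug:d%d", seq_len(n)),
                        protein = sprintf("protein:p%d", seq_len(n)),
                        label = labels)
    ds <- structure(list(pairs = pairs, features = x, tag = "attribute",
                         n_dropped = 0L), class = "pair_dataset")
    plan <- make_fold_plan(labels, k = 5L, seed = s)
    run_cv(ds, plan, classifier_logistic(), seed = s)$mean[["AUC"]]
  }, numeric(1L))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-validation is reproducible and reports are writable", {
  set.seed(61)
  n <- 60L
  labels <- rep(c(0L, 1L), each = n / 2L)
  x <- matrix(rnorm(n * 3L), ncol = 3L)
  x[, 1L] <- x[, 1L] + labels
  pairs <- data.frame(drug = sprintf("drug:d%d", seq_len(n)),
                      protein = sprintf("protein:p%d", seq_len(n)),
                      label = labels)
  ds <- structure(list(pairs = pairs, features = x, tag = "behavior",
                       n_dropped = 0L), class = "pair_dataset")
  plan <- make_fold_plan(labels, k = 5L, seed = 2L)
  r1 <- run_cv(ds, plan, classifier_random_forest(), seed = 4L)
  r2 <- run_cv(ds, plan, classifier_random_forest(), seed = 4L)
  expect_identical(r1$per_fold, r2$per_fold)
  f_csv <- tempfile(fileext = ".csv")
  write_metrics_csv(r1, f_csv)
  out <- utils::read.csv(f_csv, stringsAsFactors = FALSE)
  expect_equal(nrow(out), 6L)            # 5 folds + Average
  expect_equal(out$fold[6L], "Average")
  expect_match(out$Acc[6L], "±")
  f_json <- tempfile(fileext = ".json")
  write_metrics_json(r1, f_json)
  parsed <- jsonlite::read_json(f_json)
  expect_equal(parsed$classifier, "random_forest")
  # SVM contract honors the same interface
  r_svm <- run_cv(ds, plan, classifier_svm(), seed = 4L)
  expect_true(all(r_svm$per_fold$AUC >= 0 & r_svm$per_fold$AUC <= 1))
})

test_that("the representation ordering also holds for a margin classifier", {
  cfg <- synth_config(seed = 301)
  man <- generate_man(cfg)
  ids <- mandti:::synth_node_ids(cfg)
  prot <- generate_proteins(ids$protein, man$truth$communities, cfg)
  fp <- generate_fingerprints(ids$drug, man$truth$communities, cfg)
  ex <- run_dti_experiment(man$graph, prot, fp, classifier = "svm",
                           seed = 302, leakage = "global")
  expect_gt(ex$behavior$mean[["AUC"]], ex$attribute$mean[["AUC"]])
  expect_gt(ex$behavior$mean[["AUC"]], 0.6)
})
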