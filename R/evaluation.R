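# Balanced pair dataset construction, stratified k-fold cross-validation,
# and the confusion-matrix / ROC performance measures.

#' Sample non-interacting drug-protein pairs
#'
#' Draws `n` distinct pairs uniformly from the complement of the
#' drug-target edge set over drugs x proteins. These serve as the
#' negative class of the balanced dataset.
#'
#' @param g a `man_graph`.
#' @param n number of negatives.
#' @param seed RNG seed.
#' @param exclude optional extra data.frame (`drug`, `protein`) of pairs
#'   that must not be sampled (e.g. held-out positives).
#' @return data.frame with columns `drug`, `protein`.
#' @export
sample_negatives <- function(g, n, seed = 1L, exclude = NULL) {
  stopifnot(inherits(g, "man_graph"))
  n <- assert_scalar_int(n, "n")
  drugs <- sort(g$nodes$id[g$nodes$type == "drug"])
  prots <- sort(g$nodes$id[g$nodes$type == "protein"])
  dti <- g$edges[g$edges$relation == "drug-target", , drop = FALSE]
  d_of <- function(u, v) ifelse(node_type_of(u) == "drug", u, v)
  p_of <- function(u, v) ifelse(node_type_of(u) == "drug", v, u)
  forbid <- paste(d_of(dti$u, dti$v), p_of(dti$u, dti$v), sep = "\r")
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    forbid <- c(forbid, paste(exclude$drug, exclude$protein, sep = "\r"))
  }
  forbid <- unique(forbid)
  total <- as.double(length(drugs)) * length(prots)
  if (n > total - length(forbid)) {
    stop(sprintf("cannot sample %d negatives: only %.0f non-edges exist",
                 n, total - length(forbid)), call. = FALSE)
  }
  with_seed(seed, {
    if (total <= 2e6) {
      all_pairs <- expand.grid(drug = drugs, protein = prots,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
      key <- paste(all_pairs$drug, all_pairs$protein, sep = "\r")
      pool <- all_pairs[!(key %in% forbid), , drop = FALSE]
      take <- sample.int(nrow(pool), n)
      out <- pool[take, , drop = FALSE]
    } else {
      # rejection sampling: the non-edge set is always dense at this scale
      seen <- character(0L)
      out_d <- character(0L); out_p <- character(0L)
      while (length(out_d) < n) {
        m <- max(2L * (n - length(out_d)), 100L)
        cand_d <- drugs[sample.int(length(drugs), m, replace = TRUE)]
        cand_p <- prots[sample.int(length(prots), m, replace = TRUE)]
        key <- paste(cand_d, cand_p, sep = "\r")
        ok <- !(key %in% forbid) & !(key %in% seen) & !duplicated(key)
        out_d <- c(out_d, cand_d[ok]); out_p <- c(out_p, cand_p[ok])
        seen <- c(seen, key[ok])
      }
      out <- data.frame(drug = out_d[seq_len(n)], protein = out_p[seq_len(n)],
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

#' Build the balanced labeled pair table
#'
#' Positives are the network's drug-target edges; negatives are sampled
#' uniformly from non-edges at `negative_ratio` : 1 per positive.
#'
#' @param g a `man_graph`.
#' @param seed RNG seed for negative sampling.
#' @param negative_ratio negatives per positive (default 1, the balanced
#'   design).
#' @param extra_positives optional data.frame (`drug`, `protein`) of
#'   additional positive pairs not present as edges (e.g. held-out test
#'   interactions); they are also excluded from the negative pool.
#' @return data.frame with columns `drug`, `protein`, `label`.
#' @export
make_pair_table <- function(g, seed = 1L, negative_ratio = 1,
                            extra_positives = NULL) {
  dti <- g$edges[g$edges$relation == "drug-target", , drop = FALSE]
  pos <- data.frame(
    drug = ifelse(node_type_of(dti$u) == "drug", dti$u, dti$v),
    protein = ifelse(node_type_of(dti$u) == "drug", dti$v, dti$u),
    stringsAsFactors = FALSE)
  if (!is.null(extra_positives) && nrow(extra_positives) > 0L) {
    pos <- rbind(pos, extra_positives[, c("drug", "protein")])
    pos <- pos[!duplicated(paste(pos$drug, pos$protein, sep = "\r")), ,
               drop = FALSE]
  }
  if (nrow(pos) == 0L) stop("graph has no drug-target edges", call. = FALSE)
  n_neg <- as.integer(round(negative_ratio * nrow(pos)))
  neg <- sample_negatives(g, n_neg, seed = seed, exclude = pos)
  out <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
  rownames(out) <- NULL
  out
}

#' Stratified fold assignment
#'
#' Partitions the rows into k folds so that per-class fold sizes differ by
#' at most one — the stratified design of the 5-fold protocol.
#'
#' @param labels vector of 0/1 labels (one per dataset row).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return a `fold_plan`: integer vector of fold ids in 1..k.
#' @export
make_fold_plan <- function(labels, k = 5L, seed = 1L) {
  k <- assert_scalar_int(k, "k")
  labels <- as.integer(labels)
  if (any(table(factor(labels, levels = c(0L, 1L))) < k)) {
    stop(sprintf("need at least %d rows of each class for %d folds", k, k),
         call. = FALSE)
  }
  fold <- integer(length(labels))
  totals <- integer(k)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # spread each class's remainder over the currently smallest folds so
      # total fold sizes also differ by at most one
      sizes <- rep(base, k)
      if (extra > 0L) {
        sizes[order(totals, seq_len(k))[seq_len(extra)]] <- base + 1L
      }
      fold[idx] <- rep.int(seq_len(k), sizes)
      totals <- totals + sizes
    }
  })
  structure(fold, class = "fold_plan", k = k)
}

#' Confusion counts
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  if (!all(labels %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    stop("labels and predictions must be binary", call. = FALSE)
  }
  list(TP = sum(labels == 1L & predicted == 1L),
       FP = sum(labels == 0L & predicted == 1L),
       TN = sum(labels == 0L & predicted == 0L),
       FN = sum(labels == 1L & predicted == 0L))
}

#' Threshold classification metrics from confusion counts
#'
#' Acc = (TP+TN)/(TP+FP+TN+FN); TPR = TP/(TP+FN); TNR = TN/(FP+TN);
#' PPV = TP/(FP+TP); MCC = (TP TN - FP FN) /
#' sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)). A metric whose denominator is zero
#' is reported as `NA` (undefined), never coerced to 0.
#'
#' @param cc confusion counts from [confusion()].
#' @return named numeric vector `Acc`, `TPR`, `TNR`, `PPV`, `MCC`.
#' @export
classification_metrics <- function(cc) {
  tp <- cc$TP; fp <- cc$FP; tn <- cc$TN; fn <- cc$FN
  total <- tp + fp + tn + fn
  if (total == 0L) stop("empty confusion table", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(as.double(tp + fn)) * sqrt(as.double(tn + fp)) *
    sqrt(as.double(tp + fp)) * sqrt(as.double(tn + fn))
  c(Acc = (tp + tn) / total,
    TPR = safe_div(tp, tp + fn),
    TNR = safe_div(tn, fp + tn),
    PPV = safe_div(tp, fp + tp),
    MCC = if (mcc_den == 0) NA_real_ else
      (as.double(tp) * tn - as.double(fp) * fn) / mcc_den)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold and reports the ROC point
#' list plus the trapezoidal area, which equals the Mann-Whitney
#' probability that a random positive outscores a random negative with
#' ties counted one half.
#'
#' @param labels true 0/1 labels.
#' @param scores real-valued scores, higher = more likely positive.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]
  sc_sorted <- scores[ord]
  cum_tp <- cumsum(lab_sorted == 1L)
  cum_fp <- cumsum(lab_sorted == 0L)
  last_of_thr <- cumsum(as.integer(table(factor(sc_sorted, levels = thr))))
  points <- data.frame(
    fpr = c(0, cum_fp[last_of_thr] / n_neg),
    tpr = c(0, cum_tp[last_of_thr] / n_pos),
    threshold = c(Inf, thr))
  # rank (Mann-Whitney) form of the trapezoidal area, ties counted 1/2
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) /
    (as.double(n_pos) * n_neg)
  list(points = points, auc = auc)
}

#' Cross-validated evaluation of a representation
#'
#' For each fold, fits the classifier on the other k-1 folds and scores
#' the held-out fold; reports the five threshold metrics (at score 0.5)
#' plus AUC per fold and their mean and sample (n-1) standard deviation.
#'
#' With precomputed features (`ds`), every fold reuses the same feature
#' matrix — appropriate for attribute features, and the "global" mode for
#' behavior features (one embedding of the full network). Passing
#' `feature_builder` instead enables the leakage-safe mode: the builder is
#' called once per fold with the held-out positive pairs and must return a
#' feature matrix computed without using those interactions (see
#' [behavior_feature_builder()]).
#'
#' @param ds a `pair_dataset` from [build_pair_features()].
#' @param plan a [make_fold_plan()] assignment for `ds$pairs`.
#' @param clf a classifier contract, e.g. [classifier_random_forest()].
#' @param feature_builder optional `function(test_pairs)` returning a
#'   feature matrix for all rows of `ds$pairs`.
#' @param seed seed for per-fold classifier fitting.
#' @return a `metrics_report`: list with `per_fold` (data.frame), `mean`,
#'   `sd`, and the fold ROC curves.
#' @export
run_cv <- function(ds, plan, clf, feature_builder = NULL, seed = 1L) {
  stopifnot(inherits(ds, "pair_dataset"), inherits(plan, "fold_plan"),
            inherits(clf, "dti_classifier"))
  k <- attr(plan, "k")
  if (length(plan) != nrow(ds$pairs)) {
    stop("fold plan length does not match dataset", call. = FALSE)
  }
  labels <- ds$pairs$label
  rows <- vector("list", k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(plan == f)
    train_idx <- which(plan != f)
    x <- if (is.null(feature_builder)) {
      ds$features
    } else {
      feature_builder(ds$pairs[test_idx, , drop = FALSE])
    }
    fold_seed <- derive_seed(seed, "cv_fold", f)
    fit <- with_seed(fold_seed, clf$fit(x[train_idx, , drop = FALSE],
                                        labels[train_idx]))
    scores <- clf$score(fit, x[test_idx, , drop = FALSE])
    if (inherits(scores, "try-error") || anyNA(scores)) {
      stop(sprintf("classifier '%s' failed on fold %d", clf$name, f),
           call. = FALSE)
    }
    cc <- confusion(labels[test_idx], as.integer(scores >= 0.5))
    roc <- roc_auc(labels[test_idx], scores)
    rows[[f]] <- data.frame(fold = f, TP = cc$TP, FP = cc$FP, TN = cc$TN,
                            FN = cc$FN, t(classification_metrics(cc)),
                            AUC = roc$auc)
    rocs[[f]] <- roc$points
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("Acc", "TPR", "TNR", "PPV", "MCC", "AUC")
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_cols]),
    sd = vapply(per_fold[metric_cols], stats::sd, numeric(1L)),
    roc = rocs, tag = ds$tag, classifier = clf$name),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %s features, %s classifier\n",
              nrow(x$per_fold), x$tag, x$classifier))
  print(format(x$per_fold, digits = 4L), row.names = FALSE)
  cat("Average: ",
      paste(sprintf("%s %.4f ± %.4f", names(x$mean), x$mean, x$sd),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' Per-fold rows followed by an `Average` row in mean +/- sd form.
#'
#' @param report a `metrics_report`.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  pf <- report$per_fold
  metric_cols <- c("Acc", "TPR", "TNR", "PPV", "MCC", "AUC")
  out <- data.frame(fold = as.character(pf$fold),
                    lapply(pf[metric_cols], function(v) sprintf("%.4f", v)),
                    stringsAsFactors = FALSE)
  avg <- c("Average", sprintf("%.4f ± %.4f", report$mean, report$sd))
  out <- rbind(out, stats::setNames(as.list(avg), names(out)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path output JSON path.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(tag = report$tag, classifier = report$classifier,
         per_fold = report$per_fold,
         mean = as.list(report$mean), sd = as.list(report$sd)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Leakage-safe behavior feature builder
#'
#' Returns a closure for [run_cv()]'s `feature_builder` argument: for each
#' fold it removes that fold's positive drug-target edges from the
#' network, re-walks and re-embeds the reduced graph, and assembles the
#' pair features — so the embedding never sees the interactions it is
#' asked to predict.
#'
#' @param g the full `man_graph`.
#' @param pairs the dataset's pair table (columns `drug`, `protein`,
#'   `label`).
#' @param walk_cfg a [walk_config()].
#' @param sg_cfg a [skipgram_config()].
#' @return `function(test_pairs)` returning the feature matrix for all
#'   rows of `pairs`.
#' @export
behavior_feature_builder <- function(g, pairs, walk_cfg = walk_config(),
                                     sg_cfg = skipgram_config()) {
  force(g); force(pairs); force(walk_cfg); force(sg_cfg)
  function(test_pairs) {
    g_fold <- remove_dti_edges(g, test_pairs[test_pairs$label == 1L, ,
                                             drop = FALSE])
    emb <- train_embeddings(generate_walks(g_fold, walk_cfg), sg_cfg)
    ds <- build_pair_features(pairs, emb, emb, tag = "behavior")
    if (nrow(ds$pairs) != nrow(pairs)) {
      stop("fold embedding lost nodes present in the pair table",
           call. = FALSE)
    }
    ds$features
  }
}
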