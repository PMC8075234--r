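METRIC_NAMES <- c("accuracy", "sensitivity", "specificity", "mcc", "f1")

#' Classification metrics from a confusion matrix
#'
#' Fall-risk is the positive class.  Accuracy, sensitivity and specificity
#' are percentages; MCC lies in \[-1, 1\] and F1 in \[0, 1\]:
#' \deqn{sens = TP/(TP+FN), \quad spec = TN/(TN+FP),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)},}
#' \deqn{F1 = 2TP / (2TP + FP + FN).}
#' A metric whose denominator is zero is returned as `NA` with a warning.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (total > 0).
#' @return named list `accuracy`, `sensitivity`, `specificity`, `mcc`,
#'   `f1`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("negative confusion counts")
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(accuracy = 100 * (tp + tn) / n,
       sensitivity = 100 * safe(tp, tp + fn, "sensitivity"),
       specificity = 100 * safe(tn, tn + fp, "specificity"),
       mcc = safe(tp * tn - fp * fn, mcc_den, "MCC"),
       f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"))
}

# confusion counts from logical truth/prediction vectors
confusion_counts <- function(truth, pred) {
  list(tp = sum(truth & pred), fp = sum(!truth & pred),
       fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

#' Leave-one-out random-forest predictions
#'
#' For each participant, a random forest (bootstrap sampling + random
#' feature subsetting, majority vote) is trained on all remaining
#' participants using only the subset's feature columns, and the held-out
#' participant is predicted.  Feature preprocessing is median imputation;
#' by default it is fitted once on the full table (matching a single
#' global feature-selection pass), with `nested = TRUE` refitting the
#' imputation inside every fold.  Deterministic given `seed`.
#'
#' @param table a `feature_table`.
#' @param subset a `feature_subset`, or `NULL` / `"none"` for all
#'   features.
#' @param n_trees forest size (study baseline: 100).
#' @param seed integer RNG seed.
#' @param nested refit imputation per fold (default `FALSE`).
#' @return logical vector of predicted fall-risk labels, one per row.
#' @export
loocv_predict <- function(table, subset = NULL, n_trees = 100, seed = 1,
                          nested = FALSE) {
  y <- factor(table$fall_risk, levels = c(FALSE, TRUE))
  if (length(unique(table$fall_risk)) < 2)
    stop("need both classes for LOOCV")
  X <- feature_matrix(table)
  if (!is.null(subset) && !identical(subset, "none")) {
    if (!length(subset$feature_names)) stop("empty feature subset")
    missing <- setdiff(subset$feature_names, colnames(X))
    if (length(missing))
      stop("subset features absent from table: ",
           paste(missing, collapse = ", "))
    X <- X[, subset$feature_names, drop = FALSE]
  }
  n <- nrow(X)
  if (!nested) X <- impute_median(X)
  pred <- logical(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (nested) {
      med <- apply(Xtr, 2, median, na.rm = TRUE)
      med[is.na(med)] <- 0
      for (j in seq_len(ncol(Xtr))) {
        Xtr[is.na(Xtr[, j]), j] <- med[j]
        if (is.na(Xte[1, j])) Xte[1, j] <- med[j]
      }
    }
    fit <- randomForest::randomForest(x = Xtr, y = y[-i], ntree = n_trees)
    pred[i] <- as.logical(as.character(stats::predict(fit, Xte)) == "TRUE")
  }
  pred
}

#' LOOCV metrics for one configuration
#'
#' @inheritParams loocv_predict
#' @return a `confusion_metrics()` list with the confusion counts attached
#'   as attribute `counts`.
#' @export
loocv_metrics <- function(table, subset = NULL, n_trees = 100, seed = 1,
                          nested = FALSE) {
  pred <- loocv_predict(table, subset, n_trees, seed, nested)
  cc <- confusion_counts(table$fall_risk, pred)
  m <- suppressWarnings(confusion_metrics(cc$tp, cc$fp, cc$fn, cc$tn))
  attr(m, "counts") <- cc
  m
}

#' Evaluate the full configuration grid
#'
#' Runs LOOCV random forests for every step set in `tables` crossed with
#' every selector subset: CFS (auto-sized), Relief-F and extra-trees at
#' the top 30/20/10/5 features, plus a no-selection baseline — 10
#' configurations per table, 40 for the canonical four step sets.
#' Feature selection is performed once on the full table (the global
#' protocol the ranked-subset tables imply); see [loocv_predict()] for the
#' nested alternative.
#'
#' @param tables named list of `feature_table`s (e.g. `AS`, `S`, `T`,
#'   `S&T`), aligned on participants.
#' @param ks subset sizes for the ranked selectors (default
#'   `c(30, 20, 10, 5)`).
#' @param n_trees forest size (default 100).
#' @param seed integer RNG seed (also passed to the extra-trees ranker).
#' @param selectors which selectors to run.
#' @return data.frame of class `config_results`: one row per
#'   configuration with `set_id`, `selector`, `k`, `config`, `n_trees`,
#'   the five metrics and the confusion counts; feature subsets attached
#'   as attribute `subsets`.
#' @export
evaluate_grid <- function(tables, ks = c(30, 20, 10, 5), n_trees = 100,
                          seed = 1,
                          selectors = c("none", "CFS", "RelF", "ETC")) {
  ids <- lapply(tables, function(t) t$participant_id)
  if (!all(vapply(ids, identical, TRUE, ids[[1]])))
    stop("tables are not aligned on participants")
  rows <- list(); subsets <- list()
  for (set_id in names(tables)) {
    tab <- tables[[set_id]]
    attr(tab, "set_id") <- set_id
    p <- ncol(feature_matrix(tab))
    subs <- list()
    if ("none" %in% selectors)
      subs <- c(subs, list(feature_subset(set_id, "none", p,
                                          colnames(feature_matrix(tab)))))
    if ("CFS" %in% selectors) subs <- c(subs, list(cfs_select(tab)))
    if ("RelF" %in% selectors) {
      rk <- relieff_rank(tab)
      subs <- c(subs, lapply(ks, function(k)
        top_k(rk, k, set_id = set_id, selector = "RelF")))
    }
    if ("ETC" %in% selectors) {
      rk <- etc_rank(tab, seed = seed)
      subs <- c(subs, lapply(ks, function(k)
        top_k(rk, k, set_id = set_id, selector = "ETC")))
    }
    for (sub in subs) {
      m <- loocv_metrics(tab, if (sub$selector == "none") NULL else sub,
                         n_trees = n_trees, seed = seed)
      cc <- attr(m, "counts")
      tag <- if (sub$selector %in% c("RelF", "ETC"))
        paste0(sub$selector, sub$k) else sub$selector
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = set_id, selector = sub$selector, k = sub$k,
        config = paste0(set_id, "-", tag), n_trees = n_trees,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, mcc = m$mcc, f1 = m$f1,
        tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn)
      subsets[[paste0(set_id, "-", tag)]] <- sub
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "subsets") <- subsets
  class(res) <- c("config_results", "data.frame")
  res
}

#' Summed-rank model selection
#'
#' Each configuration is ranked on each of the five metrics (rank 1 =
#' best; ties share the mean rank, so fractional summed ranks arise) and
#' the ranks are summed.  Five is the lowest possible summed rank.  The
#' configurations are returned in ascending summed-rank order.
#'
#' @param results a data.frame with the five metric columns (e.g. from
#'   [evaluate_grid()]).
#' @param top_n how many leading configurations to return (default 5);
#'   when fewer are available all are returned with a warning.
#' @return `results` with a `summed_rank` column, ordered by it, truncated
#'   to `top_n` rows; the full ranked table is attached as attribute
#'   `full`.
#' @export
summed_rank_selection <- function(results, top_n = 5) {
  if (nrow(results) < top_n) {
    warning("fewer configurations (", nrow(results), ") than top_n")
    top_n <- nrow(results)
  }
  ranks <- vapply(METRIC_NAMES, function(m)
    rank(-results[[m]], ties.method = "average", na.last = "keep"),
    numeric(nrow(results)))
  results$summed_rank <- rowSums(ranks)
  ord <- order(results$summed_rank)
  full <- results[ord, ]
  rownames(full) <- NULL
  out <- utils::head(full, top_n)
  attr(out, "full") <- full
  out
}

#' Tree-count sweep for one configuration
#'
#' Re-evaluates a configuration's LOOCV metrics over a grid of forest
#' sizes and reports the best by accuracy (ties go to the smaller
#' forest).
#'
#' @inheritParams loocv_predict
#' @param tree_counts forest sizes to test (default the 13-point grid
#'   from 5 to 1000).
#' @return list with `per_count` (data.frame of metrics per size) and
#'   `best_n_trees`.
#' @export
tree_sweep <- function(table, subset = NULL,
                       tree_counts = c(5, 10, 25, 50, 75, 100, 150, 200,
                                       250, 300, 400, 500, 1000),
                       seed = 1, nested = FALSE) {
  if (!length(tree_counts)) stop("tree_counts is empty")
  rows <- lapply(tree_counts, function(nt) {
    m <- loocv_metrics(table, subset, n_trees = nt, seed = seed,
                       nested = nested)
    data.frame(n_trees = nt, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               mcc = m$mcc, f1 = m$f1)
  })
  per_count <- do.call(rbind, rows)
  best <- per_count$n_trees[order(-per_count$accuracy,
                                  per_count$n_trees)][1]
  list(per_count = per_count, best_n_trees = best)
}

#' Seed-robustness summary
#'
#' Rebuilds a configuration's LOOCV evaluation under several random seeds
#' and summarizes each metric's mean and standard deviation.
#'
#' @inheritParams loocv_predict
#' @param seeds integer vector of distinct seeds (study protocol: 10).
#' @return list with `per_seed` (data.frame) and `summary` (data.frame
#'   `metric`, `mean`, `sd`).
#' @export
seed_robustness <- function(table, subset = NULL, n_trees = 100,
                            seeds = 1:10, nested = FALSE) {
  if (length(seeds) < 2) stop("need at least 2 seeds")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  rows <- lapply(seeds, function(s) {
    m <- loocv_metrics(table, subset, n_trees = n_trees, seed = s,
                       nested = nested)
    data.frame(seed = s, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               mcc = m$mcc, f1 = m$f1)
  })
  per_seed <- do.call(rbind, rows)
  summary <- data.frame(
    metric = METRIC_NAMES,
    mean = vapply(METRIC_NAMES, function(m) mean(per_seed[[m]]), 1),
    sd = vapply(METRIC_NAMES, function(m) sd(per_seed[[m]]), 1),
    row.names = NULL)
  list(per_seed = per_seed, summary = summary)
}
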