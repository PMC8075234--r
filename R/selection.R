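# --- preprocessing shared by the selectors -------------------------------

# median imputation; all-NA or constant columns become all-zero
impute_median <- function(X) {
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (anyNA(x)) {
      med <- median(x, na.rm = TRUE)
      if (is.na(med)) med <- 0
      x[is.na(x)] <- med
      X[, j] <- x
    }
  }
  X
}

zscore <- function(X) {
  X <- impute_median(X)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

minmax <- function(X) {
  X <- impute_median(X)
  lo <- apply(X, 2, min)
  rg <- apply(X, 2, max) - lo
  rg[rg == 0] <- 1
  sweep(sweep(X, 2, lo), 2, rg, "/")
}

#' CFS subset merit
#'
#' Merit of a k-feature subset given its mean absolute feature-class
#' correlation and mean absolute feature-feature correlation:
#' `merit = k * r_cf / sqrt(k + k * (k - 1) * r_ff)`.  Rewards relevance,
#' penalizes redundancy.
#'
#' @param r_cf mean absolute feature-class correlation.
#' @param r_ff mean absolute pairwise feature-feature correlation.
#' @param k subset size (>= 1).
#' @return the merit.
#' @export
cfs_merit <- function(r_cf, r_ff, k) {
  stopifnot(k >= 1)
  den <- k + k * (k - 1) * r_ff
  if (den <= 0) stop("non-positive merit denominator")
  k * r_cf / sqrt(den)
}

#' Correlation-based feature selection (CFS)
#'
#' Greedy forward best-first search over the merit of [cfs_merit()]:
#' starting from the empty set, the feature whose addition most improves
#' the subset merit is added until no addition improves it.  Correlations
#' are absolute Pearson (point-biserial against the binary fall-risk
#' label), computed on median-imputed, z-scored columns.  CFS stops early
#' by itself — on gait feature tables it typically keeps fewer than five
#' features.
#'
#' @param table a `feature_table`.
#' @return a `feature_subset` list: `set_id`, `selector = "CFS"`, `k`,
#'   `feature_names`, `merit`.
#' @export
cfs_select <- function(table) {
  y <- table$fall_risk
  if (length(unique(y)) < 2) stop("fall_risk label is constant")
  X <- zscore(feature_matrix(table))
  y01 <- as.numeric(y)
  r_cf <- abs(suppressWarnings(as.numeric(stats::cor(X, y01))))
  r_cf[is.na(r_cf)] <- 0
  p <- ncol(X)
  Cff <- matrix(NA_real_, p, p)        # filled lazily
  ff <- function(i, j) {
    if (is.na(Cff[i, j])) {
      v <- abs(suppressWarnings(stats::cor(X[, i], X[, j])))
      if (is.na(v)) v <- 0
      Cff[i, j] <<- v; Cff[j, i] <<- v
    }
    Cff[i, j]
  }
  sel <- integer(0)
  best_merit <- 0
  repeat {
    cand <- setdiff(seq_len(p), sel)
    if (!length(cand)) break
    merits <- vapply(cand, function(j) {
      s <- c(sel, j); k <- length(s)
      mcf <- mean(r_cf[s])
      mff <- if (k > 1)
        mean(vapply(utils::combn(s, 2, simplify = FALSE),
                    function(pr) ff(pr[1], pr[2]), 1)) else 0
      cfs_merit(mcf, mff, k)
    }, 1)
    j <- cand[which.max(merits)]
    if (merits[which.max(merits)] <= best_merit + 1e-12) break
    best_merit <- max(merits)
    sel <- c(sel, j)
  }
  feature_subset(set_id = attr(table, "set_id"), selector = "CFS",
                 k = length(sel), feature_names = colnames(X)[sel],
                 merit = best_merit)
}

#' Relief-F feature weights
#'
#' Standard Relief-F with every instance used as a probe: features are
#' min-max normalized, neighbors found by Manhattan distance, and each
#' feature's weight accumulates the normalized value differences to the
#' `n_neighbors` nearest same-class hits (penalty) and nearest other-class
#' misses (reward, weighted by class priors).  Weights lie in \[-1, 1\];
#' a constant feature scores 0.  Redundant copies of an informative
#' feature all keep high weights — Relief-F does not remove redundancy.
#'
#' @param table a `feature_table`.
#' @param n_neighbors nearest hits/misses per probe (default 10); reduced
#'   with a warning when a class is too small.
#' @return data.frame `feature`, `weight`, `index`, sorted by descending
#'   weight (ties by ascending column index).
#' @export
relieff_rank <- function(table, n_neighbors = 10) {
  y <- table$fall_risk
  X <- minmax(feature_matrix(table))
  n <- nrow(X); p <- ncol(X)
  classes <- unique(y)
  if (length(classes) < 2) stop("need two classes")
  sizes <- vapply(split(seq_len(n), y), length, 1L)
  kmax <- min(sizes) - 1L
  k <- n_neighbors
  if (k > kmax) {
    warning("reducing n_neighbors from ", k, " to ", kmax,
            ": smallest class has ", min(sizes), " members")
    k <- kmax
  }
  if (k < 1) stop("a class has too few members for Relief-F")
  priors <- as.numeric(sizes[as.character(classes)]) / n
  names(priors) <- as.character(classes)
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  W <- numeric(p)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    same <- which(y == y[i]); same <- same[same != i]
    hits <- same[order(D[i, same])][seq_len(min(k, length(same)))]
    hit_diff <- colMeans(abs(X[hits, , drop = FALSE] -
                             matrix(X[i, ], length(hits), p, byrow = TRUE)))
    miss_diff <- numeric(p)
    for (cl in setdiff(as.character(classes), ci)) {
      oth <- which(as.character(y) == cl)
      ms <- oth[order(D[i, oth])][seq_len(min(k, length(oth)))]
      wcl <- priors[cl] / (1 - priors[ci])
      miss_diff <- miss_diff + wcl *
        colMeans(abs(X[ms, , drop = FALSE] -
                     matrix(X[i, ], length(ms), p, byrow = TRUE)))
    }
    W <- W + (miss_diff - hit_diff) / n
  }
  ord <- order(-W, seq_len(p))
  data.frame(feature = colnames(X)[ord], weight = W[ord], index = ord,
             row.names = NULL)
}

#' Extra-trees feature importances
#'
#' Impurity-based importances from an extremely-randomized-trees ensemble
#' (random split points, no bootstrap), normalized to sum to one.
#'
#' @param table a `feature_table`.
#' @param n_estimators number of trees (default 250).
#' @param seed integer RNG seed.
#' @return data.frame `feature`, `weight`, `index`, sorted by descending
#'   importance (ties by ascending column index).
#' @export
etc_rank <- function(table, n_estimators = 250, seed = 1) {
  y <- factor(table$fall_risk)
  if (nlevels(y) < 2) stop("need two classes")
  if (nrow(table) < 4) stop("need at least 4 rows")
  X <- as.data.frame(impute_median(feature_matrix(table)))
  orig <- names(X)
  names(X) <- paste0("f", seq_along(X))   # ranger dislikes exotic names
  fit <- ranger::ranger(x = X, y = y, num.trees = n_estimators,
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- pmax(fit$variable.importance, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = orig[ord], weight = unname(imp[ord]), index = ord,
             row.names = NULL)
}

#' A selected feature subset
#'
#' @param set_id which step set the parent table came from.
#' @param selector `"CFS"`, `"RelF"`, `"ETC"` or `"none"`.
#' @param k subset size.
#' @param feature_names ordered feature names.
#' @param merit optional CFS merit of the final subset.
#' @return list of class `feature_subset`.
#' @export
feature_subset <- function(set_id, selector, k, feature_names, merit = NULL) {
  if (anyDuplicated(feature_names)) stop("duplicate features in subset")
  structure(list(set_id = set_id, selector = selector, k = k,
                 feature_names = feature_names, merit = merit),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %s-%s (k=%d): %s\n",
              if (is.null(x$set_id)) "?" else x$set_id, x$selector, x$k,
              paste(utils::head(x$feature_names, 8), collapse = ", ")))
  invisible(x)
}

#' Top-k features from a ranking
#'
#' @param ranking a ranking data.frame from [relieff_rank()] or
#'   [etc_rank()] (descending weight, ties already broken by ascending
#'   column index).
#' @param k subset size; the study design uses 30, 20, 10 and 5.
#' @param set_id,selector metadata passed to [feature_subset()].
#' @return a `feature_subset` of the first `k` names; top-k subsets are
#'   nested by construction.
#' @export
top_k <- function(ranking, k, set_id = NULL, selector = "RelF") {
  if (k > nrow(ranking)) stop("k exceeds the number of ranked features")
  feature_subset(set_id = set_id, selector = selector, k = k,
                 feature_names = ranking$feature[seq_len(k)])
}
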