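# Hybrid feature selection: the low-variance filter, chi-square /
# mutual-information / Fisher scorers, top-k union, and the greedy forward
# wrapper driven by cross-validated classifier accuracy.

#' Construct a feature table
#'
#' @param values Numeric matrix, instances x features.
#' @param names Unique feature identifiers (defaults to column names).
#' @param family Per-feature provenance tag (e.g. "stats", "hjorth",
#'   "bandpower", "dwt"); recycled if length 1.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, names = colnames(values), family = "unknown") {
  values <- as.matrix(values)
  if (is.null(names)) names <- paste0("f", seq_len(ncol(values)))
  blank <- !nzchar(names)
  names[blank] <- paste0("f", which(blank))
  if (anyDuplicated(names)) stopf("feature names must be unique")
  if (length(family) == 1) family <- rep(family, ncol(values))
  colnames(values) <- names
  structure(list(values = values, names = names, family = family),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d instances x %d features (%d families)\n",
              nrow(x$values), ncol(x$values), length(unique(x$family))))
  invisible(x)
}

#' Subset the columns of a feature table
#' @param table A `feature_table`.
#' @param keep Logical or integer column selector.
#' @return The reduced `feature_table`.
#' @export
subset_features <- function(table, keep) {
  feature_table(table$values[, keep, drop = FALSE],
                table$names[keep], table$family[keep])
}

#' Impute missing feature values by the column median
#'
#' @param table A `feature_table` possibly containing NA.
#' @param medians Optional named vector of training-split medians to apply;
#'   when NULL, medians are computed from `table` itself.
#' @return List with the imputed `table` and the `medians` used.
#' @export
impute_missing <- function(table, medians = NULL) {
  v <- table$values
  if (is.null(medians)) {
    medians <- apply(v, 2, stats::median, na.rm = TRUE)
    medians[!is.finite(medians)] <- 0
  }
  for (j in which(colSums(is.na(v)) > 0))
    v[is.na(v[, j]), j] <- medians[[j]]
  list(table = feature_table(v, table$names, table$family), medians = medians)
}

selection_result <- function(scores, mask, method, names) {
  structure(list(scores = scores, ranking = order(scores, decreasing = TRUE),
                 mask = mask, method = method, names = names),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d / %d features kept\n",
              x$method, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Remove features with low variance
#'
#' Drops features whose sample variance is strictly below `threshold`;
#' a variance exactly equal to the threshold is kept.
#'
#' @param table A `feature_table` with >= 2 instances.
#' @param threshold Variance threshold (default 0.01).
#' @return A `selection_result` whose scores are the variances.
#' @export
rflv <- function(table, threshold = 0.01) {
  if (nrow(table$values) < 2) stopf("need >= 2 instances to estimate variance")
  v <- apply(table$values, 2, stats::var)
  selection_result(v, v >= threshold, "rflv", table$names)
}

plugin_mi <- function(x, y, bins = 10) {
  brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                na.rm = TRUE))
  if (length(brk) < 2) return(0)
  xb <- cut(x, breaks = brk, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Score features against binary labels
#'
#' Three univariate supervised scorers. `chi2` min-max scales each feature
#' to \[0, 1\] and computes the chi-square statistic of the 2 x classes
#' table of per-class feature mass (sums of x and of 1 - x); on a binary
#' feature this is the classical contingency chi-square. `mutual_info`
#' discretizes each feature into up to 10 quantile bins and computes
#' plug-in mutual information in nats. `fisher` is the between-class over
#' within-class variance ratio.
#'
#' @param table A `feature_table`.
#' @param labels A `label_set` or 0/1 vector.
#' @param method One of "chi2", "mutual_info", "fisher".
#' @return A `selection_result` (mask all-true; use [union_topk()] or the
#'   ranking to select).
#' @export
score_features <- function(table, labels, method = c("chi2", "mutual_info", "fisher")) {
  method <- match.arg(method)
  y <- if (inherits(labels, "label_set")) labels$labels else labels
  if (length(unique(y)) < 2) stopf("degenerate labels: a single class")
  if (length(y) != nrow(table$values)) stopf("labels/instances mismatch")
  v <- table$values
  scores <- switch(method,
    chi2 = apply(v, 2, function(x) {
      rng <- range(x)
      xs <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
      obs <- rbind(tapply(xs, y, sum), tapply(1 - xs, y, sum))
      if (any(!is.finite(obs))) return(0)
      rs <- rowSums(obs); cs <- colSums(obs)
      expd <- outer(rs, cs) / sum(obs)
      ok <- expd > 0
      sum((obs[ok] - expd[ok])^2 / expd[ok])
    }),
    mutual_info = apply(v, 2, plugin_mi, y = y),
    fisher = apply(v, 2, function(x) {
      mu <- mean(x)
      num <- 0; den <- 0
      for (cl in unique(y)) {
        xc <- x[y == cl]
        num <- num + length(xc) * (mean(xc) - mu)^2
        den <- den + length(xc) * stats::var(xc) * (length(xc) - 1) / length(xc)
      }
      if (den > 0) num / den else Inf
    }))
  selection_result(scores, rep(TRUE, ncol(v)), method, table$names)
}

#' Union of the top-k features of two rankings
#'
#' @param a,b `selection_result`s over the same feature set.
#' @param k How many top-ranked features to take from each (default 200).
#' @return A `selection_result` whose mask is the union (size between k
#'   and 2k); scores are the elementwise maxima of the two rank-normalized
#'   scores, kept only for ordering.
#' @export
union_topk <- function(a, b, k = 200) {
  if (!identical(a$names, b$names))
    stopf("selection results cover different feature sets")
  k <- min(k, length(a$names))
  mask <- rep(FALSE, length(a$names))
  mask[a$ranking[seq_len(k)]] <- TRUE
  mask[b$ranking[seq_len(k)]] <- TRUE
  ra <- rank(-a$scores); rb <- rank(-b$scores)
  selection_result(-pmin(ra, rb), mask, paste(a$method, b$method, sep = "+"),
                   a$names)
}

# Stratified fold assignment, fixed under `seed`.
make_folds <- function(y, folds, seed, groups = NULL) {
  if (is.null(groups)) groups <- seq_along(y)
  ug <- unique(groups)
  gy <- y[match(ug, groups)]
  fold_of_group <- integer(length(ug))
  with_seed(seed, {
    for (cl in unique(gy)) {
      idx <- which(gy == cl)
      fold_of_group[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold_of_group[match(groups, ug)]
}

cv_accuracy <- function(x, y, model, fold_id) {
  folds <- sort(unique(fold_id))
  acc <- numeric(length(folds))
  for (i in seq_along(folds)) {
    te <- fold_id == folds[i]
    if (length(unique(y[!te])) < 2) stopf("a class is absent from a training fold")
    fit <- fit_classifier(model, x[!te, , drop = FALSE], y[!te])
    pred <- predict_classifier(fit, x[te, , drop = FALSE])
    acc[i] <- mean(pred$class == y[te])
  }
  acc
}

#' Greedy forward wrapper selection
#'
#' Starting from the empty set, repeatedly appends the feature that
#' maximizes mean cross-validated accuracy of `model`; stops when no
#' candidate improves the accuracy by more than 1e-6. Ties are broken by
#' the lowest feature index. Fold assignment is stratified, seeded, and
#' fixed before the search so all candidate evaluations share folds.
#'
#' @param table A `feature_table` (already filtered).
#' @param labels A `label_set` or 0/1 vector.
#' @param model Classifier name: one of svm, dt, rf, lda, lr, nb, knn.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param skip_perfect Skip features whose single-feature CV accuracy is
#'   1.0 (useful on tiny datasets where one feature separates by chance).
#' @param max_features Optional cap on the selected-set size.
#' @return A `selection_result`; `cv_accuracy` holds the achieved mean
#'   accuracy and `selected` the ordered selected indices.
#' @export
forward_wrapper <- function(table, labels, model, folds = 5, seed = 1,
                            skip_perfect = FALSE, max_features = Inf) {
  y <- if (inherits(labels, "label_set")) labels$labels else labels
  v <- table$values
  if (folds > nrow(v)) stopf("more folds (%d) than instances (%d)", folds, nrow(v))
  fold_id <- make_folds(y, folds, seed)
  banned <- rep(FALSE, ncol(v))
  if (skip_perfect) {
    for (j in seq_len(ncol(v)))
      if (mean(cv_accuracy(v[, j, drop = FALSE], y, model, fold_id)) >= 1)
        banned[j] <- TRUE
  }
  selected <- integer()
  best_acc <- 0
  repeat {
    cand <- setdiff(which(!banned), selected)
    if (!length(cand) || length(selected) >= max_features) break
    accs <- vapply(cand, function(j)
      mean(cv_accuracy(v[, c(selected, j), drop = FALSE], y, model, fold_id)),
      numeric(1))
    best <- which.max(accs)  # which.max takes the first (lowest index) on ties
    if (accs[best] > best_acc + 1e-6) {
      selected <- c(selected, cand[best])
      best_acc <- accs[best]
    } else break
  }
  mask <- rep(FALSE, ncol(v))
  mask[selected] <- TRUE
  res <- selection_result(as.numeric(mask), mask,
                          paste0("forward_wrapper(", model, ")"), table$names)
  res$selected <- selected
  res$cv_accuracy <- best_acc
  res
}

#' Serialize a selection result to CSV
#'
#' @param result A `selection_result`.
#' @param table The `feature_table` it refers to (for family tags).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, table, path) {
  utils::write.csv(
    data.frame(name = result$names, family = table$family,
               score = result$scores,
               rank = match(seq_along(result$scores), result$ranking),
               kept = result$mask),
    path, row.names = FALSE)
  invisible(path)
}
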