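# Permutation feature importance for the intolerant-vs-tolerant contrast: a
# bagged decision-tree ensemble (100 trees, Gini splits) is fit on per-IDR
# feature-count vectors, and each feature's importance is the drop in
# average precision after shuffling its column.

#' Per-region feature-count vectors
#'
#' Counts, per region and feature class, how many annotation records overlap
#' the region by at least one residue (each record counted once, however
#' small the overlap).
#'
#' @param regions Region tibble.
#' @param features Feature tibble.
#' @param classes Feature classes (columns), default all 25 in canonical
#'   order.
#' @return Tibble `region_id` plus one non-negative integer column per class.
#' @export
region_feature_counts <- function(regions, features,
                                  classes = idr_feature_classes()) {
  out <- tibble(region_id = regions$region_id)
  for (cl in classes) {
    f <- features[features$feature_class == cl, , drop = FALSE]
    out[[cl]] <- vapply(seq_len(nrow(regions)), function(i) {
      sum(f$accession == regions$accession[i] &
            f$start <= regions$end[i] & f$end >= regions$start[i])
    }, integer(1))
  }
  out
}

#' Average precision of a ranking
#'
#' Summarizes the precision-recall curve as the weighted mean of precisions
#' achieved at each descending score threshold, weighted by the increase in
#' recall from the previous threshold. Tied scores form a single threshold
#' group: precision is evaluated after the whole group is admitted.
#'
#' @param labels Logical (or 0/1) vector; at least one positive required.
#' @param scores Numeric scores, larger = more positive.
#' @return Average precision in (0, 1].
#' @export
#' @examples
#' average_precision(c(TRUE, FALSE), c(0.2, 0.9)) # positive ranked 2nd: 0.5
average_precision <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    abort("labels and scores must have equal length")
  }
  n_pos <- sum(labels)
  if (n_pos == 0) abort("average precision needs at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  group_end <- which(diff(sc) != 0)
  group_end <- c(group_end, length(sc)) # last index of each tie group
  tp <- cumsum(lab)[group_end]
  precision <- tp / group_end
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Fit the intolerant-vs-tolerant classifier
#'
#' A bagged decision-tree ensemble (random forest, 100 trees, Gini impurity
#' splits) on per-region feature counts. The positive class is `intolerant`,
#' which is heavily outnumbered by `tolerant` in realistic cohorts -- hence
#' average precision, not accuracy, as the evaluation score. The model's
#' positive-class score is the fraction of trees voting `intolerant`.
#'
#' @param counts Feature-count tibble ([region_feature_counts()]).
#' @param labels Character/factor vector aligned with `counts` rows, values
#'   `intolerant` / `tolerant`; both classes must be present.
#' @param ntree Number of trees, default 100.
#' @param seed Integer seed for the ensemble.
#' @return An `idr_classifier` object; `glance()` reports the resubstitution
#'   average precision, and `predict_score()` exposes the score function.
#' @export
fit_intolerance_classifier <- function(counts, labels, ntree = 100,
                                       seed = 1) {
  y <- factor(as.character(labels), levels = c("tolerant", "intolerant"))
  if (any(is.na(y))) abort("labels must be 'intolerant' or 'tolerant'")
  if (length(unique(y)) < 2) {
    abort("both classes must be present to fit the classifier")
  }
  x <- as.data.frame(counts[, setdiff(names(counts), "region_id")])
  set.seed(seed)
  model <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  fit <- list(model = model, feature_names = names(x), x = x, y = y,
              seed = seed)
  fit$baseline_ap <- average_precision(y == "intolerant",
                                       predict_score(fit, x))
  structure(fit, class = "idr_classifier")
}

#' Positive-class score of a fitted classifier
#'
#' @param fit An `idr_classifier`.
#' @param newdata Data frame of feature counts (defaults to the training
#'   data).
#' @return Numeric vector: fraction of trees voting `intolerant`.
#' @export
predict_score <- function(fit, newdata = fit$x) {
  predict(fit$model, newdata = newdata, type = "prob")[, "intolerant"]
}

#' @export
print.idr_classifier <- function(x, ...) {
  cat("<idr_classifier> ", length(x$y), " regions (",
      sum(x$y == "intolerant"), " intolerant), ", x$model$ntree,
      " trees; resubstitution AP = ", round(x$baseline_ap, 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method glance idr_classifier
glance.idr_classifier <- function(x, ...) {
  tibble(n = length(x$y), n_intolerant = sum(x$y == "intolerant"),
         n_tolerant = sum(x$y == "tolerant"), ntree = x$model$ntree,
         baseline_ap = x$baseline_ap)
}

#' Permutation feature importance
#'
#' For each feature, its column is shuffled (breaking the feature-label
#' linkage), the model is re-scored, and the drop in average precision is
#' recorded; the mean and standard deviation over `repeats` shuffles give the
#' importance. Drops are in percentage points of AP; negative drops are
#' retained. A feature is flagged important when its mean drop is at least 5
#' percentage points. By default importance is evaluated on the training
#' cohort (resubstitution); pass a held-out `counts`/`labels` pair to
#' evaluate out-of-sample instead.
#'
#' @param fit An `idr_classifier`.
#' @param counts,labels Evaluation data; default the training cohort.
#' @param repeats Shuffles per feature, default 10.
#' @param seed Integer seed; results are byte-identical under a fixed seed.
#' @return An `idr_importance` tibble: `feature_class`, `mean_drop`,
#'   `sd_drop`, `rank` (1 = largest mean drop), `important`.
#' @export
permutation_importance <- function(fit, counts = NULL, labels = NULL,
                                   repeats = 10, seed = 1) {
  if (repeats < 1) abort("repeats must be >= 1")
  if (is.null(counts)) {
    x <- fit$x
    y <- fit$y
  } else {
    x <- as.data.frame(counts[, fit$feature_names])
    y <- factor(as.character(labels), levels = c("tolerant", "intolerant"))
  }
  pos <- y == "intolerant"
  baseline <- average_precision(pos, predict_score(fit, x))
  set.seed(seed)
  rows <- purrr::map_dfr(fit$feature_names, function(fn) {
    drops <- vapply(seq_len(repeats), function(r) {
      xp <- x
      xp[[fn]] <- xp[[fn]][sample.int(nrow(xp))]
      if (identical(xp[[fn]], x[[fn]])) return(0) # constant column: no-op
      (baseline - average_precision(pos, predict_score(fit, xp))) * 100
    }, double(1))
    tibble(feature_class = fn, mean_drop = mean(drops),
           sd_drop = if (repeats > 1) sd(drops) else NA_real_)
  })
  rows <- rows %>%
    mutate(rank = rank(-.data$mean_drop, ties.method = "first"),
           important = .data$mean_drop >= 5) %>%
    arrange(.data$rank)
  structure(rows, class = c("idr_importance", class(rows)),
            baseline_ap = baseline, repeats = repeats, seed = seed)
}
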