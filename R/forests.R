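#' Bundle a trait matrix with training labels
#'
#' @param matrix A [trait_matrix()].
#' @param labels Per-row labels: categorical (live/other, cluster id,
#'   functional group) or continuous positive biovolume targets (um^3).
#' @return List of class `labeled_training`.
#' @export
labeled_training <- function(matrix, labels) {
  stopifnot(inherits(matrix, "trait_matrix"))
  if (length(labels) != nrow(matrix$values)) {
    stop("label count (", length(labels), ") must equal row count (",
         nrow(matrix$values), ")")
  }
  structure(list(matrix = matrix, labels = labels), class = "labeled_training")
}

# shared ranger invocation; x matrix, y vector/factor
.fit_ranger <- function(x, y, n_trees, seed, importance = "none") {
  df <- as.data.frame(x)
  df[[".y"]] <- y
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 num.trees = n_trees, importance = importance,
                 seed = as.integer(seed), num.threads = 1L,
                 respect.unordered.factors = "order")
}

.check_trees <- function(n_trees) {
  if (n_trees < 3L || n_trees %% 2L == 0L) {
    stop("tree count must be odd and >= 3, got ", n_trees)
  }
}

#' Rank trait importance with a random forest
#'
#' Fits a classification forest and ranks traits by Gini mean-decrease
#' (impurity) importance, descending. Ties are broken lexicographically by
#' trait name so the ranking is deterministic. Used twice in the pipeline:
#' to find the traits that best separate live cells from other signals, and
#' the traits that best separate functional groups.
#'
#' @param train A [labeled_training()] with categorical labels, >= 2 classes
#'   and >= 10 rows per class.
#' @param n_trees Number of trees (odd; default 10001).
#' @param seed Integer seed.
#' @return data.frame of class `importance_ranking` with columns `trait` and
#'   `importance`, ordered by descending importance.
#' @export
rank_importance <- function(train, n_trees = 10001L, seed = 1L) {
  stopifnot(inherits(train, "labeled_training"))
  .check_trees(n_trees)
  y <- factor(train$labels)
  tab <- table(y)
  if (length(tab) < 2L) stop("domain error: need >= 2 classes, got 1")
  if (any(tab < 10L)) stop("domain error: every class needs >= 10 rows")
  rf <- .fit_ranger(train$matrix$values, y, n_trees, seed,
                    importance = "impurity")
  imp <- rf$variable.importance
  ord <- order(-imp, names(imp))
  structure(data.frame(trait = names(imp)[ord], importance = unname(imp)[ord],
                       stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}

#' Take the k top-ranked traits
#'
#' @param ranking An `importance_ranking` from [rank_importance()].
#' @param k Number of traits, `k <= nrow(ranking)`.
#' @return Character vector of the first `k` trait names in ranking order.
#' @export
select_top_k <- function(ranking, k) {
  if (k > nrow(ranking)) {
    stop("domain error: k (", k, ") exceeds ranking length (",
         nrow(ranking), ")")
  }
  ranking$trait[seq_len(k)]
}

#' Fit a random-forest classifier
#'
#' Trains a forest on categorical labels (e.g. density-peak cluster ids) and
#' records its out-of-bag classification error, the pipeline's internal
#' accuracy check. Prediction refuses records missing any training trait.
#'
#' @param train A [labeled_training()] with >= 2 classes.
#' @param n_trees Number of trees (odd; default 1001).
#' @param seed Integer seed.
#' @return An object of class `sfcm_forest` with fields `kind`
#'   (`"classifier"`), `traits_used`, `n_trees`, `seed`, `oob_error`,
#'   `transform_log` and the fitted forest.
#' @export
fit_classifier <- function(train, n_trees = 1001L, seed = 1L) {
  stopifnot(inherits(train, "labeled_training"))
  .check_trees(n_trees)
  y <- factor(train$labels)
  if (nlevels(y) < 2L) stop("domain error: need >= 2 classes, got 1")
  rf <- .fit_ranger(train$matrix$values, y, n_trees, seed)
  structure(list(kind = "classifier",
                 traits_used = colnames(train$matrix$values),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 oob_error = rf$prediction.error,
                 transform_log = train$matrix$transform_log,
                 levels = levels(y), rf = rf),
            class = "sfcm_forest")
}

#' Fit the biovolume random-forest regressor
#'
#' Trains a regression forest on `log10(biovolume)`; the log scale is used
#' because training biovolumes span three orders of magnitude and a
#' linear-scale fit would be dominated by the largest species. The out-of-bag
#' R^2 (`oob_r2`) is therefore also on the log10 scale. Predictions are
#' back-transformed to um^3 and strictly positive.
#'
#' @param train A [labeled_training()] whose labels are positive biovolumes
#'   (um^3).
#' @param n_trees Number of trees (odd; default 10001).
#' @param seed Integer seed.
#' @return An `sfcm_forest` with `kind = "regressor"` and `oob_r2`.
#' @export
fit_biovolume_regressor <- function(train, n_trees = 10001L, seed = 1L) {
  stopifnot(inherits(train, "labeled_training"))
  .check_trees(n_trees)
  y <- as.numeric(train$labels)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("domain error: biovolume targets must be positive and finite")
  }
  if (length(y) < 2L) stop("domain error: need >= 2 training rows")
  if (length(unique(y)) < 2L) {
    warning("single distinct biovolume target; out-of-bag R^2 is undefined")
  }
  rf <- .fit_ranger(train$matrix$values, log10(y), n_trees, seed)
  r2 <- rf$r.squared
  if (!is.finite(r2)) r2 <- NA_real_
  structure(list(kind = "regressor",
                 traits_used = colnames(train$matrix$values),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 oob_r2 = r2,
                 transform_log = train$matrix$transform_log,
                 rf = rf),
            class = "sfcm_forest")
}

#' @export
print.sfcm_forest <- function(x, ...) {
  if (x$kind == "classifier") {
    cat(sprintf("sfcm_forest classifier: %d trees, %d traits, OOB error %.4f\n",
                x$n_trees, length(x$traits_used), x$oob_error))
  } else {
    cat(sprintf("sfcm_forest regressor: %d trees, %d traits, OOB R2 %.4f (log10)\n",
                x$n_trees, length(x$traits_used), x$oob_r2))
  }
  invisible(x)
}

#' Predict from a fitted SFCM forest
#'
#' @param object An `sfcm_forest`.
#' @param newdata A [trait_matrix()], matrix or data.frame containing at
#'   least every trait in `object$traits_used` (missing traits are an
#'   error).
#' @param ... Unused.
#' @return Classifier: factor of predicted labels. Regressor: biovolumes in
#'   um^3 (back-transformed from log10, strictly positive).
#' @export
predict.sfcm_forest <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "trait_matrix")) newdata$values else as.matrix(newdata)
  missing <- setdiff(object$traits_used, colnames(x))
  if (length(missing)) {
    stop("domain error: record(s) missing required trait(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(x[, object$traits_used, drop = FALSE])
  pred <- predict(object$rf, data = df, num.threads = 1L)$predictions
  if (object$kind == "regressor") 10^pred else pred
}
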