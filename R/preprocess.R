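#' Log10-transform all strictly positive traits
#'
#' Traits whose minimum value is > 0 are replaced by `log10(value)` and
#' recorded in the matrix's `transform_log` set; traits containing zeros or
#' negative values are left untouched. Most pulse-shape traits are strongly
#' right-skewed, which hampers correlation screening and clustering; the
#' decade scale is the cytometry convention. Traits already flagged as
#' transformed are skipped, so the operation is idempotent.
#'
#' @param m A [trait_matrix()].
#' @return The transformed [trait_matrix()].
#' @export
log_transform_eligible <- function(m) {
  stopifnot(inherits(m, "trait_matrix"))
  x <- m$values
  eligible <- setdiff(colnames(x), m$transform_log)
  mins <- apply(x[, eligible, drop = FALSE], 2L, min)
  flag <- eligible[mins > 0]
  x[, flag] <- log10(x[, flag, drop = FALSE])
  trait_matrix(x, m$particle_id, m$sample_id,
               union(m$transform_log, flag))
}

#' Apply a previously recorded log-transform to new data
#'
#' Used when a transform chosen on training data must be replayed on field
#' data. Values <= 0 in a flagged trait (absent from training but possible in
#' the field) are floored to half the smallest positive value of that trait
#' before taking logs, with a warning.
#'
#' @param m A [trait_matrix()] on the original scale.
#' @param transform_log Trait names to transform (names absent from `m` are
#'   ignored).
#' @return Transformed [trait_matrix()].
#' @export
apply_trait_transform <- function(m, transform_log) {
  stopifnot(inherits(m, "trait_matrix"))
  x <- m$values
  todo <- setdiff(intersect(transform_log, colnames(x)), m$transform_log)
  n_floored <- 0L
  for (tr in todo) {
    v <- x[, tr]
    bad <- v <= 0
    if (any(bad)) {
      pos <- v[!bad]
      if (!length(pos)) stop("trait '", tr, "' has no positive values; ",
                             "cannot apply log transform")
      v[bad] <- 0.5 * min(pos)
      n_floored <- n_floored + sum(bad)
    }
    x[, tr] <- log10(v)
  }
  if (n_floored > 0L) {
    warning(sprintf("floored %d non-positive values before log transform",
                    n_floored))
  }
  trait_matrix(x, m$particle_id, m$sample_id, union(m$transform_log, todo))
}

#' Invert the recorded log-transform of a trait matrix
#' @param m A [trait_matrix()].
#' @return The matrix with flagged traits back-transformed (10^value).
#' @export
invert_trait_transform <- function(m) {
  stopifnot(inherits(m, "trait_matrix"))
  x <- m$values
  flag <- intersect(m$transform_log, colnames(x))
  x[, flag] <- 10^x[, flag, drop = FALSE]
  trait_matrix(x, m$particle_id, m$sample_id, character())
}

#' Prune highly correlated traits
#'
#' Walks the trait columns in input order; whenever a later column has
#' absolute Pearson correlation above `threshold` with an earlier kept
#' column, the later column is dropped. The surviving matrix contains no
#' pair with |r| > threshold. Which member of a correlated pair is dropped
#' is a free choice; dropping the later column keeps the rule deterministic
#' and order-documented. Constant (zero-variance) columns have their
#' correlations defined as 0 and are retained, with a warning.
#'
#' @param m A [trait_matrix()] with >= 2 rows.
#' @param threshold Absolute correlation threshold in (0, 1), default 0.8.
#' @return List with `matrix` (the pruned [trait_matrix()]) and `removed`
#'   (trait names in removal order, for the audit log).
#' @export
prune_correlated <- function(m, threshold = 0.8) {
  stopifnot(inherits(m, "trait_matrix"))
  if (nrow(m$values) < 2L) stop("need >= 2 rows to estimate correlations")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  x <- m$values
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning("constant trait(s) retained (correlation undefined, treated as 0): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  }
  C <- suppressWarnings(cor(x))
  C[!is.finite(C)] <- 0
  p <- ncol(x)
  keep <- logical(p)
  removed <- character(0)
  for (j in seq_len(p)) {
    ik <- which(keep[seq_len(j - 1L)])
    if (length(ik) && any(abs(C[ik, j]) > threshold)) {
      removed <- c(removed, colnames(x)[j])
    } else {
      keep[j] <- TRUE
    }
  }
  list(matrix = tm_select(m, colnames(x)[keep]), removed = removed)
}

#' Pool an equal-per-sample random subset of particles
#'
#' Draws `floor(target_total / n_samples)` particles uniformly without
#' replacement from every sample (all particles, with a warning, when a
#' sample is smaller than its share). Clustering the full multi-sample
#' series at once is infeasible and clustering samples separately would
#' yield incomparable clusters; an equal-per-sample pool keeps every sample
#' represented while staying tractable.
#'
#' @param samples An [sfcm_samples()] object.
#' @param target_total Total pooled size aimed for (>= number of samples).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [trait_matrix()] of the pooled particles with per-row sample
#'   provenance.
#' @export
pooled_subset <- function(samples, target_total = 100000L, seed = 1L) {
  stopifnot(inherits(samples, "sfcm_samples"))
  ids <- sample_ids(samples)
  n_samples <- length(ids)
  if (n_samples < 1L) stop("no samples to subset")
  if (target_total < n_samples) {
    stop("configuration error: target_total (", target_total,
         ") is smaller than the number of samples (", n_samples, ")")
  }
  per <- floor(target_total / n_samples)
  parts <- samples$particles
  set.seed(as.integer(seed))
  idx_by_sample <- split(seq_len(nrow(parts)), factor(parts$sample_id, levels = ids))
  short <- 0L
  take <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    rows <- idx_by_sample[[i]]
    if (length(rows) <= per) {
      take[[i]] <- rows
      if (length(rows) < per) short <- short + 1L
    } else {
      take[[i]] <- sort(sample(rows, per))
    }
  }
  if (short > 0L) {
    warning(short, " sample(s) smaller than the per-sample share of ", per,
            "; all their particles were taken")
  }
  rows <- unlist(take, use.names = FALSE)
  sub <- parts[rows, , drop = FALSE]
  traits <- particle_trait_names(parts)
  trait_matrix(as.matrix(sub[, traits, drop = FALSE]),
               particle_id = sub$particle_id, sample_id = sub$sample_id)
}
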