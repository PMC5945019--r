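# Density-peak merging clusterer: overcluster with k-means, place a smoothed
# Gaussian component on every k-means cluster, hill-climb each component mean
# to its density peak, and merge components that share a peak or whose
# connecting segment shows no density dip.

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  rn <- rowSums(X * X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  c1 <- X[idx[1L], ]
  d2 <- pmax(rn - 2 * drop(X %*% c1) + sum(c1 * c1), 0)
  for (j in 2L:k) {
    tot <- sum(d2)
    if (!is.finite(tot) || tot <= 0) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    cj <- X[idx[j], ]
    d2 <- pmin(d2, pmax(rn - 2 * drop(X %*% cj) + sum(cj * cj), 0))
  }
  X[idx, , drop = FALSE]
}

# best-of-n_restarts Lloyd k-means with k-means++ seeding
.overcluster <- function(X, k0, n_restarts, seed) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(X, k0)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart")
  best
}

# union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Density-peak clustering of a trait matrix
#'
#' Implements a k-means/density-merging clusterer in the spirit of the
#' flowPeaks algorithm: (1) each dimension is standardized to zero mean and
#' unit SD; (2) the data are overclustered into `k0` components by k-means
#' (k-means++ seeding, `n_restarts` restarts, best inertia kept); (3) each
#' component receives a smoothed covariance `h * S_k + h0 * Lambda *
#' k0^(-2/d)` where `S_k` is the component covariance and `Lambda` the
#' diagonal of the overall data covariance; (4) the density is the resulting
#' Gaussian mixture; (5) every component mean is hill-climbed to its local
#' density maximum by gradient ascent with backtracking (stopping when the
#' accepted step falls below `tol/100` in standardized units); (6) two
#' components merge when their peaks lie within Euclidean distance `tol` of
#' each other, or when the minimum density along their connecting segment
#' (sampled at 20 points) is at least `(1 - tol)` times the lower of the two
#' peak densities (no dip between them); (7) merged clusters are relabeled
#' by descending size, so cluster 1 is always the largest.
#'
#' The exact smoothing, climb and merge rules of the original flowPeaks
#' package are not reproduced bit-for-bit; this reconstruction is behavioral
#' (well-separated blobs are recovered exactly, cluster count decreases as
#' `h` grows) and is isolated behind this interface so a different merging
#' engine can be swapped in.
#'
#' @param m A [trait_matrix()] restricted to the selected traits (>= 2
#'   columns, no missing values, at least `k0` rows).
#' @param params A [cluster_params()] list (tol, h0, h, k0, seed, ...).
#' @return An object of class `flowpeaks_model` with components, smoothed
#'   covariances, peaks, `merge_map`, per-point `labels` and
#'   `cluster_sizes`.
#' @export
flowpeaks_cluster <- function(m, params = cluster_params()) {
  stopifnot(inherits(m, "trait_matrix"))
  X0 <- m$values
  n <- nrow(X0); d <- ncol(X0)
  if (d < 2L) stop("need >= 2 trait columns")
  k0 <- params$k0
  if (is.null(k0)) k0 <- min(200L, max(8L, floor(sqrt(n) / 2)))
  if (k0 > n) stop("domain error: k0 (", k0, ") exceeds row count (", n, ")")

  mu <- colMeans(X0)
  sigma <- apply(X0, 2L, sd)
  if (any(sigma == 0)) {
    warning("constant column(s) left unscaled: ",
            paste(colnames(X0)[sigma == 0], collapse = ", "))
    sigma[sigma == 0] <- 1
  }
  X <- sweep(sweep(X0, 2L, mu), 2L, sigma, "/")

  km <- .overcluster(X, k0, params$n_restarts, params$seed)
  sizes <- km$size
  nonempty <- which(sizes > 0L)
  centers <- km$centers[nonempty, , drop = FALSE]
  comp_of_point <- match(km$cluster, nonempty)
  k <- length(nonempty)
  sizes <- sizes[nonempty]
  w <- sizes / n

  Lambda <- apply(X, 2L, var) * k0^(-2 / d)
  base <- diag(params$h0 * Lambda, d)
  idx_by_comp <- split(seq_len(n), comp_of_point)
  covs <- vector("list", k)
  ics <- vector("list", k)
  logdets <- numeric(k)
  reg_needed <- FALSE
  for (j in seq_len(k)) {
    rows <- idx_by_comp[[j]]
    Sk <- if (length(rows) >= 2L) cov(X[rows, , drop = FALSE]) else matrix(0, d, d)
    Sm <- params$h * Sk + base
    ch <- tryCatch(chol(Sm), error = function(e) NULL)
    if (is.null(ch)) {
      reg_needed <- TRUE
      Sm <- Sm + diag(1e-6 * apply(X, 2L, var), d)
      ch <- chol(Sm)
    }
    covs[[j]] <- Sm
    ics[[j]] <- chol2inv(ch)
    logdets[j] <- 2 * sum(log(diag(ch)))
  }
  if (reg_needed) warning("singular smoothed covariance(s) regularized")

  IC <- array(unlist(ics), dim = c(d, d, k))
  logw <- log(w)
  ldv <- logdets

  # hill-climb every component mean to its density peak
  stop_tol <- params$tol * 1e-2
  peaks <- matrix(NA_real_, k, d)
  for (j in seq_len(k)) {
    x <- centers[j, ]
    t_step <- 0.25
    for (it in seq_len(params$max_climb_iters)) {
      g <- cpp_gmm_logdens_grad(x, centers, logw, IC, ldv)
      ng <- sqrt(sum(g$grad^2))
      if (!is.finite(ng) || ng < 1e-12) break
      dir <- as.numeric(g$grad) / ng
      accepted <- FALSE
      while (t_step >= stop_tol) {
        x2 <- x + t_step * dir
        l2 <- cpp_gmm_logdens(matrix(x2, 1L), centers, logw, IC, ldv)[1L]
        if (l2 > g$logf) { x <- x2; accepted <- TRUE; break }
        t_step <- t_step / 2
      }
      if (!accepted) break
      t_step <- min(t_step * 2, 0.25)
    }
    peaks[j, ] <- x
  }

  # merge: coincident peaks OR no density dip along the connecting segment
  peak_logf <- as.numeric(cpp_gmm_logdens(peaks, centers, logw, IC, ldv))
  parent <- seq_len(k)
  if (k > 1L) {
    pr <- t(combn(k, 2L))
    pa <- pr[, 1L]; pb <- pr[, 2L]
    dif <- peaks[pa, , drop = FALSE] - peaks[pb, , drop = FALSE]
    dist_ab <- sqrt(rowSums(dif * dif))
    ts <- seq(0, 1, length.out = 20L)
    seg <- matrix(NA_real_, length(pa) * length(ts), d)
    for (i in seq_along(ts)) {
      seg[seq_along(pa) + (i - 1L) * length(pa), ] <-
        peaks[pa, , drop = FALSE] * (1 - ts[i]) + peaks[pb, , drop = FALSE] * ts[i]
    }
    seg_logf <- matrix(as.numeric(cpp_gmm_logdens(seg, centers, logw, IC, ldv)),
                       nrow = length(pa))
    min_seg <- apply(seg_logf, 1L, min)
    no_dip <- min_seg >= log(1 - params$tol) + pmin(peak_logf[pa], peak_logf[pb])
    do_merge <- (dist_ab <= params$tol) | no_dip
    for (i in which(do_merge)) {
      ra <- .uf_find(parent, pa[i]); rb <- .uf_find(parent, pb[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), function(i) .uf_find(parent, i), integer(1))
  groups <- unique(root)
  group_sizes <- vapply(groups, function(g) sum(sizes[root == g]), numeric(1))
  ord <- order(-group_sizes)
  final_of_root <- setNames(seq_along(groups), groups[ord])
  merge_map <- unname(final_of_root[as.character(root)])
  labels <- merge_map[comp_of_point]
  cluster_sizes <- as.integer(table(factor(labels, levels = seq_along(groups))))

  structure(list(traits = colnames(X0),
                 standardization = list(mean = mu, sd = sigma),
                 k0 = k0, params = params,
                 weights = w, means = centers, covariances = covs,
                 smoothed_inverses = ics, logdets = logdets,
                 peaks = peaks, peak_logdensity = peak_logf,
                 merge_map = merge_map,
                 n_clusters = length(groups),
                 labels = labels,
                 cluster_sizes = cluster_sizes,
                 transform_log = m$transform_log),
            class = "flowpeaks_model")
}

#' @export
print.flowpeaks_model <- function(x, ...) {
  cat(sprintf("flowpeaks_model: %d clusters from %d components on %d traits\n",
              x$n_clusters, length(x$weights), length(x$traits)))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Assign new points to the clusters of a fitted model
#'
#' Each row is assigned to the final cluster of its highest-responsibility
#' mixture component. Intended for diagnostics and tests; full-dataset
#' assignment in the pipeline is done by a random-forest classifier.
#'
#' @param model A `flowpeaks_model`.
#' @param m A [trait_matrix()] with the model's training columns.
#' @return Integer vector of cluster ids.
#' @export
assign_to_clusters <- function(model, m) {
  stopifnot(inherits(model, "flowpeaks_model"), inherits(m, "trait_matrix"))
  if (!identical(colnames(m$values), model$traits)) {
    stop("domain error: columns do not match the model's training columns")
  }
  X <- sweep(sweep(m$values, 2L, model$standardization$mean), 2L,
             model$standardization$sd, "/")
  k <- length(model$weights)
  n <- nrow(X)
  best <- rep(-Inf, n)
  comp <- integer(n)
  logw <- log(model$weights)
  for (j in seq_len(k)) {
    Y <- sweep(X, 2L, model$means[j, ])
    quad <- rowSums((Y %*% model$smoothed_inverses[[j]]) * Y)
    lj <- logw[j] - 0.5 * model$logdets[j] - 0.5 * quad
    upd <- lj > best
    best[upd] <- lj[upd]
    comp[upd] <- j
  }
  model$merge_map[comp]
}

#' Per-cluster centroid summary
#'
#' @param model A `flowpeaks_model`.
#' @param m A [trait_matrix()] of the training rows (any superset of traits;
#'   row order must match the model's labels). Cluster centres are the
#'   per-trait medians of member rows, reported on the matrix scale and
#'   back-transformed to the natural scale for log10-flagged traits.
#' @return List of class `cluster_summary` with `fractions`, `sizes`,
#'   `centroids` (matrix, matrix scale) and `centroids_natural`.
#' @export
cluster_summary <- function(model, m) {
  stopifnot(inherits(model, "flowpeaks_model"), inherits(m, "trait_matrix"))
  labels <- model$labels
  if (nrow(m$values) != length(labels)) {
    stop("row count must match the model's training labels")
  }
  cl <- sort(unique(labels))
  cent <- t(vapply(cl, function(g) {
    apply(m$values[labels == g, , drop = FALSE], 2L, median)
  }, numeric(ncol(m$values))))
  rownames(cent) <- cl
  nat <- cent
  flag <- intersect(m$transform_log, colnames(nat))
  nat[, flag] <- 10^nat[, flag, drop = FALSE]
  sizes <- as.integer(table(factor(labels, levels = cl)))
  structure(list(fractions = setNames(sizes / length(labels), cl),
                 sizes = setNames(sizes, cl),
                 centroids = cent,
                 centroids_natural = nat,
                 transform_log = m$transform_log),
            class = "cluster_summary")
}
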