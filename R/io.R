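#' Trait matrix container
#'
#' Rectangular numeric container of particle trait values used by the
#' selection, clustering and forest stages. Carries row provenance
#' (particle and sample identifiers) and the set of traits that have been
#' log10-transformed.
#'
#' @param x Numeric matrix (or data.frame of numerics), one row per particle,
#'   named columns (unique trait names), finite values, no missing entries.
#' @param particle_id,sample_id Optional per-row identifiers.
#' @param transform_log Character vector of trait names already on the log10
#'   scale.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(x, particle_id = NULL, sample_id = NULL,
                         transform_log = character()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("trait matrix must have column names")
  if (anyDuplicated(colnames(x))) stop("trait names must be unique")
  if (!all(is.finite(x))) stop("trait values must be finite (no NA/NaN/Inf)")
  if (is.null(particle_id)) {
    particle_id <- rownames(x)
    if (is.null(particle_id)) particle_id <- as.character(seq_len(nrow(x)))
  }
  if (is.null(sample_id)) sample_id <- rep(NA_character_, nrow(x))
  stopifnot(length(particle_id) == nrow(x), length(sample_id) == nrow(x))
  structure(list(values = x,
                 particle_id = as.character(particle_id),
                 sample_id = as.character(sample_id),
                 transform_log = transform_log),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d particles x %d traits (%d log10-transformed)\n",
              nrow(x$values), ncol(x$values), length(x$transform_log)))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

# restrict a trait_matrix to a set of columns, preserving metadata
tm_select <- function(m, traits) {
  missing <- setdiff(traits, colnames(m$values))
  if (length(missing)) {
    stop("trait(s) not present in matrix: ", paste(missing, collapse = ", "))
  }
  trait_matrix(m$values[, traits, drop = FALSE], m$particle_id, m$sample_id,
               intersect(m$transform_log, traits))
}

#' Particle samples container
#'
#' Couples a particle trait table (one row per particle, `sample_id` and
#' `particle_id` columns plus numeric trait columns) with per-sample metadata
#' (`sample_id`, `depth` in m, `timestamp`, `volume_analyzed` in uL,
#' `particle_concentration` in particles per uL).
#'
#' @param particles data.frame of particles.
#' @param meta Optional data.frame of sample metadata.
#' @param check_concentration Verify that `particle_concentration` matches
#'   count / volume when both are available (disable for subsetted particle
#'   tables that keep the original metadata).
#' @return An object of class `sfcm_samples`.
#' @export
sfcm_samples <- function(particles, meta = NULL, check_concentration = TRUE) {
  req <- c("sample_id", "particle_id")
  if (!all(req %in% names(particles))) {
    stop("particle table must contain columns: ", paste(req, collapse = ", "))
  }
  particles$sample_id <- as.character(particles$sample_id)
  particles$particle_id <- as.character(particles$particle_id)
  dup <- duplicated(paste(particles$sample_id, particles$particle_id, sep = "\r"))
  if (any(dup)) {
    stop("integrity error: duplicate particle_id within a sample (e.g. ",
         particles$particle_id[which(dup)[1L]], ")")
  }
  if (nrow(particles) == 0L) warning("particle table contains no particles")
  if (!is.null(meta)) {
    if (!"sample_id" %in% names(meta)) stop("metadata must contain sample_id")
    meta$sample_id <- as.character(meta$sample_id)
    if ("volume_analyzed" %in% names(meta) &&
        any(meta$volume_analyzed <= 0, na.rm = TRUE)) {
      stop("volume_analyzed must be > 0")
    }
    if ("particle_concentration" %in% names(meta)) {
      if (any(meta$particle_concentration < 0, na.rm = TRUE)) {
        stop("particle_concentration must be >= 0")
      }
      if (check_concentration && "volume_analyzed" %in% names(meta)) {
        cnt <- table(factor(particles$sample_id, levels = meta$sample_id))
        implied <- as.numeric(cnt) / meta$volume_analyzed
        have <- is.finite(meta$particle_concentration) &
          meta$particle_concentration > 0 & as.numeric(cnt) > 0
        bad <- have & abs(implied - meta$particle_concentration) /
          meta$particle_concentration >= 1e-6
        if (any(bad)) {
          stop("particle_concentration inconsistent with count/volume for ",
               "sample(s): ", paste(meta$sample_id[bad], collapse = ", "))
        }
      }
    }
  }
  structure(list(particles = particles, meta = meta), class = "sfcm_samples")
}

#' @export
print.sfcm_samples <- function(x, ...) {
  ns <- length(unique(x$particles$sample_id))
  cat(sprintf("sfcm_samples: %d particles in %d samples, %d trait columns\n",
              nrow(x$particles), ns,
              ncol(x$particles) - 2L))
  invisible(x)
}

#' Sample identifiers of an sfcm_samples object, in order of appearance
#' @param samples An [sfcm_samples()] object.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(samples) unique(samples$particles$sample_id)

# trait column names of the particle table
particle_trait_names <- function(particles) {
  setdiff(names(particles), c("sample_id", "particle_id"))
}

#' Read a particle trait table (with optional side-car metadata)
#'
#' The canonical on-disk format is CSV with a header row of dotted trait
#' names exactly as the instrument prints them (`"FL.Red.Range"`), one row
#' per particle, plus `sample_id` and `particle_id` columns. Sample metadata
#' lives in a side-car CSV keyed by `sample_id`.
#'
#' @param path Path to the particle CSV.
#' @param meta_path Optional path to the metadata CSV.
#' @return An [sfcm_samples()] object; row order is preserved.
#' @export
read_particles <- function(path, meta_path = NULL) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 1L) stop("format error: file has no columns")
  num_like <- grepl("^-?[0-9.eE+]+$", names(raw))
  if (any(num_like)) {
    stop("format error: missing header row (numeric-looking column names: ",
         paste(names(raw)[num_like], collapse = ", "), ")")
  }
  if (!all(c("sample_id", "particle_id") %in% names(raw))) {
    stop("format error: particle CSV must contain sample_id and particle_id")
  }
  traits <- setdiff(names(raw), c("sample_id", "particle_id"))
  for (tr in traits) {
    vals <- suppressWarnings(as.numeric(raw[[tr]]))
    bad <- which(is.na(vals) & !is.na(raw[[tr]]) & nzchar(raw[[tr]]))
    if (length(bad) || anyNA(vals)) {
      row <- if (length(bad)) bad[1L] else which(is.na(vals))[1L]
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   tr, row))
    }
    raw[[tr]] <- vals
  }
  if (nrow(raw) == 0L) warning("particle file contains a header but no rows")
  meta <- if (!is.null(meta_path)) read.csv(meta_path, check.names = FALSE)
  sfcm_samples(raw, meta)
}

#' Write a particle trait table (and optional metadata side-car)
#'
#' @param samples An [sfcm_samples()] object.
#' @param path Output CSV path for the particle table.
#' @param meta_path Optional output path for the metadata table.
#' @return `path`, invisibly.
#' @export
write_particles <- function(samples, path, meta_path = NULL) {
  write.csv(samples$particles, path, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(samples$meta)) {
    write.csv(samples$meta, meta_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write community estimates to CSV
#'
#' One row per sample x group plus a `"total"` pseudo-group row per sample;
#' columns `sample_id`, `group`, `cell_density_per_mL`,
#' `biovolume_um3_per_mL`. Round-trips losslessly through
#' [read_estimates()].
#'
#' @param estimates data.frame as returned by [community_estimates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  req <- c("sample_id", "group", "cell_density_per_mL", "biovolume_um3_per_mL")
  if (nrow(estimates) == 0L) stop("estimates must be non-empty")
  if (!all(req %in% names(estimates))) {
    stop("estimates must contain columns: ", paste(req, collapse = ", "))
  }
  ok <- tryCatch({
    write.csv(format(estimates[, req], digits = 17, scientific = FALSE,
                     trim = TRUE),
              path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("I/O error writing estimates to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read community estimates from CSV
#' @param path CSV path written by [write_estimates()].
#' @return data.frame of estimates.
#' @export
read_estimates <- function(path) {
  est <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  est$cell_density_per_mL <- as.numeric(est$cell_density_per_mL)
  est$biovolume_um3_per_mL <- as.numeric(est$biovolume_um3_per_mL)
  est
}

#' Density-peak clustering tuning parameters
#'
#' @param tol Merge tolerance in standardized units; also scales the density
#'   dip test (default 0.25).
#' @param h0 Baseline covariance smoothing weight (default 0.05).
#' @param h Within-component covariance smoothing multiplier (default 2).
#' @param k0 Initial k-means component count; default
#'   `max(8, floor(sqrt(n)/2))` capped at 200 (resolved at fit time when
#'   `NULL`).
#' @param max_climb_iters Hill-climb iteration cap per component.
#' @param n_restarts k-means restarts (k-means++ seeding, best inertia kept).
#' @param seed Integer seed for k-means initialization.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(tol = 0.25, h0 = 0.05, h = 2, k0 = NULL,
                           max_climb_iters = 100L, n_restarts = 10L,
                           seed = 1L) {
  stopifnot(tol > 0, tol < 1, h0 >= 0, h > 0, max_climb_iters >= 1)
  structure(list(tol = tol, h0 = h0, h = h, k0 = k0,
                 max_climb_iters = as.integer(max_climb_iters),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the cleaning/grouping/quantification
#' pipeline. Defaults follow the protocol the package implements: pairs of
#' traits with |Pearson r| > 0.8 are pruned, the top 10 (cleaning) and top 8
#' (grouping) most important traits are clustered, pooled subsets hold about
#' 100,000 particles, and the three forests use 10,001 / 1,001 / 10,001
#' trees (odd counts avoid voting ties).
#'
#' @param correlation_threshold Absolute Pearson correlation above which the
#'   later member of a trait pair is dropped (default 0.8).
#' @param n_top_clean,n_top_group Number of top-ranked traits used for the
#'   cleaning and grouping cluster passes (defaults 10 and 8).
#' @param subset_size Target pooled subset size (default 100000).
#' @param trees_importance,trees_classify,trees_biovolume Forest sizes
#'   (odd, >= 3).
#' @param cluster_params A [cluster_params()] list.
#' @param min_group_fraction Minimum cluster fraction for functional-group
#'   assignment (default 0.05).
#' @param live_margin_log10 Margin in log10 FL.Red.Range above the dimmest
#'   reference cluster beyond which a cluster is flagged as live cells
#'   (default 1).
#' @param live_reference_min_fraction Minimum cluster fraction eligible to
#'   serve as the dim reference for live flagging (default 0.01).
#' @param cyano_ratio_ceiling Red1Red2.ratio below which the lowest-ratio
#'   cluster is accepted as cyanobacteria (default 1).
#' @param detection_limit_substitution_factor Factor applied to the detection
#'   limit when substituting zero microscopy counts (default 0.5).
#' @param prominence_fraction Peak prominence fraction for cell counting.
#' @param ratio_cap Red1Red2.ratio value substituted when Red2 area is zero.
#' @param live_clusters_override Optional explicit vector of cluster ids to
#'   flag as live, bypassing the margin rule.
#' @param random_seed Integer master seed.
#' @return List of class `sfcm_config`.
#' @export
sfcm_config <- function(correlation_threshold = 0.8,
                        n_top_clean = 10L,
                        n_top_group = 8L,
                        subset_size = 100000L,
                        trees_importance = 10001L,
                        trees_classify = 1001L,
                        trees_biovolume = 10001L,
                        cluster_params = sfcmflow::cluster_params(),
                        min_group_fraction = 0.05,
                        live_margin_log10 = 1.0,
                        live_reference_min_fraction = 0.01,
                        cyano_ratio_ceiling = 1.0,
                        detection_limit_substitution_factor = 0.5,
                        prominence_fraction = 0.25,
                        ratio_cap = 1e6,
                        live_clusters_override = NULL,
                        random_seed = 1L) {
  if (correlation_threshold <= 0 || correlation_threshold >= 1) {
    stop("correlation_threshold must be in (0, 1)")
  }
  if (min_group_fraction <= 0 || min_group_fraction >= 1) {
    stop("min_group_fraction must be in (0, 1)")
  }
  trees <- c(trees_importance, trees_classify, trees_biovolume)
  if (any(trees < 3L) || any(trees %% 2L == 0L)) {
    stop("all tree counts must be odd and >= 3")
  }
  structure(list(correlation_threshold = correlation_threshold,
                 n_top_clean = as.integer(n_top_clean),
                 n_top_group = as.integer(n_top_group),
                 subset_size = as.integer(subset_size),
                 trees_importance = as.integer(trees_importance),
                 trees_classify = as.integer(trees_classify),
                 trees_biovolume = as.integer(trees_biovolume),
                 cluster_params = cluster_params,
                 min_group_fraction = min_group_fraction,
                 live_margin_log10 = live_margin_log10,
                 live_reference_min_fraction = live_reference_min_fraction,
                 cyano_ratio_ceiling = cyano_ratio_ceiling,
                 detection_limit_substitution_factor =
                   detection_limit_substitution_factor,
                 prominence_fraction = prominence_fraction,
                 ratio_cap = ratio_cap,
                 live_clusters_override = live_clusters_override,
                 random_seed = as.integer(random_seed)),
            class = "sfcm_config")
}
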