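# Per-particle biovolume prediction and aggregation of per-sample community
# and functional-group cell densities (cells/mL) and biovolumes (um^3/mL).

#' Predict per-particle biovolumes in cleaned field data
#'
#' Applies the biovolume regression forest to every retained particle,
#' using all its measured traits. Predictions are back-transformed from the
#' log10 scale and strictly positive; as forest means, they lie within the
#' range of the training biovolumes.
#'
#' @param model An `sfcm_forest` regressor from
#'   [fit_biovolume_regressor()].
#' @param samples An [sfcm_samples()] object of retained (cleaned)
#'   particles.
#' @return Numeric vector of biovolumes (um^3), named by particle id.
#' @export
predict_biovolumes <- function(model, samples) {
  stopifnot(inherits(model, "sfcm_forest"))
  if (model$kind != "regressor") stop("model must be a biovolume regressor")
  parts <- samples$particles
  traits <- particle_trait_names(parts)
  missing <- setdiff(model$traits_used, traits)
  if (length(missing)) {
    stop("domain error: particles lack required trait(s): ",
         paste(missing, collapse = ", "))
  }
  x <- as.matrix(parts[, model$traits_used, drop = FALSE])
  setNames(predict(model, x), parts$particle_id)
}

#' Whole-community cell density of one sample
#'
#' Cell density is the instrument's particle concentration times the
#' proportion of particles classified as live cells:
#' `particle_concentration` (particles/uL) x 1000 x live fraction, in
#' cells/mL.
#'
#' @param particle_concentration Particles per uL.
#' @param live_fraction Fraction of particles that are live cells, in
#'   \[0, 1\].
#' @param n_particles Optional particle count; a count of zero yields
#'   density 0 with a warning.
#' @return Cell density in cells/mL.
#' @export
community_density <- function(particle_concentration, live_fraction,
                              n_particles = NULL) {
  stopifnot(live_fraction >= 0, live_fraction <= 1,
            particle_concentration >= 0)
  if (!is.null(n_particles) && n_particles == 0) {
    warning("zero particles measured; density is 0")
    return(0)
  }
  particle_concentration * 1000 * live_fraction
}

#' Functional-group cell densities of one sample
#'
#' Each group's density is the whole-community density times the fraction
#' of live cells belonging to the group.
#'
#' @param total Whole-community cell density (cells/mL).
#' @param fractions Named numeric vector of group fractions of the live
#'   cells, each in \[0, 1\], summing to at most 1 (unassigned slack).
#' @return Named vector of group densities (cells/mL).
#' @export
group_density <- function(total, fractions) {
  if (length(fractions) == 0L) return(setNames(numeric(0), character(0)))
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  if (sum(fractions) > 1 + 1e-9) {
    stop("integrity error: group fractions sum to ", sum(fractions), " > 1")
  }
  total * fractions
}

#' Total and per-group biovolume of one sample
#'
#' Total biovolume is the community cell density times the mean biovolume of
#' all retained cells; each group's biovolume is its cell density times the
#' mean biovolume of the cells belonging to that group. All biovolumes in
#' um^3/mL.
#'
#' @param total_density Whole-community density (cells/mL).
#' @param group_densities Named vector of group densities (cells/mL).
#' @param biovolumes Per-particle biovolume predictions (um^3) for the
#'   sample's retained particles.
#' @param groups Group label per particle (same length as `biovolumes`).
#' @return List with `total_biovolume`, `group_biovolume` (named vector),
#'   `mean_cell_biovolume`.
#' @export
total_and_group_biovolume <- function(total_density, group_densities,
                                      biovolumes, groups) {
  stopifnot(length(biovolumes) == length(groups))
  if (total_density > 0 && length(biovolumes) == 0L) {
    stop("integrity error: positive density with no particles")
  }
  mean_bv <- if (length(biovolumes)) mean(biovolumes) else 0
  gb <- setNames(numeric(length(group_densities)), names(group_densities))
  for (g in names(group_densities)) {
    sel <- groups == g
    if (group_densities[[g]] > 0 && !any(sel)) {
      stop("integrity error: group '", g, "' has density > 0 but no particles")
    }
    gb[[g]] <- group_densities[[g]] * (if (any(sel)) mean(biovolumes[sel]) else 0)
  }
  list(total_biovolume = total_density * mean_bv,
       group_biovolume = gb,
       mean_cell_biovolume = mean_bv)
}

#' Assemble per-sample community estimates
#'
#' Combines the cleaning result (live fractions), the grouping result
#' (per-particle functional groups) and the biovolume predictions into the
#' canonical long estimates table: one row per sample x group, plus
#' `"total"` (whole community) and, where present, `"unassigned"` rows.
#'
#' @param samples The [sfcm_samples()] field series with metadata providing
#'   `particle_concentration`.
#' @param cleaning An `sfcm_cleaning` from [run_cleaning()].
#' @param grouping An `sfcm_grouping` from [run_grouping()].
#' @param biovolume_model Optional `sfcm_forest` regressor; when `NULL`,
#'   biovolume columns are `NA`.
#' @return data.frame with `sample_id`, `group`, `cell_density_per_mL`,
#'   `biovolume_um3_per_mL`.
#' @export
community_estimates <- function(samples, cleaning, grouping,
                                biovolume_model = NULL) {
  meta <- samples$meta
  if (is.null(meta) || !"particle_concentration" %in% names(meta)) {
    stop("sample metadata with particle_concentration is required")
  }
  gp <- grouping$particles
  bv <- NULL
  if (!is.null(biovolume_model)) {
    keep <- cleaning$particles$retained
    cleaned <- sfcm_samples(samples$particles[keep, , drop = FALSE],
                            samples$meta, check_concentration = FALSE)
    bv <- predict_biovolumes(biovolume_model, cleaned)
    bv <- bv[match(gp$particle_id, names(bv))]
  }
  rows <- list()
  for (i in seq_len(nrow(cleaning$live_fraction))) {
    sid <- cleaning$live_fraction$sample_id[i]
    conc <- meta$particle_concentration[match(sid, meta$sample_id)]
    lf <- cleaning$live_fraction$live_fraction[i]
    np <- cleaning$live_fraction$n_particles[i]
    total <- suppressWarnings(community_density(conc, lf, np))
    sel <- gp$sample_id == sid
    n_ret <- sum(sel)
    grp <- gp$group[sel]
    fr <- if (n_ret > 0) table(grp) / n_ret else table(character(0))
    fractions <- setNames(as.numeric(fr), names(fr))
    gd <- group_density(total, fractions)
    if (!is.null(bv)) {
      bvs <- bv[sel]
      agg <- total_and_group_biovolume(total, gd, bvs, grp)
      total_bv <- agg$total_biovolume
      group_bv <- agg$group_biovolume
    } else {
      total_bv <- NA_real_
      group_bv <- setNames(rep(NA_real_, length(gd)), names(gd))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid,
      group = c("total", names(gd)),
      cell_density_per_mL = c(total, unname(gd)),
      biovolume_um3_per_mL = c(total_bv, unname(group_bv)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Log-log validation of paired abundance estimates
#'
#' Compares two estimates of the same quantity (e.g. SFCM vs microscopy cell
#' density) on the log10 scale: Pearson correlation and an ordinary
#' least-squares regression of `log10(y)` on `log10(x)` with 95% confidence
#' intervals, to be read against the 1:1 line (slope 1, intercept 0). Zeros
#' in `x` are replaced by `substitution_factor` times the detection limit
#' when one is supplied (a count below the detection limit is treated as
#' half the limit). Optionally excludes high-leverage points (hat value
#' greater than 3 times the average leverage 2/n) and refits.
#'
#' @param x Reference estimates (e.g. microscopy), positive; zeros allowed
#'   when `detection_limit` is given.
#' @param y Comparison estimates (e.g. SFCM), positive.
#' @param detection_limit Optional detection limit for zero substitution.
#' @param leverage_exclusion Exclude high-leverage points and refit
#'   (default FALSE).
#' @param substitution_factor Factor of the detection limit substituted for
#'   zeros (default 0.5).
#' @return List of class `loglog_validation`: `r`, `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `n`, `excluded_point_ids`.
#' @export
validate_loglog <- function(x, y, detection_limit = NULL,
                            leverage_exclusion = FALSE,
                            substitution_factor = 0.5) {
  stopifnot(length(x) == length(y))
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  if (any(x == 0)) {
    if (is.null(detection_limit)) {
      stop("zeros in x require a detection_limit for substitution")
    }
    x[x == 0] <- substitution_factor * detection_limit
  }
  if (any(x <= 0) || any(y <= 0)) stop("values must be positive")
  lx <- log10(x); ly <- log10(y)
  excluded <- character(0)
  fit_once <- function(lx, ly) {
    if (length(lx) < 3L) stop("domain error: need >= 3 points")
    lm(ly ~ lx)
  }
  fit <- fit_once(lx, ly)
  if (leverage_exclusion) {
    hv <- hatvalues(fit)
    drop <- hv > 3 * (2 / length(lx))
    if (any(drop)) {
      excluded <- ids[drop]
      lx <- lx[!drop]; ly <- ly[!drop]
      fit <- fit_once(lx, ly)
    }
  }
  ci <- confint(fit, level = 0.95)
  structure(list(r = cor(lx, ly),
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 slope_ci = unname(ci[2L, ]),
                 intercept_ci = unname(ci[1L, ]),
                 n = length(lx),
                 excluded_point_ids = excluded),
            class = "loglog_validation")
}

#' @export
print.loglog_validation <- function(x, ...) {
  cat(sprintf("log-log validation: n = %d, r = %.3f\n", x$n, x$r))
  cat(sprintf("  slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  if (length(x$excluded_point_ids)) {
    cat("  excluded high-leverage points:",
        paste(x$excluded_point_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
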