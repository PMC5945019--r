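#' Construct a single-channel pulse
#'
#' A pulse is the time-resolved intensity series recorded for one optical
#' channel as a particle transits the laser beam. Because the flow speed is
#' constant, the sampling interval maps to a spatial step along the particle.
#'
#' @param channel One of `"FWS"`, `"SWS"`, `"FL.Red"`, `"X2.FL.Red"`,
#'   `"FL.Orange"`, `"FL.Yellow"`.
#' @param values Numeric vector of intensities (mV); finite and non-negative.
#' @param step Spatial sampling interval (um per sample), > 0.
#' @return An object of class `channel_pulse`.
#' @export
channel_pulse <- function(channel, values, step = 0.5) {
  channel <- match.arg(channel, sfcm_channels)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("pulse must contain at least one sample")
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("pulse intensities must be finite and >= 0")
  }
  if (!is.finite(step) || step <= 0) stop("'step' must be > 0")
  structure(list(channel = channel, values = values, step = step),
            class = "channel_pulse")
}

#' Bundle the six channel pulses of one particle
#'
#' @param particle_id Identifier for the particle.
#' @param pulses List of six [channel_pulse()] objects, one per channel. All
#'   channels must share the same length and step.
#' @return An object of class `particle_pulses`.
#' @export
particle_pulses <- function(particle_id, pulses) {
  chn <- vapply(pulses, function(p) p$channel, character(1))
  if (!setequal(chn, sfcm_channels)) {
    stop("pulses must cover all six channels: ",
         paste(setdiff(sfcm_channels, chn), collapse = ", "), " missing")
  }
  pulses <- pulses[match(sfcm_channels, chn)]
  names(pulses) <- sfcm_channels
  len <- vapply(pulses, function(p) length(p$values), integer(1))
  stp <- vapply(pulses, function(p) p$step, numeric(1))
  if (length(unique(len)) != 1L || length(unique(stp)) != 1L) {
    stop("all channels must share the same length and step")
  }
  structure(list(particle_id = particle_id, pulses = pulses),
            class = "particle_pulses")
}

#' Basic pulse-shape statistics
#'
#' The elementary summaries of a pulse. `Total` is the area under the pulse
#' (sum times step, in mV um) and `Length` the recorded transit length
#' (samples times step, in um); the rest are in mV.
#'
#' @param pulse A [channel_pulse()].
#' @return Named list with `Maximum`, `Minimum`, `First`, `Last`, `Total`,
#'   `Average`, `Range`, `Length`.
#' @export
pulse_basic_stats <- function(pulse) {
  v <- pulse$values
  if (length(v) == 0L) stop("empty pulse")
  list(Maximum = max(v), Minimum = min(v), First = v[1L],
       Last = v[length(v)], Total = sum(v) * pulse$step, Average = mean(v),
       Range = max(v) - min(v), Length = length(v) * pulse$step)
}

#' Pulse fill factor
#'
#' Ratio of the pulse area to the area of its bounding rectangle,
#' `Total / (Maximum * Length)`: 1 for a rectangular pulse, 0.5 for a
#' symmetric triangle, 2/pi for a half-sine. A "squareness" descriptor of the
#' pulse shape, dimensionless in \[0, 1\] for non-negative pulses.
#'
#' This is an explicit reconstruction of the instrument parameter of the same
#' name; substitute your own definition if the instrument-exact formula is
#' known.
#'
#' @param pulse A [channel_pulse()].
#' @return Fill factor in \[0, 1\]; 0 (with a warning) for an all-dark pulse.
#' @export
pulse_fill_factor <- function(pulse) {
  s <- pulse_basic_stats(pulse)
  if (s$Maximum <= 0) {
    warning("flat dark pulse: fill factor undefined, returning 0")
    return(0)
  }
  s$Total / (s$Maximum * s$Length)
}

#' Mean absolute pulse gradient
#'
#' Mean of the absolute first differences of the pulse divided by the spatial
#' step (mV per um). Captures how steeply the signal changes along the
#' particle; a reconstruction of the instrument's "Gradient" parameter.
#'
#' @param pulse A [channel_pulse()].
#' @return Gradient in mV/um; 0 for a single-sample pulse.
#' @export
pulse_gradient <- function(pulse) {
  v <- pulse$values
  if (length(v) < 2L) return(0)
  mean(abs(diff(v))) / pulse$step
}

#' Count cells in a pulse by peak prominence
#'
#' Counts local maxima whose topographic prominence is at least
#' `prominence_fraction` times the pulse range. A colony of n cells in single
#' file produces n overlapping bells and therefore n prominent peaks; a
#' single smooth unimodal pulse counts 1 and a flat pulse 0. The prominence
#' threshold rejects sampling noise. Reconstruction of the instrument's
#' "Number of cells" parameter.
#'
#' @param pulse A [channel_pulse()].
#' @param prominence_fraction Fraction of the pulse range a peak's prominence
#'   must reach to be counted (default 0.25).
#' @return Integer peak count >= 0.
#' @export
pulse_peak_count <- function(pulse, prominence_fraction = 0.25) {
  v <- pulse$values
  n <- length(v)
  if (n < 3L) return(0L)
  rng <- max(v) - min(v)
  if (rng <= 0) return(0L)
  thr <- prominence_fraction * rng
  count <- 0L
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        h <- v[i]
        minl <- h
        for (t in seq(i - 1L, 1L)) {
          if (v[t] > h) break
          if (v[t] < minl) minl <- v[t]
        }
        minr <- h
        for (t in seq(j + 1L, n)) {
          if (v[t] > h) break
          if (v[t] < minr) minr <- v[t]
        }
        if (h - max(minl, minr) >= thr) count <- count + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Red1/Red2 fluorescence area ratio
#'
#' Ratio of the 488-nm-stimulated to the 642-nm-stimulated red fluorescence
#' pulse areas. Phycocyanin-rich cyanobacteria fluoresce strongly under the
#' 642 nm laser and therefore show low values; eukaryotes show high values.
#' Areas (Totals) are used rather than maxima because they are more robust to
#' single-sample noise.
#'
#' @param red1 The `FL.Red` [channel_pulse()].
#' @param red2 The `X2.FL.Red` [channel_pulse()].
#' @param cap Value returned (with a warning) when the Red2 area is zero.
#' @return Dimensionless ratio.
#' @export
red1red2_ratio <- function(red1, red2, cap = 1e6) {
  t1 <- sum(red1$values) * red1$step
  t2 <- sum(red2$values) * red2$step
  if (t2 <= 0) {
    warning("Red2 pulse area is zero; returning cap value")
    return(cap)
  }
  t1 / t2
}

#' Derive the scalar trait record of one particle
#'
#' Computes, for each of the six channels, the 11 pulse-shape features
#' (`Maximum`, `Minimum`, `First`, `Last`, `Total`, `Average`, `Range`,
#' `Length`, `Fill.factor`, `Gradient`, `Number.of.cells`) plus the
#' `Red1Red2.ratio`, yielding the 67-trait vector used throughout the
#' pipeline. Trait names follow the instrument's dotted convention
#' (`"FL.Red.Range"`, `"X2.FL.Red.Gradient"`, ...).
#'
#' @param particle A [particle_pulses()] object.
#' @param prominence_fraction Passed to [pulse_peak_count()].
#' @param ratio_cap Passed to [red1red2_ratio()].
#' @return Named numeric vector of 67 traits.
#' @export
featurize_particle <- function(particle, prominence_fraction = 0.25,
                               ratio_cap = 1e6) {
  if (!inherits(particle, "particle_pulses")) {
    stop("'particle' must be a particle_pulses object")
  }
  out <- numeric(0)
  for (ch in sfcm_channels) {
    p <- particle$pulses[[ch]]
    s <- pulse_basic_stats(p)
    feats <- c(unlist(s),
               Fill.factor = if (s$Maximum > 0) s$Total / (s$Maximum * s$Length) else 0,
               Gradient = pulse_gradient(p),
               Number.of.cells = as.numeric(pulse_peak_count(p, prominence_fraction)))
    names(feats) <- paste(ch, sfcm_pulse_features, sep = ".")
    out <- c(out, feats)
  }
  t2 <- sum(particle$pulses[["X2.FL.Red"]]$values) * particle$pulses[["X2.FL.Red"]]$step
  t1 <- sum(particle$pulses[["FL.Red"]]$values) * particle$pulses[["FL.Red"]]$step
  out["Red1Red2.ratio"] <- if (t2 > 0) t1 / t2 else ratio_cap
  out
}

#' Featurize a collection of particles
#'
#' @param particles List of [particle_pulses()] objects.
#' @param sample_id Optional sample identifier(s) recycled across particles.
#' @inheritParams featurize_particle
#' @return A data.frame with `particle_id`, `sample_id` and one column per
#'   trait, one row per particle.
#' @export
featurize_pulses <- function(particles, sample_id = NA_character_,
                             prominence_fraction = 0.25, ratio_cap = 1e6) {
  traits <- t(vapply(particles, featurize_particle,
                     numeric(length(sfcm_trait_names())),
                     prominence_fraction = prominence_fraction,
                     ratio_cap = ratio_cap))
  ids <- vapply(particles, function(p) as.character(p$particle_id), character(1))
  cbind(data.frame(particle_id = ids,
                   sample_id = rep_len(as.character(sample_id), length(ids)),
                   stringsAsFactors = FALSE),
        as.data.frame(traits))
}
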