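# Synthetic SFCM data generator.
#
# Each species archetype is a pulse-level generative model: a particle is one
# or more Gaussian intensity bells per optical channel, with per-channel
# amplitudes (mV) and bell widths encoding the group's pigment physiology --
# cyanobacteria fluoresce strongly in the 642-nm-stimulated red channel
# (phycocyanin, low Red1Red2.ratio), cryptophytes carry phycoerythrin (high
# FL.Orange) with narrow chlorophyll bells (low FL.Red.First) and smooth weak
# X2 pulses (low X2.FL.Red.Gradient), green algae have almost no phycocyanin
# (highest Red1Red2.ratio). Bell width scales with the equivalent-sphere cell
# diameter, so transit length grows with biovolume^(1/3); colonies and
# filaments are chains of overlapping bells. The non-cell "noise" component
# (bacteria, detritus, electronic noise pooled) is a low-fluorescence,
# high-variance archetype. A trigger threshold on sideward scatter truncates
# the recorded window, as in the instrument.

#' Construct a species archetype
#'
#' @param name Species name.
#' @param group Functional group: one of `"cyanobacteria"`,
#'   `"chrysophytes"`, `"cryptophytes"`, `"green_algae"`, `"diatom"`, or
#'   `"noise"` for the non-cell component.
#' @param mean_biovolume Mean per-particle biovolume (um^3).
#' @param coloniality `"unicell"` (1 cell), `"colony6"` (6 cells per colony
#'   with rare 5/7 exceptions) or `"filament"` (geometric cell count).
#' @param amplitude Named numeric vector of mean pulse amplitudes (mV) for
#'   the six channels.
#' @param width Named numeric vector of bell-width factors per channel
#'   (default 1); the bell SD is `width * diameter / 4`.
#' @param within_species_cv Coefficient of variation of the per-particle
#'   biovolume jitter (default 0.15).
#' @param elongation Cell length-to-diameter stretch (default 1).
#' @return One-row data.frame.
#' @export
species_archetype <- function(name, group, mean_biovolume, coloniality = "unicell",
                              amplitude, width = NULL, within_species_cv = 0.15,
                              elongation = 1) {
  stopifnot(mean_biovolume > 0)
  group <- match.arg(group, c("cyanobacteria", "chrysophytes", "cryptophytes",
                              "green_algae", "diatom", "noise"))
  coloniality <- match.arg(coloniality, c("unicell", "colony6", "filament"))
  if (is.null(width)) width <- setNames(rep(1, 6), sfcm_channels)
  stopifnot(all(sfcm_channels %in% names(amplitude)),
            all(sfcm_channels %in% names(width)))
  row <- data.frame(name = name, group = group,
                    mean_biovolume = mean_biovolume,
                    coloniality = coloniality,
                    within_species_cv = within_species_cv,
                    elongation = elongation, stringsAsFactors = FALSE)
  for (ch in sfcm_channels) row[[paste0("amp.", ch)]] <- unname(amplitude[ch])
  for (ch in sfcm_channels) row[[paste0("width.", ch)]] <- unname(width[ch])
  row
}

.amp <- function(FWS, SWS, FL.Red, X2.FL.Red, FL.Orange, FL.Yellow) {
  c(FWS = FWS, SWS = SWS, FL.Red = FL.Red, X2.FL.Red = X2.FL.Red,
    FL.Orange = FL.Orange, FL.Yellow = FL.Yellow)
}

#' Default archetype panel
#'
#' Ten lab-culture species spanning five functional groups, with mean
#' biovolumes from microscopy measurements of the cultures, plus the pooled
#' non-cell `"noise"` component. Channel signatures are chosen so that the
#' group-assignment heuristics (Red1Red2.ratio for cyanobacteria, low
#' X2.FL.Red.Gradient / FL.Red.First for cryptophytes, high ratio for green
#' algae) are recoverable by construction.
#'
#' @return data.frame with one row per archetype.
#' @export
default_archetypes <- function() {
  w1 <- setNames(rep(1, 6), sfcm_channels)
  w_crypto <- w1; w_crypto["FL.Red"] <- 0.5; w_crypto["X2.FL.Red"] <- 2
  w_green <- w1; w_green["X2.FL.Red"] <- 0.8
  rbind(
    species_archetype("Synechococcus", "cyanobacteria", 13.4, "unicell",
                      .amp(500, 400, 400, 700, 80, 60)),
    species_archetype("Microcystis", "cyanobacteria", 17.2, "unicell",
                      .amp(700, 550, 1200, 2400, 250, 300)),
    species_archetype("Chlorella", "green_algae", 28.7, "unicell",
                      .amp(1200, 800, 1800, 250, 100, 150), w_green),
    species_archetype("Ankistrodesmus", "green_algae", 31.6, "unicell",
                      .amp(1100, 750, 1600, 200, 50, 80), w_green,
                      elongation = 2.5),
    species_archetype("Chroomonas", "cryptophytes", 60.8, "unicell",
                      .amp(1500, 900, 1500, 150, 1000, 200), w_crypto),
    species_archetype("Synura", "chrysophytes", 152.7, "unicell",
                      .amp(3000, 1500, 2000, 450, 300, 250)),
    species_archetype("Cyclotella", "diatom", 226.2, "unicell",
                      .amp(4000, 2500, 1700, 300, 150, 400)),
    species_archetype("Cryptomonas", "cryptophytes", 896.8, "unicell",
                      .amp(6000, 3000, 2500, 250, 1500, 300), w_crypto),
    species_archetype("Asterionella", "diatom", 1964.8, "colony6",
                      .amp(3500, 2000, 2200, 350, 200, 350)),
    species_archetype("Anabaena", "cyanobacteria", 15478.7, "filament",
                      .amp(5000, 2200, 2500, 5000, 400, 500)),
    species_archetype("noise", "noise", 8.2, "unicell",
                      .amp(300, 250, 25, 25, 20, 30),
                      within_species_cv = 0.8)
  )
}

# instrument-emulation constants; the fine spatial step keeps the recorded
# window length quasi-continuous even for the smallest (~3 um) cells, so
# transit-length traits do not take visibly discrete values
.sfcm_step <- 0.125    # um per sample
.sfcm_trigger <- 99.7  # mV trigger threshold on SWS

# draw per-particle latent variables for one archetype
.sim_latents <- function(arch, n, cv = NULL) {
  if (is.null(cv)) cv <- arch$within_species_cv
  s <- sqrt(log(1 + cv^2))
  eps <- rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  biovolume <- arch$mean_biovolume * eps
  k <- switch(arch$coloniality,
              unicell = rep(1L, n),
              colony6 = sample(c(5L, 6L, 7L), n, replace = TRUE,
                               prob = c(0.05, 0.9, 0.05)),
              filament = pmin(2L + rgeom(n, prob = 1 / 8), 60L))
  v_cell <- biovolume / k
  d_cell <- (6 * v_cell / pi)^(1 / 3)
  # fluorescence and scattering scale with cross-section ~ volume^(2/3)
  amp_mult <- eps^(2 / 3)
  s_ch <- sqrt(log(1 + 0.10^2))
  amps <- matrix(NA_real_, n, 6, dimnames = list(NULL, sfcm_channels))
  for (ch in sfcm_channels) {
    base <- arch[[paste0("amp.", ch)]] * amp_mult *
      rlnorm(n, meanlog = -s_ch^2 / 2, sdlog = s_ch)
    if (ch == "SWS") {
      # the instrument only records particles whose sideward scatter rises
      # above the trigger; draw the SWS amplitude from the left-truncated
      # distribution so every simulated particle is recordable
      floor_amp <- 1.05 * .sfcm_trigger
      mlog <- log(arch[[paste0("amp.", ch)]] * amp_mult) - s_ch^2 / 2
      plo <- plnorm(floor_amp, meanlog = mlog, sdlog = s_ch)
      u <- runif(n, pmin(plo, 1 - 1e-12), 1)
      base <- qlnorm(u, meanlog = mlog, sdlog = s_ch)
    }
    amps[, ch] <- base
  }
  widths <- vapply(sfcm_channels, function(ch) arch[[paste0("width.", ch)]],
                   numeric(1))
  list(n = n, eps = eps, biovolume = biovolume, k = k, d_cell = d_cell,
       amps = amps, widths = widths, elongation = arch$elongation)
}

# build padded pulse matrices (one per channel) for a latent batch
.build_pulse_mats <- function(lat, step = .sfcm_step) {
  n <- lat$n
  d <- lat$d_cell * lat$elongation
  spacing <- d
  sig <- outer(d / 4, lat$widths)           # n x 6 bell SDs
  wmax <- apply(sig, 1L, max)
  W <- spacing * lat$k + 6 * wmax           # window length, um
  m <- pmax(pmin(ceiling(W / step), 5000L), 3L)
  mmax <- max(m)
  grid <- (seq_len(mmax) - 0.5) * step
  kmax <- max(lat$k)
  mats <- lapply(seq_len(6L), function(c) matrix(0, n, mmax))
  for (j in seq_len(kmax)) {
    rows <- which(lat$k >= j)
    cj <- W[rows] / 2 + (j - (lat$k[rows] + 1) / 2) * spacing[rows]
    dx <- outer(-cj, grid, "+")             # x - center
    for (c in seq_len(6L)) {
      mats[[c]][rows, ] <- mats[[c]][rows, ] +
        lat$amps[rows, c] * exp(-dx^2 / (2 * sig[rows, c]^2))
    }
  }
  # positive baseline noise floor on every recorded sample
  for (c in seq_len(6L)) {
    mats[[c]] <- mats[[c]] + 0.5 + matrix(rexp(n * mmax, rate = 1 / 2), n)
  }
  list(mats = mats, plen = as.integer(m))
}

# traits (67 columns) + true biovolume for n particles of one archetype;
# chunked so the padded pulse matrices stay small
.simulate_traits <- function(arch, n, cv = NULL, prominence_fraction = 0.25,
                             ratio_cap = 1e6) {
  lat <- .sim_latents(arch, n, cv)
  d <- lat$d_cell * lat$elongation
  m_est <- ceiling((d * lat$k + 6 * d * max(lat$widths) / 4) / .sfcm_step)
  chunk <- max(500L, floor(6e6 / max(m_est)))
  traits <- matrix(NA_real_, n, 67L)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    sub <- lapply(lat[c("eps", "biovolume", "k", "d_cell")], `[`, i:j)
    sub$amps <- lat$amps[i:j, , drop = FALSE]
    sub$widths <- lat$widths
    sub$elongation <- lat$elongation
    sub$n <- j - i + 1L
    pm <- .build_pulse_mats(sub)
    traits[i:j, ] <- cpp_pulse_features(pm$mats, pm$plen, .sfcm_step,
                                        .sfcm_trigger, 1L, 2L, 3L,
                                        prominence_fraction, ratio_cap)
    i <- j + 1L
  }
  colnames(traits) <- sfcm_trait_names()
  list(traits = traits, biovolume = lat$biovolume, k = lat$k)
}

#' Generate raw time-resolved pulses for one archetype
#'
#' Simulates `n` particles of the archetype at pulse level: Gaussian bells
#' per channel with lognormal amplitude variation, transit length scaling
#' with biovolume^(1/3) and cell count, overlapping bells for colonies and
#' filaments, and truncation of the recorded window to where sideward
#' scatter exceeds the trigger threshold (99.7 mV).
#'
#' @param archetype One-row archetype data.frame (see
#'   [default_archetypes()]).
#' @param n Number of particles (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param within_species_cv Optional CV override.
#' @return List of [particle_pulses()] objects with attribute `"biovolume"`
#'   (true per-particle biovolumes, um^3).
#' @export
generate_pulses <- function(archetype, n, seed = 1L, within_species_cv = NULL) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  lat <- .sim_latents(archetype, n, within_species_cv)
  pm <- .build_pulse_mats(lat)
  sws <- pm$mats[[2L]]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- pm$plen[i]
    over <- which(sws[i, seq_len(m)] >= .sfcm_trigger)
    win <- if (length(over)) over[1L]:over[length(over)] else
      which.max(sws[i, seq_len(m)])
    pulses <- lapply(seq_len(6L), function(c) {
      channel_pulse(sfcm_channels[c], pm$mats[[c]][i, win], .sfcm_step)
    })
    out[[i]] <- particle_pulses(sprintf("%s_%05d", archetype$name, i), pulses)
  }
  attr(out, "biovolume") <- lat$biovolume
  out
}

#' Generate a lab-culture training set
#'
#' Emulates the lab training data: live-cell measurements drawn equally
#' across the species archetypes and non-cell measurements from the noise
#' component, in the roughly 1:7 live:other proportion expected of field
#' samples. Each live row carries its species, functional group and true
#' per-particle biovolume.
#'
#' @param n_live Number of live-cell rows (default 1200).
#' @param n_other Number of non-cell rows (default 8400).
#' @param archetypes Archetype panel including a `"noise"` row.
#' @param seed Integer seed.
#' @param within_species_cv Optional CV override for live species.
#' @return List of class `sfcm_training` with `matrix` (a [trait_matrix()])
#'   and `labels` (data.frame with `class`, `group`, `species`,
#'   `biovolume`).
#' @export
generate_training <- function(n_live = 1200L, n_other = 8400L,
                              archetypes = default_archetypes(), seed = 1L,
                              within_species_cv = NULL) {
  live_arch <- archetypes[archetypes$group != "noise", , drop = FALSE]
  noise_arch <- archetypes[archetypes$group == "noise", , drop = FALSE]
  if (nrow(noise_arch) != 1L) stop("archetypes must contain one noise row")
  if (length(unique(live_arch$group)) < 2L) {
    stop("archetypes must cover >= 2 functional groups")
  }
  ns <- nrow(live_arch)
  per <- rep(floor(n_live / ns), ns)
  extra <- n_live - sum(per)
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  set.seed(as.integer(seed))
  blocks <- vector("list", ns + 1L)
  labels <- vector("list", ns + 1L)
  for (i in seq_len(ns)) {
    sim <- .simulate_traits(live_arch[i, ], per[i], cv = within_species_cv)
    blocks[[i]] <- sim$traits
    labels[[i]] <- data.frame(class = "live", group = live_arch$group[i],
                              species = live_arch$name[i],
                              biovolume = sim$biovolume,
                              stringsAsFactors = FALSE)
  }
  simn <- .simulate_traits(noise_arch, n_other)
  blocks[[ns + 1L]] <- simn$traits
  labels[[ns + 1L]] <- data.frame(class = "other", group = NA_character_,
                                  species = "noise",
                                  biovolume = rep(NA_real_, n_other),
                                  stringsAsFactors = FALSE)
  traits <- do.call(rbind, blocks)
  lab <- do.call(rbind, labels)
  ids <- sprintf("train_%05d", seq_len(nrow(traits)))
  structure(list(matrix = trait_matrix(traits, particle_id = ids),
                 labels = lab),
            class = "sfcm_training")
}

#' Field-series scenario
#'
#' Describes a synthetic multi-sample field campaign: number of samples,
#' particles per sample, target live-cell fraction, species composition of
#' the live community (with a smooth drift across samples so the community
#' changes over the series), and the error model of the paired "microscopy"
#' ground truth.
#'
#' @param n_samples Number of samples (default 50).
#' @param particles_per_sample Particles recorded per sample (default
#'   10000).
#' @param live_fraction Target mean live-cell fraction (default 0.05).
#' @param composition Named numeric vector of live-community species
#'   weights; names must match archetype names. Default: four abundant
#'   species (one per major functional group) plus three rare ones, all of
#'   compact morphology so that each species forms a single tight trait
#'   component (the filament archetype, whose geometric cell count spreads
#'   its transit length over about a decade, belongs to the training panel
#'   but not to the default lake community).
#' @param drift_amplitude Amplitude of the per-species log-weight sinusoidal
#'   drift across samples (default 0.25).
#' @param live_fraction_amplitude Amplitude of the log live-fraction drift
#'   (default 0.3).
#' @param microscopy_error_cv Lognormal CV of the microscopy error (default
#'   0.3).
#' @param detection_limit Microscopy detection limit in cells/mL (default
#'   28); noisy microscopy densities below it are recorded as 0.
#' @param seed Integer seed.
#' @return List of class `field_scenario`.
#' @export
field_scenario <- function(n_samples = 50L, particles_per_sample = 10000L,
                           live_fraction = 0.05,
                           composition = c(Synura = 0.42, Microcystis = 0.21,
                                           Chroomonas = 0.18, Chlorella = 0.14,
                                           Synechococcus = 0.02,
                                           Cryptomonas = 0.02,
                                           Ankistrodesmus = 0.01),
                           drift_amplitude = 0.25,
                           live_fraction_amplitude = 0.3,
                           microscopy_error_cv = 0.3,
                           detection_limit = 28,
                           seed = 1L) {
  if (live_fraction <= 0 || live_fraction >= 1) {
    stop("live_fraction must be in (0, 1)")
  }
  composition <- composition / sum(composition)
  structure(list(n_samples = as.integer(n_samples),
                 particles_per_sample = as.integer(particles_per_sample),
                 live_fraction = live_fraction,
                 composition = composition,
                 drift_amplitude = drift_amplitude,
                 live_fraction_amplitude = live_fraction_amplitude,
                 microscopy_error_cv = microscopy_error_cv,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "field_scenario")
}

#' Generate a synthetic field series with paired microscopy truth
#'
#' Simulates a multi-sample field campaign: each sample is a mixture of the
#' noise component (1 - live fraction) and live species drawn from the
#' scenario's drifting composition. The returned truth table holds, per
#' sample and per functional group (plus `"total"` over all live cells and a
#' `"noise"` bookkeeping row), the realized cell densities (cells/mL) and
#' biovolumes (um^3/mL), together with a "microscopy" copy perturbed by
#' lognormal error and truncated to 0 below the detection limit.
#'
#' @param scenario A [field_scenario()].
#' @param archetypes Archetype panel covering the scenario's species plus
#'   the noise component.
#' @return List with `samples` (an [sfcm_samples()] object), `truth`
#'   (per-sample/per-group truth table) and `particle_truth` (true species,
#'   group and biovolume of every particle; for validation only).
#' @export
generate_field_series <- function(scenario = field_scenario(),
                                  archetypes = default_archetypes()) {
  sp <- names(scenario$composition)
  missing <- setdiff(sp, archetypes$name)
  if (length(missing)) {
    stop("configuration error: composition species absent from archetypes: ",
         paste(missing, collapse = ", "))
  }
  noise_arch <- archetypes[archetypes$group == "noise", , drop = FALSE]
  if (nrow(noise_arch) != 1L) stop("archetypes must contain one noise row")
  arch_by_name <- split(archetypes, archetypes$name)
  group_of <- setNames(archetypes$group, archetypes$name)

  ns <- scenario$n_samples
  np <- scenario$particles_per_sample
  set.seed(scenario$seed)
  lf <- pmin(pmax(scenario$live_fraction *
                    exp(scenario$live_fraction_amplitude *
                          sin(2 * pi * seq_len(ns) / ns) +
                          rnorm(ns, 0, 0.05)), 0.005), 0.3)
  vol <- runif(ns, 450, 500)
  depths <- rep(c(1.0, 2.5, 4.0, 5.5, 7.0, 8.5), length.out = ns)
  t0 <- as.POSIXct("2014-08-17 00:00:00", tz = "UTC")
  stamps <- format(t0 + 4 * 3600 * ((seq_len(ns) - 1L) %/% 6L) +
                     60 * ((seq_len(ns) - 1L) %% 6L),
                   "%Y-%m-%dT%H:%M:%SZ")
  phases <- (seq_along(sp) - 1L) / length(sp)

  total_n <- ns * np
  traits <- matrix(NA_real_, total_n, 67L)
  colnames(traits) <- sfcm_trait_names()
  p_sample <- character(total_n)
  p_id <- character(total_n)
  p_species <- character(total_n)
  p_biovol <- numeric(total_n)
  truth_rows <- list()
  row0 <- 0L

  for (s in seq_len(ns)) {
    sid <- sprintf("s%03d", s)
    w <- scenario$composition *
      exp(scenario$drift_amplitude * sin(2 * pi * (s / ns + phases)))
    w <- w / sum(w)
    n_live <- rbinom(1L, np, lf[s])
    counts <- drop(rmultinom(1L, n_live, w))
    n_noise <- np - n_live
    seg <- c(setNames(as.integer(counts), sp), noise = n_noise)
    pos <- row0
    for (nm in names(seg)) {
      cnt <- seg[[nm]]
      if (cnt == 0L) next
      arch <- if (nm == "noise") noise_arch else arch_by_name[[nm]]
      sim <- .simulate_traits(arch, cnt)
      rows <- pos + seq_len(cnt)
      traits[rows, ] <- sim$traits
      p_species[rows] <- nm
      p_biovol[rows] <- if (nm == "noise") NA_real_ else sim$biovolume
      pos <- pos + cnt
    }
    rows_s <- row0 + seq_len(np)
    p_sample[rows_s] <- sid
    p_id[rows_s] <- sprintf("%s_p%05d", sid, seq_len(np))

    # realized per-group truth for this sample
    live_groups <- unique(group_of[sp])
    per_mL <- 1000 / vol[s]
    g_density <- vapply(live_groups, function(g) {
      sum(seg[sp][group_of[sp] == g]) * per_mL
    }, numeric(1))
    g_biovol <- vapply(live_groups, function(g) {
      idx <- rows_s[p_species[rows_s] %in% sp[group_of[sp] == g]]
      sum(p_biovol[idx]) * per_mL
    }, numeric(1))
    tr <- data.frame(sample_id = sid,
                     group = c(live_groups, "total", "noise"),
                     true_density = c(g_density, sum(g_density),
                                      n_noise * per_mL),
                     true_biovolume = c(g_biovol, sum(g_biovol), NA_real_),
                     stringsAsFactors = FALSE)
    truth_rows[[s]] <- tr
    row0 <- row0 + np
  }

  truth <- do.call(rbind, truth_rows)
  # noisy microscopy copy with detection-limit truncation
  cv <- scenario$microscopy_error_cv
  if (cv > 0) {
    s_mic <- sqrt(log(1 + cv^2))
    err_d <- rlnorm(nrow(truth), -s_mic^2 / 2, s_mic)
    err_b <- rlnorm(nrow(truth), -s_mic^2 / 2, s_mic)
  } else {
    err_d <- err_b <- rep(1, nrow(truth))
  }
  truth$microscopy_density <- truth$true_density * err_d
  truth$microscopy_biovolume <- truth$true_biovolume * err_b
  below <- !is.na(truth$microscopy_density) &
    truth$microscopy_density < scenario$detection_limit &
    truth$group != "noise"
  truth$microscopy_density[below] <- 0
  truth$microscopy_biovolume[below] <- 0
  truth$microscopy_density[truth$group == "noise"] <- NA_real_
  truth$microscopy_biovolume[truth$group == "noise"] <- NA_real_

  particles <- data.frame(sample_id = p_sample, particle_id = p_id,
                          stringsAsFactors = FALSE)
  particles <- cbind(particles, as.data.frame(traits))
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(ns)),
                     depth = depths, timestamp = stamps,
                     volume_analyzed = vol,
                     particle_concentration = np / vol,
                     stringsAsFactors = FALSE)
  particle_truth <- data.frame(sample_id = p_sample, particle_id = p_id,
                               species = p_species,
                               group = ifelse(p_species == "noise", "noise",
                                              unname(group_of[p_species])),
                               biovolume = p_biovol,
                               stringsAsFactors = FALSE)
  list(samples = sfcm_samples(particles, meta), truth = truth,
       particle_truth = particle_truth)
}
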