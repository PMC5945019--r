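test_that("training set has the expected composition", {
  train <- tiny_training()
  lab <- train$labels
  expect_equal(sum(lab$class == "live"), 400L)
  expect_equal(sum(lab$class == "other"), 1200L)
  expect_true(all(table(lab$species[lab$class == "live"]) == 40L))
  expect_equal(nrow(train$matrix$values), 1600L)
  expect_identical(colnames(train$matrix$values), sfcm_trait_names())
})

test_that("training biovolumes stay within the lognormal tail bound", {
  train <- tiny_training()
  bv <- train$labels$biovolume[train$labels$class == "live"]
  expect_true(all(bv >= 13.4 * 0.5))
  expect_true(all(bv <= 15478.7 * 2))
  sp <- train$labels$species[train$labels$class == "live"]
  expect_equal(mean(bv[sp == "Synechococcus"]), 13.4, tolerance = 0.1)
})

test_that("colonial archetype pulses count six cells per colony", {
  arch <- default_archetypes()
  pp <- generate_pulses(arch[arch$name == "Asterionella", ], 40, seed = 2)
  counts <- vapply(pp, function(p) {
    pulse_peak_count(p$pulses[["FL.Red"]])
  }, integer(1))
  expect_identical(as.integer(names(which.max(table(counts)))), 6L)
})

test_that("pulse length ordering follows biovolume", {
  arch <- default_archetypes()
  syn <- featurize_pulses(generate_pulses(arch[arch$name == "Synechococcus", ],
                                          60, seed = 3))
  ana <- featurize_pulses(generate_pulses(arch[arch$name == "Anabaena", ],
                                          60, seed = 4))
  expect_gte(mean(ana$FWS.Length > syn$FWS.Length), 0.95)
  synura <- featurize_pulses(generate_pulses(arch[arch$name == "Synura", ],
                                             60, seed = 5))
  expect_gt(mean(synura$FWS.Length), mean(syn$FWS.Length))
})

test_that("cyanobacteria archetypes sit below all eukaryotes in Red1Red2.ratio", {
  arch <- default_archetypes()
  live <- arch[arch$group != "noise", ]
  med <- vapply(seq_len(nrow(live)), function(i) {
    tr <- sfcmflow:::.simulate_traits(live[i, ], 100)
    median(tr$traits[, "Red1Red2.ratio"])
  }, numeric(1))
  cyan <- live$group == "cyanobacteria"
  expect_lt(max(med[cyan]), min(med[!cyan]))
})

test_that("generators are deterministic given the seed", {
  arch <- default_archetypes()
  a <- generate_pulses(arch[1, ], 10, seed = 6)
  b <- generate_pulses(arch[1, ], 10, seed = 6)
  expect_equal(a[[1]]$pulses[["FWS"]]$values, b[[1]]$pulses[["FWS"]]$values)

  sc <- field_scenario(n_samples = 2, particles_per_sample = 300, seed = 8)
  f1 <- generate_field_series(sc)
  f2 <- generate_field_series(sc)
  expect_equal(f1$samples$particles, f2$samples$particles)
  expect_equal(f1$truth, f2$truth)

  t1 <- generate_training(n_live = 50, n_other = 100, seed = 9)
  t2 <- generate_training(n_live = 50, n_other = 100, seed = 9)
  expect_equal(t1$matrix$values, t2$matrix$values)
})

test_that("field truth conserves particle counts exactly", {
  field <- tiny_field()
  truth <- field$truth
  meta <- field$samples$meta
  for (sid in meta$sample_id) {
    rows <- truth[truth$sample_id == sid, ]
    total_live <- rows$true_density[rows$group == "total"]
    noise <- rows$true_density[rows$group == "noise"]
    expect_equal(total_live + noise,
                 meta$particle_concentration[meta$sample_id == sid] * 1000,
                 tolerance = 1e-9)
    groups <- rows$group %in% c("cyanobacteria", "chrysophytes",
                                "cryptophytes", "green_algae", "diatom")
    expect_equal(sum(rows$true_density[groups]), total_live,
                 tolerance = 1e-9)
  }
})

test_that("pooled live fraction matches the scenario target", {
  field <- tiny_field()
  live <- field$particle_truth$group != "noise"
  expect_gt(mean(live), 0.03)
  expect_lt(mean(live), 0.07)
})

test_that("microscopy error and detection limit behave as configured", {
  sc0 <- field_scenario(n_samples = 3, particles_per_sample = 400,
                        microscopy_error_cv = 0, seed = 14)
  f0 <- generate_field_series(sc0)
  ok <- f0$truth$group != "noise" & f0$truth$microscopy_density > 0
  expect_equal(f0$truth$microscopy_density[ok], f0$truth$true_density[ok])

  # rare groups below the detection limit are recorded as zero
  sc1 <- field_scenario(n_samples = 6, particles_per_sample = 2000,
                        live_fraction = 0.006,
                        composition = c(Synura = 0.9, Microcystis = 0.1),
                        seed = 15)
  f1 <- generate_field_series(sc1)
  cy <- f1$truth[f1$truth$group == "cyanobacteria", ]
  expect_true(any(cy$microscopy_density == 0 & cy$true_density > 0))
})

test_that("species are recoverable from traits at default noise, degrading with cv", {
  arch <- default_archetypes()
  traits_for_cv <- function(cv) {
    a2 <- arch
    a2$within_species_cv[a2$group != "noise"] <- cv
    sc <- field_scenario(n_samples = 4, particles_per_sample = 1500, seed = 21)
    generate_field_series(sc, a2)
  }
  cluster_ari <- function(field) {
    live <- field$particle_truth$group != "noise"
    sel <- c("FL.Red.Range", "X2.FL.Red.Range", "FL.Orange.Range",
             "FL.Yellow.Range", "FWS.Range", "FWS.Length",
             "Red1Red2.ratio", "X2.FL.Red.Gradient")
    x <- as.matrix(field$samples$particles[live, sel])
    m <- log_transform_eligible(trait_matrix(x))
    fm <- flowpeaks_cluster(m, cluster_params(seed = 2))
    ari(fm$labels, field$particle_truth$species[live])
  }
  aris <- vapply(c(0.15, 0.4, 0.8), function(cv) cluster_ari(traits_for_cv(cv)),
                 numeric(1))
  expect_gte(aris[1], 0.95)
  # higher trait noise clearly degrades recovery relative to the default
  expect_lt(max(aris[2:3]), aris[1] - 0.1)
})
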