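test_that("basic statistics match closed forms", {
  p <- channel_pulse("FL.Red", rep(5, 10), step = 0.5)
  s <- pulse_basic_stats(p)
  expect_equal(s$Maximum, 5)
  expect_equal(s$Range, 0)
  expect_equal(s$Length, 5.0)
  expect_equal(s$Total, 25.0)

  p1 <- channel_pulse("FWS", 7, step = 1)
  s1 <- pulse_basic_stats(p1)
  expect_equal(s1$First, 7)
  expect_equal(s1$Last, 7)
  expect_equal(s1$Maximum, 7)
  expect_equal(s1$Range, 0)

  ramp <- channel_pulse("SWS", 0:9, step = 1)
  sr <- pulse_basic_stats(ramp)
  expect_equal(sr$Total, sum(0:9))   # brute-force sum oracle
  expect_equal(sr$Average, 4.5)
  expect_equal(sr$Range, 9)
})

test_that("fill factor matches analytic shapes", {
  expect_equal(pulse_fill_factor(channel_pulse("FWS", rep(4, 25))), 1.0)

  tri <- channel_pulse("FL.Red", c(0:10, 9:0), step = 1)
  expect_lt(abs(pulse_fill_factor(tri) - 0.5), 1 / 21)

  n <- 1000
  hs <- channel_pulse("FL.Red", sin(pi * (seq_len(n) - 0.5) / n), step = 1)
  expect_lt(abs(pulse_fill_factor(hs) - 2 / pi), 0.01)

  expect_warning(f0 <- pulse_fill_factor(channel_pulse("SWS", rep(0, 5))),
                 "flat dark")
  expect_equal(f0, 0)
})

test_that("gradient matches linear and sawtooth oracles", {
  expect_equal(pulse_gradient(channel_pulse("FWS", rep(3, 8))), 0)
  # ramp with slope 2 mV/um at step 0.5
  ramp <- channel_pulse("FWS", seq(0, 9, by = 1), step = 0.5)
  expect_equal(pulse_gradient(ramp), 2.0)
  saw <- channel_pulse("FWS", rep(c(0, 4), 10), step = 1)
  expect_equal(pulse_gradient(saw), mean(abs(diff(rep(c(0, 4), 10)))))
  expect_equal(pulse_gradient(channel_pulse("FWS", 5)), 0)
})

test_that("peak counting resolves unimodal pulses, colonies and flats", {
  x <- seq(0, 12, by = 0.1)
  g1 <- channel_pulse("FL.Red", exp(-(x - 6)^2 / 2))
  expect_equal(pulse_peak_count(g1), 1L)

  g2 <- channel_pulse("FL.Red", exp(-(x - 3)^2 / 0.8) + exp(-(x - 9)^2 / 0.8))
  expect_equal(pulse_peak_count(g2), 2L)

  # six equal bells, as for a six-cell colony in single file
  centers <- seq(2, 22, by = 4)
  xx <- seq(0, 24, by = 0.1)
  v6 <- rowSums(vapply(centers, function(c) exp(-(xx - c)^2 / 2),
                       numeric(length(xx))))
  expect_equal(pulse_peak_count(channel_pulse("FL.Red", v6)), 6L)

  expect_equal(pulse_peak_count(channel_pulse("FL.Red", rep(2, 30))), 0L)
})

test_that("R and C++ peak counters agree on random pulses", {
  set.seed(99)
  for (i in 1:100) {
    v <- abs(cumsum(rnorm(sample(5:80, 1))))
    expect_identical(pulse_peak_count(channel_pulse("FWS", v)),
                     sfcmflow:::cpp_peak_count(v, 0.25))
  }
})

test_that("red1/red2 ratio is an area ratio with a capped degenerate case", {
  r1 <- channel_pulse("FL.Red", c(1, 3, 2))
  r2 <- channel_pulse("X2.FL.Red", c(1, 3, 2))
  expect_equal(red1red2_ratio(r1, r2), 1.0)
  r1b <- channel_pulse("FL.Red", 2 * c(1, 3, 2))
  expect_equal(red1red2_ratio(r1b, r2), 2.0)
  expect_warning(rz <- red1red2_ratio(r1, channel_pulse("X2.FL.Red", rep(0, 3)),
                                      cap = 123), "zero")
  expect_equal(rz, 123)
})

test_that("featurize emits the full dotted-trait schema", {
  mk <- function(vals) {
    particle_pulses("p1", lapply(sfcmflow:::sfcm_channels, function(ch)
      channel_pulse(ch, vals)))
  }
  rec <- featurize_particle(mk(c(1, 5, 9, 5, 1)))
  expect_true("FL.Red.Range" %in% names(rec))
  expect_gte(length(rec), 67L)
  expect_identical(names(rec), sfcm_trait_names())

  rect <- featurize_particle(mk(rep(4, 12)))
  fills <- rect[grep("Fill.factor", names(rect), fixed = TRUE)]
  expect_equal(unname(fills), rep(1, 6))

  # missing channel is a domain error
  expect_error(particle_pulses("p2", list(channel_pulse("FWS", 1:3))),
               "missing")
})

test_that("features are scale-equivariant and translation-invariant", {
  set.seed(4)
  x <- seq(0, 20, by = 0.25)
  v <- 50 * exp(-(x - 10)^2 / 3) + abs(rnorm(length(x), 0, 0.5))
  p <- channel_pulse("FL.Red", v, step = 0.25)
  c0 <- 2.5
  pc <- channel_pulse("FL.Red", c0 * v, step = 0.25)
  s <- pulse_basic_stats(p); sc <- pulse_basic_stats(pc)
  for (f in c("Maximum", "Minimum", "Total", "Average", "Range")) {
    expect_equal(sc[[f]], c0 * s[[f]])
  }
  expect_equal(sc$Length, s$Length)
  expect_equal(pulse_fill_factor(pc), pulse_fill_factor(p))
  expect_equal(pulse_peak_count(pc), pulse_peak_count(p))
  expect_equal(pulse_gradient(pc), c0 * pulse_gradient(p))

  # a bell translated within the window leaves all features unchanged
  b1 <- 100 * exp(-(x - 8)^2 / 2)
  b2 <- 100 * exp(-(x - 12)^2 / 2)
  f1 <- pulse_basic_stats(channel_pulse("FWS", b1, 0.25))
  f2 <- pulse_basic_stats(channel_pulse("FWS", b2, 0.25))
  expect_equal(unlist(f1), unlist(f2), tolerance = 1e-9)
})

test_that("fill factor is within [0, 1] for random non-negative pulses", {
  set.seed(11)
  for (i in 1:200) {
    v <- abs(rnorm(sample(3:60, 1), sd = sample(1:50, 1)))
    f <- suppressWarnings(pulse_fill_factor(channel_pulse("FWS", v)))
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("bulk featurization equals the scalar path on generated pulses", {
  arch <- default_archetypes()
  for (nm in c("Synechococcus", "Chroomonas", "Asterionella")) {
    a <- arch[arch$name == nm, ]
    pp <- generate_pulses(a, 30, seed = 5)
    scalar <- featurize_pulses(pp)
    bulk <- local({ set.seed(5L); sfcmflow:::.simulate_traits(a, 30) })
    sc <- as.matrix(scalar[, sfcm_trait_names()])
    expect_equal(unname(sc), unname(bulk$traits), tolerance = 1e-9)
  }
})
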