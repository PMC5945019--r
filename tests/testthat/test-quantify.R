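test_that("community density is concentration x 1000 x live fraction", {
  expect_equal(community_density(1, 0.05), 50)
  expect_equal(community_density(1, 0), 0)
  expect_warning(d0 <- community_density(2, 0.5, n_particles = 0), "zero")
  expect_equal(d0, 0)
})

test_that("group densities partition the community density", {
  gd <- group_density(100, c(a = 0.5, b = 0.3))
  expect_equal(unname(gd), c(50, 30))
  expect_length(group_density(100, setNames(numeric(0), character(0))), 0L)
  fr <- c(a = 0.6, b = 0.4)
  expect_equal(sum(group_density(250, fr)), 250)   # conservation at sum 1
  expect_error(group_density(10, c(a = 0.7, b = 0.5)), "integrity error")
})

test_that("biovolume aggregation identities hold exactly", {
  agg <- total_and_group_biovolume(50, c(g = 50), rep(100, 10), rep("g", 10))
  expect_equal(agg$total_biovolume, 5000)
  expect_equal(unname(agg$group_biovolume), 5000)   # one group = total

  # integrity: density without particles
  expect_error(total_and_group_biovolume(50, c(g = 10), numeric(0),
                                         character(0)),
               "integrity error")

  # conservation: sum of group + unassigned contributions = total, 1e-9
  set.seed(71)
  groups <- sample(c("a", "b", "unassigned"), 500, replace = TRUE)
  bv <- rlnorm(500, 3, 1)
  total <- 1234.5
  fr <- table(groups) / 500
  gd <- group_density(total, setNames(as.numeric(fr), names(fr)))
  agg2 <- total_and_group_biovolume(total, gd, bv, groups)
  expect_equal(sum(agg2$group_biovolume), agg2$total_biovolume,
               tolerance = 1e-9)
  expect_equal(agg2$total_biovolume, total * agg2$mean_cell_biovolume,
               tolerance = 1e-9)
})

test_that("log-log validation recovers identity and scale relationships", {
  set.seed(72)
  x <- 10^runif(40, 1, 4)
  v <- suppressWarnings(validate_loglog(x, x))  # exact fit: lm advisory
  expect_equal(v$r, 1)
  expect_equal(v$slope, 1, tolerance = 1e-9)
  expect_equal(v$intercept, 0, tolerance = 1e-9)
  expect_true(v$slope_ci[1] <= v$slope && v$slope <= v$slope_ci[2])

  v2 <- suppressWarnings(validate_loglog(x, 100 * x))
  expect_equal(v2$slope, 1, tolerance = 1e-9)
  expect_equal(v2$intercept, 2, tolerance = 1e-9)

  # scale property: multiplying y shifts only the intercept
  y <- x * 10^rnorm(40, 0, 0.2)
  a <- validate_loglog(x, y)
  b <- validate_loglog(x, 7 * y)
  expect_equal(b$slope, a$slope, tolerance = 1e-9)
  expect_equal(b$r, a$r, tolerance = 1e-9)
  expect_equal(b$intercept - a$intercept, log10(7), tolerance = 1e-9)
})

test_that("zeros are substituted at half the detection limit", {
  x <- c(0, 100, 1000, 500, 80)
  y <- c(20, 110, 900, 480, 70)
  v <- validate_loglog(x, y, detection_limit = 28)
  xs <- x; xs[1] <- 14   # 0.5 * 28
  v2 <- validate_loglog(xs, y)
  expect_equal(v$slope, v2$slope)
  expect_equal(v$r, v2$r)
  expect_error(validate_loglog(x, y), "detection_limit")
})

test_that("high-leverage points can be excluded and are reported", {
  set.seed(73)
  x <- 10^rnorm(30, 2, 0.2)
  y <- x * 10^rnorm(30, 0, 0.05)
  x <- c(x, 1e6); y <- c(y, 2e6)
  names(x) <- names(y) <- paste0("s", seq_along(x))
  v <- validate_loglog(x, y, leverage_exclusion = TRUE)
  expect_true("s31" %in% v$excluded_point_ids)
  expect_equal(v$n, 30)
  expect_error(validate_loglog(c(1, 2), c(1, 2)), "3 points")
})

test_that("community estimates table reconciles with cleaning and grouping", {
  cl <- tiny_cleaning()
  gr <- tiny_grouping()
  field <- tiny_field()
  est <- community_estimates(field$samples, cl, gr)
  expect_setequal(unique(est$sample_id), sample_ids(field$samples))
  for (sid in unique(est$sample_id)) {
    rows <- est[est$sample_id == sid, ]
    tot <- rows$cell_density_per_mL[rows$group == "total"]
    expect_equal(sum(rows$cell_density_per_mL[rows$group != "total"]), tot,
                 tolerance = 1e-9)
  }
  # total density = concentration * 1000 * live fraction
  meta <- field$samples$meta
  lf <- cl$live_fraction
  sid <- lf$sample_id[1]
  expected <- meta$particle_concentration[match(sid, meta$sample_id)] * 1000 *
    lf$live_fraction[1]
  expect_equal(est$cell_density_per_mL[est$sample_id == sid &
                                         est$group == "total"],
               expected, tolerance = 1e-12)
})
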