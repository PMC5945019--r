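# fixture: one informative trait (class means 10 SD apart), nine noise traits
sep_fixture <- function(n_per = 60, seed = 31) {
  set.seed(seed)
  y <- rep(c("live", "other"), each = n_per)
  x <- matrix(rnorm(2 * n_per * 10), ncol = 10,
              dimnames = list(NULL, paste0("tr", 1:10)))
  x[, 1] <- x[, 1] + ifelse(y == "live", 10, 0)
  list(train = labeled_training(trait_matrix(x), y), x = x, y = y)
}

test_that("importance ranking puts the informative trait first", {
  fx <- sep_fixture()
  r <- rank_importance(fx$train, n_trees = 501L, seed = 1)
  expect_identical(r$trait[1L], "tr1")
  expect_true(all(diff(r$importance) <= 0))
  expect_setequal(r$trait, paste0("tr", 1:10))
})

test_that("permuted labels give no consistently top-ranked trait", {
  set.seed(77)
  x <- matrix(rnorm(100 * 5), ncol = 5,
              dimnames = list(NULL, paste0("tr", 1:5)))
  y <- rep(c("a", "b"), each = 50)
  tops <- vapply(1:20, function(s) {
    set.seed(s)
    yy <- sample(y)
    r <- rank_importance(labeled_training(trait_matrix(x), yy),
                         n_trees = 201L, seed = s)
    r$trait[1L]
  }, character(1))
  expect_lt(max(table(tops)) / 20, 0.6)
})

test_that("duplicating the top trait does not inflate noise importance", {
  fx <- sep_fixture()
  r1 <- rank_importance(fx$train, n_trees = 501L, seed = 5)
  noise1 <- sum(r1$importance[r1$trait != "tr1"])
  x2 <- cbind(fx$x, tr1copy = fx$x[, 1])
  r2 <- rank_importance(labeled_training(trait_matrix(x2), fx$y),
                        n_trees = 501L, seed = 5)
  noise2 <- sum(r2$importance[!r2$trait %in% c("tr1", "tr1copy")])
  expect_lte(noise2, noise1 * 1.05 + 1e-8)
})

test_that("select_top_k slices the ranking in order", {
  r <- structure(data.frame(trait = c("a", "b", "c"), importance = 3:1),
                 class = c("importance_ranking", "data.frame"))
  expect_identical(select_top_k(r, 3), c("a", "b", "c"))
  expect_identical(select_top_k(r, 1), "a")
  expect_error(select_top_k(r, 4), "domain error")
})

test_that("classifier separates well-separated classes almost perfectly", {
  fx <- sep_fixture(n_per = 150)
  clf <- fit_classifier(fx$train, n_trees = 201L, seed = 2)
  expect_lt(clf$oob_error, 0.005)
  self <- predict(clf, fx$train$matrix)
  expect_gte(mean(as.character(self) == fx$y), 0.99)
  expect_error(fit_classifier(labeled_training(fx$train$matrix,
                                               rep("one", nrow(fx$x))),
                              201L, 1), "domain error")
})

test_that("tree counts must be odd", {
  fx <- sep_fixture()
  expect_error(fit_classifier(fx$train, n_trees = 200L), "odd")
  expect_error(rank_importance(fx$train, n_trees = 100L), "odd")
})

test_that("forests are deterministic given (train, n_trees, seed)", {
  fx <- sep_fixture()
  a <- fit_classifier(fx$train, 201L, seed = 9)
  b <- fit_classifier(fx$train, 201L, seed = 9)
  expect_identical(a$oob_error, b$oob_error)
  expect_identical(as.character(predict(a, fx$train$matrix)),
                   as.character(predict(b, fx$train$matrix)))
  r1 <- rank_importance(fx$train, 201L, seed = 9)
  r2 <- rank_importance(fx$train, 201L, seed = 9)
  expect_identical(r1, r2)
})

test_that("biovolume regressor handles a constant target exactly", {
  set.seed(41)
  x <- matrix(rnorm(50 * 4), ncol = 4,
              dimnames = list(NULL, paste0("tr", 1:4)))
  expect_warning(
    reg <- fit_biovolume_regressor(labeled_training(trait_matrix(x),
                                                    rep(28.7, 50)),
                                   n_trees = 101L, seed = 1),
    "single distinct")
  pred <- predict(reg, x)
  expect_equal(unname(pred), rep(28.7, 50), tolerance = 1e-6)
  expect_true(is.na(reg$oob_r2))
})

test_that("regressor predictions stay within the training target range", {
  set.seed(42)
  n <- 120
  x <- matrix(rnorm(n * 5), ncol = 5, dimnames = list(NULL, paste0("tr", 1:5)))
  y <- 10^(1 + 2 * plogis(x[, 1]) + rnorm(n, 0, 0.05))
  reg <- fit_biovolume_regressor(labeled_training(trait_matrix(x), y),
                                 n_trees = 201L, seed = 3)
  pred <- predict(reg, x)
  expect_true(all(pred > 0))
  expect_gte(min(pred), min(y) * (1 - 1e-9))
  expect_lte(max(pred), max(y) * (1 + 1e-9))
  expect_error(fit_biovolume_regressor(labeled_training(trait_matrix(x),
                                                        c(-1, y[-1])), 201L, 1),
               "positive")
})

test_that("prediction refuses records missing a required trait", {
  fx <- sep_fixture()
  clf <- fit_classifier(fx$train, 201L, seed = 2)
  expect_error(predict(clf, fx$x[, 1:5]), "missing required trait")
})
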