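test_that("triangular membership interpolates linearly between vertices", {
  expect_equal(trimf(2, 0, 1, 3), 0.5)       # (3-2)/(3-1)
  expect_equal(trimf(1, 0, 1, 3), 1)         # peak
  expect_equal(trimf(0, 0, 1, 3), 0)         # left vertex
  expect_equal(trimf(c(-5, 10), 0, 1, 3), c(0, 0))  # out of range
  expect_equal(trimf(0.5, 0, 1, 3), 0.5)
  expect_error(trimf(0, 1, 0, 3), "vertices")
})

test_that("grid partition enumerates the full rule base", {
  set.seed(20)
  X4 <- matrix(runif(84), 21, 4,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  m <- anfis_init(X4, mfs_per_input = 2)
  expect_equal(nrow(m$rules), 16)
  expect_equal(nrow(coef(m)), 16)
  expect_equal(ncol(coef(m)), 5)  # intercept + 4 inputs per rule
  expect_equal(nrow(unique(as.data.frame(m$rules))), 16)  # all distinct
  expect_equal(nrow(anfis_init(X4[, 1:2])$rules), 4)
  expect_equal(nrow(anfis_init(X4[, 1, drop = FALSE],
                               mfs_per_input = 3)$rules), 3)
  X4[, 2] <- 1
  expect_error(anfis_init(X4), "constant input")
})

test_that("the two grid MFs cover the observed range with total membership 1", {
  set.seed(21)
  X <- matrix(runif(40, -3, 7), 20, 2, dimnames = list(NULL, c("u", "v")))
  m <- anfis_init(X, standardize = FALSE)
  for (j in 1:2) {
    mf <- m$mfs[[j]]
    xs <- seq(min(X[, j]), max(X[, j]), length.out = 50)
    tot <- trimf(xs, mf[1, 1], mf[1, 2], mf[1, 3]) +
      trimf(xs, mf[2, 1], mf[2, 2], mf[2, 3])
    expect_equal(tot, rep(1, 50))
  }
})

test_that("membership accessor reports layer-1 degrees", {
  X <- matrix(seq(0, 1, length.out = 11), ncol = 1,
              dimnames = list(NULL, "x"))
  m <- anfis_init(X, standardize = FALSE)
  deg <- memberships(m, 0)     # at the first MF's peak
  expect_equal(deg$x, c(1, 0))
  expect_equal(memberships(m, 1)$x, c(0, 1))
  expect_equal(memberships(m, 0.25)$x, c(0.75, 0.25))
})

test_that("inference matches a hand-enumerated forward pass", {
  X <- matrix(seq(0, 1, length.out = 11), ncol = 1,
              dimnames = list(NULL, "x"))
  m <- anfis_init(X, standardize = FALSE)
  m$consequents <- matrix(c(1, 2, -1, 0.5), 2, 2, byrow = TRUE,
                          dimnames = dimnames(m$consequents))
  x0 <- 0.3
  # by hand: mu = (0.7, 0.3); f = (1 + 2 x, -1 + 0.5 x)
  f1 <- 1 + 2 * x0; f2 <- -1 + 0.5 * x0
  expect_equal(predict(m, matrix(x0, dimnames = list(NULL, "x"))),
               0.7 * f1 + 0.3 * f2)
  # single-rule model: normalized weight is 1 regardless of firing
  m1 <- m
  m1$rules <- m1$rules[1, , drop = FALSE]
  m1$consequents <- matrix(c(2, 3), 1, 2,
                           dimnames = list(NULL, c("c0", "x")))
  expect_equal(predict(m1, matrix(0.4, dimnames = list(NULL, "x"))),
               2 + 3 * 0.4)
})

test_that("constant consequents predict the constant anywhere in range", {
  set.seed(22)
  X <- matrix(runif(60, -2, 5), 20, 3, dimnames = list(NULL, c("a","b","c")))
  m <- anfis_init(X)
  m$consequents[, 1] <- 7.5   # c0 = k, slopes 0
  xs <- matrix(runif(30, -2, 5), 10, 3, dimnames = list(NULL, c("a","b","c")))
  expect_equal(predict(m, xs), rep(7.5, 10))  # normalized strengths sum to 1
})

test_that("prediction is invariant under rule-order permutation", {
  set.seed(23)
  pl <- make_planted_ts(50, sigma = 0.2, seed = 23)
  m <- anfis_train(anfis_init(pl$X, standardize = FALSE), pl$X, pl$y,
                   epochs = 3)
  perm <- sample(nrow(m$rules))
  m2 <- m
  m2$rules <- m$rules[perm, , drop = FALSE]
  m2$consequents <- m$consequents[perm, , drop = FALSE]
  expect_equal(predict(m2, pl$X), predict(m, pl$X))
})

test_that("inputs outside the fuzzified range raise an informative error", {
  X <- matrix(seq(0, 1, length.out = 11), ncol = 1,
              dimnames = list(NULL, "x"))
  m <- anfis_init(X, standardize = FALSE)
  expect_error(predict(m, matrix(-5, dimnames = list(NULL, "x"))),
               "no rule fires")
})

test_that("training recovers a planted model of the same architecture", {
  pl <- make_planted_ts(60, sigma = 0, seed = 24)
  fit <- anfis_train(anfis_init(pl$X, standardize = FALSE), pl$X, pl$y,
                     epochs = 5)
  expect_lt(fit$trace[length(fit$trace)], 1e-3 * var(pl$y))
})

test_that("training rejects invalid configuration", {
  pl <- make_planted_ts(30, seed = 25)
  m <- anfis_init(pl$X)
  expect_error(anfis_train(m, pl$X, pl$y, epochs = 0), "epochs")
  expect_error(anfis_train(m, pl$X, pl$y[-1]), "rows of X")
})

test_that("study-scale training yields a full, non-increasing error trace", {
  sim <- generate_qsar_data(n = 21, seed = 26)
  fit <- anfis(activity ~ A_FC + chi_FC + I_QB7 + nOH,
               cbind(sim$features, activity = sim$activity), epochs = 100)
  expect_length(fit$trace, 100)
  expect_true(all(diff(fit$trace) <= 1e-6 * max(fit$trace) + 1e-10))
})

test_that("with frozen premises repeated least squares cannot increase MSE", {
  pl <- make_planted_ts(40, sigma = 0.5, seed = 27)
  fit <- anfis_train(anfis_init(pl$X, standardize = FALSE), pl$X, pl$y,
                     epochs = 20, learning_rate = 0)  # premises never move
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("test RMSE approaches the planted noise level as n grows", {
  sigma <- 0.5
  pl <- make_planted_ts(400, sigma = sigma, seed = 28)
  fit <- anfis_train(anfis_init(pl$X, standardize = FALSE), pl$X, pl$y,
                     epochs = 20)
  test <- make_planted_ts(400, sigma = sigma, seed = 29)
  rmse <- sqrt(mean((predict(fit, test$X) - test$y)^2))
  expect_lt(rmse, 1.25 * sigma)
  expect_gt(rmse, 0.75 * sigma)
})

test_that("pure-gradient training reduces the error on a smooth target", {
  pl <- make_planted_ts(80, sigma = 0.1, seed = 30)
  fit <- anfis_train(anfis_init(pl$X, standardize = FALSE), pl$X, pl$y,
                     epochs = 50, learning_rate = 0.5, solver = "gradient")
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
})

test_that("formula fit exposes the standard modelling accessors", {
  set.seed(31)
  d <- data.frame(x1 = runif(60), x2 = runif(60))
  d$y <- 2 * d$x1 - d$x2 + rnorm(60, sd = 0.05)
  fit <- anfis(y ~ x1 + x2, d, epochs = 15)
  expect_s3_class(fit, "anfis")
  expect_equal(fitted(fit) + residuals(fit), d$y)
  expect_equal(predict(fit, d[, c("x1", "x2")]), fitted(fit))
  expect_output(print(fit), "4 rules")
  s <- summary(fit)
  expect_output(print(s), "Q-squared")
  expect_gt(s$train_q2, 0.9)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(60, 3))
})

test_that("model serialization round-trips losslessly", {
  sim <- generate_qsar_data(n = 21, seed = 32)
  fit <- anfis(activity ~ A_FC + chi_FC + I_QB7 + nOH,
               cbind(sim$features, activity = sim$activity), epochs = 10)
  tf <- tempfile(fileext = ".json")
  write_anfis(fit, tf)
  back <- read_anfis(tf)
  expect_equal(back$mfs, fit$mfs, tolerance = 0)
  expect_equal(back$consequents, fit$consequents, tolerance = 0)
  expect_equal(back$rules, fit$rules)
  expect_equal(back$scaling, fit$scaling, tolerance = 0)
  expect_equal(back$trace, fit$trace, tolerance = 0)
  expect_equal(predict(back, sim$features), predict(fit, sim$features))
  writeLines("{\"format\": \"other\"}", tf)
  expect_error(read_anfis(tf), "not an anfisqsar model")
})
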