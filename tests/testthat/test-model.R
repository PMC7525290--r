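test_that("an all-zero network predicts exactly 0.5", {
  m <- manual_model(W1 = matrix(0, 18, 4), b1 = rep(0, 4),
                    w2 = rep(0, 4), b2 = 0)
  expect_equal(unname(predict_risk(m, rnorm(18))), 0.5)
})

test_that("predictions stay strictly inside (0, 1)", {
  set.seed(1)
  m <- manual_model(W1 = matrix(rnorm(18 * 8, sd = 0.5), 18, 8),
                    b1 = rnorm(8), w2 = rnorm(8), b2 = 2)
  X <- matrix(rnorm(50 * 18, sd = 3), 50, 18)
  p <- predict_risk(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_risk(m, rnorm(7)), "features")
})

test_that("analytic input gradients match central finite differences", {
  set.seed(11)
  for (i in 1:20) {
    m <- manual_model(W1 = matrix(rnorm(18 * 6), 18, 6), b1 = rnorm(6),
                      w2 = rnorm(6), b2 = rnorm(1))
    m$center <- rnorm(18); m$scale <- runif(18, 0.5, 2)
    x <- rnorm(18)
    g <- predict_risk_gradient(m, x)
    h <- 1e-5
    fd <- vapply(1:18, function(j) {
      xp <- x; xm <- x
      xp[j] <- x[j] + h; xm[j] <- x[j] - h
      (predict_risk(m, xp) - predict_risk(m, xm)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("backprop weight gradients match central finite differences", {
  set.seed(12)
  n <- 7; d <- 5; H <- 3
  X <- matrix(rnorm(n * d), n, d)
  y <- rbinom(n, 1, 0.5)
  W <- list(W1 = matrix(rnorm(d * H), d, H), b1 = rnorm(H),
            w2 = matrix(rnorm(H), H, 1), b2 = rnorm(1))
  loss_of <- function(W) mean((pjaplan:::mlp_forward(W, X)$p - y)^2)
  g <- pjaplan:::mlp_backward(W, X, y, pjaplan:::mlp_forward(W, X))
  h <- 1e-6
  for (k in names(W)) {
    fd <- W[[k]]
    for (i in seq_along(fd)) {
      Wp <- W; Wm <- W
      Wp[[k]][i] <- W[[k]][i] + h
      Wm[[k]][i] <- W[[k]][i] - h
      fd[i] <- (loss_of(Wp) - loss_of(Wm)) / (2 * h)
    }
    expect_equal(as.numeric(g[[k]]), as.numeric(fd), tolerance = 1e-5)
  }
})

test_that("training is bit-reproducible and the loss decreases", {
  set.seed(5)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- as.integer(X[, 1] + 0.3 * rnorm(20) > 0)
  cfg <- train_config(hidden_width = 4, epochs = 400, seed = 99)
  m1 <- train_risk_model(X, y, cfg)
  m2 <- train_risk_model(X, y, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  expect_lte(m1$loss[length(m1$loss)], m1$loss[1])
})

test_that("a separable toy problem trains to low error", {
  set.seed(6)
  X <- cbind(c(rnorm(10, -2), rnorm(10, 2)), rnorm(20))
  y <- rep(c(0, 1), each = 10)
  m <- train_risk_model(X, y, train_config(seed = 1))
  expect_lt(m$loss[length(m$loss)], 0.05)
})

test_that("single-class training warns; bad labels are rejected", {
  X <- matrix(rnorm(10 * 3), 10, 3)
  expect_warning(train_risk_model(X, rep(1, 10),
                                  train_config(epochs = 5)),
                 "single-class")
  expect_error(train_risk_model(X, rep(2, 10), train_config(epochs = 5)),
               "binary")
})

test_that("LOOCV produces one held-out prediction per patient", {
  set.seed(8)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 1] <- X[, 1] + 5 * rep(c(0, 1), each = 6)
  y <- rep(c(0, 1), each = 6)
  cv <- loocv(X, y, train_config(hidden_width = 3, epochs = 500, seed = 2))
  expect_equal(nrow(cv$predictions), n)
  expect_equal(cv$predictions$fold, 1:n)
  expect_true(all(cv$predictions$risk > 0 & cv$predictions$risk < 1))
  expect_gte(cv$accuracy, 0.8)
  expect_error(loocv(X[1:2, ], y[1:2]), "at least 3")
})

test_that("AUC equals the Mann-Whitney statistic with ties as one half", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(13)
  s <- runif(1000); y <- rbinom(1000, 1, 0.5)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.05)
})

test_that("accuracy and AUC agree with an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- runif(n)
    ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                 direction = "<",
                                                 quiet = TRUE)))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("model JSON serialisation round-trips predictions exactly", {
  set.seed(15)
  X <- matrix(rnorm(15 * 18), 15, 18,
              dimnames = list(NULL, feature_names()))
  y <- rbinom(15, 1, 0.4)
  y[1:2] <- c(0, 1)
  m <- train_risk_model(X, y, train_config(epochs = 100, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  m2 <- read_risk_model(path)
  expect_equal(predict_risk(m2, X), predict_risk(m, X), tolerance = 1e-15)
  expect_equal(m2$center, m$center)
})

test_that("risk response is monotone in a single informative feature", {
  set.seed(16)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(X[, 1] > 0)
  m <- train_risk_model(X, y, train_config(hidden_width = 4, seed = 4))
  grid <- seq(min(X[, 1]), max(X[, 1]), length.out = 40)
  probe <- cbind(grid, 0, 0)
  p <- predict_risk(m, probe)
  expect_true(all(diff(p) > -1e-9))
})
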