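test_that("DX score matches the closed form on constructed classes", {
  # class means 0 and 1, both variances 0.5 -> DX = 1
  x1 <- c(0, 1, -1, 0.5, -0.5)          # mean 0
  x1 <- x1 / sd(x1) * sqrt(0.5)
  x2 <- x1 + 1                           # mean 1, same variance
  X <- cbind(f = c(x1, x2), g = rep(1:2, each = 5) * 1.0)
  X[, "g"] <- rnorm(10)                  # uninformative
  y <- rep(c(0, 1), each = 5)
  r <- dx_score(X, y)
  expect_equal(r$score[r$feature == "f"], 1.0, tolerance = 1e-9)
  # identical class means -> DX 0
  X0 <- cbind(h = rep(c(1, 2, 3), 4))
  y0 <- rep(c(0, 1), each = 6)
  expect_equal(dx_score(X0, y0)$score, 0, tolerance = 1e-9)
})

test_that("DX scores are invariant under affine feature rescaling", {
  set.seed(21)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rbinom(30, 1, 0.5); y[1:4] <- c(0, 0, 1, 1)
  r1 <- dx_score(X, y)
  X2 <- sweep(sweep(X, 2, runif(6, 0.5, 4), "*"), 2, rnorm(6), "+")
  r2 <- dx_score(X2, y)
  expect_equal(r1$score, r2$score, tolerance = 1e-9)
  expect_equal(r1$feature, r2$feature)
})

test_that("ranking is invariant to sample order and equivariant in features", {
  set.seed(22)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(40, 1, 0.5); y[1:4] <- c(0, 0, 1, 1)
  perm <- sample(40)
  expect_equal(dx_score(X, y)$score, dx_score(X[perm, ], y[perm])$score)
  cperm <- c(3, 1, 5, 2, 4)
  r1 <- dx_score(X, y); r2 <- dx_score(X[, cperm], y)
  expect_equal(r1$score[order(r1$feature)], r2$score[order(r2$feature)])
})

test_that("top-k selection and impact percentages behave", {
  set.seed(23)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(30, 1, 0.5); y[1:4] <- c(0, 0, 1, 1)
  r <- dx_score(X, y)
  expect_setequal(top_k(r, 4), paste0("f", 1:4))
  expect_equal(impact_percentage(r, r$feature), 100)
  expect_equal(sum(r$impact_pct), 100)
  expect_lte(impact_percentage(r, top_k(r, 2)), 100)
  expect_error(top_k(r, 5), "out of range")
  expect_error(impact_percentage(r, "nope"), "unknown")
})

test_that("the signal-carrying feature ranks first on synthetic data", {
  set.seed(24)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rbinom(n, 1, plogis(3 * X[, 7]))
  if (length(unique(y)) == 2) {
    r <- dx_score(X, y)
    expect_equal(r$feature[1], "f7")
  }
})

test_that("a constant-output model has zero sensitivity everywhere", {
  m <- manual_model(W1 = matrix(0, 18, 4), b1 = rep(0, 4),
                    w2 = rep(0, 4), b2 = 1)
  X <- matrix(rnorm(10 * 18), 10, 18, dimnames = list(NULL, feature_names()))
  rep_ <- sensitivity(m, X, c("age", "dmax_NAR"))
  expect_equal(rep_$max_change_pct, c(0, 0))
})

test_that("features outside the model's support have zero sensitivity", {
  W1 <- matrix(0, 18, 2)
  W1[1, ] <- c(1, -0.5)                # only dmax_FAL enters
  m <- manual_model(W1, b1 = c(0.1, 0.2), w2 = c(1, 1), b2 = 0)
  X <- matrix(rnorm(8 * 18), 8, 18, dimnames = list(NULL, feature_names()))
  rep_ <- sensitivity(m, X, c("dmax_FAL", "age"))
  expect_gt(rep_$max_change_pct[rep_$feature == "dmax_FAL"], 0)
  expect_equal(rep_$max_change_pct[rep_$feature == "age"], 0)
})

test_that("sensitivity is non-decreasing in the perturbation range", {
  set.seed(25)
  m <- manual_model(W1 = matrix(rnorm(18 * 5, sd = 0.3), 18, 5),
                    b1 = rnorm(5, sd = 0.1), w2 = rnorm(5), b2 = 0)
  X <- matrix(rnorm(12 * 18), 12, 18, dimnames = list(NULL, feature_names()))
  subset <- c("dmax_NAR", "davg_NPL", "age")
  s1 <- sensitivity(m, X, subset, range_pct = 1)$max_change_pct
  s5 <- sensitivity(m, X, subset, range_pct = 5)$max_change_pct
  s10 <- sensitivity(m, X, subset, range_pct = 10)$max_change_pct
  expect_true(all(s5 >= s1 - 1e-12))
  expect_true(all(s10 >= s5 - 1e-12))
})

test_that("zero-valued features fall back to additive perturbation", {
  set.seed(26)
  m <- manual_model(W1 = matrix(rnorm(18 * 3, sd = 0.5), 18, 3),
                    b1 = rnorm(3), w2 = rnorm(3), b2 = 0)
  X <- matrix(rnorm(6 * 18), 6, 18, dimnames = list(NULL, feature_names()))
  X[, "gender"] <- c(0, 1, 0, 1, 0, 1)   # contains exact zeros
  rep_ <- sensitivity(m, X, c("gender", "age"))
  expect_true(rep_$additive[rep_$feature == "gender"])
  expect_false(rep_$additive[rep_$feature == "age"])
  expect_gte(rep_$max_change_pct[rep_$feature == "gender"], 0)
})
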