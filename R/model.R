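#' Training configuration for the risk network
#'
#' The risk model is a fully connected network with one hidden layer of
#' width \code{hidden_width} (tanh activation) and a sigmoid output unit,
#' trained full-batch by Adam on the mean squared error between the
#' predicted risk and the binary PJK outcome.
#'
#' @param hidden_width Hidden-layer width. Default 8.
#' @param learning_rate Adam step size. Default 0.01.
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decays and
#'   stabiliser. Defaults 0.9, 0.999, 1e-8.
#' @param epochs Number of full-batch epochs. Default 2000.
#' @param seed Integer seed fixing every random draw (weight
#'   initialisation). Default 1.
#' @param init_scale Multiplier on the Xavier-uniform initialisation
#'   limit. Default 1.
#' @param standardize Standardise features with training-set statistics
#'   before fitting. Default TRUE.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(hidden_width = 8, learning_rate = 0.01,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_epsilon = 1e-8, epochs = 2000, seed = 1,
                         init_scale = 1, standardize = TRUE) {
  vals <- c(hidden_width, learning_rate, adam_beta1, adam_beta2,
            adam_epsilon, epochs, init_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all training configuration values must be positive")
  if (adam_beta1 >= 1 || adam_beta2 >= 1)
    stop("Adam moment decays must be < 1")
  structure(list(hidden_width = as.integer(hidden_width),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_scale = init_scale, standardize = isTRUE(standardize)),
            class = "train_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# evaluate the RNG-consuming expression under a local seed, leaving the
# caller's RNG state untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

init_weights <- function(n_in, h, init_scale) {
  lim1 <- init_scale * sqrt(6 / (n_in + h))
  lim2 <- init_scale * sqrt(6 / (h + 1))
  list(W1 = matrix(stats::runif(n_in * h, -lim1, lim1), n_in, h),
       b1 = numeric(h),
       w2 = matrix(stats::runif(h, -lim2, lim2), h, 1),
       b2 = 0)
}

mlp_forward <- function(W, X) {
  Z <- sweep(X %*% W$W1, 2, W$b1, "+")
  A <- tanh(Z)
  o <- as.numeric(A %*% W$w2) + W$b2
  p <- sigmoid(o)
  list(A = A, p = p)
}

# gradients of the mean-squared-error loss w.r.t. all parameters, plus the
# per-sample gradient of the prediction w.r.t. the (standardised) inputs
mlp_backward <- function(W, X, y, fw) {
  n <- nrow(X)
  dp <- 2 * (fw$p - y) / n
  do_ <- dp * fw$p * (1 - fw$p)
  dW2 <- crossprod(fw$A, do_)              # H x 1
  db2 <- sum(do_)
  dA <- matrix(do_, ncol = 1) %*% t(W$w2)            # n x H
  dZ <- dA * (1 - fw$A^2)
  list(W1 = crossprod(X, dZ), b1 = colSums(dZ), w2 = dW2, b2 = db2)
}

#' Train the two-layer PJK risk network
#'
#' Minimises the mean squared error between the sigmoid network output and
#' the binary outcome by full-batch Adam.  Bit-reproducible for a fixed
#' configuration seed.
#'
#' @param features Numeric matrix, one row per patient, columns in
#'   \code{feature_names()} order (or any fixed feature set).
#' @param labels Binary outcome vector (1 = PJK).
#' @param config A \code{train_config}.
#' @return An object of class \code{risk_model}: weights, standardisation
#'   statistics captured from the training set, the loss trajectory and
#'   the configuration.
#' @export
train_risk_model <- function(features, labels, config = train_config()) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (length(unique(y)) < 2)
    warning("single-class training set: model may output a constant")

  if (config$standardize) {
    st <- standardize_fit(X)
    Xs <- st$X; center <- st$center; scale <- st$scale
  } else {
    Xs <- X
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }

  W <- with_local_seed(config$seed,
                       init_weights(ncol(X), config$hidden_width,
                                    config$init_scale))
  m <- lapply(W, function(w) w * 0)
  v <- lapply(W, function(w) w * 0)
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  eps <- config$adam_epsilon; lr <- config$learning_rate
  loss <- numeric(config$epochs)
  for (t in seq_len(config$epochs)) {
    fw <- mlp_forward(W, Xs)
    loss[t] <- mean((fw$p - y)^2)
    g <- mlp_backward(W, Xs, y, fw)
    for (k in names(W)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^t)
      vhat <- v[[k]] / (1 - b2^t)
      W[[k]] <- W[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(W1 = W$W1, b1 = W$b1, w2 = W$w2, b2 = W$b2,
                 center = center, scale = scale,
                 feature_names = colnames(X), loss = loss, config = config),
            class = "risk_model")
}

#' Predict PJK risk for one or more feature vectors
#'
#' @param model A trained \code{risk_model}.
#' @param x Feature vector (length matching the training features) or a
#'   matrix with one row per patient, on the raw feature scale.
#' @return Predicted risk(s) in (0, 1).
#' @export
predict_risk <- function(model, x) {
  stopifnot(inherits(model, "risk_model"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != nrow(model$W1))
    stop(sprintf("expected %d features, got %d", nrow(model$W1), ncol(X)))
  Xs <- standardize_apply(X, model$center, model$scale)
  mlp_forward(model, Xs)$p
}

#' Gradient of the predicted risk with respect to the raw inputs
#'
#' Analytic chain-rule gradient through the standardisation and both
#' layers; used by the PJA optimiser.
#'
#' @param model A trained \code{risk_model}.
#' @param x A single feature vector on the raw scale.
#' @return Numeric gradient vector, same length as \code{x}.
#' @export
predict_risk_gradient <- function(model, x) {
  stopifnot(inherits(model, "risk_model"))
  xs <- as.numeric(standardize_apply(matrix(x, nrow = 1),
                                     model$center, model$scale))
  z <- as.numeric(crossprod(model$W1, xs)) + model$b1
  a <- tanh(z)
  p <- sigmoid(sum(a * model$w2) + model$b2)
  dz <- as.numeric(model$w2) * (1 - a^2) * p * (1 - p)
  as.numeric(model$W1 %*% dz) / model$scale
}

#' Leave-one-out cross-validation of the risk network
#'
#' Each fold trains on n - 1 patients (re-standardising within the fold)
#' and predicts the held-out patient; the per-fold seed is derived from
#' the configuration seed.
#'
#' @param features Feature matrix, one row per patient.
#' @param labels Binary outcomes.
#' @param config A \code{train_config}.
#' @param threshold Classification threshold on the predicted risk.
#'   Default 0.5.
#' @return A list with \code{predictions} (data frame: id, risk, label,
#'   fold, single_class_fold), \code{accuracy}, and \code{auc}.
#' @export
loocv <- function(features, labels, config = train_config(),
                  threshold = 0.5) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs at least 3 patients")
  risk <- numeric(n)
  single_class <- logical(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    tr <- setdiff(seq_len(n), i)
    single_class[i] <- length(unique(y[tr])) < 2
    fit <- suppressWarnings(train_risk_model(X[tr, , drop = FALSE], y[tr],
                                             cfg_i))
    risk[i] <- predict_risk(fit, X[i, , drop = FALSE])
  }
  pred <- data.frame(id = seq_len(n), risk = risk, label = y,
                     fold = seq_len(n), single_class_fold = single_class)
  acc <- mean((risk >= threshold) == (y == 1))
  auc <- if (length(unique(y)) == 2) roc_auc(risk, y) else NA_real_
  list(predictions = pred, accuracy = acc, auc = auc)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random PJK case is
#' ranked above a random non-PJK case, counting ties as one half.
#'
#' @param scores Predicted risks.
#' @param labels Binary outcomes (1 = positive class).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(scores) != length(y)) stop("length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Two-layer PJK risk network\n")
  cat(sprintf("  input %d -> hidden %d (tanh) -> 1 (sigmoid)\n",
              nrow(x$W1), ncol(x$W1)))
  cat(sprintf("  trained %d epochs, final MSE %.4g\n",
              length(x$loss), x$loss[length(x$loss)]))
  invisible(x)
}

#' Serialise a risk model to JSON
#'
#' @param model A \code{risk_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(
    type = "pjaplan_risk_model",
    hidden_width = ncol(model$W1),
    n_features = nrow(model$W1),
    feature_names = model$feature_names,
    W1 = model$W1, b1 = model$b1,
    w2 = as.numeric(model$w2), b2 = model$b2,
    center = model$center, scale = model$scale,
    final_loss = model$loss[length(model$loss)],
    config = unclass(model$config)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a risk model from JSON
#'
#' @param path Path written by \code{write_risk_model}.
#' @return A \code{risk_model} (loss trajectory reduced to the stored
#'   final value).
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "pjaplan_risk_model"))
    stop("not a pjaplan risk model file")
  cfg <- do.call(train_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(W1 = matrix(obj$W1, obj$n_features, obj$hidden_width),
                 b1 = as.numeric(obj$b1),
                 w2 = matrix(obj$w2, ncol = 1), b2 = obj$b2,
                 center = stats::setNames(as.numeric(obj$center),
                                          obj$feature_names),
                 scale = stats::setNames(as.numeric(obj$scale),
                                         obj$feature_names),
                 feature_names = obj$feature_names,
                 loss = obj$final_loss, config = cfg),
            class = "risk_model")
}
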