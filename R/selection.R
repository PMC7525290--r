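#' DX discrimination score feature ranking
#'
#' For each feature the DX score is the squared difference of the class
#' means divided by the sum of the class (sample) variances:
#' \deqn{DX_j = (\mu_{j,PJK} - \mu_{j,nonPJK})^2 / (\sigma^2_{j,PJK} +
#'   \sigma^2_{j,nonPJK})}
#' A small guard (1e-12) is added to the denominator so that features that
#' are constant within both classes score 0 rather than NaN.
#'
#' @param features Feature matrix, one row per patient.
#' @param labels Binary outcomes (1 = PJK).
#' @return An object of class \code{feature_ranking}: a data frame with
#'   columns \code{feature}, \code{score}, \code{rank} and
#'   \code{impact_pct} (score as a percentage of the total score), ordered
#'   by descending score with ties broken by the fixed feature order.
#' @export
dx_score <- function(features, labels) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("each class needs at least 2 samples for a variance")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  v1 <- apply(X[y == 1, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[y == 0, , drop = FALSE], 2, stats::var)
  score <- (m1 - m0)^2 / (v1 + v0 + 1e-12)
  ord <- order(-score, seq_along(score))
  total <- sum(score)
  out <- data.frame(feature = colnames(X)[ord], score = score[ord],
                    rank = seq_along(score),
                    impact_pct = if (total > 0) 100 * score[ord] / total
                                 else rep(0, length(score)),
                    row.names = NULL)
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Top-k features from a DX ranking
#'
#' @param ranking A \code{feature_ranking}.
#' @param k Number of features to keep.
#' @return Character vector of the k highest-scoring feature names.
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k < 1 || k > nrow(ranking)) stop("k out of range")
  ranking$feature[seq_len(k)]
}

#' Combined impact percentage of a feature subset
#'
#' @param ranking A \code{feature_ranking}.
#' @param subset Character vector of feature names.
#' @return Sum of the subset's DX scores as a percentage of the total.
#' @export
impact_percentage <- function(ranking, subset) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!all(subset %in% ranking$feature)) stop("unknown feature in subset")
  sum(ranking$impact_pct[ranking$feature %in% subset])
}

#' Perturbation sensitivity of the trained risk model
#'
#' For each feature in \code{subset} and each patient, the predicted risk
#' is re-evaluated with that feature perturbed multiplicatively,
#' x_j (1 + delta), for delta on a symmetric 11-point grid spanning
#' +/- \code{range_pct}\%.  Features whose cohort value is (near) zero are
#' perturbed additively by delta times the feature's cohort standard
#' deviation instead, and flagged.  The per-feature statistic is the
#' maximum relative change of the predicted risk (percent of the
#' unperturbed risk) over patients and grid points.
#'
#' @param model A trained \code{risk_model}.
#' @param features Cohort feature matrix (raw scale).
#' @param subset Character vector of feature names to perturb.
#' @param range_pct Perturbation half-range in percent. Default 5.
#' @param n_grid Number of grid points (odd, includes 0). Default 11.
#' @return An object of class \code{sensitivity_report}: data frame with
#'   columns \code{feature}, \code{max_change_pct}, \code{additive} and
#'   one \code{patient_<i>} column per patient (per-patient maximum
#'   relative change, percent).
#' @export
sensitivity <- function(model, features, subset, range_pct = 5,
                        n_grid = 11) {
  stopifnot(inherits(model, "risk_model"))
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- model$feature_names
  if (length(subset) == 0 || !all(subset %in% colnames(X)))
    stop("subset must name columns of the feature matrix")
  if (n_grid %% 2 == 0) n_grid <- n_grid + 1
  deltas <- seq(-range_pct / 100, range_pct / 100, length.out = n_grid)
  base <- as.numeric(predict_risk(model, X))
  n <- nrow(X)
  rows <- vector("list", length(subset))
  for (s in seq_along(subset)) {
    j <- match(subset[s], colnames(X))
    sdj <- stats::sd(X[, j])
    additive <- any(abs(X[, j]) < 1e-12)
    per_patient <- numeric(n)
    for (d in deltas) {
      Xp <- X
      Xp[, j] <- if (additive) X[, j] + d * sdj else X[, j] * (1 + d)
      p <- as.numeric(predict_risk(model, Xp))
      per_patient <- pmax(per_patient, abs(p - base) / pmax(base, 1e-12))
    }
    rows[[s]] <- data.frame(feature = subset[s],
                            max_change_pct = 100 * max(per_patient),
                            additive = additive,
                            t(stats::setNames(100 * per_patient,
                                              paste0("patient_", seq_len(n)))))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}
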