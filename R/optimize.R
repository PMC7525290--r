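#' Per-subregion summaries of the unit-load stress field
#'
#' Solves the FEM once with a unit load (G = 1 N, alpha = 0, so F = 1 N)
#' and returns the 16 stress summaries.  Because the model is linear, the
#' summaries for any load case are this vector times F = G cos(alpha),
#' which makes the risk curve over alpha cheap and exact.
#'
#' @param mesh A labelled \code{tet_mesh}.
#' @param materials A \code{material_params}.
#' @return Named 16-vector of unit-load summaries (MPa per N).
#' @export
unit_stress_summary <- function(mesh, materials = material_params()) {
  sol <- assemble_and_solve(mesh, materials, load_case(G = 1, alpha = 0))
  s <- summary_to_vector(summarize_stress(sol, mesh))
  names(s) <- feature_names()[1:16]
  s
}

#' Define a PJA optimisation problem for one patient
#'
#' @param patient List (or one-row data frame) with \code{G} (N, gravity
#'   above the UIV), \code{pre_pja} (degrees), \code{age} (years) and
#'   \code{gender} ("M"/"F" or 0/1).
#' @param model A trained \code{risk_model}.
#' @param unit_summary 16-vector from \code{unit_stress_summary} for the
#'   patient's disc geometry.
#' @param bounds Feasible post-operative PJA range, degrees. Default
#'   c(0, 45).
#' @param tolerance Risk tolerance for tie-breaking. Default 1e-3.
#' @return An object of class \code{pja_problem}.
#' @export
pja_problem <- function(patient, model, unit_summary,
                        bounds = c(0, 45), tolerance = 1e-3) {
  stopifnot(inherits(model, "risk_model"), length(unit_summary) == 16)
  need <- c("G", "pre_pja", "age", "gender")
  if (!all(need %in% names(patient)))
    stop("patient must provide G, pre_pja, age, gender")
  if (bounds[1] >= bounds[2] || bounds[1] < 0 || bounds[2] >= 90)
    stop("bounds must satisfy 0 <= lo < hi < 90 degrees")
  structure(list(patient = patient, model = model,
                 unit_summary = as.numeric(unit_summary),
                 pre_summary = as.numeric(unit_summary) *
                   compute_loading_force(patient$G, patient$pre_pja),
                 bounds = bounds, tolerance = tolerance),
            class = "pja_problem")
}

#' Predicted PJK risk as a function of the post-operative PJA
#'
#' Uses the linear scaling of the stress field in the load magnitude:
#' the post-operative summaries are the unit-load summaries times
#' G cos(alpha), so no FEM re-solve is needed per angle.
#'
#' @param problem A \code{pja_problem}.
#' @param alpha Post-operative PJA, degrees (vectorised).
#' @return Predicted risk(s) in (0, 1).
#' @export
risk_of_alpha <- function(problem, alpha) {
  stopifnot(inherits(problem, "pja_problem"))
  if (any(alpha < problem$bounds[1] - 1e-9) ||
      any(alpha > problem$bounds[2] + 1e-9))
    stop("alpha outside the problem bounds")
  p <- problem$patient
  F_post <- compute_loading_force(p$G, alpha)
  delta <- outer(F_post, problem$unit_summary) -
    matrix(problem$pre_summary, length(alpha), 16, byrow = TRUE)
  X <- cbind(delta, age = p$age, gender = encode_gender(p$gender))
  colnames(X) <- feature_names()
  as.numeric(predict_risk(problem$model, X))
}

# d(risk)/d(alpha in degrees) via the chain rule through delta(alpha)
risk_alpha_gradient <- function(problem, alpha) {
  p <- problem$patient
  delta <- problem$unit_summary * compute_loading_force(p$G, alpha) -
    problem$pre_summary
  x <- build_feature_vector(stats::setNames(delta, feature_names()[1:16]),
                            p$age, p$gender)
  g <- predict_risk_gradient(problem$model, x)
  arad <- alpha * pi / 180
  sum(g[1:16] * (-problem$unit_summary * p$G * sin(arad))) * pi / 180
}

#' Optimal post-operative PJA for one patient
#'
#' Minimises the predicted PJK risk over the feasible angle range by a
#' coarse grid scan (0.1 degree steps) followed by Adam refinement from
#' the best grid point with the analytic chain-rule gradient.  Angles
#' whose risk lies within \code{tolerance} of the minimum are treated as
#' ties and resolved toward the patient's pre-operative PJA.
#'
#' @param problem A \code{pja_problem}.
#' @param grid_step Grid spacing in degrees. Default 0.1.
#' @param refine_iter Adam refinement iterations. Default 200.
#' @param refine_lr Adam step size in degrees. Default 0.05.
#' @return An object of class \code{pja_result}: \code{alpha_hat}
#'   (degrees), \code{risk} at the optimum, \code{risk_curve} (data frame
#'   alpha/risk over the grid) and \code{diagnostics}.
#' @export
optimal_pja <- function(problem, grid_step = 0.1, refine_iter = 200,
                        refine_lr = 0.05) {
  stopifnot(inherits(problem, "pja_problem"))
  lo <- problem$bounds[1]; hi <- problem$bounds[2]
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  risks <- risk_of_alpha(problem, grid)

  cand_a <- grid; cand_r <- risks
  a <- grid[which.min(risks)]
  m <- 0; v <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(refine_iter)) {
    g <- risk_alpha_gradient(problem, a)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    a <- a - refine_lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    a <- min(max(a, lo), hi)
    cand_a <- c(cand_a, a)
    cand_r <- c(cand_r, risk_of_alpha(problem, a))
  }

  rmin <- min(cand_r)
  flat <- (max(risks) - min(risks)) < problem$tolerance
  ties <- which(cand_r <= rmin + problem$tolerance)
  pick <- ties[which.min(abs(cand_a[ties] - problem$patient$pre_pja))]
  structure(list(
    alpha_hat = cand_a[pick],
    risk = cand_r[pick],
    risk_curve = data.frame(alpha = grid, risk = risks),
    diagnostics = list(flat = flat, grid_min = min(risks),
                       refined_min = rmin, n_ties = length(ties))
  ), class = "pja_result")
}

#' @export
print.pja_result <- function(x, ...) {
  cat("Optimal post-operative PJA\n")
  cat(sprintf("  alpha_hat = %.2f deg, predicted risk %.4f\n",
              x$alpha_hat, x$risk))
  if (x$diagnostics$flat) cat("  note: risk curve is flat over the bounds\n")
  invisible(x)
}
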