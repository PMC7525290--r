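#' Names of the 18 model input features, in the fixed documented order
#'
#' 16 stress-difference features — the per-subregion maximum then the
#' per-subregion volume-weighted average von Mises stress change
#' (post-operative minus pre-operative), each over the eight subregions in
#' \code{subregion_names()} order — followed by age and gender.
#'
#' @return Character vector of length 18.
#' @export
feature_names <- function() {
  c(paste0("dmax_", subregion_names()),
    paste0("davg_", subregion_names()),
    "age", "gender")
}

#' Summarise a stress field over the eight disc subregions
#'
#' @param solution A \code{fem_solution} computed on \code{mesh}.
#' @param mesh The labelled \code{tet_mesh} the solution was computed on.
#' @return An object of class \code{subregion_summary}: a matrix with one
#'   row per subregion and columns \code{max} (maximum element von Mises,
#'   MPa) and \code{avg} (volume-weighted mean element von Mises, MPa).
#' @export
summarize_stress <- function(solution, mesh) {
  stopifnot(inherits(solution, "fem_solution"), inherits(mesh, "tet_mesh"))
  if (is.null(mesh$subregion)) stop("mesh has no subregion labels")
  if (length(solution$von_mises) != nrow(mesh$tets))
    stop("solution and mesh sizes disagree")
  regs <- subregion_names()
  out <- matrix(NA_real_, length(regs), 2,
                dimnames = list(regs, c("max", "avg")))
  for (r in regs) {
    idx <- which(mesh$subregion == r)
    if (length(idx) == 0)
      stop(sprintf("subregion %s is empty: mesh resolution too coarse", r))
    vm <- solution$von_mises[idx]
    v <- mesh$volumes[idx]
    out[r, "max"] <- max(vm)
    out[r, "avg"] <- sum(vm * v) / sum(v)
  }
  structure(out, class = c("subregion_summary", "matrix"))
}

# flatten a subregion summary into the 16-feature order (all max, all avg)
summary_to_vector <- function(summary) {
  c(summary[, "max"], summary[, "avg"])
}

#' Stress-difference features between two operative states
#'
#' Signed difference, post-operative minus pre-operative, of the per-
#' subregion stress summaries.  Both summaries must come from the same
#' disc model.
#'
#' @param pre,post \code{subregion_summary} objects from the pre- and
#'   post-operative load cases on the same mesh.
#' @return Named numeric vector of 16 delta-sigma values (MPa), in
#'   \code{feature_names()} order.
#' @export
delta_features <- function(pre, post) {
  stopifnot(inherits(pre, "subregion_summary"),
            inherits(post, "subregion_summary"))
  if (!identical(dimnames(pre), dimnames(post)))
    stop("pre and post summaries are not on the same model")
  d <- summary_to_vector(post) - summary_to_vector(pre)
  names(d) <- feature_names()[1:16]
  d
}

#' Assemble the 18-dimensional model input
#'
#' @param delta Named 16-vector of stress-difference features (MPa).
#' @param age Age at operation, years.
#' @param gender \code{"M"} or \code{"F"} (encoded M = 0, F = 1), or an
#'   already-encoded 0/1 value.
#' @return Named numeric vector of length 18 in \code{feature_names()} order.
#' @export
build_feature_vector <- function(delta, age, gender) {
  if (length(delta) != 16 || any(!is.finite(delta)))
    stop("delta must be 16 finite values")
  if (missing(age) || is.null(age) || !is.finite(age))
    stop("age is required")
  g <- encode_gender(gender)
  x <- c(as.numeric(delta), age, g)
  names(x) <- feature_names()
  x
}

encode_gender <- function(gender) {
  if (is.character(gender) || is.factor(gender)) {
    gender <- as.character(gender)
    if (!all(gender %in% c("M", "F")))
      stop("gender must be 'M' or 'F'")
    as.numeric(gender == "F")
  } else if (all(gender %in% c(0, 1))) {
    as.numeric(gender)
  } else stop("gender must be 'M'/'F' or 0/1")
}

# Column standardisation with zero-variance guard.  Returns the scaled
# matrix and the statistics so test cases can be transformed with
# training-set statistics only.
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

standardize_apply <- function(X, center, scale) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, center), 2, scale, "/")
}
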