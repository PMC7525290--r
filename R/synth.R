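#' The packaged twelve-patient cohort table
#'
#' The published adolescent-idiopathic-scoliosis cohort used to develop
#' the planning approach: 12 patients followed at least two years after
#' long posterior instrumentation and fusion, of whom 3 developed proximal
#' junctional kyphosis.  Columns: patient id, PJK outcome (0/1), weight
#' (kg), age at operation (years), gender, the originally reported model
#' output (\code{reported_risk}), pre-operative PJA, applied
#' post-operative PJA and the originally reported optimal post-operative
#' PJA (degrees).
#'
#' @return A 12-row data frame.
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort12.csv", package = "pjaplan",
                      mustWork = TRUE)
  read_cohort_csv(path)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the developmental cohort's envelope: weight uniform on
#' 32.5-71 kg, age uniform on 13-20 years, pre-operative PJA normal
#' (mean 7 deg, sd 5 deg) truncated to [0, 20] deg, 2/3 female, and a
#' target PJK prevalence around 25 percent (3/12).
#'
#' @param n Cohort size (>= 4).
#' @param seed Integer seed; fixes every random draw.
#' @param weight_range,age_range,pre_pja_range Demographic ranges.
#' @param pre_pja_mean,pre_pja_sd Pre-op PJA truncated-normal parameters.
#' @param post_pja_shift_sd SD of the (zero-mean) intra-operative PJA
#'   change, degrees. Default 5.
#' @param prob_female Probability of gender F. Default 2/3.
#' @param mechanism_feature Name of the stress feature that drives risk.
#'   Default \code{"dmax_NAR"} (max-stress change, right anterior
#'   nucleus).
#' @param beta0,beta1 Risk mechanism intercept and slope on the
#'   cohort-standardised mechanism feature. Defaults -1.4 and 2.5.
#' @param label_rule \code{"bernoulli"} (draw labels with probability
#'   sigmoid(beta0 + beta1 z)) or \code{"threshold"} (deterministic
#'   label, 1 when beta0 + beta1 z > 0).
#' @param margin Class-separation margin for the threshold rule, in
#'   standardised units of the mechanism feature: the generator
#'   oversamples patients and keeps only those whose mechanism feature
#'   lies outside the band of half-width \code{margin} around the
#'   decision boundary, so the two classes are separated by a gap.
#'   0 (default) disables the margin; requires the threshold rule.
#' @param geometry_jitter Relative jitter of the disc radii/height per
#'   patient (uniform +/- this fraction); nucleus_scale is jittered by
#'   +/- half this fraction absolute. Default 0.1.
#' @param feature_noise_sd SD of independent additive Gaussian noise per
#'   stress feature, expressed as a fraction of that feature's cohort
#'   standard deviation.  It emulates patient-specific disc-shape effects
#'   that the parametric jitter cannot represent: the idealised geometry
#'   keeps the 16 features nearly proportional across patients, so without
#'   this term a single-feature mechanism would not be identifiable by
#'   any ranking method.  The mechanism acts on the noisy feature.
#'   Default 0.35.
#' @param uiv_fraction Fraction of body weight above the UIV. Default 0.5.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n = 60, seed = 1,
                         weight_range = c(32.5, 71),
                         age_range = c(13, 20),
                         pre_pja_range = c(0, 20),
                         pre_pja_mean = 7, pre_pja_sd = 5,
                         post_pja_shift_sd = 5,
                         prob_female = 2 / 3,
                         mechanism_feature = "dmax_NAR",
                         beta0 = -1.4, beta1 = 2.5,
                         label_rule = c("bernoulli", "threshold"),
                         margin = 0,
                         geometry_jitter = 0.1,
                         feature_noise_sd = 0.35,
                         uiv_fraction = 0.5) {
  if (n < 4) stop("n must be at least 4")
  label_rule <- match.arg(label_rule)
  if (!mechanism_feature %in% feature_names()[1:16])
    stop("mechanism_feature must be one of the 16 stress features")
  if (margin < 0) stop("margin must be non-negative")
  if (margin > 0 && label_rule != "threshold")
    stop("a separation margin requires the threshold label rule")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 weight_range = weight_range, age_range = age_range,
                 pre_pja_range = pre_pja_range, pre_pja_mean = pre_pja_mean,
                 pre_pja_sd = pre_pja_sd,
                 post_pja_shift_sd = post_pja_shift_sd,
                 prob_female = prob_female,
                 mechanism_feature = mechanism_feature,
                 beta0 = beta0, beta1 = beta1, label_rule = label_rule,
                 margin = margin,
                 geometry_jitter = geometry_jitter,
                 feature_noise_sd = feature_noise_sd,
                 uiv_fraction = uiv_fraction),
            class = "synth_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic patient cohort with a known risk mechanism
#'
#' Samples demographics from the configured ranges, assigns each patient
#' a disc geometry jittered around the default, computes the true stress
#' features through the FEM and feature modules (one unit-load solve per
#' patient), and assigns PJK labels from the configured mechanism on one
#' designated stress feature.  Identical seeds give identical cohorts.
#'
#' @param config A \code{synth_config}.
#' @param materials Material constants used for the FEM solves.
#' @return A list with \code{cohort} (data frame in the cohort-CSV
#'   layout), \code{features} (n x 18 matrix in \code{feature_names()}
#'   order), \code{unit_summaries} (n x 16, per-patient unit-load
#'   summaries), \code{geometries} (list of \code{disc_geometry}) and
#'   \code{truth} (the generating mechanism: feature name, beta0, beta1,
#'   standardisation statistics, label rule, seed).
#' @export
generate_cohort <- function(config = synth_config(),
                            materials = material_params()) {
  stopifnot(inherits(config, "synth_config"))
  n_target <- config$n
  # with a separation margin, oversample and keep patients clear of the
  # decision boundary
  n <- if (config$margin > 0) as.integer(ceiling(1.6 * n_target) + 8)
       else n_target
  with_local_seed(config$seed, {
    weight <- stats::runif(n, config$weight_range[1], config$weight_range[2])
    age <- round(stats::runif(n, config$age_range[1], config$age_range[2]))
    gender <- ifelse(stats::runif(n) < config$prob_female, "F", "M")
    pre_pja <- rtruncnorm1(n, config$pre_pja_mean, config$pre_pja_sd,
                           config$pre_pja_range[1], config$pre_pja_range[2])
    post_pja <- rtruncnorm1(n, pre_pja, config$post_pja_shift_sd,
                            0, 30)
    jit <- config$geometry_jitter
    geoms <- lapply(seq_len(n), function(i) {
      disc_geometry(
        lateral_radius = 20 * (1 + stats::runif(1, -jit, jit)),
        ap_radius = 14 * (1 + stats::runif(1, -jit, jit)),
        height = 8 * (1 + stats::runif(1, -jit, jit)),
        nucleus_scale = 0.6 + stats::runif(1, -jit / 2, jit / 2)
      )
    })

    unit_summaries <- matrix(NA_real_, n, 16,
                             dimnames = list(NULL, feature_names()[1:16]))
    for (i in seq_len(n)) {
      mesh <- build_disc_mesh(geoms[[i]])
      unit_summaries[i, ] <- unit_stress_summary(mesh, materials)
    }

    G <- body_weight_to_G(weight, config$uiv_fraction)
    f_pre <- compute_loading_force(G, pre_pja)
    f_post <- compute_loading_force(G, post_pja)
    delta <- unit_summaries * (f_post - f_pre)
    if (config$feature_noise_sd > 0) {
      sds <- apply(delta, 2, stats::sd)
      sds[!is.finite(sds)] <- 0
      delta <- delta + sweep(matrix(stats::rnorm(n * 16), n, 16), 2,
                             sds, "*") * config$feature_noise_sd
    }
    features <- cbind(delta, age = age, gender = as.numeric(gender == "F"))
    colnames(features) <- feature_names()

    z_raw <- delta[, config$mechanism_feature]
    z_center <- mean(z_raw); z_scale <- stats::sd(z_raw)
    if (!is.finite(z_scale) || z_scale < 1e-12) z_scale <- 1
    eta <- config$beta0 + config$beta1 * (z_raw - z_center) / z_scale
    label <- if (config$label_rule == "bernoulli") {
      as.integer(stats::runif(n) < sigmoid(eta))
    } else {
      as.integer(eta > 0)
    }
    keep <- seq_len(n)
    if (config$margin > 0) {
      zstd <- (z_raw - z_center) / z_scale
      q <- -config$beta0 / config$beta1
      clear <- which(abs(zstd - q) > config$margin)
      if (length(clear) < n_target)
        stop("margin too wide: not enough patients clear of the boundary")
      keep <- clear[seq_len(n_target)]
    }
    label <- label[keep]
    if (length(unique(label)) < 2)
      warning("mechanism produced a single class at this n; resample with ",
              "another seed or adjust beta0")

    cohort <- data.frame(id = seq_along(keep), pjk = label,
                         weight_kg = weight[keep], age_years = age[keep],
                         gender = gender[keep],
                         pre_pja_deg = pre_pja[keep],
                         post_pja_deg = post_pja[keep])
    list(cohort = cohort, features = features[keep, , drop = FALSE],
         unit_summaries = unit_summaries[keep, , drop = FALSE],
         geometries = geoms[keep],
         truth = list(mechanism_feature = config$mechanism_feature,
                      beta0 = config$beta0, beta1 = config$beta1,
                      z_center = z_center, z_scale = z_scale,
                      label_rule = config$label_rule,
                      margin = config$margin, seed = config$seed))
  })
}
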