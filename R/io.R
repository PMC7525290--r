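cohort_required_cols <- c("id", "pjk", "weight_kg", "age_years", "gender",
                          "pre_pja_deg", "post_pja_deg")

#' Read a patient cohort table
#'
#' Required columns: id, pjk (0/1), weight_kg, age_years, gender (M/F),
#' pre_pja_deg, post_pja_deg.  Additional columns (for example
#' \code{reported_risk}) are kept as-is.
#'
#' @param path CSV file path.
#' @return Data frame, one row per patient.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("weight_kg", "age_years", "pre_pja_deg", "post_pja_deg")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop(sprintf("non-numeric value in column %s (row %s)", col,
                   paste(bad, collapse = ", ")))
    }
  }
  if (!all(df$pjk %in% c(0, 1)))
    stop("pjk labels must be 0 or 1 (rows ",
         paste(which(!df$pjk %in% c(0, 1)), collapse = ", "), ")")
  if (!all(df$gender %in% c("M", "F")))
    stop("gender must be 'M' or 'F' (rows ",
         paste(which(!df$gender %in% c("M", "F")), collapse = ", "), ")")
  if (any(df$weight_kg <= 0)) stop("weights must be positive")
  if (any(df$pre_pja_deg < 0 | df$pre_pja_deg >= 90) ||
      any(df$post_pja_deg < 0 | df$post_pja_deg >= 90))
    stop("PJA values must lie in [0, 90) degrees")
  df
}

#' Write a patient cohort table
#'
#' @param cohort Data frame with the documented cohort columns.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing_cols <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a tetrahedral mesh as legacy ASCII VTK
#'
#' Writes an unstructured grid with the tetrahedral cells and the
#' "component" and "subregion" cell-data arrays (integer-coded, with the
#' coding recorded in the header comment line is not possible in legacy
#' VTK, so components are 0 = annulus, 1 = nucleus and subregions are
#' 1..8 in \code{subregion_names()} order).
#'
#' @param mesh A \code{tet_mesh}.
#' @param path Output .vtk path.
#' @param cell_scalars Optional named list of extra per-element numeric
#'   arrays.
#' @param point_vectors Optional named list of per-node 3-column matrices.
#' @return \code{path}, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, cell_scalars = NULL,
                           point_vectors = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n_nodes <- nrow(mesh$nodes); n_el <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "pjaplan disc mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n_nodes)), con)
  utils::write.table(format(mesh$nodes, scientific = TRUE, digits = 10),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", n_el, 5 * n_el), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", n_el), con)
  writeLines(as.character(rep(10L, n_el)), con)

  writeLines(sprintf("CELL_DATA %d", n_el), con)
  writeLines(c("SCALARS component int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$component == "nucleus")), con)
  writeLines(c("SCALARS subregion int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$subregion)), con)
  for (nm in names(cell_scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cell_scalars[[nm]], scientific = TRUE, digits = 10),
               con)
  }
  if (!is.null(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", n_nodes), con)
    for (nm in names(point_vectors)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      utils::write.table(format(point_vectors[[nm]], scientific = TRUE,
                                digits = 10), con, row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' Export a FEM solution as legacy ASCII VTK
#'
#' Cell data "von_mises" (MPa) plus point-data "displacement" (mm) on the
#' mesh the solution was computed on.
#'
#' @param solution A \code{fem_solution}.
#' @param mesh The \code{tet_mesh} it was computed on.
#' @param path Output .vtk path.
#' @return \code{path}, invisibly.
#' @export
write_vtk_solution <- function(solution, mesh, path) {
  stopifnot(inherits(solution, "fem_solution"))
  write_vtk_mesh(mesh, path,
                 cell_scalars = list(von_mises = solution$von_mises),
                 point_vectors = list(displacement =
                                        solution$displacements))
}

default_run_config <- function() {
  list(
    geometry = list(lateral_radius = 20, ap_radius = 14, height = 8,
                    nucleus_scale = 0.6, n_radial = 4,
                    n_circumferential = 16, n_axial = 4),
    materials = list(nucleus = list(E = 1.0, nu = 0.49),
                     annulus = list(E = 3.4, nu = 0.45)),
    load = list(uiv_fraction = 0.5, gravity = 9.81),
    training = list(hidden_width = 8, learning_rate = 0.01,
                    adam_beta1 = 0.9, adam_beta2 = 0.999,
                    adam_epsilon = 1e-8, epochs = 2000, init_scale = 1,
                    standardize = TRUE),
    optimization = list(bounds = c(0, 45), tolerance = 1e-3,
                        grid_step = 0.1),
    seed = 1
  )
}

#' Read and validate a run configuration
#'
#' YAML file with blocks \code{geometry}, \code{materials}, \code{load},
#' \code{training}, \code{optimization} and a top-level \code{seed};
#' every key is validated against the schema and unknown keys are
#' rejected.  Missing keys take the documented defaults.
#'
#' @param path YAML path, or NULL for the defaults.
#' @return A validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "config")
  }
  validate_run_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) stop(sprintf("config block '%s' must be a mapping",
                                   where))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key '%s' in '%s'", unknown[1], where))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]], paste(where, k, sep = "."))
    else user[[k]]
  }
  base
}

validate_run_config <- function(cfg) {
  g <- cfg$geometry
  do.call(disc_geometry, g)               # validates geometry block
  do.call(material_params, cfg$materials) # validates materials block
  if (cfg$load$uiv_fraction <= 0 || cfg$load$uiv_fraction > 1)
    stop("load.uiv_fraction must lie in (0, 1]")
  do.call(train_config,
          c(cfg$training, list(seed = cfg$seed)))
  ob <- cfg$optimization$bounds
  if (length(ob) != 2 || ob[1] >= ob[2] || ob[1] < 0 || ob[2] >= 90)
    stop("optimization.bounds must satisfy 0 <= lo < hi < 90")
  if (cfg$seed != round(cfg$seed)) stop("seed must be an integer")
  invisible(cfg)
}

config_geometry <- function(cfg) do.call(disc_geometry, cfg$geometry)
config_materials <- function(cfg) do.call(material_params, cfg$materials)
config_training <- function(cfg)
  do.call(train_config, c(cfg$training, list(seed = cfg$seed)))
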