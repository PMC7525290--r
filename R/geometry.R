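#' Disc geometry parameters
#'
#' Parameters of the idealised cephalad intervertebral disc: an elliptic
#' cylinder made of an outer annulus fibrosus and an inner nucleus pulposus.
#' The nucleus occupies the region inside the inner ellipse whose semi-axes
#' are the outer semi-axes scaled by \code{nucleus_scale}.
#'
#' Coordinate convention: +x = patient left, +y = anterior, +z = cephalad;
#' origin at the centroid of the inferior face.
#'
#' @param lateral_radius Semi-axis in the lateral (x) direction, mm.
#' @param ap_radius Semi-axis in the anterior-posterior (y) direction, mm.
#' @param height Disc height, mm.
#' @param nucleus_scale Fraction in (0, 1) scaling the inner ellipse that
#'   bounds the nucleus.
#' @param n_radial,n_circumferential,n_axial Mesh resolutions (>= 2):
#'   number of radial rings, circumferential sectors and axial layers.
#' @return An object of class \code{disc_geometry}.
#' @export
disc_geometry <- function(lateral_radius = 20, ap_radius = 14, height = 8,
                          nucleus_scale = 0.6, n_radial = 4,
                          n_circumferential = 16, n_axial = 4) {
  if (!all(is.finite(c(lateral_radius, ap_radius, height))) ||
      lateral_radius <= 0 || ap_radius <= 0 || height <= 0)
    stop("disc dimensions must be positive and finite")
  if (!is.finite(nucleus_scale) || nucleus_scale <= 0 || nucleus_scale >= 1)
    stop("nucleus_scale must lie strictly in (0, 1)")
  res <- c(n_radial, n_circumferential, n_axial)
  if (any(res < 2) || any(res != round(res)))
    stop("mesh resolutions must be integers >= 2")
  structure(list(lateral_radius = lateral_radius, ap_radius = ap_radius,
                 height = height, nucleus_scale = nucleus_scale,
                 n_radial = as.integer(n_radial),
                 n_circumferential = as.integer(n_circumferential),
                 n_axial = as.integer(n_axial)),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat("Disc geometry (elliptic cylinder)\n")
  cat(sprintf("  semi-axes: %.6g x %.6g mm, height %.6g mm\n",
              x$lateral_radius, x$ap_radius, x$height))
  cat(sprintf("  nucleus scale: %.6g\n", x$nucleus_scale))
  cat(sprintf("  resolution: %d radial x %d circumferential x %d axial\n",
              x$n_radial, x$n_circumferential, x$n_axial))
  invisible(x)
}

# Split one triangular prism into 3 tetrahedra, cutting every quadrilateral
# face along the diagonal through its smallest global node index.  Because
# the cut depends only on the face, adjacent prisms make matching cuts and
# the tetrahedral mesh is conforming.
split_prism <- function(bot, top) {
  v <- c(bot, top)
  k <- ((which.min(v) - 1L) %% 3L)
  if (k > 0L) {
    rot <- c(((0:2 + k) %% 3L) + 1L)
    bot <- bot[rot]; top <- top[rot]
  }
  p0 <- bot[1]; p1 <- bot[2]; p2 <- bot[3]
  p3 <- top[1]; p4 <- top[2]; p5 <- top[3]
  quad <- c(p1, p2, p5, p4)
  m <- quad[which.min(quad)]
  if (m == p1 || m == p5) {
    rbind(c(p0, p1, p2, p5), c(p0, p1, p5, p4), c(p0, p4, p5, p3))
  } else {
    rbind(c(p0, p1, p2, p4), c(p0, p4, p2, p5), c(p0, p4, p5, p3))
  }
}

#' Signed volumes of tetrahedral elements
#'
#' @param nodes Numeric matrix, one row per node, columns x, y, z (mm).
#' @param tets Integer matrix, one row per element, 4 node indices.
#' @return Numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

element_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
     nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

#' Build the parametric tetrahedral disc mesh
#'
#' Meshes the elliptic-cylinder disc with a structured polar scaffold
#' (centre wedge + quad rings per layer, each cell split into tetrahedra
#' with face-consistent diagonals), labels every element by component
#' (annulus/nucleus) and anatomical subregion, and records the inferior
#' (z = 0) and superior (z = height) boundary node sets.
#'
#' @param params A \code{disc_geometry} object.
#' @return An object of class \code{tet_mesh} with fields \code{nodes},
#'   \code{tets}, \code{component}, \code{subregion}, \code{inferior_nodes},
#'   \code{superior_nodes}, \code{volumes} and \code{params}.
#' @export
build_disc_mesh <- function(params) {
  stopifnot(inherits(params, "disc_geometry"))
  a <- params$lateral_radius; b <- params$ap_radius; h <- params$height
  nr <- params$n_radial; nc <- params$n_circumferential; nz <- params$n_axial

  per_layer <- 1L + nr * nc
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  ring_x <- outer(seq_len(nr) / nr, a * cos(theta))   # nr x nc
  ring_y <- outer(seq_len(nr) / nr, b * sin(theta))
  layer_xy <- rbind(c(0, 0), cbind(as.vector(t(ring_x)), as.vector(t(ring_y))))
  zs <- h * (0:nz) / nz
  nodes <- cbind(
    rep(layer_xy[, 1], nz + 1L),
    rep(layer_xy[, 2], nz + 1L),
    rep(zs, each = per_layer)
  )

  # 2D footprint triangles in within-layer local indices (1-based)
  loc <- function(i, j) 1L + (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  tris <- vector("list", nc * (2L * nr - 1L))
  t_i <- 0L
  for (j in seq_len(nc)) {        # centre wedges
    t_i <- t_i + 1L
    tris[[t_i]] <- c(1L, loc(1L, j), loc(1L, j + 1L))
  }
  for (i in seq_len(nr - 1L)) {   # quad rings, min-index diagonal
    for (j in seq_len(nc)) {
      p00 <- loc(i, j); p10 <- loc(i + 1L, j)
      p11 <- loc(i + 1L, j + 1L); p01 <- loc(i, j + 1L)
      m <- min(p00, p10, p11, p01)
      if (m == p00 || m == p11) {
        t1 <- c(p00, p10, p11); t2 <- c(p00, p11, p01)
      } else {
        t1 <- c(p00, p10, p01); t2 <- c(p10, p11, p01)
      }
      tris[[t_i + 1L]] <- t1; tris[[t_i + 2L]] <- t2
      t_i <- t_i + 2L
    }
  }
  tris <- do.call(rbind, tris)

  tets <- vector("list", nrow(tris) * nz)
  e_i <- 0L
  for (k in seq_len(nz)) {
    off_b <- (k - 1L) * per_layer
    off_t <- k * per_layer
    for (t in seq_len(nrow(tris))) {
      e_i <- e_i + 1L
      tets[[e_i]] <- split_prism(tris[t, ] + off_b, tris[t, ] + off_t)
    }
  }
  tets <- do.call(rbind, tets)

  # orient for positive signed volume (swap last two nodes where negative)
  vol <- tet_volumes(nodes, tets)
  neg <- which(vol < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
    vol[neg] <- -vol[neg]
  }
  if (any(vol <= 0)) stop("mesh contains degenerate or inverted elements")

  cent <- element_centroids(nodes, tets)
  s <- params$nucleus_scale
  inside <- (cent[, 1] / (a * s))^2 + (cent[, 2] / (b * s))^2 <= 1
  component <- ifelse(inside, "nucleus", "annulus")

  mesh <- structure(list(
    nodes = nodes, tets = tets,
    component = component, subregion = NULL,
    inferior_nodes = which(nodes[, 3] <= 0),
    superior_nodes = which(nodes[, 3] >= h - 1e-9 * h),
    volumes = vol, params = params
  ), class = "tet_mesh")
  label_subregions(mesh)
}

#' Label the eight anatomical subregions
#'
#' Each element gets one of eight labels: component (F = annulus fibrosus,
#' N = nucleus) x anterior/posterior (centroid y >= 0 is anterior) x
#' left/right (centroid x >= 0 is left).  Centroids exactly on a dividing
#' plane are assigned to the non-negative side.
#'
#' @param mesh A \code{tet_mesh} with component labels.
#' @return The mesh with a \code{subregion} factor filled in.
#' @export
label_subregions <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"), !is.null(mesh$component))
  cent <- element_centroids(mesh$nodes, mesh$tets)
  comp <- ifelse(mesh$component == "annulus", "F", "N")
  ap <- ifelse(cent[, 2] >= 0, "A", "P")
  lr <- ifelse(cent[, 1] >= 0, "L", "R")
  mesh$subregion <- factor(paste0(comp, ap, lr), levels = subregion_names())
  mesh
}

#' Names of the eight disc subregions, in the package's fixed order
#'
#' F/N = annulus fibrosus / nucleus; A/P = anterior/posterior;
#' L/R = patient left/right.
#' @return Character vector of length 8.
#' @export
subregion_names <- function() {
  c("FAL", "FAR", "FPL", "FPR", "NAL", "NAR", "NPL", "NPR")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral disc mesh\n")
  cat(sprintf("  %d nodes, %d elements (annulus %d, nucleus %d)\n",
              nrow(x$nodes), nrow(x$tets), sum(x$component == "annulus"),
              sum(x$component == "nucleus")))
  cat(sprintf("  volume: %.4g mm^3; inferior/superior boundary nodes: %d/%d\n",
              sum(x$volumes), length(x$inferior_nodes),
              length(x$superior_nodes)))
  if (!is.null(x$subregion)) {
    tab <- table(x$subregion)
    cat("  elements per subregion: ",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
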