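#' Material parameters for the two disc components
#'
#' Linear-elastic, homogeneous, isotropic constants (Hooke's law) for the
#' nucleus pulposus and annulus fibrosus.  Defaults are the standard
#' soft-tissue values used for idealised disc models: nucleus E = 1.0 MPa,
#' nu = 0.49; annulus E = 3.4 MPa, nu = 0.45.
#'
#' @param nucleus,annulus Named lists with entries \code{E} (Young's
#'   modulus, MPa) and \code{nu} (Poisson's ratio).
#' @return An object of class \code{material_params}.
#' @export
material_params <- function(nucleus = list(E = 1.0, nu = 0.49),
                            annulus = list(E = 3.4, nu = 0.45)) {
  for (m in list(nucleus, annulus)) {
    if (!is.finite(m$E) || m$E <= 0) stop("Young's modulus must be positive")
    if (!is.finite(m$nu) || m$nu < 0 || m$nu >= 0.5)
      stop("Poisson's ratio must lie in [0, 0.5)")
  }
  structure(list(nucleus = nucleus, annulus = annulus),
            class = "material_params")
}

#' Loading force magnitude from gravity and the proximal junctional angle
#'
#' The contact force on the disc's superior surface is the component of the
#' supported body weight along the surface normal: F = G * cos(alpha).
#'
#' @param G Gravity force of the body weight above the UIV, N.
#' @param alpha Proximal junctional angle, degrees, in [0, 90).
#' @return Force magnitude, N.
#' @export
compute_loading_force <- function(G, alpha) {
  if (any(!is.finite(G)) || any(G < 0)) stop("G must be non-negative")
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha >= 90))
    stop("alpha must lie in [0, 90) degrees")
  G * cos(alpha * pi / 180)
}

#' Gravity force above the UIV from body weight
#'
#' @param weight Body weight, kg.
#' @param uiv_fraction Fraction of body weight carried above the UIV,
#'   in (0, 1]. Default 0.5.
#' @return Gravity force G, N (g = 9.81 m/s^2).
#' @export
body_weight_to_G <- function(weight, uiv_fraction = 0.5) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be positive")
  if (!is.finite(uiv_fraction) || uiv_fraction <= 0 || uiv_fraction > 1)
    stop("uiv_fraction must lie in (0, 1]")
  weight * 9.81 * uiv_fraction
}

#' Load case for one FEM run
#'
#' @param G Gravity force above the UIV, N.
#' @param alpha PJA, degrees.
#' @return An object of class \code{load_case}; the load direction is fixed
#'   along -z (normal to the superior face), only the magnitude
#'   F = G cos(alpha) depends on alpha.
#' @export
load_case <- function(G, alpha) {
  force <- compute_loading_force(G, alpha)   # validates G, alpha
  structure(list(G = G, alpha = alpha, force = force,
                 direction = c(0, 0, -1)), class = "load_case")
}

# 6x6 isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx)
elasticity_matrix <- function(E, nu) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- E / (2 * (1 + nu))
  D
}

# Strain-displacement matrix (6 x 12) and volume of a linear tetrahedron.
# Shape-function gradients come from inverting [1 | x y z] row-wise.
tet_b_matrix <- function(coords) {
  M <- cbind(1, coords)
  V <- det(M) / 6
  if (!is.finite(V) || abs(V) < .Machine$double.eps * 100)
    stop("degenerate tetrahedron")
  Cinv <- solve(M)
  grads <- Cinv[2:4, , drop = FALSE]   # 3 x 4: d/dx,d/dy,d/dz of N1..N4
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    gx <- grads[1, i]; gy <- grads[2, i]; gz <- grads[3, i]
    col <- 3 * (i - 1)
    B[1, col + 1] <- gx
    B[2, col + 2] <- gy
    B[3, col + 3] <- gz
    B[4, col + 1] <- gy; B[4, col + 2] <- gx
    B[5, col + 2] <- gz; B[5, col + 3] <- gy
    B[6, col + 1] <- gz; B[6, col + 3] <- gx
  }
  list(B = B, V = abs(V))
}

#' Element stiffness matrix of a 4-node tetrahedron
#'
#' Constant-strain formulation: K = V * B' D B.  The matrix is symmetric
#' with exactly six zero-energy modes (rigid translations and infinitesimal
#' rotations).
#'
#' @param tet_coords 4 x 3 matrix of node coordinates (mm).
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @return 12 x 12 stiffness matrix (N/mm scale in the mm-N-MPa system).
#' @export
element_stiffness <- function(tet_coords, E, nu) {
  bb <- tet_b_matrix(tet_coords)
  D <- elasticity_matrix(E, nu)
  bb$V * t(bb$B) %*% D %*% bb$B
}

# Triangles of tets lying on the superior face, and per-node tributary
# areas of a consistently lumped uniform traction (area/3 per vertex).
superior_node_weights <- function(mesh) {
  sup <- mesh$superior_nodes
  in_sup <- logical(nrow(mesh$nodes))
  in_sup[sup] <- TRUE
  w <- numeric(nrow(mesh$nodes))
  hits <- matrix(in_sup[mesh$tets], ncol = 4)
  cand <- which(rowSums(hits) == 3L)
  for (e in cand) {
    tri <- mesh$tets[e, hits[e, ]]
    p <- mesh$nodes[tri, , drop = FALSE]
    ar <- 0.5 * sqrt(sum(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
    w[tri] <- w[tri] + ar / 3
  }
  if (sum(w) <= 0) stop("no superior-face triangles found")
  w / sum(w)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Assemble and solve the linear-elastic system for one load case
#'
#' All inferior-surface nodes are fixed in all three degrees of freedom;
#' the total load F = G cos(alpha) is applied along -z over the superior
#' face, lumped per node in proportion to tributary area.  The constrained
#' system is solved by row/column elimination with a sparse direct
#' factorisation, and the constant element stress tensor is recovered from
#' the displacement gradients via Hooke's law.
#'
#' @param mesh A labelled \code{tet_mesh}.
#' @param materials A \code{material_params} object.
#' @param load A \code{load_case} object.
#' @return An object of class \code{fem_solution}: \code{displacements}
#'   (n_nodes x 3, mm), \code{stress} (n_elements x 6 Voigt, MPa),
#'   \code{von_mises} (per element, MPa), \code{reactions} (forces at
#'   constrained DOFs, N) and the load case.
#' @export
assemble_and_solve <- function(mesh, materials, load) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(materials, "material_params"),
            inherits(load, "load_case"))
  if (length(mesh$inferior_nodes) == 0)
    stop("no constrained nodes: the system is singular")
  n_nodes <- nrow(mesh$nodes)
  n_el <- nrow(mesh$tets)

  Bs <- vector("list", n_el)
  Ds <- list(nucleus = elasticity_matrix(materials$nucleus$E,
                                         materials$nucleus$nu),
             annulus = elasticity_matrix(materials$annulus$E,
                                         materials$annulus$nu))
  ii <- vector("list", n_el); jj <- vector("list", n_el)
  xx <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    tn <- mesh$tets[e, ]
    bb <- tet_b_matrix(mesh$nodes[tn, , drop = FALSE])
    Bs[[e]] <- bb
    D <- Ds[[mesh$component[e]]]
    Ke <- bb$V * crossprod(bb$B, D %*% bb$B)
    dofs <- as.vector(rbind(3 * tn - 2, 3 * tn - 1, 3 * tn))
    ii[[e]] <- rep(dofs, times = 12)
    jj[[e]] <- rep(dofs, each = 12)
    xx[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * n_nodes, 3 * n_nodes))

  f <- numeric(3 * n_nodes)
  w <- superior_node_weights(mesh)
  f[3 * seq_len(n_nodes)] <- load$force * load$direction[3] * w

  fixed_dofs <- as.vector(rbind(3 * mesh$inferior_nodes - 2,
                                3 * mesh$inferior_nodes - 1,
                                3 * mesh$inferior_nodes))
  free <- setdiff(seq_len(3 * n_nodes), fixed_dofs)
  u <- numeric(3 * n_nodes)
  Kff <- K[free, free, drop = FALSE]
  sol <- Matrix::solve(Kff, f[free])
  u[free] <- as.numeric(sol)
  if (any(!is.finite(u))) stop("solver returned non-finite displacements")

  resid <- as.numeric(K %*% u) - f
  reactions <- numeric(3 * n_nodes)
  reactions[fixed_dofs] <- resid[fixed_dofs]

  stress <- matrix(0, n_el, 6,
                   dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  for (e in seq_len(n_el)) {
    tn <- mesh$tets[e, ]
    dofs <- as.vector(rbind(3 * tn - 2, 3 * tn - 1, 3 * tn))
    stress[e, ] <- Ds[[mesh$component[e]]] %*% (Bs[[e]]$B %*% u[dofs])
  }

  structure(list(
    displacements = matrix(u, ncol = 3, byrow = TRUE),
    stress = stress,
    von_mises = von_mises(stress),
    reactions = matrix(reactions, ncol = 3, byrow = TRUE),
    load = load
  ), class = "fem_solution")
}

#' Von Mises equivalent stress
#'
#' Rotation-invariant scalar from the second deviatoric invariant.
#'
#' @param stress Either a symmetric 3 x 3 tensor or a matrix with Voigt
#'   columns (xx, yy, zz, xy, yz, zx), MPa.
#' @return Scalar (or vector, one per row), MPa.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && nrow(stress) == 3 && ncol(stress) == 3) {
    stress <- matrix(c(stress[1, 1], stress[2, 2], stress[3, 3],
                       stress[1, 2], stress[2, 3], stress[3, 1]), nrow = 1)
  }
  sqrt(0.5 * ((stress[, 1] - stress[, 2])^2 +
                (stress[, 2] - stress[, 3])^2 +
                (stress[, 3] - stress[, 1])^2) +
         3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("FEM solution\n")
  cat(sprintf("  load: G = %.4g N, alpha = %.4g deg, F = %.4g N\n",
              x$load$G, x$load$alpha, x$load$force))
  cat(sprintf("  max |u_z| = %.4g mm; von Mises range [%.4g, %.4g] MPa\n",
              max(abs(x$displacements[, 3])), min(x$von_mises),
              max(x$von_mises)))
  invisible(x)
}
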