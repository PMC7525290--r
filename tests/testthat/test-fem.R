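test_that("loading force follows G cos(alpha)", {
  expect_equal(compute_loading_force(100, 0), 100)
  expect_equal(compute_loading_force(200, 60), 100)
  expect_equal(compute_loading_force(300, 8.4), 300 * cos(8.4 * pi / 180))
  expect_error(compute_loading_force(100, 90), "alpha")
  expect_error(compute_loading_force(100, -1), "alpha")
  expect_error(compute_loading_force(-5, 10), "G")
  # monotone decreasing on [0, 90)
  a <- seq(0, 89, by = 1)
  expect_true(all(diff(compute_loading_force(50, a)) < 0))
})

test_that("body weight converts to gravity load above the UIV", {
  expect_equal(body_weight_to_G(49, 0.5), 240.345)
  expect_equal(body_weight_to_G(70, 1.0), 9.81 * 70)
  expect_equal(body_weight_to_G(32.5, 0.5) / body_weight_to_G(71, 0.5),
               32.5 / 71)
  expect_error(body_weight_to_G(0), "positive")
  expect_error(body_weight_to_G(50, 0), "uiv_fraction")
})

test_that("element stiffness is symmetric with six rigid-body modes", {
  set.seed(42)
  coords <- rbind(c(0, 0, 0), c(2, 0.1, 0), c(0.2, 1.5, 0), c(0.1, 0.3, 1.2))
  K <- element_stiffness(coords, E = 3.4, nu = 0.45)
  expect_equal(K, t(K), tolerance = 1e-12)
  # translations
  for (d in 1:3) {
    u <- rep(0, 12); u[seq(d, 12, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-10)
  }
  # infinitesimal rotations about each axis: u = omega x r
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    u <- as.vector(t(t(apply(coords, 1, function(r)
      c(ax[2] * r[3] - ax[3] * r[2], ax[3] * r[1] - ax[1] * r[3],
        ax[1] * r[2] - ax[2] * r[1])))))
    expect_lt(max(abs(K %*% u)), 1e-9)
  }
  expect_equal(sum(abs(eigen(K, only.values = TRUE)$values) < 1e-9), 6)
  expect_error(element_stiffness(rbind(coords[1:3, ], coords[1, ]), 1, 0.3),
               "degenerate")
})

test_that("uniaxial strain energy matches the closed form at nu = 0", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 0.9))
  E <- 2.5; eps <- 0.01
  K <- element_stiffness(coords, E = E, nu = 0)
  u <- rep(0, 12)
  u[seq(3, 12, by = 3)] <- eps * coords[, 3]   # uz = eps * z
  V <- abs(tet_volumes(coords, matrix(1:4, 1)))
  expect_equal(as.numeric(0.5 * t(u) %*% K %*% u), 0.5 * V * E * eps^2,
               tolerance = 1e-12)
})

test_that("uniform pressure patch test is exact at nu = 0", {
  mesh <- build_disc_mesh(small_geometry())
  mats <- material_params(nucleus = list(E = 1, nu = 0),
                          annulus = list(E = 1, nu = 0))
  # meshed superior area (equals meshed footprint area = volume / height)
  area <- sum(mesh$volumes) / mesh$params$height
  p <- 0.1
  sol <- assemble_and_solve(mesh, mats, load_case(G = p * area, alpha = 0))
  expect_equal(unname(sol$stress[, "zz"]), rep(-p, nrow(mesh$tets)),
               tolerance = 1e-8)
  others <- sol$stress[, c("xx", "yy", "xy", "yz", "zx")]
  expect_lt(max(abs(others)), 1e-8 * p)
  expect_equal(sol$von_mises, rep(p, nrow(mesh$tets)), tolerance = 1e-8)
  # top-face axial displacement: -p h / E
  h <- mesh$params$height
  expect_equal(unname(sol$displacements[mesh$superior_nodes, 3]),
               rep(-p * h / 1, length(mesh$superior_nodes)),
               tolerance = 1e-8)
  # fixed nodes do not move
  expect_true(all(sol$displacements[mesh$inferior_nodes, ] == 0))
})

test_that("reactions balance the applied load and the solve is linear", {
  mesh <- build_disc_mesh(small_geometry())
  mats <- material_params()
  s1 <- assemble_and_solve(mesh, mats, load_case(G = 200, alpha = 10))
  F <- compute_loading_force(200, 10)
  expect_equal(sum(s1$reactions[, 3]), F, tolerance = 1e-8 * F)
  expect_lt(abs(sum(s1$reactions[, 1])) + abs(sum(s1$reactions[, 2])),
            1e-8 * F)
  s2 <- assemble_and_solve(mesh, mats, load_case(G = 400, alpha = 10))
  expect_equal(s2$displacements, 2 * s1$displacements, tolerance = 1e-9)
  expect_equal(s2$stress, 2 * s1$stress, tolerance = 1e-9)
  expect_true(all(s1$von_mises >= 0))
})

test_that("stress field scales with G cos(alpha) across angles", {
  mesh <- build_disc_mesh(small_geometry())
  mats <- material_params()
  unit <- assemble_and_solve(mesh, mats, load_case(G = 1, alpha = 0))
  for (a in c(5, 20, 40)) {
    f <- compute_loading_force(150, a)
    sol <- assemble_and_solve(mesh, mats, load_case(G = 150, alpha = a))
    expect_equal(sol$von_mises, f * unit$von_mises, tolerance = 1e-9)
  }
})

test_that("mirrored mesh under the same axial load gives mirrored fields", {
  mesh <- build_disc_mesh(small_geometry())
  mirrored <- mirror_mesh(mesh)
  lc <- load_case(100, 5)
  s1 <- assemble_and_solve(mesh, material_params(), lc)
  s2 <- assemble_and_solve(mirrored, material_params(), lc)
  ref <- max(abs(s1$displacements))
  expect_equal(s2$displacements[, 1], -s1$displacements[, 1],
               tolerance = 1e-8 * ref)
  expect_equal(s2$displacements[, 2:3], s1$displacements[, 2:3],
               tolerance = 1e-8 * ref)
  expect_equal(s2$von_mises, s1$von_mises, tolerance = 1e-8)
})

test_that("von Mises scalarisation is exact on known tensors", {
  expect_equal(von_mises(diag(c(5, 5, 5))), 0)
  expect_equal(von_mises(diag(c(-3, 0, 0))), 3)
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3); S <- (A + t(A)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    oracle <- sqrt(((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                      (ev[3] - ev[1])^2) / 2)
    expect_equal(von_mises(S), oracle, tolerance = 1e-12)
  }
})

test_that("solver rejects a system with no constrained nodes", {
  mesh <- build_disc_mesh(small_geometry())
  mesh$inferior_nodes <- integer(0)
  expect_error(assemble_and_solve(mesh, material_params(),
                                  load_case(100, 0)), "singular")
})
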