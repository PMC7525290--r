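# Shared fixtures: small meshes and hand-built models, constructed in code.

small_geometry <- function(...) {
  disc_geometry(n_radial = 2, n_circumferential = 8, n_axial = 2, ...)
}

# a single regular tetrahedron wrapped as a minimal labelled tet_mesh
toy_tet_mesh <- function(shift = c(0, 0, 0), component = "nucleus") {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  nodes <- sweep(nodes, 2, shift, "+")
  tets <- matrix(1:4, nrow = 1)
  mesh <- structure(list(
    nodes = nodes, tets = tets, component = component, subregion = NULL,
    inferior_nodes = 1L, superior_nodes = 4L,
    volumes = abs(tet_volumes(nodes, tets)),
    params = NULL
  ), class = "tet_mesh")
  label_subregions(mesh)
}

# a risk_model with explicitly chosen weights (identity standardisation)
manual_model <- function(W1, b1, w2, b2, n_features = 18) {
  structure(list(
    W1 = W1, b1 = b1, w2 = matrix(w2, ncol = 1), b2 = b2,
    center = rep(0, n_features), scale = rep(1, n_features),
    feature_names = feature_names()[seq_len(n_features)],
    loss = NA_real_, config = train_config()
  ), class = "risk_model")
}

# model whose output depends on a single stress feature u = x[j] through
# g(u) = sum_k w2_k tanh(k_k (u - u0)); used to build analytic risk curves
single_feature_model <- function(j, ks, w2, u0) {
  W1 <- matrix(0, 18, length(ks))
  W1[j, ] <- ks
  manual_model(W1, b1 = -ks * u0, w2 = w2, b2 = 0)
}

# Analytic optimisation fixture: a model whose output depends on one
# stress feature u through g(u) = A [tanh(k(u-u0)) - tanh(m(u-u0))] + b2.
# With k > m > 0 the bracket has a unique minimum at u - u0 = -d*, where
# d* > 0 solves k sech^2(k d) = m sech^2(m d); u(alpha) = G cos(alpha) -
# G cos(pre_pja) is strictly decreasing in alpha, so choosing u0 places
# the risk minimum at any prescribed angle.
bowl_problem <- function(alpha_star = 7.3, pre_pja = 10, k = 4, m = 1,
                         A = 1e5, bounds = c(0, 45), tolerance = 1e-3) {
  dstar <- uniroot(function(d) k / cosh(k * d)^2 - m / cosh(m * d)^2,
                   c(1e-6, 5), tol = 1e-14)$root
  g_min <- tanh(-k * dstar) - tanh(-m * dstar)
  u_star <- cos(alpha_star * pi / 180) - cos(pre_pja * pi / 180)
  u0 <- u_star + dstar
  model <- single_feature_model(j = 1, ks = c(k, m), w2 = A * c(1, -1),
                                u0 = u0)
  model$b2 <- -A * g_min
  s_unit <- c(1, rep(0, 15))
  patient <- list(G = 1, pre_pja = pre_pja, age = 16, gender = "F")
  pja_problem(patient, model, s_unit, bounds = bounds,
              tolerance = tolerance)
}

# reflect a mesh through the x = 0 plane: node x-coordinates negate,
# element orientation is restored by swapping two nodes, labels rebuilt
mirror_mesh <- function(mesh) {
  m <- mesh
  m$nodes[, 1] <- -m$nodes[, 1]
  tmp <- m$tets[, 3]
  m$tets[, 3] <- m$tets[, 4]
  m$tets[, 4] <- tmp
  m$volumes <- tet_volumes(m$nodes, m$tets)
  stopifnot(all(m$volumes > 0))
  label_subregions(m)
}

# wrap a von Mises field as a minimal fem_solution for summarize_stress
fake_solution <- function(vm, G = 1, alpha = 0) {
  structure(list(von_mises = vm, stress = NULL, displacements = NULL,
                 reactions = NULL, load = load_case(G, alpha)),
            class = "fem_solution")
}
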