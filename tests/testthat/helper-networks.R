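# Small hand-built networks and a memoised default fixture shared across
# test files. All fixtures are generated in code; nothing is stored on disk.

# a single vessel between two pressure boundaries
two_vertex_net <- function(d = 20, len = 100, p_in = 100, p_out = 10) {
  vascular_network(
    vertices = data.frame(id = 1:2, x = c(0, len), y = 0, z = 0,
                          role = c("cow_inflow", "av_root")),
    vessels = data.frame(id = 1L, v1 = 1L, v2 = 2L, diameter = d,
                         length = len, vtype = "SA", side = "MCA"),
    boundary_conditions = data.frame(vertex = 1:2,
                                     pressure = c(p_in, p_out)))
}

# chain of equal vessels: cow -- v2 -- ... -- av_root
series_net <- function(n = 2, d = 20, len = 100) {
  vascular_network(
    vertices = data.frame(id = seq_len(n + 1),
                          x = seq(0, by = len, length.out = n + 1), y = 0,
                          z = 0,
                          role = c("cow_inflow", rep("internal", n - 1),
                                   "av_root")),
    vessels = data.frame(id = seq_len(n), v1 = seq_len(n),
                         v2 = seq_len(n) + 1, diameter = d, length = len,
                         vtype = "SA", side = "MCA"),
    boundary_conditions = data.frame(vertex = c(1L, n + 1L),
                                     pressure = c(100, 10)))
}

# two equal vessels in parallel between the boundaries
parallel_net <- function(d = 20, len = 100) {
  vascular_network(
    vertices = data.frame(id = 1:2, x = c(0, len), y = 0, z = 0,
                          role = c("cow_inflow", "av_root")),
    vessels = data.frame(id = 1:2, v1 = 1L, v2 = 2L, diameter = d,
                         length = len, vtype = "SA", side = "MCA"),
    boundary_conditions = data.frame(vertex = 1:2, pressure = c(100, 10)))
}

# random connected network: n_extra internal vertices on a noisy grid,
# random edges plus a spanning chain, two boundary vertices
random_net <- function(n_vert = 20, n_edge = 40, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(3 * n_vert, 0, 500), ncol = 3)
  roles <- c("cow_inflow", rep("internal", n_vert - 2), "av_root")
  chain <- cbind(seq_len(n_vert - 1), 2:n_vert)
  m <- max(n_edge - nrow(chain), 0)
  extra <- matrix(0L, m, 2)
  for (k in seq_len(m)) extra[k, ] <- sample(n_vert, 2)
  ee <- rbind(chain, extra)
  chord <- sqrt(rowSums((pos[ee[, 1], , drop = FALSE] -
                           pos[ee[, 2], , drop = FALSE])^2))
  vascular_network(
    vertices = data.frame(id = seq_len(n_vert), x = pos[, 1], y = pos[, 2],
                          z = pos[, 3], role = roles),
    vessels = data.frame(id = seq_len(nrow(ee)), v1 = ee[, 1], v2 = ee[, 2],
                         diameter = runif(nrow(ee), 4, 30),
                         length = chord * runif(nrow(ee), 1.01, 1.4) + 1,
                         vtype = "SA", side = "none"),
    boundary_conditions = data.frame(vertex = c(1L, n_vert),
                                     pressure = c(100, 10)))
}

# dense direct solve of the same linear system (independent oracle)
dense_flow_oracle <- function(net) {
  v <- net$vertices; e <- net$vessels; bc <- net$boundary_conditions
  n <- nrow(v)
  i1 <- match(e$v1, v$id); i2 <- match(e$v2, v$id)
  G <- edge_conductance(e$diameter, e$length, net$hematocrit,
                        net$plasma_viscosity, net$viscosity_law)
  L <- matrix(0, n, n)
  for (k in seq_along(G)) {
    L[i1[k], i1[k]] <- L[i1[k], i1[k]] + G[k]
    L[i2[k], i2[k]] <- L[i2[k], i2[k]] + G[k]
    L[i1[k], i2[k]] <- L[i1[k], i2[k]] - G[k]
    L[i2[k], i1[k]] <- L[i2[k], i1[k]] - G[k]
  }
  ib <- match(bc$vertex, v$id)
  free <- setdiff(seq_len(n), ib)
  p <- numeric(n); p[ib] <- bc$pressure
  p[free] <- solve(L[free, free, drop = FALSE],
                   -L[free, ib, drop = FALSE] %*% bc$pressure)
  list(pressure = stats::setNames(p, v$id),
       flow = G * (p[i1] - p[i2]))
}

# the default fixture and derived objects are expensive; build once per run
fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    fixture_cache$fx <- default_fixture(seed = 1)
  }
  fixture_cache$fx
}

cached_base_solution <- function() {
  if (is.null(fixture_cache$sol)) {
    fixture_cache$sol <- solve_flow(cached_fixture()$network)
  }
  fixture_cache$sol
}

cached_measurements <- function() {
  if (is.null(fixture_cache$meas)) {
    fx <- cached_fixture()
    fixture_cache$meas <- synth_measurements(fx$network,
                                             cached_base_solution(),
                                             fx$fixture_config)
  }
  fixture_cache$meas
}

# the tuned network underlying the scenario analyses (expensive: built once)
cached_tuned <- function() {
  if (is.null(fixture_cache$tuned)) {
    m <- cached_measurements()
    fixture_cache$tuned <- tune_diameters(m$net, m$constraints)
  }
  fixture_cache$tuned
}

cached_states <- function() {
  if (is.null(fixture_cache$states)) {
    fixture_cache$states <- scenario_states(cached_tuned()$network)
  }
  fixture_cache$states
}

cached_sides <- function() {
  if (is.null(fixture_cache$sides)) {
    st <- cached_states()
    fixture_cache$sides <- assign_sides(st$Base$network, st$Base$solution)
  }
  fixture_cache$sides
}
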