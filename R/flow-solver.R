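#' Empirical relative apparent blood viscosity
#'
#' The diameter- and haematocrit-dependent relative apparent viscosity of
#' blood flowing in narrow tubes, after Pries and co-workers. The default is
#' the in vitro (glass tube) parametrisation
#' \deqn{\mu_{0.45}(d) = 220 e^{-1.3 d} + 3.2 - 2.44 e^{-0.06 d^{0.645}}}
#' with the haematocrit shape exponent
#' \deqn{C(d) = (0.8 + e^{-0.075 d})(-1 + f) + f,\quad
#'       f = (1 + 10^{-11} d^{12})^{-1}}
#' and
#' \deqn{\mu_{rel}(d, H_D) = 1 + (\mu_{0.45}(d) - 1)
#'       \frac{(1-H_D)^C - 1}{(1-0.45)^C - 1}.}
#' The `"in_vivo"` dialect replaces \eqn{\mu_{0.45}} by
#' \eqn{6 e^{-0.085 d} + 3.2 - 2.44 e^{-0.06 d^{0.645}}} and multiplies by the
#' wall-layer factor \eqn{(d/(d-1.1))^2} (also applied inside the haematocrit
#' term), per the in vivo viscosity law. No endothelial-surface-layer
#' correction beyond this is applied.
#'
#' @param d vessel diameter in um (> 0); vectorised.
#' @param hematocrit discharge haematocrit in [0, 1).
#' @param law `"in_vitro"` (default) or `"in_vivo"`.
#' @return dimensionless relative viscosity, same length as `d`.
#' @export
relative_viscosity <- function(d, hematocrit = 0.3,
                               law = c("in_vitro", "in_vivo")) {
  law <- match.arg(law)
  if (any(d <= 0)) stop("diameter must be positive")
  if (hematocrit < 0 || hematocrit >= 1) stop("hematocrit must be in [0, 1)")
  f <- 1 / (1 + 1e-11 * d^12)
  C <- (0.8 + exp(-0.075 * d)) * (-1 + f) + f
  hfrac <- ((1 - hematocrit)^C - 1) / ((1 - 0.45)^C - 1)
  if (law == "in_vitro") {
    mu45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
    1 + (mu45 - 1) * hfrac
  } else {
    mu45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
    wl <- (d / (d - 1.1))^2
    (1 + (mu45 - 1) * hfrac * wl) * wl
  }
}

# d(mu_rel)/dd by central difference on the smooth empirical law.
# h = 1e-4 * d keeps the truncation error ~1e-9 relative, far below the
# 1e-5 adjoint-vs-finite-difference acceptance tolerance.
relative_viscosity_dd <- function(d, hematocrit = 0.3, law = "in_vitro") {
  h <- 1e-4 * d
  (relative_viscosity(d + h, hematocrit, law) -
     relative_viscosity(d - h, hematocrit, law)) / (2 * h)
}

MMHG_PA <- 133.322

#' Hydraulic conductance of a vessel
#'
#' Poiseuille conductance \eqn{G = \pi d^4 / (128 \mu_{eff} L)} with
#' \eqn{\mu_{eff} = \mu_p \mu_{rel}(d, H_D)}, expressed in um^3/(s mmHg)
#' (the mmHg-to-Pa conversion is folded in here and nowhere else).
#'
#' @param d diameter um; vectorised.
#' @param length length um.
#' @param hematocrit discharge haematocrit.
#' @param plasma_viscosity mPa s.
#' @param law viscosity dialect, see [relative_viscosity()].
#' @return conductance in um^3/(s mmHg).
#' @export
edge_conductance <- function(d, length, hematocrit = 0.3,
                             plasma_viscosity = 1.2, law = "in_vitro") {
  mu_eff <- plasma_viscosity * relative_viscosity(d, hematocrit, law) # mPa s
  # mu in Pa s = mu_eff * 1e-3; G[um^3/(s Pa)] = pi d^4/(128 mu L)
  pi * d^4 / (128 * mu_eff * 1e-3 * length) * MMHG_PA
}

# dG/dd at fixed length (analytic in d^4, finite-difference in mu_rel)
edge_conductance_dd <- function(d, length, hematocrit = 0.3,
                                plasma_viscosity = 1.2, law = "in_vitro") {
  mu_rel <- relative_viscosity(d, hematocrit, law)
  dmu <- relative_viscosity_dd(d, hematocrit, law)
  G <- pi * d^4 / (128 * plasma_viscosity * mu_rel * 1e-3 * length) * MMHG_PA
  G * (4 / d - dmu / mu_rel)
}

#' Solve steady Poiseuille flow on a vascular network
#'
#' Assembles the sparse weighted graph Laplacian with edge conductances from
#' [edge_conductance()], eliminates the Dirichlet pressure boundary vertices,
#' and solves the symmetric positive-definite system with a sparse Cholesky
#' factorisation. Flow is signed positive from endpoint `v1` to `v2`;
#' velocity is the bulk mean \eqn{u = q / (\pi d^2/4)}, reported in mm/s.
#' Red-blood-cell velocity is taken equal to the bulk mean (phase separation
#' and the Fahraeus effect are neglected, consistent with the constant
#' haematocrit assumption).
#'
#' @param net a [vascular_network()] with at least two boundary pressures.
#' @return object of class `flow_solution`: list with `pressure` (mmHg,
#'   named by vertex id), `flow` (um^3/s per vessel, signed v1 -> v2),
#'   `velocity` (mm/s, signed), `wss` (Pa), `mu_eff` (mPa s),
#'   `conductance` (um^3/(s mmHg)) and `vessel_id`.
#' @export
solve_flow <- function(net) {
  v <- net$vertices; e <- net$vessels; bc <- net$boundary_conditions
  if (nrow(bc) < 2) stop("need at least one inflow and one outflow boundary condition")
  n <- nrow(v)
  i1 <- match(e$v1, v$id); i2 <- match(e$v2, v$id)
  if (anyNA(i1) || anyNA(i2)) stop("vessel endpoints missing from vertex table")
  G <- edge_conductance(e$diameter, e$length, net$hematocrit,
                        net$plasma_viscosity, net$viscosity_law)

  ib <- match(bc$vertex, v$id)
  is_bc <- rep(FALSE, n); is_bc[ib] <- TRUE
  pfull <- rep(NA_real_, n); pfull[ib] <- bc$pressure
  free <- which(!is_bc)
  if (length(free) > 0) {
    # weighted Laplacian, restricted to free vertices
    idx <- c(i1, i2, i1, i2)
    jdx <- c(i2, i1, i1, i2)
    val <- c(-G, -G, G, G)
    L <- Matrix::sparseMatrix(i = idx, j = jdx, x = val, dims = c(n, n))
    A <- L[free, free, drop = FALSE]
    b <- -(L[free, ib, drop = FALSE] %*% bc$pressure)
    # disconnected free components have a zero diagonal block -> singular
    dg <- Matrix::diag(A)
    if (any(dg <= 0)) {
      stop("singular flow system: free vertices with no incident vessel: ",
           paste(v$id[free[dg <= 0]], collapse = ", "))
    }
    pf <- tryCatch(
      as.numeric(Matrix::solve(A, b, sparse = TRUE)),
      error = function(err) stop(
        "singular flow system (boundary-disconnected component): ",
        conditionMessage(err)))
    pfull[free] <- pf
  }

  dp <- pfull[i1] - pfull[i2]
  q <- G * dp                                  # um^3/s
  area <- pi * e$diameter^2 / 4                # um^2
  u <- q / area / 1000                         # mm/s
  mu_eff <- net$plasma_viscosity *
    relative_viscosity(e$diameter, net$hematocrit, net$viscosity_law)
  wss <- wall_shear_stress(q, e$diameter, mu_eff)

  structure(list(pressure = stats::setNames(pfull, v$id),
                 flow = q, velocity = u, wss = wss,
                 mu_eff = mu_eff, conductance = G,
                 vessel_id = e$id),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("Flow solution:", length(x$pressure), "vertices,",
      length(x$flow), "vessels\n")
  cat(sprintf("  pressure [mmHg]: %.2f .. %.2f\n",
              min(x$pressure), max(x$pressure)))
  cat(sprintf("  |velocity| [mm/s]: median %.3f, max %.3f\n",
              stats::median(abs(x$velocity)), max(abs(x$velocity))))
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  print(object)
  cat(sprintf("  |flow| [um^3/s]: median %.1f, max %.1f\n",
              stats::median(abs(object$flow)), max(abs(object$flow))))
  cat(sprintf("  WSS [Pa]: median %.3f, max %.3f\n",
              stats::median(object$wss), max(object$wss)))
  invisible(object)
}

#' Wall shear stress under a parabolic velocity profile
#'
#' \eqn{WSS = 32 |q| \mu_{eff} / (\pi d^3)}, in Pa.
#'
#' @param q flow rate um^3/s (sign ignored).
#' @param d diameter um.
#' @param mu_eff effective viscosity mPa s.
#' @return WSS in Pa.
#' @export
wall_shear_stress <- function(q, d, mu_eff) {
  if (any(d <= 0)) stop("diameter must be positive")
  # q[m^3/s] = q*1e-18, d[m] = d*1e-6, mu[Pa s] = mu*1e-3
  32 * abs(q) * 1e-18 * mu_eff * 1e-3 / (pi * (d * 1e-6)^3)
}

#' Net signed flow imbalance at every vertex
#'
#' Mass-conservation diagnostic: the sum of signed incident flows at each
#' vertex (zero at interior vertices of a converged solution).
#'
#' @param net a [vascular_network()].
#' @param sol the matching [solve_flow()] solution.
#' @return numeric vector named by vertex id, um^3/s.
#' @export
vertex_flow_balance <- function(net, sol) {
  v <- net$vertices; e <- net$vessels
  bal <- rep(0, nrow(v))
  i1 <- match(e$v1, v$id); i2 <- match(e$v2, v$id)
  # q > 0 leaves v1, enters v2
  bal <- bal - unname(tapply(sol$flow, factor(i1, levels = seq_len(nrow(v))),
                             sum, default = 0)) +
    unname(tapply(sol$flow, factor(i2, levels = seq_len(nrow(v))),
                  sum, default = 0))
  stats::setNames(as.numeric(bal), v$id)
}
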