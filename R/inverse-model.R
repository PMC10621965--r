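#' Velocity constraints for the inverse model
#'
#' Two kinds of red-blood-cell velocity constraints drive the diameter
#' tuning: a precise target value (where a line-scan measurement exists) and
#' an admissible range (physiological bounds at tree roots). Both are
#' parabolic in the deviation: zero at the target / inside the range,
#' quadratic outside. Velocity magnitudes are compared (line scans measure
#' speed, not direction).
#'
#' @param edge vessel id(s).
#' @param u_meas target velocity magnitude, mm/s (> 0).
#' @param u_min,u_max admissible range, mm/s (0 < u_min < u_max).
#' @param weight relative weight of the constraint.
#' @return data.frame with columns `edge`, `kind`, `u_meas`, `u_min`,
#'   `u_max`, `weight`.
#' @export
velocity_target <- function(edge, u_meas, weight = 1) {
  stopifnot(all(u_meas > 0))
  if (length(edge) == 0)
    return(data.frame(edge = integer(), kind = character(),
                      u_meas = numeric(), u_min = numeric(),
                      u_max = numeric(), weight = numeric()))
  data.frame(edge = edge, kind = "target", u_meas = u_meas,
             u_min = NA_real_, u_max = NA_real_, weight = weight)
}

#' @rdname velocity_target
#' @export
velocity_range <- function(edge, u_min, u_max, weight = 1) {
  stopifnot(all(u_min > 0), all(u_max > u_min))
  if (length(edge) == 0)
    return(velocity_target(integer(), numeric()))
  data.frame(edge = edge, kind = "range", u_meas = NA_real_,
             u_min = u_min, u_max = u_max, weight = weight)
}

#' Parabolic constraint cost and its velocity derivative
#'
#' Target kind: \eqn{w (|u| - u^{meas})^2}. Range kind: zero inside
#' \eqn{[u^{min}, u^{max}]}, \eqn{w (|u| - u^{min})^2} below and
#' \eqn{w (|u| - u^{max})^2} above. With `normalize = TRUE` each parabola is
#' divided by the squared target (or range midpoint) so constraints on mm/s
#' scales that differ by orders of magnitude weigh comparably. The
#' derivative is with respect to the signed velocity `u` (chain rule through
#' \eqn{|u|}), is continuous, and vanishes on the zero-cost set.
#'
#' @param u signed velocity, mm/s (vectorised, matched to rows of
#'   `constraints`).
#' @param constraints constraint table (see [velocity_target()]).
#' @param normalize logical; scale-normalise each parabola (default TRUE).
#' @return list with numeric vectors `cost` and `dcost_du`.
#' @export
constraint_cost <- function(u, constraints, normalize = TRUE) {
  au <- abs(u)
  w <- constraints$weight
  if (normalize) {
    scale <- ifelse(constraints$kind == "target", constraints$u_meas,
                    (constraints$u_min + constraints$u_max) / 2)
    w <- w / scale^2
  }
  tgt <- constraints$kind == "target"
  dev <- numeric(length(u))
  dev[tgt] <- au[tgt] - constraints$u_meas[tgt]
  lo <- !tgt & au < constraints$u_min
  hi <- !tgt & au > constraints$u_max
  dev[lo] <- au[lo] - constraints$u_min[lo]
  dev[hi] <- au[hi] - constraints$u_max[hi]
  cost <- w * dev^2
  dcost_du <- 2 * w * dev * sign(u)
  list(cost = cost, dcost_du = dcost_du)
}

#' Total inverse-model cost of a flow solution
#'
#' Sum of [constraint_cost()] over all constraints; zero iff every
#' constraint is satisfied.
#'
#' @param net a [vascular_network()].
#' @param sol the matching [solve_flow()] solution.
#' @param constraints constraint table.
#' @param normalize see [constraint_cost()].
#' @return scalar cost.
#' @export
total_cost <- function(net, sol, constraints, normalize = TRUE) {
  if (nrow(constraints) == 0) return(0)
  i <- match(constraints$edge, sol$vessel_id)
  if (anyNA(i)) stop("constraint on missing edge: ",
                     paste(constraints$edge[is.na(i)], collapse = ", "))
  sum(constraint_cost(sol$velocity[i], constraints, normalize)$cost)
}

# shared assembly for forward and adjoint solves
flow_system <- function(net) {
  v <- net$vertices; e <- net$vessels; bc <- net$boundary_conditions
  n <- nrow(v)
  i1 <- match(e$v1, v$id); i2 <- match(e$v2, v$id)
  G <- edge_conductance(e$diameter, e$length, net$hematocrit,
                        net$plasma_viscosity, net$viscosity_law)
  ib <- match(bc$vertex, v$id)
  free <- setdiff(seq_len(n), ib)
  L <- Matrix::sparseMatrix(i = c(i1, i2, i1, i2), j = c(i2, i1, i1, i2),
                            x = c(-G, -G, G, G), dims = c(n, n))
  list(n = n, i1 = i1, i2 = i2, G = G, ib = ib, free = free, L = L,
       p_bc = bc$pressure)
}

#' Adjoint gradient of the inverse-model cost w.r.t. vessel diameters
#'
#' The cost depends on a diameter both directly (cross-section area and
#' conductance of the constrained edge) and indirectly through the pressure
#' solution. The gradient is computed with one extra linear solve of the
#' (symmetric) system: \eqn{A \lambda = \partial c / \partial p} and
#' \eqn{dC/dd_k = \partial c/\partial d_k -
#' G'_k (\lambda_i - \lambda_j)(p_i - p_j)} for edge k with endpoints
#' (i, j), \eqn{\lambda = 0} at Dirichlet vertices.
#'
#' @param net a [vascular_network()].
#' @param sol matching [solve_flow()] solution (recomputed if NULL).
#' @param constraints constraint table.
#' @param normalize see [constraint_cost()].
#' @param tunable logical/index vector selecting the tunable vessels
#'   (default: all).
#' @return numeric gradient, one entry per tunable vessel, named by vessel
#'   id.
#' @export
cost_gradient_adjoint <- function(net, sol = NULL, constraints,
                                  normalize = TRUE, tunable = NULL) {
  if (is.null(sol)) sol <- solve_flow(net)
  e <- net$vessels
  if (is.null(tunable)) tunable <- seq_len(nrow(e))
  sys <- flow_system(net)
  p <- sol$pressure[match(net$vertices$id, names(sol$pressure))]
  p <- as.numeric(sol$pressure) # ordered as net$vertices

  ci <- match(constraints$edge, e$id)
  if (anyNA(ci)) stop("constraint on missing edge")
  area <- pi * e$diameter[ci]^2 / 4
  cc <- constraint_cost(sol$velocity[ci], constraints, normalize)

  # dC/dp (free vertices): u = G dp / (area * 1000)
  dudp <- sys$G[ci] / area / 1000
  rhs_full <- numeric(sys$n)
  add_at <- function(vec, idx, val) {
    s <- tapply(val, idx, sum)
    vec[as.integer(names(s))] <- vec[as.integer(names(s))] + as.numeric(s)
    vec
  }
  rhs_full <- add_at(rhs_full, sys$i1[ci], cc$dcost_du * dudp)
  rhs_full <- add_at(rhs_full, sys$i2[ci], -cc$dcost_du * dudp)

  lambda <- numeric(sys$n)
  if (length(sys$free) > 0 && any(rhs_full[sys$free] != 0)) {
    A <- sys$L[sys$free, sys$free, drop = FALSE]
    lambda[sys$free] <- as.numeric(
      Matrix::solve(A, rhs_full[sys$free], sparse = TRUE))
  }

  Gp <- edge_conductance_dd(e$diameter, e$length, net$hematocrit,
                            net$plasma_viscosity, net$viscosity_law)
  dp_edge <- p[sys$i1] - p[sys$i2]
  grad <- -Gp * (lambda[sys$i1] - lambda[sys$i2]) * dp_edge

  # direct term on constrained edges: d(u)/dd at fixed pressures
  dudd <- dp_edge[ci] / 1000 *
    (Gp[ci] / area - sys$G[ci] * (pi * e$diameter[ci] / 2) / area^2)
  direct <- numeric(nrow(e))
  s <- tapply(cc$dcost_du * dudd, ci, sum)
  direct[as.integer(names(s))] <- as.numeric(s)
  grad <- grad + direct
  stats::setNames(grad[tunable], e$id[tunable])
}

#' Options for diameter tuning
#'
#' Box half-widths follow the stated uncertainty model: +-5% around the
#' prior for surface arteries with a diameter measurement, +-20% for
#' unmeasured surface arteries (including LMCs and the feeder edges), and
#' +-50% for all other vessel types (DAs, capillaries, AVs).
#'
#' @param beta_sa_measured,beta_sa_unmeasured,beta_other box half-width as
#'   a fraction of the prior diameter, per category.
#' @param max_iter iteration cap for the projected gradient descent.
#' @param cost_tol terminate when the cost falls below this value.
#' @param step0 initial step size (scaled internally by the gradient norm).
#' @param armijo_c sufficient-decrease constant of the backtracking line
#'   search.
#' @param normalize scale-normalise the parabolas, see [constraint_cost()].
#' @return list of class `tuning_options`.
#' @export
tuning_options <- function(beta_sa_measured = 0.05,
                           beta_sa_unmeasured = 0.20,
                           beta_other = 0.50,
                           max_iter = 800L,
                           cost_tol = 1e-6,
                           step0 = 1,
                           armijo_c = 1e-4,
                           normalize = TRUE) {
  stopifnot(beta_sa_measured > 0, beta_sa_measured < 1,
            beta_sa_unmeasured > 0, beta_sa_unmeasured < 1,
            beta_other > 0, beta_other < 1)
  structure(list(beta_sa_measured = beta_sa_measured,
                 beta_sa_unmeasured = beta_sa_unmeasured,
                 beta_other = beta_other,
                 max_iter = as.integer(max_iter), cost_tol = cost_tol,
                 step0 = step0, armijo_c = armijo_c, normalize = normalize),
            class = "tuning_options")
}

# per-vessel box half-width fraction
diameter_bounds <- function(net, opts) {
  e <- net$vessels
  pial <- e$vtype %in% c("SA", "SA_to_CoW", "LMC")
  beta <- ifelse(pial & e$measured, opts$beta_sa_measured,
                 ifelse(pial, opts$beta_sa_unmeasured, opts$beta_other))
  list(lower = (1 - beta) * e$d_prior, upper = (1 + beta) * e$d_prior,
       beta = beta)
}

#' Tune vessel diameters to sparse velocity constraints
#'
#' Fits the network's vessel diameters so that solved red-blood-cell
#' velocities satisfy the given targets and ranges, by projected gradient
#' descent with Armijo backtracking on the parabolic cost, gradients from
#' the adjoint method ([cost_gradient_adjoint()]), and projection onto the
#' per-category boxes around the prior diameters ([tuning_options()]).
#' The cost is non-increasing over accepted steps and every iterate respects
#' the boxes. The solution is deliberately non-unique (far more diameters
#' than constraints); only the cost and the constraint residuals are
#' identified, not the individual diameters.
#'
#' @param net a valid [vascular_network()]; `d_prior` records the diameters
#'   the boxes are centred on.
#' @param constraints constraint table ([velocity_target()],
#'   [velocity_range()], [standard_root_constraints()]).
#' @param opts a [tuning_options()].
#' @param exclude vessel ids to freeze (e.g. an occluded segment).
#' @return object of class `diameter_fit` with methods [coef.diameter_fit()],
#'   [predict.diameter_fit()], [residuals.diameter_fit()],
#'   [fitted.diameter_fit()], `print`, `summary`, `plot`.
#' @export
tune_diameters <- function(net, constraints, opts = tuning_options(),
                           exclude = integer()) {
  e <- net$vessels
  tunable <- which(!(e$id %in% exclude))
  bounds <- diameter_bounds(net, opts)
  d_prior <- e$d_prior
  # optimize in relative-diameter space theta = d / d_prior: equalizes the
  # gradient scale across vessel calibres and turns the boxes into
  # [1 - beta, 1 + beta] intervals
  th_lo <- bounds$lower[tunable] / d_prior[tunable]
  th_hi <- bounds$upper[tunable] / d_prior[tunable]
  clip <- function(th) pmin(th_hi, pmax(th_lo, th))
  set_theta <- function(n, th) {
    n$vessels$diameter[tunable] <- th * d_prior[tunable]
    n
  }
  theta <- clip(net$vessels$diameter[tunable] / d_prior[tunable])
  net <- set_theta(net, theta)

  sol <- solve_flow(net)
  cost <- total_cost(net, sol, constraints, opts$normalize)
  if (!is.finite(cost)) stop("non-finite initial cost")
  history <- data.frame(iteration = 0L, cost = cost, max_rel_step = 0)
  converged <- cost <= opts$cost_tol

  grad_theta <- function(n, s) {
    g <- cost_gradient_adjoint(n, s, constraints, opts$normalize, tunable)
    unname(g) * d_prior[tunable]
  }
  g <- if (!converged) grad_theta(net, sol) else numeric(length(tunable))
  step <- opts$step0 * 0.02 / max(abs(g), 1e-300)
  theta_prev <- NULL; g_prev <- NULL

  it <- 0L
  while (!converged && it < opts$max_iter) {
    it <- it + 1L
    if (max(abs(g)) == 0) break
    # Barzilai-Borwein step from the previous accepted move
    if (!is.null(theta_prev)) {
      s <- theta - theta_prev; y <- g - g_prev
      sy <- sum(s * y)
      if (is.finite(sy) && sy > 0) step <- sum(s * s) / sy
    }
    step <- min(max(step, 1e-12), 1e3)
    accepted <- FALSE
    for (bt in 1:40) {
      th_try <- clip(theta - step * g)
      move <- th_try - theta
      if (max(abs(move)) == 0) break
      net_try <- set_theta(net, th_try)
      sol_try <- solve_flow(net_try)
      cost_try <- total_cost(net_try, sol_try, constraints, opts$normalize)
      if (!is.finite(cost_try)) {
        bad <- which.max(abs(move))
        stop("non-finite cost during line search (vessel ",
             e$id[tunable[bad]], ")")
      }
      # Armijo sufficient decrease on the projected step
      if (cost_try <= cost + opts$armijo_c * sum(g * move)) {
        theta_prev <- theta; g_prev <- g
        theta <- th_try; net <- net_try; sol <- sol_try
        cost <- cost_try
        history <- rbind(history,
                         data.frame(iteration = it, cost = cost,
                                    max_rel_step = max(abs(move / theta_prev))))
        g <- grad_theta(net, sol)
        accepted <- TRUE
        break
      }
      step <- step / 4
    }
    if (!accepted) break
    if (cost <= opts$cost_tol) converged <- TRUE
  }

  structure(list(network = net, solution = sol, constraints = constraints,
                 options = opts, bounds = bounds, tunable = tunable,
                 history = history, cost = cost, iterations = it,
                 converged = converged),
            class = "diameter_fit")
}

#' @export
print.diameter_fit <- function(x, ...) {
  cat("Diameter fit:", length(x$tunable), "tunable vessels,",
      nrow(x$constraints), "velocity constraints\n")
  cat(sprintf("  final cost %.3e after %d iterations (%s)\n", x$cost,
              x$iterations,
              if (x$converged) "converged" else "iteration cap / stalled"))
  invisible(x)
}

#' Summary of a diameter fit
#'
#' @param object a `diameter_fit`.
#' @param ... unused.
#' @return invisibly, a list with per-kind residual summaries.
#' @export
summary.diameter_fit <- function(object, ...) {
  print(object)
  r <- residuals(object)
  k <- object$constraints$kind
  cat(sprintf("  target constraints: %d, max |residual| %.4f mm/s\n",
              sum(k == "target"),
              if (any(k == "target")) max(abs(r[k == "target"])) else 0))
  cat(sprintf("  range constraints: %d, satisfied %d\n",
              sum(k == "range"), sum(k == "range" & r == 0)))
  rel <- abs(object$network$vessels$diameter / object$network$vessels$d_prior - 1)
  cat(sprintf("  max |diameter change| vs prior: %.1f%%\n", 100 * max(rel)))
  invisible(list(residuals = r, kind = k))
}

#' @export
coef.diameter_fit <- function(object, ...) {
  stats::setNames(object$network$vessels$diameter, object$network$vessels$id)
}

#' Velocities at the constrained edges of a diameter fit
#'
#' @param object a `diameter_fit`.
#' @param ... unused.
#' @return signed velocities (mm/s) at the constraint edges.
#' @export
fitted.diameter_fit <- function(object, ...) {
  i <- match(object$constraints$edge, object$solution$vessel_id)
  stats::setNames(object$solution$velocity[i], object$constraints$edge)
}

#' Constraint residuals of a diameter fit
#'
#' Target constraints: `|u| - u_meas`. Range constraints: signed distance to
#' the nearest bound, zero inside the range.
#'
#' @param object a `diameter_fit`.
#' @param ... unused.
#' @return numeric residuals, mm/s, named by constraint edge id.
#' @export
residuals.diameter_fit <- function(object, ...) {
  u <- abs(fitted(object))
  cn <- object$constraints
  r <- ifelse(cn$kind == "target", u - cn$u_meas,
              ifelse(u < cn$u_min, u - cn$u_min,
                     ifelse(u > cn$u_max, u - cn$u_max, 0)))
  stats::setNames(r, cn$edge)
}

#' Solve flow on the tuned network (or a perturbed variant of it)
#'
#' @param object a `diameter_fit`.
#' @param newdata optionally a modified [vascular_network()] (e.g. a
#'   scenario state built from the tuned network); defaults to the tuned
#'   network itself.
#' @param ... unused.
#' @return a [solve_flow()] `flow_solution`.
#' @export
predict.diameter_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$solution)
  solve_flow(newdata)
}

#' Convergence history plot
#'
#' @param x a `diameter_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diameter_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$iteration, h$cost, type = "b", log = "y",
                 xlab = "iteration", ylab = "cost",
                 main = "Diameter tuning convergence", ...)
  invisible(x)
}
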