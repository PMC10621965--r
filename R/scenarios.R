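#' Apply a middle-cerebral-artery occlusion
#'
#' Mimics a stroke at the MCA by splitting a `segment_length` (default
#' 50 um) sub-segment out of the feeding edge upstream of the pial network
#' and constricting it to `residual_fraction` (default 10%) of its baseline
#' diameter. All other diameters are untouched. The constricted segment is
#' recorded in the `occluded_edges` attribute and must be excluded from
#' tuning and dilation.
#'
#' @param net a [vascular_network()] (never mutated; a modified copy is
#'   returned).
#' @param edge id of the edge to occlude; default: the MCA-side
#'   `SA_to_CoW` feeder edge.
#' @param segment_length um; if the edge is shorter, the whole edge is
#'   constricted.
#' @param residual_fraction remaining fraction of the baseline diameter,
#'   in (0, 1].
#' @return the occluded network, with `attr(net, "occluded_edges")` set.
#' @export
apply_mcao <- function(net, edge = NULL, segment_length = 50,
                       residual_fraction = 0.10) {
  stopifnot(residual_fraction > 0, residual_fraction <= 1)
  e <- net$vessels
  if (is.null(edge)) {
    edge <- e$id[e$vtype == "SA_to_CoW" & e$side == "MCA"]
    if (length(edge) != 1)
      stop("cannot identify a unique MCA feeder edge; pass `edge`")
  }
  i <- match(edge, e$id)
  if (is.na(i)) stop("occlusion edge ", edge, " not found")
  if (e$side[i] == "ACA")
    stop("occlusion edge ", edge, " is on the ACA path; MCAo must occlude the MCA feeder")

  if (e$length[i] <= segment_length) {
    net$vessels$diameter[i] <- e$diameter[i] * residual_fraction
    attr(net, "occluded_edges") <- edge
    return(net)
  }
  # split: upstream part keeps the baseline diameter, a segment_length piece
  # near the downstream end (toward the pial network) is constricted
  v <- net$vertices
  t <- 1 - segment_length / e$length[i]
  a <- v[match(e$v1[i], v$id), ]; b <- v[match(e$v2[i], v$id), ]
  split_id <- next_id(v$id)
  net$vertices <- rbind(v, data.frame(
    id = split_id,
    x = a$x + t * (b$x - a$x), y = a$y + t * (b$y - a$y),
    z = a$z + t * (b$z - a$z), role = "internal"))
  occ <- e[i, ]
  occ$id <- next_id(e$id)
  occ$v1 <- split_id
  occ$length <- segment_length
  occ$diameter <- e$diameter[i] * residual_fraction
  occ$d_prior <- occ$diameter
  net$vessels$v2[i] <- split_id
  net$vessels$length[i] <- e$length[i] - segment_length
  net$vessels <- rbind(net$vessels, occ)
  attr(net, "occluded_edges") <- occ$id
  net
}

#' Dilate a selection of vessels
#'
#' Multiplies the selected diameters by a factor: the uniform collateral
#' dilation factor 1.7 for LMCs without in vivo dilation measurements, or
#' 1.10 (+10%) for surface and descending arteries in the full arterial-
#' dilation state. Occluded segments are never dilated.
#'
#' @param net a [vascular_network()].
#' @param vtypes vessel types to dilate (e.g. `"LMC"` or `c("SA", "DA")`),
#'   or NULL when `edges` is given.
#' @param factor scalar dilation factor, or a vector named by edge id.
#' @param edges explicit vessel ids (overrides `vtypes`).
#' @return the dilated network.
#' @export
apply_dilation <- function(net, vtypes = NULL, factor = 1.7, edges = NULL) {
  stopifnot(all(factor > 0))
  e <- net$vessels
  sel <- if (!is.null(edges)) e$id %in% edges else e$vtype %in% vtypes
  occ <- attr(net, "occluded_edges")
  if (!is.null(occ)) sel <- sel & !(e$id %in% occ)
  if (!any(sel)) {
    warning("empty dilation selection; network unchanged")
    return(net)
  }
  f <- if (!is.null(names(factor))) {
    fv <- factor[as.character(e$id[sel])]
    ifelse(is.na(fv), 1, fv)
  } else factor
  net$vessels$diameter[sel] <- e$diameter[sel] * f
  net
}

#' Elasticity parameters for passive diameter changes
#'
#' Linear pressure-diameter coupling around a reference (baseline) state:
#' \eqn{d = d_{ref} (1 + c (p_{mid} - p_{mid,ref}))} with compliance `c` in
#' fractional diameter change per mmHg. The default compliance (0.0012/mmHg,
#' i.e. 0.12% diameter per mmHg) is calibrated so that the passive
#' constrictions induced by an MCA occlusion stay below 10% on the default
#' fixture, matching the reported behaviour of the linear-elastic tube law.
#'
#' @param compliance scalar or vector named by vessel type, 1/mmHg.
#' @param max_iter fixed-point iteration cap.
#' @param tol convergence tolerance on the maximum relative diameter change
#'   between iterations.
#' @return list of class `elasticity_params`.
#' @export
elasticity_params <- function(compliance = 0.0012, max_iter = 50L,
                              tol = 1e-8) {
  stopifnot(all(compliance >= 0), tol > 0)
  structure(list(compliance = compliance, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "elasticity_params")
}

#' Mid-edge pressures of a flow solution
#'
#' Mean of the two endpoint pressures per vessel, mmHg; the per-vessel
#' pressure summary used by the elastic coupling and the pressure-change
#' reports.
#'
#' @param net a [vascular_network()].
#' @param sol the matching [solve_flow()] solution.
#' @return numeric vector aligned to `net$vessels`.
#' @export
edge_mid_pressure <- function(net, sol) {
  i1 <- match(net$vessels$v1, net$vertices$id)
  i2 <- match(net$vessels$v2, net$vertices$id)
  (as.numeric(sol$pressure)[i1] + as.numeric(sol$pressure)[i2]) / 2
}

#' Flow solve with passive elastic diameter coupling
#'
#' Fixed-point iteration: solve flow, update every elastic vessel's diameter
#' from the linear pressure-diameter law around the reference state,
#' re-solve, until the maximum relative diameter change between iterations
#' falls below tolerance. With compliance zero this reproduces the rigid
#' solve exactly.
#'
#' @param net the (possibly perturbed, e.g. occluded) network to solve.
#' @param params an [elasticity_params()].
#' @param reference list with `p_mid` (baseline mid-edge pressures for the
#'   edges of `net`, NA for edges absent at baseline) and `d_ref` (baseline
#'   diameters). Build it with [elastic_reference()].
#' @return list with `network` (converged passive diameters), `solution`
#'   (matching [solve_flow()] result) and `iterations`.
#' @export
elastic_coupled_solve <- function(net, params, reference) {
  e <- net$vessels
  comp <- params$compliance
  c_edge <- if (!is.null(names(comp))) {
    cv <- comp[e$vtype]; ifelse(is.na(cv), 0, cv)
  } else rep(comp, nrow(e))
  occ <- attr(net, "occluded_edges")
  elastic <- is.finite(reference$p_mid) & c_edge > 0 & !(e$id %in% occ)

  sol <- solve_flow(net)
  if (!any(elastic)) return(list(network = net, solution = sol, iterations = 0L))
  for (it in seq_len(params$max_iter)) {
    p_mid <- edge_mid_pressure(net, sol)
    d_new <- net$vessels$diameter
    d_new[elastic] <- reference$d_ref[elastic] *
      (1 + c_edge[elastic] * (p_mid[elastic] - reference$p_mid[elastic]))
    d_new[elastic] <- pmax(d_new[elastic], 0.2 * reference$d_ref[elastic])
    delta <- max(abs(d_new - net$vessels$diameter) / net$vessels$diameter)
    net$vessels$diameter <- d_new
    sol <- solve_flow(net)
    if (delta < params$tol)
      return(list(network = net, solution = sol, iterations = it))
  }
  stop("elastic coupling did not converge within ", params$max_iter,
       " iterations (last max relative change ", signif(delta, 3), ")")
}

#' Baseline reference state for the elastic coupling
#'
#' @param net baseline network.
#' @param sol baseline [solve_flow()] solution.
#' @param target the (scenario) network whose edges the reference must
#'   match; edges absent at baseline get NA (treated rigid).
#' @return list with `p_mid`, `d_ref` aligned to `target$vessels`.
#' @export
elastic_reference <- function(net, sol, target = net) {
  p_mid <- edge_mid_pressure(net, sol)
  i <- match(target$vessels$id, net$vessels$id)
  list(p_mid = p_mid[i], d_ref = net$vessels$diameter[i])
}

#' Randomly remove leptomeningeal collaterals
#'
#' Keeps `round(keep_fraction * n_LMC)` LMC edges, selected uniformly at
#' random; removed edges are deleted and any vertex left with degree zero is
#' dropped. Used to build the 100% / 50% / 0% LMC scenarios.
#'
#' @param net a [vascular_network()].
#' @param keep_fraction in [0, 1].
#' @param seed integer seed (determinism contract).
#' @return the pruned network.
#' @export
remove_lmcs <- function(net, keep_fraction, seed = 1L) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  lmc <- net$vessels$id[net$vessels$vtype == "LMC"]
  if (keep_fraction >= 1 || length(lmc) == 0) return(net)
  set.seed(seed)
  n_keep <- round(keep_fraction * length(lmc))
  keep <- if (n_keep > 0) sample(lmc, n_keep) else integer()
  drop <- setdiff(lmc, keep)
  net$vessels <- net$vessels[!(net$vessels$id %in% drop), ]
  used <- unique(c(net$vessels$v1, net$vessels$v2))
  net$vertices <- net$vertices[net$vertices$id %in% used, ]
  net$boundary_conditions <-
    net$boundary_conditions[net$boundary_conditions$vertex %in% used, ]
  net
}

#' Sequentially add leptomeningeal collaterals across the watershed
#'
#' Rejection sampling after the stated construction: candidate collaterals
#' connect a randomly chosen MCA-side pial vertex near the watershed line to
#' the closest ACA-side pial vertex; a candidate is accepted iff its planar
#' distance to every existing LMC exceeds `spacing_min` (310 um) and its
#' length does not exceed `length_max` (1000 um). New edges are typed LMC
#' with log-normal diameters.
#'
#' @param net a [vascular_network()] whose pial vertices can be sided (the
#'   fixture records sides on SA edges).
#' @param n_target number of LMCs to add.
#' @param spacing_min um, minimum planar distance between LMC midpoints.
#' @param length_max um, maximum LMC length.
#' @param diameter_median um; log-normal median of new LMC diameters.
#' @param diameter_sdlog log-sd of new LMC diameters.
#' @param seed integer seed.
#' @return network with added LMC edges (a warning is given if fewer than
#'   `n_target` could be placed under the spacing rule).
#' @export
add_lmcs <- function(net, n_target, spacing_min = 310, length_max = 1000,
                     diameter_median = 10, diameter_sdlog = 0.25,
                     seed = 1L) {
  if (n_target <= 0) return(net)
  set.seed(seed)
  v <- net$vertices; e <- net$vessels
  side_of_vertex <- function(side) {
    ids <- unique(c(e$v1[e$vtype == "SA" & e$side == side],
                    e$v2[e$vtype == "SA" & e$side == side]))
    v[v$id %in% ids & v$z == 0, ]
  }
  mca <- side_of_vertex("MCA"); aca <- side_of_vertex("ACA")
  if (nrow(mca) == 0 || nrow(aca) == 0)
    stop("cannot side pial vertices; SA edges need MCA/ACA annotations")

  lmc_mid <- function(ee) {
    i1 <- match(ee$v1, v$id); i2 <- match(ee$v2, v$id)
    cbind((v$x[i1] + v$x[i2]) / 2, (v$y[i1] + v$y[i2]) / 2)
  }
  existing <- lmc_mid(e[e$vtype == "LMC", , drop = FALSE])

  placed <- 0L
  order_m <- sample(nrow(mca))
  for (k in order_m) {
    if (placed >= n_target) break
    d2 <- (aca$x - mca$x[k])^2 + (aca$y - mca$y[k])^2
    j <- which.min(d2)
    len <- sqrt(d2[j])
    if (len > length_max || len < 1) next
    mid <- c((mca$x[k] + aca$x[j]) / 2, (mca$y[k] + aca$y[j]) / 2)
    if (nrow(existing) > 0 &&
        min(sqrt((existing[, 1] - mid[1])^2 + (existing[, 2] - mid[2])^2)) <=
          spacing_min) next
    d_lmc <- diameter_median * exp(stats::rnorm(1, 0, diameter_sdlog))
    new <- e[1, ]
    new$id <- next_id(e$id); new$v1 <- mca$id[k]; new$v2 <- aca$id[j]
    new$diameter <- d_lmc; new$d_prior <- d_lmc
    new$length <- len * 1.1; new$vtype <- "LMC"; new$side <- "none"
    new$measured <- FALSE; new$is_connector <- FALSE
    e <- rbind(e, new)
    existing <- rbind(existing, mid)
    placed <- placed + 1L
  }
  if (placed < n_target)
    warning("placed ", placed, " of ", n_target,
            " LMCs; spacing rule exhausted the candidates")
  net$vessels <- e
  net
}

#' Build and solve the four canonical perturbation states
#'
#' Convenience wrapper producing Base, MCAo, MCAo & LMC-dil and
#' MCAo & LMC/SA/DA-dil from one (typically tuned) network: the occlusion
#' constricts a 50 um feeder segment to 10% diameter, LMCs are then dilated
#' by 1.7 and finally SAs and DAs by 10%. All transforms are pure; the input
#' network is never mutated.
#'
#' @param net baseline network (tuned).
#' @param lmc_dilation uniform LMC dilation factor.
#' @param arterial_dilation fractional SA/DA dilation.
#' @param occlusion_edge forwarded to [apply_mcao()].
#' @param elasticity optional [elasticity_params()]; when given, every
#'   non-Base state is solved with passive elastic coupling around Base.
#' @return list of four elements (`Base`, `MCAo`, `MCAo_LMC_dil`,
#'   `MCAo_LMC_SA_DA_dil`), each a list with `network` and `solution`.
#' @export
scenario_states <- function(net, lmc_dilation = 1.7,
                            arterial_dilation = 0.10,
                            occlusion_edge = NULL,
                            elasticity = NULL) {
  base_sol <- solve_flow(net)
  occ <- apply_mcao(net, edge = occlusion_edge)
  lmc <- apply_dilation(occ, "LMC", lmc_dilation)
  all_dil <- apply_dilation(lmc, c("SA", "DA", "SA_to_CoW"),
                            1 + arterial_dilation)
  solve_state <- function(state) {
    if (is.null(elasticity)) {
      list(network = state, solution = solve_flow(state))
    } else {
      ref <- elastic_reference(net, base_sol, target = state)
      out <- elastic_coupled_solve(state, elasticity, ref)
      list(network = out$network, solution = out$solution)
    }
  }
  list(Base = list(network = net, solution = base_sol),
       MCAo = solve_state(occ),
       MCAo_LMC_dil = solve_state(lmc),
       MCAo_LMC_SA_DA_dil = solve_state(all_dil))
}
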