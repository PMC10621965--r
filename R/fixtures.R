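#' Configuration for synthetic pial fixtures
#'
#' The fixture emulates the structure of an experimentally traced pial
#' surface-artery map: two feeding branches (MCA and ACA) joined to a single
#' circle-of-Willis inflow, two branching SA trees filling opposite halves
#' of a planar footprint, and leptomeningeal collaterals (LMCs) spanning the
#' midline watershed. The default footprint is 1 mm^2 (desk scale; the
#' in vivo reconstructions the model targets are ~30x larger).
#'
#' @param footprint_um c(width, height) of the pial footprint, um.
#' @param n_sa_per_side trunk branch points per feeding territory.
#' @param n_lmc number of midline-spanning LMC edges (placed on alternating
#'   branch tips so the >310 um LMC spacing rule holds).
#' @param lmc_gap um, planar midline gap bridged by each LMC.
#' @param sa_diameter_range um, c(min, max) surface-artery taper range.
#' @param lmc_diameter um, median LMC diameter (log-normal spread 0.2).
#' @param measurement_fraction fraction of SAs with synthetic velocity and
#'   diameter measurements.
#' @param lmc_measurement_fraction fraction of LMCs with a velocity
#'   measurement; the remainder fall back to the median measured LMC
#'   velocity (0.53 mm/s when none was measured). Default 1: the
#'   desk-scale fixture has very few, strongly coupled LMCs, and a shared
#'   fallback target would be structurally infeasible for them.
#' @param velocity_noise_sd multiplicative (log-scale) noise on synthetic
#'   velocity measurements.
#' @param rng_seed integer seed.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(footprint_um = c(1000, 1000),
                           n_sa_per_side = 5,
                           n_lmc = 3,
                           lmc_gap = 300,
                           sa_diameter_range = c(12, 40),
                           lmc_diameter = 4,
                           measurement_fraction = 0.4,
                           lmc_measurement_fraction = 1,
                           velocity_noise_sd = 0.1,
                           rng_seed = 1L) {
  stopifnot(all(footprint_um > 0), n_sa_per_side >= 1,
            measurement_fraction >= 0, measurement_fraction <= 1)
  structure(list(footprint_um = footprint_um,
                 n_sa_per_side = n_sa_per_side,
                 n_lmc = n_lmc, lmc_gap = lmc_gap,
                 sa_diameter_range = sa_diameter_range,
                 lmc_diameter = lmc_diameter,
                 measurement_fraction = measurement_fraction,
                 lmc_measurement_fraction = lmc_measurement_fraction,
                 velocity_noise_sd = velocity_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_config")
}

#' Generate a synthetic pial surface-artery network
#'
#' Builds the pial-only graph described in [fixture_config()]: one
#' `cow_inflow` vertex, an MCA and an ACA feeder edge (`SA_to_CoW`), one
#' trunk per side with branches toward and away from the midline, and
#' `n_lmc` LMC edges connecting matched branch tips across the watershed.
#' Diameters taper from the feeder toward the tips. Deterministic per seed.
#'
#' @param cfg a [fixture_config()].
#' @return a pial-only [vascular_network()] (no boundary conditions yet).
#' @export
synth_pial <- function(cfg = fixture_config()) {
  set.seed(cfg$rng_seed)
  w <- cfg$footprint_um[1]; h <- cfg$footprint_um[2]
  n <- cfg$n_sa_per_side
  dmin <- cfg$sa_diameter_range[1]; dmax <- cfg$sa_diameter_range[2]

  vid <- 0L; eid <- 0L
  verts <- list(); edges <- list()
  addv <- function(x, y, role = "internal") {
    vid <<- vid + 1L
    verts[[vid]] <<- data.frame(id = vid, x = x, y = y, z = 0, role = role)
    vid
  }
  adde <- function(a, b, d, vtype, side, tort = 1.05) {
    eid <<- eid + 1L
    p <- do.call(rbind, verts)
    ca <- p[p$id == a, ]; cb <- p[p$id == b, ]
    chord <- sqrt((ca$x - cb$x)^2 + (ca$y - cb$y)^2)
    edges[[eid]] <<- data.frame(id = eid, v1 = a, v2 = b, diameter = d,
                                length = max(chord * tort, 1), vtype = vtype,
                                side = side)
    eid
  }

  cow <- addv(w / 2, -400, "cow_inflow")
  fx <- c(0.2, 0.8) * w
  sides <- c("MCA", "ACA")
  tip_ids <- list(MCA = integer(n), ACA = integer(n))
  for (s in 1:2) {
    feeder <- addv(fx[s], 0)
    adde(cow, feeder, dmax, "SA_to_CoW", sides[s], tort = 1.02)
    prev <- feeder
    for (k in seq_len(n)) {
      yk <- k * h / (n + 1)
      trunk <- addv(fx[s] + stats::rnorm(1, 0, 15), yk)
      # trunk tapers from dmax*0.85 down to ~dmin*1.6
      d_tr <- dmax * 0.85 - (dmax * 0.85 - dmin * 1.6) * (k - 1) / max(n - 1, 1)
      adde(prev, trunk, d_tr, "SA", sides[s])
      prev <- trunk
      # inner branch toward the midline (LMC candidate tip); tips carry a
      # descending-artery root so every branch is perfused at baseline,
      # mirroring collaterals that join perfused distal branches
      tip_x <- w / 2 + (if (s == 1) -1 else 1) * cfg$lmc_gap / 2
      tip <- addv(tip_x, yk + stats::rnorm(1, 0, 10), "da_root")
      adde(trunk, tip, 0.55 * d_tr + 0.45 * dmin, "SA", sides[s])
      tip_ids[[sides[s]]][k] <- tip
      # outer branch filling the lateral half, also root-bearing
      out_x <- (if (s == 1) 0.04 else 0.96) * w
      outer <- addv(out_x, yk + stats::rnorm(1, 0, 10), "da_root")
      adde(trunk, outer, 0.45 * d_tr + 0.55 * dmin, "SA", sides[s])
    }
  }

  # LMCs on alternating tips so pairwise separation exceeds the spacing rule
  if (cfg$n_lmc > 0) {
    cand <- seq(1, n, by = 2)
    if (length(cand) < cfg$n_lmc)
      stop("infeasible LMC count under the spacing rule: at most ",
           length(cand), " LMCs fit ", n, " branch rows")
    pick <- cand[seq_len(cfg$n_lmc)]
    for (k in pick) {
      d_lmc <- cfg$lmc_diameter * exp(stats::rnorm(1, 0, 0.2))
      adde(tip_ids$MCA[k], tip_ids$ACA[k], d_lmc, "LMC", "none", tort = 1.1)
    }
  }

  vascular_network(do.call(rbind, verts), do.call(rbind, edges))
}

#' Build the default assembled fixture network
#'
#' Runs the full generation pipeline on the synthetic pial fixture:
#' [synth_pial()] -> [refine_pial_network()] -> [place_av_roots()] ->
#' [assemble_network()]. The result passes [validate_network()] and is the
#' network used throughout the examples and the scenario analyses.
#'
#' @param seed integer seed driving both fixture and generation randomness.
#' @param fixture a [fixture_config()]; its `rng_seed` is overridden by
#'   `seed`.
#' @param generation a [generation_config()]; its `rng_seed` is overridden
#'   by `seed`.
#' @return list with elements `network` (assembled [vascular_network()]),
#'   `pial` (the refined pial subnetwork), `fixture_config`,
#'   `generation_config`.
#' @export
default_fixture <- function(seed = 1L,
                            fixture = fixture_config(),
                            generation = generation_config()) {
  fixture$rng_seed <- as.integer(seed)
  generation$rng_seed <- as.integer(seed) + 1000L
  pial <- synth_pial(fixture)
  pial <- refine_pial_network(pial, generation)
  pial <- place_av_roots(pial, generation)
  net <- assemble_network(pial, generation)
  list(network = net, pial = pial,
       fixture_config = fixture, generation_config = generation)
}

#' Root edges of the penetrating trees
#'
#' The vessel ids of the most superficial segment of each descending-artery
#' or ascending-vein tree (the edge incident to the root vertex). These are
#' the edges the physiological range constraints and the root-velocity
#' summaries refer to.
#'
#' @param net a [vascular_network()].
#' @param kind `"DA"` or `"AV"`.
#' @return integer vessel ids.
#' @export
root_edges <- function(net, kind = c("DA", "AV")) {
  kind <- match.arg(kind)
  role <- if (kind == "DA") "da_root" else "av_root"
  roots <- net$vertices$id[net$vertices$role == role]
  e <- net$vessels
  e$id[e$vtype == kind & !e$is_connector & (e$v1 %in% roots | e$v2 %in% roots)]
}

#' Synthesize sparse velocity measurements from a reference solution
#'
#' Emulates the sparse two-photon line-scan data the inverse model consumes:
#' a random fraction of surface arteries receives a velocity target (the
#' reference solution's velocity perturbed by multiplicative log-normal
#' noise) and a diameter-measurement flag; measured LMCs receive targets the
#' same way, unmeasured LMCs fall back to the median measured LMC velocity
#' (0.53 mm/s if no LMC was measured); every DA root edge receives the
#' standard 2-10 mm/s range constraint and every AV root edge the standard
#' 0.4-2 mm/s range.
#'
#' @param net assembled [vascular_network()].
#' @param sol reference [solve_flow()] solution (ground truth).
#' @param cfg a [fixture_config()] (`measurement_fraction`,
#'   `velocity_noise_sd`, `rng_seed + 2` drive the sampling).
#' @return list with `constraints` (see [velocity_target()]), `net` (the
#'   network with `measured` flags set) and `truth` (data.frame of the
#'   unperturbed velocities for recovery experiments).
#' @export
synth_measurements <- function(net, sol, cfg = fixture_config()) {
  set.seed(cfg$rng_seed + 2L)
  e <- net$vessels
  u <- stats::setNames(sol$velocity, sol$vessel_id)

  # only perfused SAs are measurable (dead-end branches carry no flow)
  sa <- e$id[e$vtype == "SA" &
               abs(u[as.character(e$id)]) > 0.01]
  n_meas <- round(cfg$measurement_fraction * length(sa))
  meas_sa <- if (n_meas > 0) sample(sa, n_meas) else integer()
  lmc <- e$id[e$vtype == "LMC"]
  n_lm <- round(cfg$lmc_measurement_fraction * length(lmc))
  meas_lmc <- if (n_lm > 0) sample(lmc, n_lm) else integer()

  noisy <- function(ids) abs(u[as.character(ids)]) *
    exp(stats::rnorm(length(ids), 0, cfg$velocity_noise_sd))

  cons <- list()
  if (length(meas_sa) > 0)
    cons[[length(cons) + 1L]] <- velocity_target(meas_sa, noisy(meas_sa))
  if (length(lmc) > 0) {
    u_lmc_meas <- noisy(meas_lmc)
    fallback <- if (length(u_lmc_meas) > 0) stats::median(u_lmc_meas) else 0.53
    un <- setdiff(lmc, meas_lmc)
    if (length(meas_lmc) > 0)
      cons[[length(cons) + 1L]] <- velocity_target(meas_lmc, u_lmc_meas)
    if (length(un) > 0)
      cons[[length(cons) + 1L]] <- velocity_target(un, rep(fallback, length(un)))
  }
  cons[[length(cons) + 1L]] <- standard_root_constraints(net)
  constraints <- do.call(rbind, cons)

  net$vessels$measured <- net$vessels$id %in% c(meas_sa, meas_lmc)
  truth <- data.frame(edge = e$id, u_true = as.numeric(u[as.character(e$id)]))
  if (length(meas_sa) == 0 && length(lmc) == 0)
    warning("no surface measurements generated (empty constraint set apart from root ranges)")
  list(constraints = constraints, net = net, truth = truth)
}

#' Standard physiological range constraints at the tree roots
#'
#' 2-10 mm/s at every descending-artery root edge and 0.4-2 mm/s at every
#' ascending-vein root edge.
#'
#' @param net assembled [vascular_network()].
#' @return constraint data.frame (see [velocity_range()]).
#' @export
standard_root_constraints <- function(net) {
  rbind(velocity_range(root_edges(net, "DA"), 2, 10),
        velocity_range(root_edges(net, "AV"), 0.4, 2))
}
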