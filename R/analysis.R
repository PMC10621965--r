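#' Assign MCA/ACA territory sides to every vessel
#'
#' Each descending-artery (DA) root is labelled by tracing its baseline
#' supply upstream along surface-artery edges - at every vertex following
#' the incoming edge carrying the largest inflow - until the MCA or ACA
#' feeder edge at the circle of Willis is reached. DA tree edges inherit
#' their root's label; capillaries and ascending-vein trees take the label
#' of the nearest DA root in the pial plane (the DA-root Voronoi cell that
#' contains them); surface arteries are labelled by the same upstream trace
#' from their higher-pressure endpoint. LMC edges have side `"none"`.
#' The watershed line is the boundary between differently labelled Voronoi
#' cells.
#'
#' @param net a [vascular_network()].
#' @param base_solution baseline [solve_flow()] solution.
#' @return data.frame with columns `vessel_id`, `side`.
#' @export
assign_sides <- function(net, base_solution) {
  v <- net$vertices; e <- net$vessels
  sol <- base_solution
  i1 <- match(e$v1, v$id); i2 <- match(e$v2, v$id)
  p <- as.numeric(sol$pressure)

  pial_types <- c("SA", "SA_to_CoW")
  pial <- which(e$vtype %in% pial_types)
  feeder <- which(e$vtype == "SA_to_CoW")
  if (length(feeder) < 2) stop("need MCA and ACA feeder (SA_to_CoW) edges")
  cow <- v$id[v$role == "cow_inflow"]

  # incidence over pial edges only
  inc <- split(rep(pial, 2), c(e$v1[pial], e$v2[pial]))

  trace_cache <- new.env(parent = emptyenv())
  trace_side <- function(vid) {
    key <- as.character(vid)
    if (!is.null(trace_cache[[key]])) return(trace_cache[[key]])
    path <- integer(0)
    cur <- vid
    side <- NA_character_
    for (step in seq_len(length(pial) + 2L)) {
      if (cur == cow) { side <- NA_character_; break }
      inc_e <- inc[[as.character(cur)]]
      if (is.null(inc_e)) { side <- NA_character_; break }
      # inflow into cur: q > 0 flows v1 -> v2
      qin <- ifelse(e$v2[inc_e] == cur, sol$flow[inc_e], -sol$flow[inc_e])
      k <- inc_e[which.max(qin)]
      if (e$vtype[k] == "SA_to_CoW") { side <- e$side[k]; break }
      path <- c(path, cur)
      nxt <- if (e$v1[k] == cur) e$v2[k] else e$v1[k]
      if (nxt %in% path) { # cycle guard: fall back to geometric side
        side <- NA_character_
        break
      }
      cur <- nxt
    }
    if (is.na(side)) {
      # isolated or cyclic: nearest feeder endpoint in the plane
      fx <- v[match(e$v2[feeder], v$id), c("x", "y")]
      d2 <- (fx$x - v$x[match(vid, v$id)])^2 + (fx$y - v$y[match(vid, v$id)])^2
      side <- e$side[feeder[which.min(d2)]]
    }
    trace_cache[[key]] <- side
    side
  }

  side <- rep(NA_character_, nrow(e))
  side[e$vtype == "LMC"] <- "none"

  # SA edges: trace from the upstream (higher-pressure) endpoint
  for (k in pial) {
    up <- if (p[i1[k]] >= p[i2[k]]) e$v1[k] else e$v2[k]
    side[k] <- if (up == cow) e$side[k] else trace_side(up)
  }

  # DA roots and their trees
  da_roots <- v[v$role == "da_root", ]
  root_side <- vapply(da_roots$id, trace_side, character(1))
  # propagate down each DA tree by graph reachability over DA edges
  da_e <- which(e$vtype == "DA")
  if (length(da_e) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$v1[da_e]), to = as.character(e$v2[da_e])),
      directed = FALSE)
    comp <- igraph::components(g)$membership
    vert_comp <- comp[as.character(da_roots$id)]
    edge_comp <- comp[as.character(e$v1[da_e])]
    side[da_e] <- root_side[match(edge_comp, vert_comp)]
  }

  # capillaries + AV trees: nearest DA root in the pial plane
  rest <- which(e$vtype %in% c("C", "AV"))
  if (length(rest) > 0 && nrow(da_roots) > 0) {
    mid <- edge_midpoints(net)[rest, , drop = FALSE]
    nearest <- vapply(seq_len(nrow(mid)), function(k) {
      which.min((da_roots$x - mid[k, 1])^2 + (da_roots$y - mid[k, 2])^2)
    }, integer(1))
    side[rest] <- root_side[nearest]
  }
  data.frame(vessel_id = e$id, side = side)
}

#' Approximate DA-root Voronoi cell areas by grid quadrature
#'
#' Areas of the Voronoi cells around the DA roots, clipped to the convex-
#' hull footprint of the pial vertices, computed by nearest-root counting on
#' a dense regular grid. The areas sum to the footprint area by
#' construction, up to grid resolution.
#'
#' @param net a [vascular_network()].
#' @param grid_n grid points per axis.
#' @return list with `areas_um2` (named by DA-root vertex id),
#'   `footprint_um2`.
#' @export
voronoi_cell_areas <- function(net, grid_n = 200) {
  v <- net$vertices
  roots <- v[v$role == "da_root", ]
  if (nrow(roots) == 0) stop("no DA roots")
  pial_v <- v[v$z == 0, ]
  hull <- pial_v[grDevices::chull(pial_v$x, pial_v$y), c("x", "y")]
  hull <- as.matrix(hull)
  bb <- apply(hull, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = grid_n)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = grid_n)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  pts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  inside <- in_convex_polygon(pts, hull)
  pts <- pts[inside, , drop = FALSE]
  nearest <- vapply(seq_len(nrow(pts)), function(k) {
    which.min((roots$x - pts[k, 1])^2 + (roots$y - pts[k, 2])^2)
  }, integer(1))
  areas <- tabulate(nearest, nbins = nrow(roots)) * cell
  list(areas_um2 = stats::setNames(areas, roots$id),
       footprint_um2 = polygon_area(hull))
}

#' Classify surface arteries by shortest paths to the collaterals
#'
#' For each LMC endpoint, the geometric-length shortest path from the
#' circle-of-Willis vertex over SA / SA_to_CoW edges is computed (all tied
#' shortest paths are kept); every SA edge on any such path is classed
#' `on_path_to_LMC`, the remainder `other`.
#'
#' @param net a [vascular_network()].
#' @return data.frame `vessel_id`, `path_class` for the pial artery edges.
#' @export
classify_sa_paths <- function(net) {
  e <- net$vessels
  pial <- which(e$vtype %in% c("SA", "SA_to_CoW"))
  lmc <- which(e$vtype == "LMC")
  out <- data.frame(vessel_id = e$id[pial], path_class = "other")
  if (length(lmc) == 0) return(out)
  cow <- net$vertices$id[net$vertices$role == "cow_inflow"]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$v1[pial]),
               to = as.character(e$v2[pial]),
               weight = e$length[pial],
               eid = e$id[pial]),
    directed = FALSE)
  targets <- unique(c(e$v1[lmc], e$v2[lmc]))
  targets <- targets[as.character(targets) %in% igraph::V(g)$name]
  on_path <- character(0)
  for (tg in targets) {
    sp <- igraph::all_shortest_paths(g, from = as.character(cow),
                                     to = as.character(tg),
                                     weights = igraph::E(g)$weight)
    for (pth in sp$res) {
      eids <- igraph::E(g, path = pth)$eid
      on_path <- union(on_path, eids)
    }
  }
  out$path_class[out$vessel_id %in% as.numeric(on_path)] <- "on_path_to_LMC"
  out
}

#' Relative change of an aggregate between two states
#'
#' \eqn{(agg(new) - agg(base)) / agg(base)} with aggregator mean or sum.
#' Flow values should be passed as magnitudes (flows reverse under
#' occlusion and perfusion is reported positive); pressures enter signed.
#'
#' @param values_base,values_new numeric vectors over the same vessel class.
#' @param aggregator `"mean"` or `"sum"`.
#' @return fraction (0.5 means +50%); NA with a warning if the baseline
#'   aggregate is zero.
#' @export
relative_change <- function(values_base, values_new,
                            aggregator = c("mean", "sum")) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "mean") mean else sum
  b <- agg(values_base)
  if (b == 0) {
    warning("zero baseline aggregate; relative change undefined")
    return(NA_real_)
  }
  (agg(values_new) - b) / b
}

#' Planar distance of every vessel to the nearest LMC, binned
#'
#' Distance from each vessel midpoint to the nearest LMC segment in the
#' (x, y) pial plane; bin index is `floor(distance / spacing)` with the
#' conventional 250 um spacing.
#'
#' @param net a [vascular_network()].
#' @param spacing bin width, um.
#' @return data.frame `vessel_id`, `distance_um`, `bin`.
#' @export
distance_bins <- function(net, spacing = 250) {
  e <- net$vessels; v <- net$vertices
  lmc <- which(e$vtype == "LMC")
  mid <- edge_midpoints(net)
  if (length(lmc) == 0) {
    return(data.frame(vessel_id = e$id, distance_um = Inf,
                      bin = NA_integer_))
  }
  a <- v[match(e$v1[lmc], v$id), c("x", "y")]
  b <- v[match(e$v2[lmc], v$id), c("x", "y")]
  dist <- vapply(seq_len(nrow(e)), function(k) {
    pr <- project_to_segment(mid[k, 1], mid[k, 2], a$x, a$y, b$x, b$y)
    min(pr$dist)
  }, numeric(1))
  data.frame(vessel_id = e$id, distance_um = dist,
             bin = as.integer(floor(dist / spacing)))
}

#' Cerebral blood flow summary
#'
#' Total network inflow normalised per pial surface area, per tissue volume
#' (area x lattice depth) and per tissue mass (density 1046 kg/m^3).
#'
#' @param net a [vascular_network()].
#' @param sol a [solve_flow()] solution.
#' @param depth_um tissue depth used for the volume normalisation; default
#'   the deepest vertex.
#' @return list with `inflow_um3_s`, `per_area_ml_min_mm2`,
#'   `per_volume_ml_min_ml`, `per_mass_ml_min_100g`, `footprint_mm2`.
#' @export
cbf_summary <- function(net, sol, depth_um = NULL) {
  if (is.null(depth_um)) depth_um <- max(net$vertices$z)
  vor <- voronoi_cell_areas(net)
  area_um2 <- vor$footprint_um2
  if (area_um2 <= 0) stop("zero footprint area")
  bal <- vertex_flow_balance(net, sol)
  cow <- as.character(net$vertices$id[net$vertices$role == "cow_inflow"])
  inflow <- abs(bal[cow])                       # um^3/s leaving the inflow BC
  # um^3/s -> ml/min: 1 um^3 = 1e-12 ml
  ml_min <- inflow * 1e-12 * 60
  per_area <- ml_min / (area_um2 * 1e-6)        # ml/min per mm^2
  vol_ml <- area_um2 * depth_um * 1e-12         # 1 ml = 1 cm^3 = 1e12 um^3
  per_volume <- ml_min / vol_ml                 # ml blood / (ml tissue min)
  mass_100g <- vol_ml * 1.046 / 100             # ml tissue * g/ml / 100
  per_mass <- ml_min / mass_100g
  list(inflow_um3_s = unname(inflow),
       per_area_ml_min_mm2 = unname(per_area),
       per_volume_ml_min_ml = unname(per_volume),
       per_mass_ml_min_100g = unname(per_mass),
       footprint_mm2 = area_um2 * 1e-6)
}

#' Vessels whose flow direction flips between two solutions
#'
#' @param sol_a,sol_b two [solve_flow()] solutions on the same network (or
#'   on two states sharing edge ids, e.g. baseline vs occluded; only common
#'   edges are compared).
#' @param tol flows with magnitude below `tol` (relative to the larger
#'   median magnitude) in either state are treated as dead and excluded.
#' @return vessel ids with `sign(q_a) != sign(q_b)`.
#' @export
direction_changes <- function(sol_a, sol_b, tol = 1e-10) {
  common <- intersect(sol_a$vessel_id, sol_b$vessel_id)
  ia <- match(common, sol_a$vessel_id); ib <- match(common, sol_b$vessel_id)
  qa <- sol_a$flow[ia]; qb <- sol_b$flow[ib]
  scale <- max(stats::median(abs(qa)), stats::median(abs(qb)))
  alive <- abs(qa) > tol * scale & abs(qb) > tol * scale
  common[alive & (qa * qb < 0)]
}

#' Stratified relative-change report between two scenario states
#'
#' Tidy table of the mean-based and sum-based relative flow changes and the
#' mean-based pressure change, stratified by vessel class (vessel type x
#' territory side, plus the LMC class). Flow enters as magnitude, pressure
#' signed (edge midpoint pressure). Feeder (`SA_to_CoW`) edges and
#' leaf-to-capillary connectors are excluded from the class statistics.
#'
#' @param net the network both solutions refer to.
#' @param sol_base,sol_new two [solve_flow()] solutions on `net`.
#' @param sides side classification from [assign_sides()].
#' @param label_base,label_new state-pair labels for the report.
#' @return data.frame `class`, `state_pair`, `metric`, `value`, `n`.
#' @export
change_report <- function(net, sol_base, sol_new, sides,
                          label_base = "Base", label_new = "New") {
  e <- net$vessels
  side <- sides$side[match(e$id, sides$vessel_id)]
  keep <- e$vtype != "SA_to_CoW" & !e$is_connector
  cls <- ifelse(e$vtype == "LMC", "LMC", paste(side, e$vtype))
  p_base <- edge_mid_pressure(net, sol_base)
  p_new <- edge_mid_pressure(net, sol_new)
  pair <- paste(label_base, "->", label_new)
  out <- list()
  for (cl in sort(unique(cls[keep]))) {
    k <- keep & cls == cl
    out[[length(out) + 1L]] <- data.frame(
      class = cl, state_pair = pair,
      metric = c("dq_rel_mean", "dQ_rel_sum", "dp_rel_mean"),
      value = c(relative_change(abs(sol_base$flow[k]), abs(sol_new$flow[k]), "mean"),
                relative_change(abs(sol_base$flow[k]), abs(sol_new$flow[k]), "sum"),
                relative_change(p_base[k], p_new[k], "mean")),
      n = sum(k))
  }
  do.call(rbind, out)
}
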