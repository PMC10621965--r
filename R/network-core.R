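#' Construct a vascular network
#'
#' The central container shared by every stage of the pipeline: a geometric
#' graph of vessels with diameters, vessel types, territory sides and pressure
#' boundary conditions.
#'
#' Units are fixed network-wide: micrometres (positions, diameters, lengths),
#' mmHg (pressures), mm/s (velocities), um^3/s (flow rates) and mPa s
#' (viscosities). The conversion 1 mmHg = 133.322 Pa is applied only inside
#' the flow solver.
#'
#' @param vertices data.frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (um; `z` is cortical depth, 0 at the pial surface, increasing
#'   downward) and `role` (one of `"internal"`, `"cow_inflow"`, `"da_root"`,
#'   `"av_root"`, `"tree_leaf"`).
#' @param vessels data.frame with columns `id` (integer, unique), `v1`, `v2`
#'   (endpoint vertex ids), `diameter` (um), `length` (um), `vtype` (one of
#'   `"SA"`, `"SA_to_CoW"`, `"LMC"`, `"DA"`, `"C"`, `"AV"`) and `side`
#'   (`"MCA"`, `"ACA"` or `"none"`). Optional columns `measured` (logical,
#'   diameter measurement available), `d_prior` (um, diameter before tuning)
#'   and `is_connector` (logical, tree-leaf-to-capillary connector) are added
#'   with defaults when absent.
#' @param boundary_conditions data.frame with columns `vertex` (id) and
#'   `pressure` (mmHg).
#' @param hematocrit discharge haematocrit, dimensionless. The model assumes
#'   it constant throughout the network (phase separation is neglected).
#' @param plasma_viscosity plasma viscosity in mPa s.
#' @param viscosity_law `"in_vitro"` (default) or `"in_vivo"`; see
#'   [relative_viscosity()].
#' @return An object of class `vascular_network`.
#' @seealso [validate_network()], [solve_flow()], [category_counts()]
#' @export
vascular_network <- function(vertices, vessels,
                             boundary_conditions = NULL,
                             hematocrit = 0.3,
                             plasma_viscosity = 1.2,
                             viscosity_law = c("in_vitro", "in_vivo")) {
  viscosity_law <- match.arg(viscosity_law)
  vertices <- as.data.frame(vertices)
  vessels <- as.data.frame(vessels)
  need_v <- c("id", "x", "y", "z", "role")
  if (!all(need_v %in% names(vertices)))
    stop("vertices must have columns: ", paste(need_v, collapse = ", "))
  need_e <- c("id", "v1", "v2", "diameter", "length", "vtype", "side")
  if (!all(need_e %in% names(vessels)))
    stop("vessels must have columns: ", paste(need_e, collapse = ", "))
  if (is.null(vessels$measured)) vessels$measured <- FALSE
  if (is.null(vessels$d_prior)) vessels$d_prior <- vessels$diameter
  if (is.null(vessels$is_connector)) vessels$is_connector <- FALSE
  if (is.null(boundary_conditions))
    boundary_conditions <- data.frame(vertex = integer(), pressure = numeric())
  structure(
    list(vertices = vertices,
         vessels = vessels,
         boundary_conditions = as.data.frame(boundary_conditions),
         hematocrit = hematocrit,
         plasma_viscosity = plasma_viscosity,
         viscosity_law = viscosity_law),
    class = "vascular_network")
}

VESSEL_TYPES <- c("SA", "SA_to_CoW", "LMC", "DA", "C", "AV")
VERTEX_ROLES <- c("internal", "cow_inflow", "da_root", "av_root", "tree_leaf")

#' @export
print.vascular_network <- function(x, ...) {
  cat("Vascular network:", nrow(x$vertices), "vertices,",
      nrow(x$vessels), "vessels\n")
  tt <- table(factor(x$vessels$vtype, levels = VESSEL_TYPES))
  cat("  vessel types:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  cat("  boundary conditions:", nrow(x$boundary_conditions),
      "| haematocrit:", x$hematocrit,
      "| plasma viscosity:", x$plasma_viscosity, "mPa s\n")
  invisible(x)
}

#' @export
summary.vascular_network <- function(object, ...) {
  cc <- category_counts(object)
  print(object)
  cat("\nPer-type totals:\n")
  print(cc)
  invisible(cc)
}

euclid_dist <- function(p1, p2) sqrt(rowSums((p1 - p2)^2))

vertex_xyz <- function(net, ids) {
  i <- match(ids, net$vertices$id)
  as.matrix(net$vertices[i, c("x", "y", "z"), drop = FALSE])
}

#' Validate the structural invariants of a vascular network
#'
#' Checks id uniqueness, positive diameters and lengths, length >= chord
#' (tortuosity >= 1), endpoint referential integrity, the single-inflow
#' contract, outflow boundary conditions on every ascending-vein root,
#' and connectivity from the inflow vertex to every boundary vertex.
#' Violations are reported, never raised.
#'
#' @param net a [vascular_network()].
#' @param tol relative slack allowed on the length >= chord check.
#' @return character vector of violation messages; empty if the network is
#'   valid.
#' @export
validate_network <- function(net, tol = 1e-6) {
  v <- net$vertices; e <- net$vessels; bc <- net$boundary_conditions
  bad <- character()
  rpt <- function(...) bad <<- c(bad, sprintf(...))

  if (anyDuplicated(v$id)) rpt("duplicate vertex ids")
  if (anyDuplicated(e$id)) rpt("duplicate vessel ids")
  if (!all(is.finite(as.matrix(v[, c("x", "y", "z")]))))
    rpt("non-finite vertex positions")
  if (!all(v$role %in% VERTEX_ROLES)) rpt("unknown vertex role")
  if (!all(e$vtype %in% VESSEL_TYPES)) rpt("unknown vessel type")

  n_inflow <- sum(v$role == "cow_inflow")
  if (n_inflow != 1L) rpt("network must have exactly 1 inflow vertex (found %d)", n_inflow)

  dangling <- !(e$v1 %in% v$id) | !(e$v2 %in% v$id)
  if (any(dangling)) rpt("dangling endpoints on vessels: %s",
                         paste(e$id[dangling], collapse = ", "))

  np <- which(!(e$diameter > 0))
  for (i in np) rpt("nonpositive diameter on vessel %d", e$id[i])
  if (any(!(e$length > 0))) rpt("nonpositive length")

  if (!any(dangling) && nrow(e) > 0) {
    chord <- euclid_dist(vertex_xyz(net, e$v1), vertex_xyz(net, e$v2))
    short <- e$length < chord * (1 - tol)
    if (any(short)) rpt("length below endpoint distance on vessels: %s",
                        paste(e$id[short], collapse = ", "))
  }

  av <- v$id[v$role == "av_root"]
  missing_bc <- setdiff(av, bc$vertex)
  if (length(missing_bc) > 0)
    rpt("av_root vertices without boundary condition: %s",
        paste(missing_bc, collapse = ", "))
  if (nrow(bc) > 0 && !all(bc$vertex %in% v$id))
    rpt("boundary condition on unknown vertex")

  # connectivity: every boundary vertex reachable from the inflow vertex
  if (n_inflow == 1L && nrow(e) > 0 && !any(dangling) && nrow(bc) > 0) {
    g <- igraph::graph_from_edgelist(
      cbind(match(e$v1, v$id), match(e$v2, v$id)), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(v) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    src <- comp[match(v$id[v$role == "cow_inflow"], v$id)]
    tgt <- comp[match(bc$vertex, v$id)]
    off <- bc$vertex[tgt != src]
    if (length(off) > 0)
      rpt("boundary vertices disconnected from inflow: %s",
          paste(off, collapse = ", "))
  }
  bad
}

#' Per-type edge counts, total lengths and total volumes
#'
#' Volume per vessel is pi d^2 / 4 * L (cylinder).
#'
#' @param net a [vascular_network()].
#' @return data.frame with one row per vessel type: `n`, `length_um`,
#'   `volume_um3`.
#' @export
category_counts <- function(net) {
  e <- net$vessels
  vol <- pi * e$diameter^2 / 4 * e$length
  f <- factor(e$vtype, levels = VESSEL_TYPES)
  data.frame(
    vtype = VESSEL_TYPES,
    n = as.integer(tabulate(f, nbins = length(VESSEL_TYPES))),
    length_um = as.numeric(tapply(e$length, f, sum, default = 0)),
    volume_um3 = as.numeric(tapply(vol, f, sum, default = 0)),
    row.names = NULL)
}

# midpoint coordinates of every vessel (matrix, um)
edge_midpoints <- function(net) {
  (vertex_xyz(net, net$vessels$v1) + vertex_xyz(net, net$vessels$v2)) / 2
}

next_id <- function(ids) if (length(ids) == 0) 1L else max(ids) + 1L
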