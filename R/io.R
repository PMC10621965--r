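#' Write / read a vascular network as CSV tables
#'
#' The canonical interchange format: a vertex table (id, x, y, z, role,
#' boundary pressure) and an edge table (id, endpoints, diameter, length,
#' vtype, side, measured flag, prior diameter, connector flag). The
#' write -> read round trip is lossless on all fields.
#'
#' @param net a [vascular_network()].
#' @param vertices_path,edges_path CSV file paths.
#' @return `write_network` invisibly returns the paths; `read_network`
#'   returns the [vascular_network()].
#' @export
write_network <- function(net, vertices_path, edges_path) {
  v <- net$vertices
  bc <- net$boundary_conditions
  v$boundary_pressure <- bc$pressure[match(v$id, bc$vertex)]
  utils::write.csv(v, vertices_path, row.names = FALSE)
  utils::write.csv(net$vessels, edges_path, row.names = FALSE)
  invisible(c(vertices_path, edges_path))
}

#' @rdname write_network
#' @param hematocrit,plasma_viscosity,viscosity_law forwarded to
#'   [vascular_network()].
#' @export
read_network <- function(vertices_path, edges_path, hematocrit = 0.3,
                         plasma_viscosity = 1.2,
                         viscosity_law = "in_vitro") {
  v <- utils::read.csv(vertices_path)
  e <- utils::read.csv(edges_path)
  need_v <- c("id", "x", "y", "z", "role")
  miss <- setdiff(need_v, names(v))
  if (length(miss) > 0) stop("vertex table missing column(s): ",
                             paste(miss, collapse = ", "))
  need_e <- c("id", "v1", "v2", "diameter", "length", "vtype", "side")
  miss <- setdiff(need_e, names(e))
  if (length(miss) > 0) stop("edge table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(v$id))
    stop("duplicate vertex id at row ", which(duplicated(v$id))[1])
  if (anyDuplicated(e$id))
    stop("duplicate edge id at row ", which(duplicated(e$id))[1])
  dang <- which(!(e$v1 %in% v$id) | !(e$v2 %in% v$id))
  if (length(dang) > 0)
    stop("edge ", e$id[dang[1]], " references an absent vertex (row ",
         dang[1], ")")
  bc <- data.frame(vertex = v$id, pressure = v$boundary_pressure)
  bc <- bc[is.finite(bc$pressure), ]
  v$boundary_pressure <- NULL
  vascular_network(v, e, bc, hematocrit = hematocrit,
                   plasma_viscosity = plasma_viscosity,
                   viscosity_law = viscosity_law)
}

#' Export a network as GraphML
#'
#' @param net a [vascular_network()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
export_graphml <- function(net, path) {
  e <- net$vessels
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$v1), to = as.character(e$v2),
               vessel_id = e$id, diameter = e$diameter, length = e$length,
               vtype = e$vtype, side = e$side),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$vertices$id),
                          x = net$vertices$x, y = net$vertices$y,
                          z = net$vertices$z, role = net$vertices$role))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network (with optional solution) as VTK XML PolyData
#'
#' ASCII `.vtp` polydata: one two-point line cell per vessel, per-cell
#' arrays for diameter, vessel type code, and - when a solution is given -
#' flow, velocity and wall shear stress, plus per-point pressure.
#'
#' @param net a [vascular_network()].
#' @param path output file (conventionally `.vtp`).
#' @param solution optional [solve_flow()] solution.
#' @return invisibly, the path.
#' @export
export_vtp <- function(net, path, solution = NULL) {
  v <- net$vertices; e <- net$vessels
  idx <- match(c(rbind(e$v1, e$v2)), v$id) - 1L # zero-based, interleaved
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(format(x, trim = TRUE, scientific = TRUE,
                                  digits = 9), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('<PolyData><Piece NumberOfPoints="%d" NumberOfLines="%d">',
    nrow(v), nrow(e))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w('%s', num(as.numeric(t(as.matrix(v[, c("x", "y", "z")])))))
  w('</DataArray></Points>')
  w('<Lines><DataArray type="Int64" Name="connectivity" format="ascii">')
  w('%s', paste(idx, collapse = " "))
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  w('%s', paste(2L * seq_len(nrow(e)), collapse = " "))
  w('</DataArray></Lines>')
  w('<CellData>')
  arr <- function(name, x) {
    w('<DataArray type="Float64" Name="%s" format="ascii">', name)
    w('%s', num(x)); w('</DataArray>')
  }
  arr("diameter", e$diameter)
  arr("vtype_code", as.numeric(factor(e$vtype, levels = VESSEL_TYPES)))
  if (!is.null(solution)) {
    arr("flow", solution$flow)
    arr("velocity", solution$velocity)
    arr("wss", solution$wss)
  }
  w('</CellData>')
  if (!is.null(solution)) {
    w('<PointData>')
    arr("pressure", as.numeric(solution$pressure))
    w('</PointData>')
  }
  w('</Piece></PolyData></VTKFile>')
  invisible(path)
}
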