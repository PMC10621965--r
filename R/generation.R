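#' Configuration for semi-realistic network generation
#'
#' Defaults encode the stated physiology: capillary diameter 4 um, length
#' 62 um, tortuosity 1.37, a descending-artery (DA) to ascending-vein (AV)
#' root ratio of 1:3, and penetrating trees scaled to 2/3 of reference (rat)
#' dimensions via the depth and diameter defaults.
#'
#' @param target_da_root_density DA roots per mm^2 of pial footprint.
#' @param av_per_da AV roots placed around each DA root.
#' @param av_root_offset um, radial offset of AV roots from their DA root on
#'   the rhombic pattern.
#' @param capillary_diameter um.
#' @param capillary_length um (hydraulic length of a lattice edge).
#' @param capillary_tortuosity length / chord of a lattice edge.
#' @param lattice_depth um, depth of the deepest capillary layer.
#' @param lattice_layers number of stacked hexagonal layers.
#' @param tree_scale scaling applied to reference tree dimensions.
#' @param da_root_diameter,av_root_diameter um, penetrating-tree root
#'   diameters (before Murray tapering toward the leaves).
#' @param tree_leaves target leaf count per penetrating tree.
#' @param min_root_spacing um, rejection radius between sampled DA roots.
#' @param max_connector_length um, longest admissible leaf-to-capillary
#'   connector.
#' @param interlayer_fraction fraction of lattice vertices joined to the
#'   layer below (controls vertical capillary path density).
#' @param rng_seed integer seed used by the stochastic generation steps.
#' @return list of class `generation_config`.
#' @export
generation_config <- function(target_da_root_density = 12,
                              av_per_da = 3,
                              av_root_offset = 80,
                              capillary_diameter = 4,
                              capillary_length = 62,
                              capillary_tortuosity = 1.37,
                              lattice_depth = 500,
                              lattice_layers = 4,
                              tree_scale = 2 / 3,
                              da_root_diameter = 14,
                              av_root_diameter = 18,
                              tree_leaves = 2,
                              min_root_spacing = 140,
                              max_connector_length = 200,
                              interlayer_fraction = 0.2,
                              rng_seed = 1L) {
  cfg <- list(target_da_root_density = target_da_root_density,
              av_per_da = av_per_da, av_root_offset = av_root_offset,
              capillary_diameter = capillary_diameter,
              capillary_length = capillary_length,
              capillary_tortuosity = capillary_tortuosity,
              lattice_depth = lattice_depth,
              lattice_layers = lattice_layers,
              tree_scale = tree_scale,
              da_root_diameter = da_root_diameter,
              av_root_diameter = av_root_diameter,
              tree_leaves = tree_leaves,
              min_root_spacing = min_root_spacing,
              max_connector_length = max_connector_length,
              interlayer_fraction = interlayer_fraction,
              rng_seed = as.integer(rng_seed))
  stopifnot(av_per_da >= 1, capillary_tortuosity >= 1,
            all(vapply(cfg[1:14], function(x) all(x > 0), TRUE)))
  class(cfg) <- "generation_config"
  cfg
}

# convex hull of the pial (x, y) vertices, as a polygon matrix; the
# circle-of-Willis stem lies outside the cortical window and is excluded
footprint_hull <- function(net) {
  v <- net$vertices[net$vertices$role != "cow_inflow", ]
  xy <- as.matrix(v[, c("x", "y")])
  xy[grDevices::chull(xy), , drop = FALSE]
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# points-in-convex-polygon (vertices in chull order)
in_convex_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr <= 1e-9 * max(abs(poly)) # chull order is clockwise
  }
  if (!any(inside)) { # orientation was the other way
    inside <- rep(TRUE, nrow(pts))
    for (k in seq_len(n)) {
      a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
      cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
      inside <- inside & cr >= -1e-9 * max(abs(poly))
    }
  }
  inside
}

#' Refine a pial network by sampling additional DA roots
#'
#' Samples descending-artery root locations uniformly over the convex-hull
#' footprint of the pial vertices (with a minimum-spacing rejection rule)
#' until the root count matches `round(density * footprint area)`, and
#' connects each new root to the nearest surface artery (SA) by splitting
#' that SA at the orthogonal projection point and adding a short new SA
#' vessel. Original SA edges are never removed, only split; ties between
#' equidistant SAs are broken by the lower edge id.
#'
#' @param pial a pial-only [vascular_network()] (SA / SA_to_CoW / LMC edges,
#'   z = 0).
#' @param cfg a [generation_config()].
#' @return the refined network, with new vertices of role `da_root`.
#' @export
refine_pial_network <- function(pial, cfg) {
  set.seed(cfg$rng_seed)
  hull <- footprint_hull(pial)
  area_mm2 <- polygon_area(hull) / 1e6
  target <- round(cfg$target_da_root_density * area_mm2)
  have <- sum(pial$vertices$role == "da_root")
  if (target <= have) return(pial)
  n_new <- target - have
  # feasibility: hexagonal packing bound
  if (n_new * pi * (cfg$min_root_spacing / 2)^2 > 2 * polygon_area(hull))
    stop("target DA-root density unreachable at minimum spacing ",
         cfg$min_root_spacing, " um")

  bb <- apply(hull, 2, range)
  pts <- matrix(numeric(0), ncol = 2)
  existing <- as.matrix(
    pial$vertices[pial$vertices$role == "da_root", c("x", "y"), drop = FALSE])
  tries <- 0
  while (nrow(pts) < n_new && tries < 20000) {
    tries <- tries + 1
    cand <- c(stats::runif(1, bb[1, 1], bb[2, 1]),
              stats::runif(1, bb[1, 2], bb[2, 2]))
    if (!in_convex_polygon(matrix(cand, 1), hull)) next
    all_pts <- rbind(existing, pts)
    if (nrow(all_pts) > 0 &&
        min(sqrt((all_pts[, 1] - cand[1])^2 + (all_pts[, 2] - cand[2])^2)) <
          cfg$min_root_spacing) next
    pts <- rbind(pts, cand)
  }
  if (nrow(pts) < n_new)
    stop("target DA-root density unreachable at minimum spacing ",
         cfg$min_root_spacing, " um (placed ", nrow(pts), " of ", n_new, ")")

  net <- pial
  for (k in seq_len(nrow(pts))) {
    net <- attach_da_root(net, pts[k, 1], pts[k, 2])
  }
  net
}

# project point p onto segment a-b in the plane; returns list(t, dist, foot)
project_to_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  fx <- ax + t * vx; fy <- ay + t * vy
  list(t = t, dist = sqrt((px - fx)^2 + (py - fy)^2), fx = fx, fy = fy)
}

# add one DA-root vertex at (x, y), split the nearest SA edge at the
# projection foot and connect root to the split vertex
attach_da_root <- function(net, x, y) {
  v <- net$vertices; e <- net$vessels
  sa <- which(e$vtype == "SA")
  p1 <- vertex_xyz(net, e$v1[sa]); p2 <- vertex_xyz(net, e$v2[sa])
  pr <- project_to_segment(x, y, p1[, 1], p1[, 2], p2[, 1], p2[, 2])
  best <- sa[order(pr$dist, e$id[sa])[1]]
  bi <- match(best, e$id[sa]) # index within sa subset
  bi <- which(sa == best)
  t <- pr$t[bi]; fx <- pr$fx[bi]; fy <- pr$fy[bi]

  root_id <- next_id(v$id)
  v <- rbind(v, data.frame(id = root_id, x = x, y = y, z = 0,
                           role = "da_root"))
  host <- e[best, ]
  if (t > 1e-6 && t < 1 - 1e-6) {
    split_id <- next_id(v$id)
    v <- rbind(v, data.frame(id = split_id, x = fx, y = fy, z = 0,
                             role = "internal"))
    # shorten host to v1 -> split, add split -> v2 (same id family)
    new_edge <- host
    new_edge$id <- next_id(e$id)
    new_edge$v1 <- split_id
    new_edge$length <- host$length * (1 - t)
    e$v2[e$id == host$id] <- split_id
    e$length[e$id == host$id] <- host$length * t
    e <- rbind(e, new_edge)
    join <- split_id
  } else {
    join <- if (t <= 1e-6) host$v1 else host$v2
  }
  jxy <- v[match(join, v$id), c("x", "y")]
  conn_len <- max(sqrt((x - jxy$x)^2 + (y - jxy$y)^2), 1)
  conn <- e[1, ]
  conn$id <- next_id(e$id)
  conn$v1 <- join; conn$v2 <- root_id
  conn$diameter <- max(0.7 * host$diameter, 8)
  conn$length <- conn_len
  conn$vtype <- "SA"; conn$side <- host$side
  conn$measured <- FALSE; conn$d_prior <- conn$diameter
  conn$is_connector <- FALSE
  e <- rbind(e, conn)
  net$vertices <- v; net$vessels <- e
  net
}

#' Place ascending-vein roots around each DA root
#'
#' Positions `av_per_da` AV-root vertices on a rhombic pattern around every
#' DA root (fixed angular offsets, deterministic given the seed), mimicking
#' the observed 1:3 DA:AV surface arrangement. The outflow boundary
#' conditions for these roots are assigned later, in [assemble_network()].
#'
#' @param net refined pial network (DA roots present).
#' @param cfg a [generation_config()].
#' @return network with added `av_root` vertices.
#' @export
place_av_roots <- function(net, cfg) {
  set.seed(cfg$rng_seed + 1L)
  v <- net$vertices
  roots <- v[v$role == "da_root", ]
  if (nrow(roots) == 0) stop("no DA roots placed")
  base_angles <- c(90, 210, 330) * pi / 180
  out <- vector("list", nrow(roots))
  for (k in seq_len(nrow(roots))) {
    nk <- cfg$av_per_da
    ang <- base_angles[((seq_len(nk) - 1) %% 3) + 1] +
      2 * pi * ((seq_len(nk) - 1) %/% 3) / 6 +
      stats::runif(1, 0, 2 * pi / 12)
    r <- cfg$av_root_offset * (1 + 0.25 * ((seq_len(nk) - 1) %/% 3))
    out[[k]] <- data.frame(x = roots$x[k] + r * cos(ang),
                           y = roots$y[k] + r * sin(ang))
  }
  av <- do.call(rbind, out)
  ids <- next_id(v$id) + seq_len(nrow(av)) - 1L
  net$vertices <- rbind(v, data.frame(id = ids, x = av$x, y = av$y, z = 0,
                                      role = "av_root"))
  net
}

#' Generate one synthetic penetrating tree
#'
#' A random bifurcating tree descending from the pial surface (z = 0) toward
#' the capillary lattice depth. Diameters taper from the root by the
#' symmetric Murray rule \eqn{d_{child} = d_{parent} 2^{-1/3}} (so
#' \eqn{d_{parent}^3 = \sum d_{child}^3} exactly for symmetric splits).
#' Ascending-vein trees use the same geometry with the flow contract
#' reversed (drainage toward the root). This generator stands in for a
#' reference anatomical tree database that is not distributed; its scale is
#' set by `cfg$tree_scale` and the depth/diameter defaults.
#'
#' @param root_x,root_y planar root position um.
#' @param root_id vertex id to use for the (existing) root vertex.
#' @param kind `"DA"` or `"AV"`.
#' @param cfg a [generation_config()].
#' @param id_base first free vertex id and edge id, `c(vid, eid)`.
#' @return list with `vertices`, `vessels` data.frames (root vertex not
#'   included; edges reference `root_id`).
#' @export
generate_penetrating_tree <- function(root_x, root_y, root_id, kind, cfg,
                                      id_base) {
  if (cfg$lattice_depth <= 0) stop("lattice depth must be positive")
  stopifnot(kind %in% c("DA", "AV"))
  d_root <- if (kind == "DA") cfg$da_root_diameter else cfg$av_root_diameter
  depth <- cfg$lattice_depth
  vid <- id_base[1]; eid <- id_base[2]
  verts <- list(); edges <- list()
  # stack of open branch ends: (vertex id, x, y, z, diameter, leaves left)
  new_vertex <- function(x, y, z, role) {
    id <- vid; vid <<- vid + 1L
    verts[[length(verts) + 1L]] <<- data.frame(id = id, x = x, y = y, z = z,
                                               role = role)
    id
  }
  new_edge <- function(a, b, d, len) {
    edges[[length(edges) + 1L]] <<- data.frame(
      id = eid, v1 = a, v2 = b, diameter = d, length = len,
      vtype = kind, side = "none", measured = FALSE, d_prior = d,
      is_connector = FALSE)
    eid <<- eid + 1L
  }
  grow <- function(from_id, x, y, z, d, n_leaves) {
    seg <- depth / 5 * stats::runif(1, 0.7, 1.3) * cfg$tree_scale * 1.5
    nz <- min(z + seg, depth * stats::runif(1, 0.92, 1.0))
    nx <- x + stats::rnorm(1, 0, 18); ny <- y + stats::rnorm(1, 0, 18)
    chord <- sqrt((nx - x)^2 + (ny - y)^2 + (nz - z)^2)
    if (n_leaves <= 1 || nz >= depth * 0.9) {
      leaf <- new_vertex(nx, ny, nz, "tree_leaf")
      new_edge(from_id, leaf, d, chord * 1.1)
      return(invisible())
    }
    node <- new_vertex(nx, ny, nz, "internal")
    new_edge(from_id, node, d, chord * 1.1)
    d_child <- d / 2^(1 / 3)
    nl <- c(ceiling(n_leaves / 2), floor(n_leaves / 2))
    grow(node, nx, ny, nz, d_child, nl[1])
    grow(node, nx, ny, nz, d_child, nl[2])
  }
  grow(root_id, root_x, root_y, 0, d_root, cfg$tree_leaves)
  list(vertices = do.call(rbind, verts), vessels = do.call(rbind, edges),
       next_ids = c(vid, eid))
}

#' Generate a stacked hexagonal capillary lattice
#'
#' Honeycomb layers stacked in z. Every lattice edge carries the configured
#' capillary diameter and hydraulic length; node spacing (chord) is
#' `capillary_length / capillary_tortuosity` so per-edge tortuosity equals
#' the configured value exactly. Interior vertices have degree 3 within a
#' layer; vertically aligned vertices of adjacent layers are joined by
#' connector edges of the same diameter.
#'
#' @param bbox list/vector `c(xmin, xmax, ymin, ymax)` um.
#' @param cfg a [generation_config()].
#' @param id_base first free vertex id and edge id, `c(vid, eid)`.
#' @return list with `vertices`, `vessels`.
#' @export
generate_capillary_lattice <- function(bbox, cfg, id_base) {
  a <- cfg$capillary_length / cfg$capillary_tortuosity # chord / bond length
  w <- bbox[2] - bbox[1]; h <- bbox[4] - bbox[3]
  if (w < 3 * a || h < 2 * a) stop("bbox smaller than one hexagon")
  # honeycomb as a brick-wall embedding: rows of vertices, alternating offset
  dx <- a * sqrt(3) / 2
  nx <- floor(w / dx) + 1
  ny <- floor(h / (a * 1.5)) + 1
  layers <- cfg$lattice_layers
  zs <- cfg$lattice_depth * seq_len(layers) / layers

  verts <- list(); edges <- list()
  vid <- id_base[1]; eid <- id_base[2]
  idx <- array(NA_integer_, dim = c(nx, ny, layers))
  for (l in seq_len(layers)) {
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        x <- bbox[1] + (i - 1) * dx
        y <- bbox[3] + (j - 1) * 1.5 * a + ((i + j) %% 2) * 0.5 * a
        idx[i, j, l] <- vid
        verts[[length(verts) + 1L]] <- data.frame(
          id = vid, x = x, y = y, z = zs[l], role = "internal")
        vid <- vid + 1L
      }
    }
  }
  # in-plane bonds carry the stated capillary length exactly; the sparser
  # inter-layer connectors span the layer gap, so their hydraulic length is
  # chord * tortuosity when the gap exceeds the in-plane chord
  add_edge <- function(a_, b_, len = cfg$capillary_length) {
    edges[[length(edges) + 1L]] <<- data.frame(
      id = eid, v1 = a_, v2 = b_, diameter = cfg$capillary_diameter,
      length = len, vtype = "C", side = "none",
      measured = FALSE, d_prior = cfg$capillary_diameter,
      is_connector = FALSE)
    eid <<- eid + 1L
  }
  zgap <- if (layers > 1) zs[2] - zs[1] else 0
  zlen <- max(cfg$capillary_length, zgap * cfg$capillary_tortuosity)
  for (l in seq_len(layers)) {
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        # horizontal zig-zag bonds
        if (i < nx) add_edge(idx[i, j, l], idx[i + 1, j, l])
        # vertical bond only where the honeycomb has one: when this vertex
        # sits at the lower offset of its column pair
        if (j < ny && (i + j) %% 2 == 1) add_edge(idx[i, j, l], idx[i, j + 1, l])
      }
    }
    if (l < layers) {
      # inter-layer connectors on a thinned set (every 2nd vertex) to keep
      # the vertical bond density comparable to in-plane density
      period <- max(1L, round(1 / cfg$interlayer_fraction))
      for (j in seq_len(ny)) for (i in seq_len(nx)) {
        if ((i + 2 * j) %% period == 0) add_edge(idx[i, j, l], idx[i, j, l + 1],
                                                 len = zlen)
      }
    }
  }
  list(vertices = do.call(rbind, verts), vessels = do.call(rbind, edges),
       next_ids = c(vid, eid))
}

#' Assemble the full semi-realistic network
#'
#' Grows a penetrating tree from every DA and AV root of the refined pial
#' network, generates the capillary lattice under the pial footprint, joins
#' every tree leaf to its nearest lattice vertex by a connector edge, and
#' sets the pressure boundary conditions: 100 mmHg at the single circle-of-
#' Willis inflow vertex and 10 mmHg at every AV root.
#'
#' @param pial refined pial network (DA and AV roots placed; one
#'   `cow_inflow` vertex).
#' @param cfg a [generation_config()].
#' @param p_in,p_out boundary pressures, mmHg.
#' @return a complete [vascular_network()] that passes [validate_network()].
#' @export
assemble_network <- function(pial, cfg, p_in = 100, p_out = 10) {
  set.seed(cfg$rng_seed + 2L)
  v <- pial$vertices; e <- pial$vessels
  vid <- next_id(v$id); eid <- next_id(e$id)

  hull <- footprint_hull(pial)
  bbox <- c(range(hull[, 1]), range(hull[, 2]))
  lat <- generate_capillary_lattice(bbox, cfg, c(vid, eid))
  vid <- lat$next_ids[1]; eid <- lat$next_ids[2]

  trees_v <- list(); trees_e <- list()
  roots <- v[v$role %in% c("da_root", "av_root"), ]
  for (k in seq_len(nrow(roots))) {
    kind <- if (roots$role[k] == "da_root") "DA" else "AV"
    tr <- generate_penetrating_tree(roots$x[k], roots$y[k], roots$id[k],
                                    kind, cfg, c(vid, eid))
    vid <- tr$next_ids[1]; eid <- tr$next_ids[2]
    trees_v[[k]] <- tr$vertices; trees_e[[k]] <- tr$vessels
  }
  tv <- do.call(rbind, trees_v); te <- do.call(rbind, trees_e)

  v2 <- rbind(v, lat$vertices, tv)
  if (is.null(e$measured)) e$measured <- FALSE
  if (is.null(e$d_prior)) e$d_prior <- e$diameter
  if (is.null(e$is_connector)) e$is_connector <- FALSE
  e2 <- rbind(e[, names(te)], lat$vessels, te)

  # connect tree leaves to nearest capillary vertex
  leaves <- tv[tv$role == "tree_leaf", ]
  lxyz <- as.matrix(leaves[, c("x", "y", "z")])
  cxyz <- as.matrix(lat$vertices[, c("x", "y", "z")])
  conn <- vector("list", nrow(leaves))
  tree_type <- te$vtype[match(leaves$id, te$v2)]
  for (k in seq_len(nrow(leaves))) {
    d2 <- (cxyz[, 1] - lxyz[k, 1])^2 + (cxyz[, 2] - lxyz[k, 2])^2 +
      (cxyz[, 3] - lxyz[k, 3])^2
    j <- which.min(d2)
    len <- sqrt(d2[j])
    if (len > cfg$max_connector_length)
      stop("tree leaf ", leaves$id[k], " farther than ",
           cfg$max_connector_length, " um from any capillary")
    conn[[k]] <- data.frame(
      id = eid, v1 = leaves$id[k], v2 = lat$vertices$id[j],
      diameter = cfg$capillary_diameter + 1,
      length = max(len, 1) * 1.05, vtype = tree_type[k], side = "none",
      measured = FALSE, d_prior = cfg$capillary_diameter + 1,
      is_connector = TRUE)
    eid <- eid + 1L
  }
  e2 <- rbind(e2, do.call(rbind, conn))

  cow <- v2$id[v2$role == "cow_inflow"]
  if (length(cow) != 1) stop("pial network must have exactly one cow_inflow vertex")
  av <- v2$id[v2$role == "av_root"]
  bc <- data.frame(vertex = c(cow, av),
                   pressure = c(p_in, rep(p_out, length(av))))

  out <- vascular_network(v2, e2, bc,
                          hematocrit = pial$hematocrit,
                          plasma_viscosity = pial$plasma_viscosity,
                          viscosity_law = pial$viscosity_law)
  out
}
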