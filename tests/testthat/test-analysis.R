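test_that("territory sides split the symmetric fixture roughly in half", {
  net <- cached_states()$Base$network
  sides <- cached_sides()
  e <- net$vessels
  side <- sides$side[match(e$id, sides$vessel_id)]
  expect_true(all(side[e$vtype == "LMC"] == "none"))
  expect_false(any(is.na(side[e$vtype != "LMC"])))
  # DA roots divide between territories near 50/50 (lattice-boundary slack)
  i_da <- match(root_edges(net, "DA"), e$id)
  frac <- mean(side[i_da] == "MCA")
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
  # capillaries on the far left are MCA, far right ACA (Voronoi membership)
  mid <- (net$vertices$x[match(e$v1, net$vertices$id)] +
            net$vertices$x[match(e$v2, net$vertices$id)]) / 2
  capL <- e$vtype == "C" & mid < 150
  capR <- e$vtype == "C" & mid > 850
  expect_true(all(side[capL] == "MCA"))
  expect_true(all(side[capR] == "ACA"))
})

test_that("side labels are invariant under edge-id relabeling", {
  net <- cached_states()$Base$network
  sides <- cached_sides()
  perm_net <- net
  set.seed(42)
  newid <- sample(1e5, nrow(net$vessels)) # random distinct ids
  perm_net$vessels$id <- newid
  sol <- cached_states()$Base$solution
  perm_sol <- sol
  perm_sol$vessel_id <- newid
  perm <- assign_sides(perm_net, perm_sol)
  expect_identical(perm$side, sides$side)
})

test_that("shortest-path classes mark the pial routes to the collaterals", {
  net <- cached_states()$Base$network
  pc <- classify_sa_paths(net)
  expect_setequal(unique(pc$path_class), c("on_path_to_LMC", "other"))
  # the feeder edges are on every path, so both must be flagged
  feeders <- net$vessels$id[net$vessels$vtype == "SA_to_CoW"]
  expect_true(all(pc$path_class[pc$vessel_id %in% feeders] == "on_path_to_LMC"))
  # no collaterals: everything is "other"
  bare <- remove_lmcs(net, 0, seed = 1)
  pc0 <- classify_sa_paths(bare)
  expect_true(all(pc0$path_class == "other"))
})

test_that("tied shortest paths are all retained", {
  # diamond: cow -> a -> t and cow -> b -> t with equal lengths, LMC at t
  v <- data.frame(id = 1:5,
                  x = c(0, 100, 100, 200, 300), y = c(0, 80, -80, 0, 0),
                  z = 0,
                  role = c("cow_inflow", "internal", "internal", "internal",
                           "av_root"))
  e <- data.frame(id = 1:5,
                  v1 = c(1, 1, 2, 3, 4), v2 = c(2, 3, 4, 4, 5),
                  diameter = 20, length = c(130, 130, 130, 130, 100),
                  vtype = c("SA", "SA", "SA", "SA", "LMC"),
                  side = c("MCA", "MCA", "MCA", "MCA", "none"))
  net <- vascular_network(v, e, data.frame(vertex = c(1, 5),
                                           pressure = c(100, 10)))
  pc <- classify_sa_paths(net)
  expect_true(all(pc$path_class[pc$vessel_id %in% 1:4] == "on_path_to_LMC"))
})

test_that("relative change implements the mean/sum aggregates", {
  expect_equal(relative_change(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(relative_change(c(1, 2), c(2, 4), "mean"), 1)
  expect_equal(relative_change(c(1, 2), c(2, 4), "sum"), 1)
  expect_equal(relative_change(c(2, 4), c(1, 5), "mean"), 0)
  expect_equal(relative_change(c(2, 4), c(1, 5), "sum"), 0)
  expect_warning(out <- relative_change(c(0, 0), c(1, 1)), "zero baseline")
  expect_true(is.na(out))
})

test_that("sum-based changes combine flow-weighted over subclasses", {
  base <- list(a = c(10, 20), b = c(5, 15))
  new <- list(a = c(12, 22), b = c(4, 12))
  whole <- relative_change(unlist(base), unlist(new), "sum")
  parts <- vapply(names(base),
                  function(k) relative_change(base[[k]], new[[k]], "sum"),
                  numeric(1))
  wts <- vapply(base, sum, numeric(1)) / sum(unlist(base))
  expect_equal(whole, sum(parts * wts), tolerance = 1e-12)
})

test_that("distance bins follow the 250 um spacing from the collaterals", {
  net <- cached_states()$Base$network
  db <- distance_bins(net)
  e <- net$vessels
  lmc <- db$vessel_id %in% e$id[e$vtype == "LMC"]
  expect_true(all(db$bin[lmc] == 0))
  expect_equal(db$bin, as.integer(floor(db$distance_um / 250)))
  # translation invariance
  shifted <- net
  shifted$vertices$x <- shifted$vertices$x + 1234
  db2 <- distance_bins(shifted)
  expect_equal(db2$distance_um, db$distance_um, tolerance = 1e-9)
  # no collaterals: infinite distance, no bin
  bare <- remove_lmcs(net, 0, seed = 1)
  db0 <- distance_bins(bare)
  expect_true(all(is.infinite(db0$distance_um)))
})

test_that("CBF summary scales linearly and converts units consistently", {
  net <- cached_states()$Base$network
  sol <- cached_states()$Base$solution
  cbf <- cbf_summary(net, sol)
  expect_gt(cbf$per_mass_ml_min_100g, 30)
  expect_lt(cbf$per_mass_ml_min_100g, 400)
  # per-mass is per-volume rescaled by the tissue density 1.046 g/ml
  expect_equal(cbf$per_mass_ml_min_100g,
               cbf$per_volume_ml_min_ml / 1.046 * 100, tolerance = 1e-9)
  # doubling the boundary pressure difference doubles all three numbers
  net2 <- net
  net2$boundary_conditions$pressure <-
    ifelse(net2$boundary_conditions$pressure == 100, 190, 10)
  cbf2 <- cbf_summary(net2, solve_flow(net2))
  expect_equal(cbf2$per_area_ml_min_mm2 / cbf$per_area_ml_min_mm2, 2,
               tolerance = 1e-9)
})

test_that("direction changes detect exactly the sign flips", {
  sol <- cached_states()$Base$solution
  expect_length(direction_changes(sol, sol), 0)
  flipped <- sol
  flipped$flow <- -flipped$flow
  alive <- abs(sol$flow) > 1e-10 * stats::median(abs(sol$flow))
  expect_setequal(direction_changes(sol, flipped), sol$vessel_id[alive])
  # every collateral with baseline flow toward ACA flips after MCAo
  st <- cached_states()
  dc <- direction_changes(st$Base$solution, st$MCAo$solution)
  net <- st$Base$network
  e <- net$vessels; v <- net$vertices
  lmc <- which(e$vtype == "LMC")
  x1 <- v$x[match(e$v1[lmc], v$id)]; x2 <- v$x[match(e$v2[lmc], v$id)]
  qB <- st$Base$solution$flow
  toward_aca <- ifelse(x1 < x2, qB[lmc] > 0, qB[lmc] < 0) &
    abs(qB[lmc]) > 1e-8 * stats::median(abs(qB))
  expect_true(all(e$id[lmc][toward_aca] %in% dc))
})

test_that("change reports aggregate magnitudes by class", {
  st <- cached_states()
  rep <- change_report(st$Base$network, st$Base$solution, st$MCAo$solution,
                       cached_sides(), "Base", "MCAo")
  expect_true(all(c("class", "state_pair", "metric", "value", "n") %in%
                    names(rep)))
  mca_sa <- rep[rep$class == "MCA SA", ]
  expect_equal(nrow(mca_sa), 3)
  # the MCA-side SA flow collapse appears in both aggregators
  expect_lt(mca_sa$value[mca_sa$metric == "dq_rel_mean"], -0.5)
  expect_lt(mca_sa$value[mca_sa$metric == "dQ_rel_sum"], -0.5)
  # identical states: all zero
  rep0 <- change_report(st$Base$network, st$Base$solution, st$Base$solution,
                        cached_sides())
  expect_true(all(abs(rep0$value) < 1e-12))
})
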