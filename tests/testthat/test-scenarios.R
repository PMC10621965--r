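test_that("MCAo constricts a 50 um segment to 10% of baseline", {
  net <- cached_tuned()$network
  feeder <- net$vessels[net$vessels$vtype == "SA_to_CoW" &
                          net$vessels$side == "MCA", ]
  occ <- apply_mcao(net)
  oid <- attr(occ, "occluded_edges")
  seg <- occ$vessels[occ$vessels$id == oid, ]
  expect_equal(seg$length, 50)
  expect_equal(seg$diameter, 0.10 * feeder$diameter, tolerance = 1e-12)
  # host edge shortened, total length preserved
  host <- occ$vessels[occ$vessels$id == feeder$id, ]
  expect_equal(host$length + seg$length, feeder$length)
  # all other diameters untouched
  others <- setdiff(occ$vessels$id, c(oid, feeder$id))
  expect_equal(occ$vessels$diameter[match(others, occ$vessels$id)],
               net$vessels$diameter[match(others, net$vessels$id)])
  # base network not mutated; occluding the ACA feeder is a misconfiguration
  expect_length(validate_network(net), 0)
  aca <- net$vessels$id[net$vessels$vtype == "SA_to_CoW" &
                          net$vessels$side == "ACA"]
  expect_error(apply_mcao(net, edge = aca), "ACA")
  # an edge shorter than the segment is constricted whole
  short <- net
  short$vessels$length[short$vessels$id == feeder$id] <- 40
  occ2 <- apply_mcao(short)
  expect_equal(occ2$vessels$diameter[occ2$vessels$id == feeder$id],
               0.10 * feeder$diameter, tolerance = 1e-12)
})

test_that("dilation multiplies the selected diameters and spares the occlusion", {
  net <- cached_tuned()$network
  lmc <- net$vessels$vtype == "LMC"
  dil <- apply_dilation(net, "LMC", 1.7)
  expect_equal(dil$vessels$diameter[lmc], 1.7 * net$vessels$diameter[lmc])
  expect_equal(dil$vessels$diameter[!lmc], net$vessels$diameter[!lmc])
  sa <- net$vessels$vtype %in% c("SA", "DA")
  dil2 <- apply_dilation(net, c("SA", "DA"), 1.10)
  expect_equal(dil2$vessels$diameter[sa], 1.10 * net$vessels$diameter[sa])
  # occluded segment is never dilated
  occ <- apply_mcao(net)
  oid <- attr(occ, "occluded_edges")
  dil3 <- apply_dilation(occ, c("SA", "SA_to_CoW"), 1.10)
  expect_equal(dil3$vessels$diameter[dil3$vessels$id == oid],
               occ$vessels$diameter[occ$vessels$id == oid])
  expect_warning(apply_dilation(net, "nonexistent_type", 1.5), "empty")
})

test_that("stroke redistributes flow from ACA to MCA over the collaterals", {
  st <- cached_states()
  net <- st$Base$network
  e <- net$vessels
  sides <- cached_sides()
  side <- sides$side[match(e$id, sides$vessel_id)]
  qB <- st$Base$solution$flow; qM <- st$MCAo$solution$flow
  qL <- st$MCAo_LMC_dil$solution$flow

  # MCAo collapses perfusion in MCA-side surface arteries
  sa_mca <- e$vtype == "SA" & side == "MCA"
  expect_gte(mean(abs(qM[sa_mca]) < abs(qB[sa_mca])), 0.95)
  # mean MCA-side SA pressure drops sharply, ACA-side mildly
  pB <- edge_mid_pressure(net, st$Base$solution)
  pM <- edge_mid_pressure(net, st$MCAo$solution)
  expect_lt(relative_change(pB[sa_mca], pM[sa_mca]), -0.3)
  sa_aca <- e$vtype == "SA" & side == "ACA"
  expect_lt(abs(relative_change(pB[sa_aca], pM[sa_aca])), 0.15)
  # every collateral carries more flow, directed ACA -> MCA
  lmc <- which(e$vtype == "LMC")
  expect_true(all(abs(qM[lmc]) > abs(qB[lmc])))
  v <- net$vertices
  x1 <- v$x[match(e$v1[lmc], v$id)]; x2 <- v$x[match(e$v2[lmc], v$id)]
  to_mca <- ifelse(x1 < x2, qM[lmc] < 0, qM[lmc] > 0) # MCA is the low-x half
  expect_true(all(to_mca))
  # collateral dilation further increases every LMC flow
  expect_true(all(abs(qL[lmc]) > abs(qM[lmc])))
})

test_that("elastic coupling reduces to the rigid solve at zero compliance", {
  net <- cached_tuned()$network
  base <- cached_states()$Base$solution
  occ <- apply_mcao(net)
  ref <- elastic_reference(net, base, target = occ)
  rigid <- solve_flow(occ)
  r0 <- elastic_coupled_solve(occ, elasticity_params(compliance = 0), ref)
  expect_identical(r0$solution$pressure, rigid$pressure)
  expect_identical(r0$network$vessels$diameter, occ$vessels$diameter)
})

test_that("passive diameters follow the pressure monotonically", {
  # a pressure drop on an edge shrinks it; magnitude set by the compliance
  net <- cached_tuned()$network
  base <- cached_states()$Base$solution
  occ <- apply_mcao(net)
  ref <- elastic_reference(net, base, target = occ)
  out <- elastic_coupled_solve(occ, elasticity_params(), ref)
  p_new <- edge_mid_pressure(out$network, out$solution)
  keep <- !(occ$vessels$id %in% attr(occ, "occluded_edges"))
  dp <- p_new[keep] - ref$p_mid[keep]
  dd <- out$network$vessels$diameter[keep] / occ$vessels$diameter[keep] - 1
  expect_true(all(sign(dd[abs(dp) > 1e-6]) == sign(dp[abs(dp) > 1e-6])))
})

test_that("LMC removal keeps the requested count deterministically", {
  net <- cached_tuned()$network
  n_lmc <- sum(net$vessels$vtype == "LMC")
  expect_identical(remove_lmcs(net, 1.0, seed = 3), net)
  half <- remove_lmcs(net, 0.5, seed = 3)
  expect_equal(sum(half$vessels$vtype == "LMC"), round(0.5 * n_lmc))
  half2 <- remove_lmcs(net, 0.5, seed = 3)
  expect_identical(half$vessels$id, half2$vessels$id)
  none <- remove_lmcs(net, 0, seed = 3)
  expect_equal(sum(none$vessels$vtype == "LMC"), 0)
  expect_length(validate_network(none), 0)
})

test_that("added LMCs honour the spacing and length acceptance rules", {
  net <- cached_tuned()$network
  bare <- remove_lmcs(net, 0, seed = 1)
  grown <- suppressWarnings(add_lmcs(bare, n_target = 3, seed = 5))
  lmc <- grown$vessels[grown$vessels$vtype == "LMC", ]
  expect_gt(nrow(lmc), 0)
  expect_true(all(lmc$length <= 1000 * 1.1 + 1e-9)) # hydraulic = 1.1 x chord
  v <- grown$vertices
  mid <- cbind((v$x[match(lmc$v1, v$id)] + v$x[match(lmc$v2, v$id)]) / 2,
               (v$y[match(lmc$v1, v$id)] + v$y[match(lmc$v2, v$id)]) / 2)
  if (nrow(mid) > 1) {
    dmin <- min(stats::dist(mid))
    expect_gt(dmin, 310)
  }
  # target zero is a no-op
  expect_identical(add_lmcs(bare, 0, seed = 5), bare)
  # determinism
  grown2 <- suppressWarnings(add_lmcs(bare, n_target = 3, seed = 5))
  expect_identical(grown$vessels, grown2$vessels)
})

test_that("MCA-side recovery is monotone in the number of collaterals", {
  net <- cached_tuned()$network
  rec <- vapply(c(0, 0.5, 1), function(kf) {
    nk <- remove_lmcs(net, kf, seed = 7)
    occ <- apply_mcao(nk)
    dil <- suppressWarnings(apply_dilation(occ, "LMC", 1.7))
    sol <- solve_flow(dil)
    base_sol <- solve_flow(nk)
    sides <- assign_sides(nk, base_sol)
    ek <- nk$vessels
    sdk <- sides$side[match(ek$id, sides$vessel_id)]
    ii <- match(root_edges(nk, "DA"), ek$id)
    sum(abs(sol$flow[match(ek$id[ii], sol$vessel_id)][sdk[ii] == "MCA"]))
  }, numeric(1))
  expect_false(is.unsorted(rec))
})
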