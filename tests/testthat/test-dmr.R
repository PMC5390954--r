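test_that("single-bixel patch solves the closed form", {
  infl <- toy_influence(matrix(0.5, 1, 1))
  p <- fluence_patch(infl, w = 10, v = 1, dd = 2)
  expect_equal(p$delta, 4)
  expect_equal(p$achieved, 2)
  # zero request gives a zero patch
  p0 <- fluence_patch(infl, w = 10, v = 1, dd = 0)
  expect_equal(p0$achieved, 0)
  expect_true(all(p0$delta == 0))
})

test_that("minimum-norm patch matches a brute-force constrained search", {
  a <- c(1.0, 0.5, 0.25)
  infl <- toy_influence(rbind(a, 0, 0))
  dd <- 2
  p <- fluence_patch(infl, w = rep(100, 3), v = 1, dd = dd)
  # brute force: refine a grid over (p1, p2) with p3 fixed by the
  # constraint a . P = dd, minimizing ||P||
  c1 <- 0; c2 <- 0; width <- 5
  for (round in 1:9) {
    g1 <- seq(c1 - width, c1 + width, length.out = 41)
    g2 <- seq(c2 - width, c2 + width, length.out = 41)
    gr <- expand.grid(p1 = g1, p2 = g2)
    gr$p3 <- (dd - a[1] * gr$p1 - a[2] * gr$p2) / a[3]
    nrm <- gr$p1^2 + gr$p2^2 + gr$p3^2
    b <- which.min(nrm)
    c1 <- gr$p1[b]; c2 <- gr$p2[b]
    width <- width / 10
  }
  best <- c(c1, c2, (dd - a[1] * c1 - a[2] * c2) / a[3])
  expect_lt(max(abs(p$delta - best)), 1e-6)
  expect_equal(p$achieved, dd, tolerance = 1e-12)
})

test_that("patches are clamped to keep fluence non-negative", {
  a <- c(1, 1)
  infl <- toy_influence(rbind(a, 0))
  w <- c(0.5, 5)
  p <- fluence_patch(infl, w, v = 1, dd = -4)
  expect_true(all(w[p$bixels] + p$delta >= 0))
  expect_equal(p$achieved, -4)            # second bixel absorbs the rest
  # request beyond what non-negativity allows: partial achievement
  p2 <- fluence_patch(infl, w, v = 1, dd = -10)
  expect_true(all(w[p2$bixels] + p2$delta >= -1e-12))
  expect_equal(p2$achieved, -5.5)         # all weight removed
  # zero influence row is infeasible
  expect_error(fluence_patch(infl, w, v = 2, dd = 1), class = "ids_infeasible")
})

test_that("recovery candidates are ranked by deviation with deterministic ties", {
  ref <- rep(10, 20)
  new <- ref
  new[c(3, 7, 11, 15)] <- c(13, 8, 12.5, 11.4)
  new[5] <- 13            # tie with voxel 3
  plan <- identify_recovery(ref, new, vm = 19L, tau = 1, nr = 10)
  expect_equal(plan$voxels, c(3, 5, 11, 7, 15))
  expect_equal(plan$deviations, c(3, 3, 2.5, -2, 1.4))
  # budget truncation keeps the largest deviations
  set.seed(1)
  new2 <- ref <- rep(50, 60)
  new2[1:40] <- ref[1:40] + sample(seq(0.5, 20, by = 0.5), 40)
  plan2 <- identify_recovery(ref, new2, vm = integer(0), tau = 0.2, nr = 15)
  expect_length(plan2$voxels, 15)
  allc <- sort(abs(new2 - ref), decreasing = TRUE)
  expect_equal(sort(abs(plan2$deviations), decreasing = TRUE), allc[1:15])
  # identical fields -> empty plan
  expect_length(identify_recovery(ref, ref, integer(0), 0.1, 15)$voxels, 0)
})

test_that("DMR achieves the request and restores recovery voxels exactly on a separable toy", {
  toy <- separable_toy()
  st <- toy$state
  ref <- st$dose
  st2 <- apply_dmr(st, list(v = 1, dd = 2), tau = 0.05, nr = 15)
  res <- attr(st2, "dmr_result")
  # requested change achieved exactly at v
  expect_equal(st2$dose[1] - ref[1], 2, tolerance = 1e-12)
  expect_equal(res$achieved, 2, tolerance = 1e-12)
  # the collateral voxel (shares bixel 2) is restored exactly via its
  # private bixel 3, which cannot disturb v
  expect_equal(st2$dose[2], ref[2], tolerance = 1e-12)
  expect_equal(res$recovery_voxels, 2L)
  # voxel 3 moves only through bixel 3's recovery: -0.4 * 0.2
  expect_equal(st2$dose[3] - ref[3], -0.08, tolerance = 1e-12)
  expect_equal(res$residual_max, 0.08, tolerance = 1e-12)
})

test_that("DMR with zero request or zero budget degenerates correctly", {
  toy <- separable_toy()
  st <- toy$state
  st0 <- apply_dmr(st, list(v = 1, dd = 0), tau = 0.05, nr = 15)
  expect_equal(st0$dose, st$dose)
  expect_equal(st0$w, st$w)
  expect_length(attr(st0, "dmr_result")$recovery_voxels, 0)
  st1 <- apply_dmr(st, list(v = 1, dd = 2), tau = 0.05, nr = 0)
  expect_equal(attr(st1, "dmr_result")$n_patches, 1)
  expect_equal(st1$dose[1] - st$dose[1], 2, tolerance = 1e-12)
})

test_that("every DMR instance preserves fluence non-negativity and never grows the deviation set", {
  for (seed in 1:20) {
    st <- random_toy_plan(seed = seed)
    set.seed(seed + 100)
    for (k in 1:5) {
      v <- sample(which(lengths(lapply(seq_len(12), function(i)
        influence_row(st$infl, i)$a)) > 0), 1)
      dd <- rnorm(1, sd = 2)
      st <- apply_dmr(st, list(v = v, dd = dd), tau = 0.1, nr = 5)
      res <- attr(st, "dmr_result")
      expect_true(all(st$w >= -1e-12))
      expect_lte(res$n_over_tau_post, res$n_over_tau_pre)
      expect_true(res$achieved == 0 || sign(res$achieved) == sign(dd))
      expect_lt(max(abs(st$dose - compute_dose(st$infl, st$w))), 1e-8)
    }
  }
})

test_that("sphere gestures enumerate exactly the in-radius body voxels", {
  e <- small_engine(1)
  st <- init_plan(e$ph, e$infl)
  v <- which(e$ph$vois$ptv$mask)[5]
  ctr <- as.numeric(voxel_centers(st$grid, v))
  R <- 20
  reqs <- tool_requests(st, list(type = "sphere", center = ctr, radius = R, dd = -3))
  # exhaustive oracle
  cc <- voxel_centers(st$grid)
  r <- sqrt((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2 + (cc[, 3] - ctr[3])^2)
  expected <- which(r <= R & e$ph$vois$body$mask)
  expect_equal(vapply(reqs, `[[`, integer(1), "v"), expected)
  # cosine falloff: the center voxel gets the full request
  dd <- vapply(reqs, `[[`, numeric(1), "dd")
  expect_equal(dd[match(v, expected)], -3)
  expect_true(all(abs(dd) <= 3 + 1e-12))
  # sub-voxel sphere: exactly one request at the center voxel
  reqs1 <- tool_requests(st, list(type = "sphere", center = ctr,
                                  radius = 0.4 * min(st$grid$spacing), dd = 1))
  expect_length(reqs1, 1)
  expect_equal(reqs1[[1]]$v, v)
  # sphere entirely outside the body is a geometry error
  expect_error(tool_requests(st, list(type = "sphere", center = c(1, 1, 1),
                                      radius = 2, dd = 1)),
               class = "ids_geometry_error")
})

test_that("isodose drag translates to raise/lower requests along the segment", {
  e <- small_engine(1)
  st <- init_plan(e$ph, e$infl)
  # identity gesture
  p <- as.numeric(voxel_centers(st$grid, which(e$ph$vois$ptv$mask)[1]))
  expect_length(tool_requests(st, list(type = "isodose_drag", level = 40,
                                       from = p, to = p)), 0)
  # outward drag: from inside the 50 Gy region towards a colder point
  pc <- colMeans(voxel_centers(st$grid, which(st$vois$ptv$mask)))
  pout <- pc + c(0, 90, 0)
  reqs <- tool_requests(st, list(type = "isodose_drag", level = 50,
                                 from = pc, to = pout))
  expect_gt(length(reqs), 0)
  for (rq in reqs) {
    expect_lt(st$dose[rq$v], 50)
    expect_equal(st$dose[rq$v] + rq$dd, 50, tolerance = 1e-9)
  }
  # level outside the dose range errors
  expect_error(tool_requests(st, list(type = "isodose_drag", level = 1e4,
                                      from = pc, to = pout)),
               class = "ids_value_error")
})

test_that("executing a gesture equals applying its requests sequentially", {
  e <- small_engine(1)
  st <- init_plan(e$ph, e$infl)
  hot <- which(e$ph$vois$rectum$mask)
  v <- hot[which.max(st$dose[hot])]
  g <- list(type = "sphere", center = as.numeric(voxel_centers(st$grid, v)),
            radius = 10, dd = -2)
  st_tool <- execute_tool(st, g, tau = 0.38, nr = 15)
  st_man <- st
  for (rq in tool_requests(st, g))
    st_man <- apply_dmr(st_man, rq, tau = 0.38, nr = 15)
  expect_equal(st_tool$dose, st_man$dose, tolerance = 1e-12)
  expect_equal(st_tool$w, st_man$w, tolerance = 1e-12)
  expect_false(attr(st_tool, "aborted"))
  # a decrease gesture lowers the mean dose inside the sphere
  sph <- vapply(tool_requests(st, g), `[[`, integer(1), "v")
  expect_lt(mean(st_tool$dose[sph]), mean(st$dose[sph]))
})
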