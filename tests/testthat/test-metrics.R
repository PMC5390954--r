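mask1d <- function(n, sel = seq_len(n)) {
  m <- array(FALSE, c(n, 1, 1)); m[sel] <- TRUE; m
}

test_that("DVH is an exact cumulative >=-dose curve", {
  # uniform 10 Gy: step from 1 to 0 at 10 Gy
  d <- rep(10, 50)
  curve <- dvh(d, mask1d(50), bin = 1)
  expect_equal(curve$volume[curve$dose <= 10], rep(1, 11))
  expect_equal(curve$volume[curve$dose > 10], 0)
  expect_equal(curve$volume[1], 1)
  # 5-voxel toy {1..5}: fraction >= 3 Gy is 0.6
  curve5 <- dvh(1:5, mask1d(5), bin = 1)
  expect_equal(curve5$volume[curve5$dose == 3], 0.6)
  # monotone non-increasing on random fields
  set.seed(1)
  for (k in 1:5) {
    c2 <- dvh(runif(200, 0, 80), mask1d(200), bin = 0.5)
    expect_true(all(diff(c2$volume) <= 0))
    expect_equal(c2$volume[length(c2$volume)], 0)
  }
  expect_error(dvh(1:5, mask1d(5, integer(0))), class = "ids_value_error")
})

test_that("Dq% follows the voxel-exact definition", {
  d5 <- c(1, 2, 3, 4, 5)
  m5 <- mask1d(5)
  expect_equal(dose_at_volume(d5, m5, 2), 5)
  expect_equal(dose_at_volume(d5, m5, 98), 1)
  expect_equal(dose_at_volume(d5, m5, 50), median(d5))
  # uniform field: all quantiles equal
  for (q in c(2, 50, 98)) expect_equal(dose_at_volume(rep(7, 9), mask1d(9), q), 7)
  # D50 equals the sample median for odd-sized VOIs
  set.seed(2)
  d <- runif(31, 10, 80)
  expect_equal(dose_at_volume(d, mask1d(31), 50), median(d))
  expect_error(dose_at_volume(d5, m5, 0), class = "ids_value_error")
})

test_that("Vx counts the fraction at or above threshold", {
  d10 <- c(70, 66, 65, 60, 50, 40, 30, 20, 10, 0)
  expect_equal(volume_at_dose(d10, mask1d(10), 65), 30)
  expect_equal(volume_at_dose(rep(0, 4), mask1d(4), 50), 0)
  expect_equal(volume_at_dose(d10, mask1d(10), 0), 100)
  expect_error(volume_at_dose(d10, mask1d(10), -1), class = "ids_value_error")
})

test_that("Dq and Vx are mutually consistent on random fields", {
  set.seed(3)
  for (k in 1:20) {
    d <- runif(173, 0, 80)
    m <- mask1d(173)
    for (q in c(2, 20, 50, 80, 98))
      expect_gte(volume_at_dose(d, m, dose_at_volume(d, m, q)), q)
  }
})

test_that("conformity matches the hand-counted toy and its degenerate cases", {
  # 20 body voxels, first 10 are target; 9 target + 3 other body voxels
  # above threshold -> CI1 = 0.9, CI2 = 9/12, CI = 0.675
  n <- 20
  body <- mask1d(n)
  target <- mask1d(n, 1:10)
  rx <- 70; thr <- 0.95 * rx
  d <- rep(0, n)
  d[1:9] <- thr + 1
  d[11:13] <- thr + 1
  ci <- conformity(d, target, body, rx)
  expect_equal(ci$ci1, 0.9)
  expect_equal(ci$ci2, 0.75)
  expect_equal(ci$ci, 0.675)
  # exactly conformal
  d2 <- rep(0, n); d2[1:10] <- thr
  expect_equal(conformity(d2, target, body, rx),
               list(ci1 = 1, ci2 = 1, ci = 1))
  # everything below threshold
  expect_equal(conformity(rep(1, n), target, body, rx),
               list(ci1 = 0, ci2 = 0, ci = 0))
})

test_that("conformity and NTID agree with exhaustive voxel-counting oracles on random instances", {
  set.seed(4)
  for (k in 1:50) {
    dims <- c(16, 16, 16)
    nvox <- prod(dims)
    dose <- runif(nvox, 0, 90)
    tsel <- sample(nvox, 200)
    bsel <- unique(c(tsel, sample(nvox, 2000)))
    target <- array(FALSE, dims); target[tsel] <- TRUE
    body <- array(FALSE, dims); body[bsel] <- TRUE
    rx <- runif(1, 60, 80)
    ci <- conformity(dose, target, body, rx)
    # oracle: direct counting over every voxel
    thr <- 0.95 * rx
    vtref <- 0; vref <- 0
    for (i in bsel) {
      if (dose[i] >= thr) {
        vref <- vref + 1
        if (target[i]) vtref <- vtref + 1
      }
    }
    if (vref == 0) {
      expect_equal(ci, list(ci1 = 0, ci2 = 0, ci = 0))
    } else {
      expect_equal(ci$ci1, vtref / 200)
      expect_equal(ci$ci2, vtref / vref)
      expect_equal(ci$ci, ci$ci1 * ci$ci2)
    }
    # NTID oracle: rho * voxel volume * sum of doses
    vv <- 3.2
    nt <- ntid(dose, body, vv)
    acc <- 0
    for (i in bsel) acc <- acc + dose[i]
    expect_equal(nt, vv * 1e-6 * acc)
  }
})

test_that("homogeneity is the population standard deviation", {
  expect_equal(homogeneity(c(70, 74), mask1d(2)), 2)
  expect_equal(homogeneity(rep(42, 17), mask1d(17)), 0)
  set.seed(5)
  d <- runif(100, 60, 80)
  expect_equal(homogeneity(d, mask1d(100)), homogeneity(d + 13.7, mask1d(100)))
})

test_that("NTID closed forms and linearity", {
  # 1 litre at uniform 1 Gy with unit density: 1 litre Gy
  n <- 1000
  expect_equal(ntid(rep(1, n), mask1d(n), 1000), 1)
  # 1000 voxels of 8 mm^3 at mean 50 Gy: 0.4 litre Gy
  set.seed(6)
  d <- rnorm(1000, 50, 3); d <- d - mean(d) + 50
  expect_equal(ntid(d, mask1d(1000), 8), 8e-6 * 1000 * 50)
  # linear in rho and in dose
  expect_equal(ntid(d, mask1d(1000), 8, rho = 2), 2 * ntid(d, mask1d(1000), 8))
  expect_equal(ntid(2 * d, mask1d(1000), 8), 2 * ntid(d, mask1d(1000), 8))
  # permutation invariant
  expect_equal(ntid(sample(d), mask1d(1000), 8), ntid(d, mask1d(1000), 8))
})

test_that("metrics are invariant to mask voxel order", {
  set.seed(7)
  d <- runif(500, 0, 80)
  idx <- sample(500, 120)
  for (f in list(function(i) dose_at_volume(d, i, 50),
                 function(i) volume_at_dose(d, i, 40),
                 function(i) homogeneity(d, i)))
    expect_equal(f(idx), f(sample(idx)))
})

test_that("the Quantec table has the published structure and strict limits", {
  n <- 100
  rectum <- mask1d(n, 1:50); bladder <- mask1d(n, 51:100)
  q0 <- quantec_check(rep(0, n), rectum, bladder)
  expect_equal(nrow(q0), 9)
  expect_equal(sum(q0$structure == "rectum"), 5)
  expect_equal(sum(q0$structure == "bladder"), 4)
  expect_equal(q0$x, c(50, 60, 65, 70, 75, 65, 70, 75, 80))
  expect_equal(q0$limit, c(50, 35, 25, 20, 15, 50, 35, 25, 15))
  expect_true(all(q0$pass))
  # rectum uniformly at 72 Gy: V70 = 100 fails the 20% limit
  d <- rep(0, n); d[1:50] <- 72
  q1 <- quantec_check(d, rectum, bladder)
  expect_false(q1$pass[q1$structure == "rectum" & q1$x == 70])
  expect_equal(q1$value[q1$structure == "rectum" & q1$x == 70], 100)
  # strictness: a value exactly at the limit fails
  d2 <- rep(0, n); d2[1:25] <- 51   # rectum V50 = 50
  q2 <- quantec_check(d2, rectum, bladder)
  expect_false(q2$pass[q2$x == 50])
})

test_that("a full metrics report carries every indicator", {
  e <- small_engine(1)
  st <- init_plan(e$ph, e$infl)
  rep <- metrics_report(st$dose, st$vois, st$rx, st$grid)
  expect_setequal(rep$indicators$voi, names(st$vois))
  expect_true(all(c("mean", "d50", "d98", "d2", "hi") %in% names(rep$indicators)))
  expect_equal(nrow(rep$quantec), 9)
  expect_true(rep$ntid > 0)
  expect_true(rep$conformity$boost$ci <= 1 && rep$conformity$boost$ci >= 0)
  f <- tempfile()
  write_metrics(rep, f)
  expect_true(file.exists(paste0(f, ".json")))
  long <- read.csv(paste0(f, ".csv"))
  expect_true(all(c("V50", "V75", "ntid") %in% long$indicator))
})
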