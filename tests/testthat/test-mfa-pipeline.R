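test_that("normalize_counts: flat ratios, linearity, masking, rescaling", {
  L <- 100000; b <- 1000; n <- 100
  flat <- binned_counts(rep(50, n), b, L, "s")
  ctrl <- binned_counts(rep(80, n), b, L, "c")
  p <- normalize_counts(flat, ctrl)
  expect_equal(p$values, rep(1, n))
  # doubling one sample bin doubles its ratio relative to the others
  up <- binned_counts(c(100, rep(50, n - 1)), b, L, "s")
  p2 <- normalize_counts(up, ctrl)
  expect_equal(p2$values[1] / p2$values[2], 2)
  expect_equal(mean(p2$values), 1)
  # control floor masks bins; all-masked input errors
  ctrl2 <- binned_counts(c(rep(3, 10), rep(80, n - 10)), b, L, "c")
  p3 <- normalize_counts(flat, ctrl2, control_floor = 10)
  expect_true(all(is.na(p3$values[1:10])))
  expect_equal(mean(p3$values, na.rm = TRUE), 1)
  expect_error(normalize_counts(flat, binned_counts(rep(1, n), b, L), control_floor = 10),
               "masked")
  expect_error(normalize_counts(flat, binned_counts(rep(80, 50), b, 50000)),
               "mismatch")
})

test_that("Poisson counts recover the generating profile within 3 SE", {
  m <- mg1655_map()
  truth <- marker_frequency(replication_schedule(m, cell_class("oriC"), sim_params()))
  depth <- 400
  sam <- simulate_counts(truth, noise_spec(depth = depth, seed = 31))
  ctl <- simulate_control(m, noise_spec(depth = depth, seed = 32))
  p <- normalize_counts(sam, ctl)
  scaled_truth <- truth$values / mean(truth$values)
  # ratio of two Poisson draws: CV^2 = 1/(depth * f) + 1/depth
  se <- scaled_truth * sqrt(1 / (depth * truth$values) + 1 / depth)
  frac_in <- mean(abs(p$values - scaled_truth) <= 3 * se, na.rm = TRUE)
  expect_gt(frac_in, 0.99)
})

test_that("circular LOESS: constant input, rotation equivariance, mean", {
  n <- 200; L <- n * 1000
  p <- mfa_profile(rep(2, n), 1000, L, source = "data")
  expect_equal(circular_loess(p)$values, rep(2, n))
  set.seed(3)
  y <- 1 + 0.4 * cos(2 * pi * (1:n) / n) + rnorm(n, 0, 0.05)
  p2 <- mfa_profile(pmax(y, 0.01), 1000, L, source = "data")
  s2 <- circular_loess(p2)
  k <- 37
  rot <- mfa_profile(c(p2$values[-(1:k)], p2$values[1:k]), 1000, L, source = "data")
  srot <- circular_loess(rot)
  expect_equal(srot$values, c(s2$values[-(1:k)], s2$values[1:k]), tolerance = 1e-12)
  expect_equal(mean(s2$values), mean(p2$values), tolerance = 1e-3)
})

test_that("circular LOESS matches the brute-force per-point oracle", {
  set.seed(9)
  n <- 300; L <- n * 1000
  y <- 1 + 0.3 * sin(2 * pi * (1:n) / n) + rnorm(n, 0, 0.08)
  y[sample(n, 20)] <- NA  # exercise the masked fallback path
  p <- mfa_profile(pmax(y, 0.01), 1000, L, source = "data")
  for (span in c(0.1, 0.25)) {
    sm <- circular_loess(p, loess_config(span, 2))
    expect_lt(max(abs(sm$values - pmax(loess_oracle(y, span, 2), 0))), 1e-9)
  }
  sm1 <- circular_loess(p, loess_config(0.15, 1))
  expect_lt(max(abs(sm1$values - pmax(loess_oracle(y, 0.15, 1), 0))), 1e-9)
  expect_error(circular_loess(mfa_profile(rep(1, 4), 1000, 4000, source = "data"),
                              loess_config(1)), "window")
})

test_that("find_extrema: single origin, flat profile, low point vs midpoint", {
  m <- mg1655_map()
  single <- circular_loess(marker_frequency(
    replication_schedule(m, cell_class("oriC"), sim_params())))
  ext <- find_extrema(single)
  expect_equal(nrow(ext$peaks), 1)
  expect_lt(abs(ext$peaks$position - 3925860), 5000)
  # trap-free double origin: low point within 20 kb of the arc midpoint
  dtus <- circular_loess(marker_frequency(
    replication_schedule(m, cell_class(c("oriC", "oriX"), tus_active = FALSE),
                         sim_params())))
  mid <- arc_midpoint(m, 3925860, 2738575, through = 0)
  expect_lt(abs(find_extrema(dtus)$low_point - mid), 20000)
  flat <- mfa_profile(rep(1, 100), 1000, 100000, source = "data")
  fe <- find_extrema(flat)
  expect_true(fe$flat)
  expect_equal(nrow(fe$peaks), 0)
})

test_that("detect_steps labels the trap signature and nothing else", {
  m <- mg1655_map()
  # noiseless model profiles localise to within one bin
  cx <- marker_frequency(replication_schedule(m, cell_class(c("oriC", "oriX")),
                                              sim_params()))
  st <- detect_steps(cx, m)
  expect_equal(st$steps$ter, "terA")
  expect_lt(abs(st$steps$position - 1341427), 1001)
  cz <- marker_frequency(replication_schedule(m, cell_class(c("oriC", "oriZ")),
                                              sim_params()))
  stz <- detect_steps(cz, m)
  expect_true(any(stz$steps$ter %in% c("terC", "terB")))
  # continuous profile -> nothing
  free <- marker_frequency(replication_schedule(
    m, cell_class(c("oriC", "oriX"), tus_active = FALSE), sim_params()))
  stf <- detect_steps(free, m)
  expect_equal(nrow(stf$steps), 0)
  expect_equal(nrow(stf$discontinuities), 0)
})

test_that("step detection is invariant to global rescaling", {
  m <- mg1655_map()
  cx <- marker_frequency(replication_schedule(m, cell_class(c("oriC", "oriX")),
                                              sim_params()))
  st1 <- detect_steps(cx, m)
  cx2 <- cx; cx2$values <- cx$values * 7
  st2 <- detect_steps(cx2, m)
  expect_equal(st2$steps$position, st1$steps$position)
  expect_equal(st2$steps$magnitude, 7 * st1$steps$magnitude)
})

test_that("origin_activity reports relative peak heights", {
  m <- mg1655_map()
  single <- circular_loess(marker_frequency(
    replication_schedule(m, cell_class("oriC"), sim_params())))
  expect_equal(unname(origin_activity(single, m, "oriC")), 1)
  # equal-firing double origin: both peaks within 2%
  both <- circular_loess(marker_frequency(
    replication_schedule(m, cell_class(c("oriC", "oriX")), sim_params())))
  act <- origin_activity(both, m, c("oriC", "oriX"))
  expect_gt(min(act), 0.98)
  # 0.5/0.4/0.1 mixture: oriC strictly highest
  mk <- function(...) marker_frequency(replication_schedule(m, cell_class(c(...)),
                                                            sim_params()))
  mx <- circular_loess(mixture_profile(list(mk("oriC", "oriX"), mk("oriC", "oriZ"),
                                            mk("oriC", "oriX", "oriZ")),
                                       c(0.5, 0.4, 0.1)))
  a3 <- origin_activity(mx, m, c("oriC", "oriX", "oriZ"))
  expect_equal(names(which.max(a3)), "oriC")
  expect_true(all(a3[c("oriX", "oriZ")] < 1))
})

test_that("re-normalising against a flat control is the identity up to scale", {
  m <- mg1655_map()
  truth <- marker_frequency(replication_schedule(m, cell_class("oriC"), sim_params()))
  counts <- binned_counts(round(truth$values * 1000), 1000, m$length_bp, "s")
  flat <- binned_counts(rep(1000, length(truth$values)), 1000, m$length_bp, "c")
  p <- normalize_counts(counts, flat)
  expect_equal(p$values / p$values[1], truth$values / truth$values[1],
               tolerance = 2e-3)
})
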