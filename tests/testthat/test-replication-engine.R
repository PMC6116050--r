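test_that("single origin, no trap: t(x) = d(x)/v with fusion at the antipode", {
  m <- toy_map(L = 200000, origins = c(o1 = 50000))
  pp <- sim_params(fork_speed = 1000)
  s <- replication_schedule(m, cell_class("o1", tus_active = FALSE), pp, 1000)
  mids <- forktrap:::bin_mids(m$length_bp, 1000)
  d <- pmin(forktrap:::pmod(mids - 50000, m$length_bp),
            forktrap:::pmod(50000 - mids, m$length_bp))
  ob <- forktrap:::bin_index(50000, 1000, m$length_bp)
  expect_equal(s$t[-ob], (d / 1000)[-ob])
  expect_equal(s$t[ob], 0)
  expect_equal(mids[which.max(s$t)], forktrap:::pmod(50000 + 100000, m$length_bp) + 500 - 1000)
  expect_equal(nrow(s$block_events), 0)
})

test_that("every bin is assigned exactly once and t rises along each fork path", {
  m <- two_origin_map()
  s <- replication_schedule(m, cell_class(c("oA", "oB")), sim_params(), 1000)
  expect_false(anyNA(s$t))
  expect_true(all(s$t >= 0))
  expect_equal(length(s$fork_id), length(s$t))
  for (f in unique(s$fork_id)) {
    idx <- which(s$fork_id == f)
    dir <- sub(".*:", "", f)
    org <- sub(":.*", "", f)
    p0 <- m$origins$position_bp[m$origins$name == org]
    mids <- forktrap:::bin_mids(m$length_bp, 1000)[idx]
    d <- if (dir == "cw") forktrap:::pmod(mids - p0, m$length_bp)
         else forktrap:::pmod(p0 - mids, m$length_bp)
    expect_true(all(diff(s$t[idx][order(d)]) > 0))
  }
})

test_that("closed-form fusion times for two origins 1000 kb apart", {
  m <- two_origin_map()
  cl <- cell_class(c("oA", "oB"))
  # each fork covers ~500 kb of the inter-origin stretch; 769 s at 650 nt/s,
  # 500 s at 1000 nt/s — bracketing the 10-12 min literature estimate
  for (v in c(650, 1000)) {
    s <- replication_schedule(m, cl, sim_params(fork_speed = v), 1000)
    fuse <- s$fusion_events[order(s$fusion_events$time), ]
    expect_equal(fuse$time[1], 500000 / v, tolerance = 1e-2)
    expect_equal(fuse$position[1], 700000, tolerance = 1000)
  }
})

test_that("oriC+oriX with the trap blocks the oriX fork at terA", {
  m <- mg1655_map()
  s <- replication_schedule(m, cell_class(c("oriC", "oriX")), sim_params(), 1000)
  expect_equal(s$block_events$ter, "terA")
  expect_equal(s$block_events$fork, "oriX:ccw")
  # t jumps discontinuously across terA
  bi <- forktrap:::bin_index(1341427, 1000, m$length_bp)
  expect_gt(abs(s$t[bi + 3] - s$t[bi - 3]), 300)
  # no step without the trap
  s2 <- replication_schedule(m, cell_class(c("oriC", "oriX"), tus_active = FALSE))
  expect_equal(nrow(s2$block_events), 0)
  expect_lt(abs(s2$t[bi + 3] - s2$t[bi - 3]), 10)
})

test_that("trap polarity: no bin beyond a blocking ter belongs to the blocked fork", {
  m <- mg1655_map()
  s <- replication_schedule(m, cell_class(c("oriC", "oriZ")), sim_params(), 1000)
  expect_equal(s$block_events$ter, "terC")
  # oriZ's cw fork owns nothing beyond terC
  mids <- forktrap:::bin_mids(m$length_bp, 1000)
  owned <- mids[s$fork_id == "oriZ:cw"]
  d <- forktrap:::pmod(owned - 343482, m$length_bp)
  expect_true(all(d <= forktrap:::pmod(1608788 - 343482, m$length_bp)))
})

test_that("head-on transcription slows forks only downstream of the feature", {
  txn <- data.frame(name = "rrnX", start_bp = 80000, end_bp = 90000,
                    direction = "ccw", highly_transcribed = TRUE,
                    stringsAsFactors = FALSE)
  m <- toy_map(L = 200000, origins = c(o1 = 10000), txn = txn)
  base <- replication_schedule(m, cell_class("o1", tus_active = FALSE),
                               sim_params(headon_speed_factor = 1), 1000)
  slow <- replication_schedule(m, cell_class("o1", tus_active = FALSE),
                               sim_params(headon_speed_factor = 0.5), 1000)
  mids <- forktrap:::bin_mids(m$length_bp, 1000)
  # the cw fork meets rrnX head-on; upstream bins are untouched, downstream
  # bins are strictly delayed wherever the cw fork still wins
  upstream <- mids > 10000 & mids < 80000
  expect_equal(slow$t[upstream], base$t[upstream])
  downstream <- mids > 90000 & mids < 100000 & slow$fork_id == "o1:cw"
  expect_true(all(slow$t[downstream] > base$t[downstream]))
  # extra time inside the feature equals len * (1/(v*f) - 1/v)
  i <- which(mids > 90000 & slow$fork_id == "o1:cw")[1]
  expect_equal(slow$t[i] - base$t[i], 10000 * (1 / 500 - 1 / 1000))
})

test_that("marker frequency is the 2^(-t/tau) law", {
  m <- toy_map(L = 120000, origins = c(o1 = 0))
  s <- replication_schedule(m, cell_class("o1", tus_active = FALSE),
                            sim_params(fork_speed = 1000, tau = 1), 1000)
  i <- which.max(s$t)
  # t = tau -> f = 1/2 exactly; t = 0 -> f = 1
  f1 <- marker_frequency(s, tau = s$t[i] / 60)
  expect_equal(max(f1$values), 1)
  expect_equal(f1$values[i], 0.5, tolerance = 1e-12)
  # single-origin schedule with t_last = 2*tau: origin:last ratio = 4
  f2 <- marker_frequency(s, tau = s$t[i] / 2 / 60)
  expect_equal(1 / min(f2$values), 4)
  # monotone decay in t
  expect_true(all(diff(f1$values[order(s$t)]) <= 0))
})

test_that("wild-type profile decreases monotonically from oriC along each replichore", {
  m <- mg1655_map()
  s <- replication_schedule(m, cell_class("oriC"), sim_params(), 1000)
  f <- marker_frequency(s)
  cw <- setdiff(which(s$fork_id == "oriC:cw"),
                forktrap:::bin_index(3925860, 1000, m$length_bp))
  mids <- forktrap:::bin_mids(m$length_bp, 1000)
  d <- forktrap:::pmod(mids[cw] - 3925860, m$length_bp)
  expect_true(all(diff(f$values[cw][order(d)]) < 0))
})

test_that("mixture_profile is linear with validated weights", {
  m <- two_origin_map()
  p1 <- marker_frequency(replication_schedule(m, cell_class("oA"), sim_params(), 1000))
  p2 <- marker_frequency(replication_schedule(m, cell_class("oB"), sim_params(), 1000))
  expect_equal(mixture_profile(list(p1), 1)$values, p1$values)
  expect_equal(mixture_profile(list(p1, p1), c(0.5, 0.5))$values, p1$values)
  mx <- mixture_profile(list(p1, p2), c(0.3, 0.7))
  expect_equal(mx$values, 0.3 * p1$values + 0.7 * p2$values)
  expect_error(mixture_profile(list(p1, p2), c(0.5, 0.6)), "sum to 1")
  p3 <- marker_frequency(replication_schedule(m, cell_class("oA"), sim_params(), 2000))
  expect_error(mixture_profile(list(p1, p3), c(0.5, 0.5)), "mismatch")
})

test_that("triple-origin mixture has an interior terminus maximum", {
  m <- mg1655_map()
  mk <- function(...) marker_frequency(replication_schedule(m, cell_class(c(...)),
                                                            sim_params(), 1000))
  mx <- mixture_profile(list(mk("oriC", "oriX"), mk("oriC", "oriZ"),
                             mk("oriC", "oriX", "oriZ")), c(0.5, 0.4, 0.1))
  ext <- find_extrema(circular_loess(mx))
  # peaks at all three origins plus a maximum between terA and terC; a 460 kb
  # smoothing window shifts the apex of an asymmetric tent by a few tens of kb
  near <- function(p, x, tol = 50000) any(abs(p - x) < tol)
  expect_true(near(ext$peaks$position, 3925860))
  expect_true(near(ext$peaks$position, 2738575))
  expect_true(near(ext$peaks$position, 343482))
  expect_true(any(ext$peaks$position > 1341427 & ext$peaks$position < 1608788))
})

test_that("engine rejects bad inputs and unreplicable maps", {
  m <- mg1655_map()
  expect_error(cell_class(character(0)), "at least one")
  expect_error(replication_schedule(m, cell_class("nope")), "unknown origin")
  expect_error(replication_schedule(m, cell_class("oriC"),
                                    sim_params(ter_leakage = 0.2)),
               "ter_leakage")
  # two ccw-blocking sites bracketing a region with no origin deadlock it
  bad <- toy_map(L = 100000, origins = c(o1 = 10000),
                 ters = data.frame(name = c("tA", "tB"),
                                   position_bp = c(40000, 60000),
                                   blocks = c("cw", "ccw"),
                                   stringsAsFactors = FALSE))
  expect_error(replication_schedule(bad, cell_class("o1")), "unreplicable")
})
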