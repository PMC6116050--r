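test_that("the 820 kb inversion flips exactly the five restrictive ter sites", {
  m <- mg1655_map()
  r <- rearrangement("inversion", 575000, 1394000)
  expect_equal(r$end_bp - r$start_bp, 819000)  # the reported ~820 kb
  mi <- apply_rearrangement(m, r)
  flipped <- c("terA", "terD", "terE", "terH", "terI")
  for (nm in m$ter_sites$name) {
    before <- m$ter_sites$blocks[m$ter_sites$name == nm]
    after <- mi$ter_sites$blocks[mi$ter_sites$name == nm]
    if (nm %in% flipped) expect_false(after == before, label = nm)
    else expect_equal(after, before, label = nm)
  }
  # feature counts conserved
  expect_equal(nrow(mi$ter_sites), nrow(m$ter_sites))
  expect_equal(nrow(mi$is_elements), nrow(m$is_elements))
  expect_equal(mi$length_bp, m$length_bp)
})

test_that("inversion is an involution on maps", {
  m <- mg1655_map()
  for (r in list(rearrangement("inversion", 575000, 1394000),
                 rearrangement("inversion", 1394000, 2288000))) {
    m2 <- apply_rearrangement(apply_rearrangement(m, r), r)
    expect_equal(m2$origins, m$origins, ignore_attr = TRUE)
    srt <- function(d) d[order(d$name), ]
    expect_equal(srt(m2$ter_sites), srt(m$ter_sites), ignore_attr = TRUE)
    expect_equal(srt(m2$transcribed_features), srt(m$transcribed_features),
                 ignore_attr = TRUE)
    expect_equal(srt(m2$is_elements), srt(m$is_elements), ignore_attr = TRUE)
  }
})

test_that("duplication of the 175 kb rrnA/rrnB stretch grows the map", {
  m <- mg1655_map()
  r <- rearrangement("duplication", 4030000, 4205000, copies = 2)
  md <- apply_rearrangement(m, r)
  expect_equal(md$length_bp, m$length_bp + 175000)
  expect_equal(sum(grepl("^rrnA", md$transcribed_features$name)), 2)
  expect_equal(sum(grepl("^rrnB", md$transcribed_features$name)), 2)
  # features downstream of the segment are shifted by one segment length
  expect_equal(md$transcribed_features$start_bp[md$transcribed_features$name == "rrnE"],
               m$transcribed_features$start_bp[m$transcribed_features$name == "rrnE"] +
                 175000)
  # feature count grows by exactly the contained features x (copies - 1)
  expect_equal(nrow(md$transcribed_features), nrow(m$transcribed_features) + 2)
  # duplicating an origin is allowed but flagged
  r2 <- rearrangement("duplication", 3900000, 3990000, copies = 2)
  expect_message(apply_rearrangement(m, r2), "origin")
})

test_that("rearrangement validation", {
  m <- mg1655_map()
  expect_error(rearrangement("inversion", 100, 100), "zero-length")
  expect_error(rearrangement("inversion", 2000, 1000), "wrapping")
  expect_error(rearrangement("duplication", 0, 1000, copies = 1), "copies")
  # a breakpoint inside an annotated feature is refused
  expect_error(apply_rearrangement(m, rearrangement("inversion", 3424000, 3600000)),
               "inside")
  expect_error(apply_rearrangement(m, rearrangement("inversion", 575500, 1394000)),
               "inside")  # bisects the IS5 at 575 kb
})

test_that("profile projection: symmetry, involution, duplication pile-up", {
  L <- 100000; b <- 1000
  r <- rearrangement("inversion", 20000, 60000)
  # profile symmetric about the segment centre is unchanged
  x <- forktrap:::bin_mids(L, b)
  sym <- mfa_profile(1 + cos(2 * pi * (x - 40000) / 30000) * (x >= 20000 & x < 60000),
                     b, L, source = "model")
  expect_equal(project_profile(sym, r)$values, sym$values)
  # involution / round trip
  set.seed(12)
  p <- mfa_profile(runif(L / b, 0.5, 1.5), b, L, source = "data")
  expect_equal(project_profile(project_profile(p, r), r)$values, p$values)
  # duplication: forward sums copies, reference round trip is the identity
  rd <- rearrangement("duplication", 20000, 30000, copies = 3)
  long <- mfa_profile(runif((L + 20000) / b, 0.5, 1.5), b, L + 20000, source = "data")
  proj <- project_profile(long, rd)
  expect_equal(length(proj$values), L / b)
  expect_equal(proj$values[21:30],
               long$values[21:30] + long$values[31:40] + long$values[41:50])
  back <- project_profile(project_profile(p, rd, inverse = TRUE), rd)
  expect_equal(back$values, p$values)
  expect_error(project_profile(p, rearrangement("inversion", 500, 60000)), "grid")
})

test_that("a model profile simulated on the inverted map jumps at the breakpoints", {
  m <- mg1655_map()
  r <- rearrangement("inversion", 575000, 1394000)
  mi <- apply_rearrangement(m, r)
  prof <- marker_frequency(replication_schedule(mi, cell_class("oriX"), sim_params()))
  proj <- project_profile(prof, r)
  jump <- function(p, pos) {
    i <- forktrap:::bin_index(pos, p$bin_size, p$length_bp)
    abs(p$values[i + 1] - p$values[i - 1])
  }
  expect_gt(jump(proj, 575000), 0.1)
  expect_gt(jump(proj, 1394000), 0.1)
  expect_lt(jump(prof, 575000), 0.01)   # continuous before projection
})

test_that("continuity score separates true breakpoints from background", {
  m <- mg1655_map()
  r <- rearrangement("inversion", 575000, 1394000)
  mi <- apply_rearrangement(m, r)
  prof <- marker_frequency(replication_schedule(mi, cell_class("oriX"), sim_params()))
  proj <- project_profile(prof, r)
  s_true <- continuity_score(proj, c(575000, 1394000))
  s_null <- continuity_score(proj, c(2100000, 3300000))
  expect_gt(s_true, 100 * max(s_null, 1e-6))
  expect_equal(continuity_score(prof, c(575000, 1394000)), 0, tolerance = 30)
})

test_that("evaluate_candidate recovers both studied inversions from noisy data", {
  m <- mg1655_map()
  for (scen in c("doriC_oriX_inv820", "doriC_oriX_rpo_inv895")) {
    sc <- generate_scenario(scen, seed = 42)
    raw <- normalize_counts(sc$sample, sc$control)
    tr <- sc$truth$rearrangement
    true_r <- rearrangement(tr$kind, tr$start_bp, tr$end_bp)
    ev <- evaluate_candidate(raw, true_r)
    expect_lt(ev$ratio, 0.1)
    # identity-like wrong candidate does not restore continuity
    wrong <- rearrangement("inversion", 2288000, 3288000)
    expect_gt(evaluate_candidate(raw, wrong)$ratio, 0.5)
  }
})

test_that("IS-pair enumeration covers both studied inversions", {
  m <- mg1655_map()
  cands <- enumerate_is_candidates(m)
  key <- vapply(cands, function(r) paste(r$start_bp, r$end_bp), character(1))
  expect_equal(length(cands), 3)
  expect_true("575000 1394000" %in% key)
  expect_true("1394000 2288000" %in% key)
})
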