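#' Define a cell class
#'
#' A cell class is a subpopulation in which a fixed set of origins fires
#' simultaneously at t = 0 and the ter/Tus fork trap is either active or not.
#' Observed population profiles are mixtures of class profiles.
#'
#' @param active_origins Character vector of origin names (>= 1), which must
#'   exist in the map the class is used with.
#' @param tus_active Is the fork trap functional (`tus+`)? Default `TRUE`.
#' @param label Class label; defaults to `origin1+origin2[+...]`.
#' @return An object of class `cell_class`.
#' @export
cell_class <- function(active_origins, tus_active = TRUE, label = NULL) {
  active_origins <- unique(as.character(active_origins))
  if (!length(active_origins)) stop("a cell class needs at least one active origin")
  structure(list(active_origins = active_origins, tus_active = isTRUE(tus_active),
                 label = label %||% paste(active_origins, collapse = "+")),
            class = "cell_class")
}

#' Replication model parameters
#'
#' @param fork_speed Fork velocity v in nt/s (default 1000; the literature
#'   range is 650–1000 nt/s).
#' @param tau Inter-initiation period of the modelled population in minutes
#'   (default 25): origins fire every `tau` minutes in steady state, so a
#'   locus replicated at time t after initiation has relative copy number
#'   `2^(-t / tau)`.
#' @param headon_speed_factor Multiplier in (0, 1] applied to the fork speed
#'   inside highly transcribed features traversed against their direction of
#'   transcription (head-on conflicts). Default 1 (constant speed, as in the
#'   basic model); an rpo*-like allele corresponds to moving the factor back
#'   towards 1.
#' @param ter_leakage Probability that a fork passes a blocking ter site
#'   (default 0 = hard stop). Only honoured by the stochastic event simulator;
#'   the analytic schedule requires 0.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(fork_speed = 1000, tau = 25, headon_speed_factor = 1,
                       ter_leakage = 0) {
  stopifnot(fork_speed > 0, tau > 0,
            headon_speed_factor > 0, headon_speed_factor <= 1,
            ter_leakage >= 0, ter_leakage < 1)
  structure(list(fork_speed = fork_speed, tau = tau,
                 headon_speed_factor = headon_speed_factor,
                 ter_leakage = ter_leakage), class = "sim_params")
}

# Fork table for a class: one cw and one ccw fork per active origin, cw forks
# first so ties in arrival time resolve to the clockwise fork.
fork_table <- function(map, class) {
  idx <- match(class$active_origins, map$origins$name)
  if (anyNA(idx)) stop("unknown origin(s): ",
                       paste(class$active_origins[is.na(idx)], collapse = ", "))
  pos <- map$origins$position_bp[idx]
  data.frame(origin = rep(class$active_origins, 2),
             pos = rep(pos, 2),
             dir = rep(c("cw", "ccw"), each = length(pos)),
             id = paste0(rep(class$active_origins, 2), ":",
                         rep(c("cw", "ccw"), each = length(pos))),
             stringsAsFactors = FALSE)
}

# Head-on features for a fork direction: highly transcribed features whose
# transcription direction opposes the fork's travel.
headon_features <- function(map, dir) {
  tf <- map$transcribed_features
  tf[tf$highly_transcribed & tf$direction != dir, , drop = FALSE]
}

# union of head-on intervals: overlapping features slow a fork once, not twice
headon_intervals <- function(map, dir) {
  ho <- headon_features(map, dir)
  if (!nrow(ho)) return(ho[, c("start_bp", "end_bp")])
  ho <- ho[order(ho$start_bp), , drop = FALSE]
  s <- ho$start_bp[1]; e <- ho$end_bp[1]
  out <- list()
  for (k in seq_len(nrow(ho))[-1]) {
    if (ho$start_bp[k] <= e) e <- max(e, ho$end_bp[k])
    else { out[[length(out) + 1L]] <- c(s, e); s <- ho$start_bp[k]; e <- ho$end_bp[k] }
  }
  out[[length(out) + 1L]] <- c(s, e)
  data.frame(start_bp = vapply(out, `[`, 1, 1), end_bp = vapply(out, `[`, 1, 2))
}

# Time for a fork starting at `from`, travelling `dist` bp in `dir`, with
# speed v scaled by `factor` inside head-on transcribed features. Vectorised
# over `dist`. The path from `from` over distance d covers, in shifted
# coordinates u in [0, d], the feature as the interval [o1, o1 + len] with
# o1 = (start - from) mod L for cw and (from - end) mod L for ccw; a second
# wrapped image at o1 - L handles features the fork starts inside of.
travel_time <- function(map, from, dist, dir, params) {
  v <- params$fork_speed
  tt <- dist / v
  fac <- params$headon_speed_factor
  if (fac < 1) {
    L <- map$length_bp
    ho <- headon_intervals(map, dir)
    extra_per_bp <- 1 / (v * fac) - 1 / v
    for (k in seq_len(nrow(ho))) {
      len <- ho$end_bp[k] - ho$start_bp[k]
      o1 <- if (dir == "cw") pmod(ho$start_bp[k] - from, L) else pmod(from - ho$end_bp[k], L)
      ov <- pmax(0, pmin(dist, o1 + len) - o1) +
            pmax(0, pmin(dist, o1 + len - L) - pmax(0, o1 - L))
      tt <- tt + ov * extra_per_bp
    }
  }
  tt
}

# Arc distance from a fork origin to the first ter site that blocks travel in
# `dir` (Inf when the trap is off or no such site lies ahead; a site exactly
# at the origin does not count).
block_distance <- function(map, from, dir, tus_active) {
  if (!tus_active) return(list(dist = Inf, ter = NA_character_))
  ts <- map$ter_sites[map$ter_sites$blocks == dir, , drop = FALSE]
  if (!nrow(ts)) return(list(dist = Inf, ter = NA_character_))
  L <- map$length_bp
  d <- if (dir == "cw") pmod(ts$position_bp - from, L) else pmod(from - ts$position_bp, L)
  d[d == 0] <- L  # a ter at the origin position blocks only after a full lap
  i <- which.min(d)
  list(dist = d[i], ter = ts$name[i])
}

#' Analytic replication schedule for one cell class
#'
#' Computes the fork-arrival time of every bin on the circular chromosome
#' under the deterministic model: all active origins fire simultaneously at
#' t = 0, each launching one clockwise and one counter-clockwise fork at
#' constant speed (optionally slowed inside head-on highly transcribed
#' features); a fork reaching a ter site whose polarity matches its travel
#' direction halts there (hard stop, when `tus_active`) and waits for the
#' converging fork; each bin is replicated by whichever fork arrives first,
#' and converging forks fuse where their arrival times meet.
#'
#' @param map A [chrom_map].
#' @param class A [cell_class].
#' @param params A [sim_params] (with `ter_leakage = 0`).
#' @param bin_size Bin width in bp (default 1000).
#' @return An object of class `replication_schedule`: per-bin arrival times
#'   `t` (seconds; exactly 0 at active-origin bins), per-bin `fork_id`,
#'   `block_events` and `fusion_events` data frames.
#' @export
replication_schedule <- function(map, class, params = sim_params(), bin_size = 1000) {
  stopifnot(inherits(map, "chrom_map"), inherits(class, "cell_class"))
  if (params$ter_leakage > 0)
    stop("the analytic schedule is deterministic: ter_leakage must be 0 ",
         "(use simulate_schedule_events() for leaky traps)")
  L <- map$length_bp
  forks <- fork_table(map, class)
  mids <- bin_mids(L, bin_size)
  n <- length(mids)

  tmat <- matrix(Inf, nrow = nrow(forks), ncol = n)
  blocks <- vector("list", nrow(forks))
  for (f in seq_len(nrow(forks))) {
    dir <- forks$dir[f]; from <- forks$pos[f]
    d <- if (dir == "cw") pmod(mids - from, L) else pmod(from - mids, L)
    bl <- block_distance(map, from, dir, class$tus_active)
    blocks[[f]] <- bl
    reach <- d <= bl$dist
    tmat[f, reach] <- travel_time(map, from, d[reach], dir, params)
  }

  t_bin <- apply(tmat, 2L, min)
  widx <- apply(tmat, 2L, which.min)  # ties -> first row = cw fork
  if (any(!is.finite(t_bin)))
    stop("unreplicable bins: ", sum(!is.finite(t_bin)),
         " bins cannot be reached by any fork under the hard-stop trap model")

  # active-origin bins replicate at t = 0 by definition
  ob <- bin_index(forks$pos[forks$dir == "cw"], bin_size, L)
  t_bin[ob] <- 0
  widx[ob] <- match(forks$id[forks$dir == "cw"], forks$id)

  # block events: fork f actually reaches its blocking ter iff it gets there
  # before any other fork replicates that point
  bev <- list()
  for (f in seq_len(nrow(forks))) {
    bl <- blocks[[f]]
    if (!is.finite(bl$dist)) next
    tb <- travel_time(map, forks$pos[f], bl$dist, forks$dir[f], params)
    ter_pos <- pmod(forks$pos[f] + (if (forks$dir[f] == "cw") 1 else -1) * bl$dist, L)
    t_others <- vapply(seq_len(nrow(forks))[-f], function(g) {
      dg <- if (forks$dir[g] == "cw") pmod(ter_pos - forks$pos[g], L)
            else pmod(forks$pos[g] - ter_pos, L)
      if (dg > blocks[[g]]$dist) return(Inf)
      travel_time(map, forks$pos[g], dg, forks$dir[g], params)
    }, numeric(1))
    if (tb < min(t_others, Inf)) {
      bev[[length(bev) + 1L]] <- data.frame(
        ter = bl$ter, fork = forks$id[f], time = tb, position = ter_pos,
        fusion_time = if (length(t_others) && any(is.finite(t_others)))
          min(t_others) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  block_events <- if (length(bev)) do.call(rbind, bev) else
    data.frame(ter = character(), fork = character(), time = numeric(),
               position = numeric(), fusion_time = numeric())

  # fusion events: circular boundaries where the winning fork changes and
  # neither side is an origin bin (t > 0 on both sides)
  nxt <- c(2:n, 1L)
  chg <- which(widx != widx[nxt] & t_bin > 0 & t_bin[nxt] > 0)
  fusion_events <- data.frame(
    position = pmod(chg * bin_size, L),
    time = pmax(t_bin[chg], t_bin[nxt][chg]))

  structure(list(bin_size = bin_size, length_bp = L,
                 t = t_bin, fork_id = forks$id[widx],
                 block_events = block_events, fusion_events = fusion_events,
                 class = class, params = params),
            class = "replication_schedule")
}

#' @export
print.replication_schedule <- function(x, ...) {
  cat(sprintf("<replication_schedule> %s (%s): %d bins x %d bp\n",
              x$class$label, if (x$class$tus_active) "tus+" else "tus-",
              length(x$t), as.integer(x$bin_size)))
  cat(sprintf("  t in [0, %.0f] s; %d block event(s), %d fusion boundary(ies)\n",
              max(x$t), nrow(x$block_events), nrow(x$fusion_events)))
  invisible(x)
}

#' Marker-frequency profile of a replication schedule
#'
#' In a steady-state exponential population in which each cell class initiates
#' every `tau` minutes, the relative copy number of a locus replicated at time
#' t after initiation is `f = 2^(-t / tau)`: the origin (t = 0) is at 1 and a
#' locus replicated one full period later is at 1/2. Origin:terminus ratios
#' above 2 (overlapping rounds) arise naturally when the last locus replicates
#' later than `tau`.
#'
#' @param schedule A [replication_schedule].
#' @param tau Inter-initiation period in minutes; defaults to the value in the
#'   schedule's parameters.
#' @return An [mfa_profile] (`source = "model"`, maximum 1 at active origins).
#' @export
marker_frequency <- function(schedule, tau = NULL) {
  tau <- tau %||% schedule$params$tau
  stopifnot(tau > 0)
  f <- 2^(-schedule$t / (tau * 60))
  mfa_profile(f, schedule$bin_size, schedule$length_bp, source = "model",
              normalisation = sprintf("2^(-t/tau), tau=%g min", tau))
}
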