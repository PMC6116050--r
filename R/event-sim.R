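#' Discrete-event replication simulation (brute-force oracle)
#'
#' Time-stepped counterpart of [replication_schedule()]: every unblocked fork
#' advances `v * dt` per step (piecewise-exactly across speed-changing feature
#' boundaries), claiming bin midpoints at their exact crossing times. A fork
#' crossing a midpoint already claimed by another fork fuses and stops; a fork
#' reaching a blocking ter site halts (or passes with probability
#' `ter_leakage`) and waits for the converging fork. Used as the independent
#' oracle for the analytic schedule; near-simultaneous fork interactions are
#' resolved with step granularity, so arrival times agree with the analytic
#' model to within ~2 dt.
#'
#' @param map A [chrom_map].
#' @param class A [cell_class].
#' @param params A [sim_params]; `ter_leakage > 0` is honoured stochastically.
#' @param bin_size Bin width in bp.
#' @param dt Time step in seconds.
#' @param max_steps Non-termination guard.
#' @return A `replication_schedule` (fusion event times carry step-level
#'   granularity).
#' @export
simulate_schedule_events <- function(map, class, params = sim_params(),
                                     bin_size = 1000, dt = 1, max_steps = 1e6) {
  stopifnot(inherits(map, "chrom_map"), inherits(class, "cell_class"), dt > 0)
  L <- map$length_bp
  forks <- fork_table(map, class)
  nf <- nrow(forks)
  mids <- bin_mids(L, bin_size)
  n <- length(mids)
  v <- params$fork_speed
  eps <- 1e-7

  claimed_t <- rep(NA_real_, n)
  claimed_by <- rep(NA_integer_, n)
  # origin bins replicate at t = 0; mark owner as -origin so both of an
  # origin's forks may cross their own origin bin but foreign forks fuse there
  ocw <- which(forks$dir == "cw")
  origin_of <- match(forks$origin, forks$origin[ocw])
  ob <- bin_index(forks$pos[ocw], bin_size, L)
  if (anyDuplicated(ob)) stop("two active origins share a bin; use a smaller bin_size")
  claimed_t[ob] <- 0
  claimed_by[ob] <- -seq_along(ocw)

  pos <- forks$pos
  sgn <- ifelse(forks$dir == "cw", 1, -1)
  alive <- rep(TRUE, nf)
  blocked <- rep(FALSE, nf)
  passed_ter <- vector("list", nf)  # ters leaked through, per fork

  ho_cw <- headon_features(map, "cw")
  ho_ccw <- headon_features(map, "ccw")
  speed_bounds <- function(dir) {
    ho <- if (dir == "cw") ho_cw else ho_ccw
    sort(unique(pmod(c(ho$start_bp, ho$end_bp), L)))
  }
  bnd <- list(cw = speed_bounds("cw"), ccw = speed_bounds("ccw"))
  in_headon <- function(x, dir) {
    ho <- if (dir == "cw") ho_cw else ho_ccw
    any(x >= ho$start_bp & x < ho$end_bp)
  }
  local_speed <- function(x, dir) {
    if (params$headon_speed_factor < 1 && in_headon(x, dir))
      v * params$headon_speed_factor else v
  }
  dist_ahead <- function(from, to, dir) {
    d <- if (dir == "cw") pmod(to - from, L) else pmod(from - to, L)
    d[d < eps] <- L
    d
  }

  blocking <- lapply(c(cw = "cw", ccw = "ccw"), function(d)
    map$ter_sites[map$ter_sites$blocks == d, , drop = FALSE])

  block_events <- list()
  fusion_events <- list()
  mid_next <- function(from, dir) {
    d <- dist_ahead(from, mids, dir)
    i <- which.min(d)
    c(d[i], i)
  }

  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) stop("event simulation exceeded max_steps")
    if (!anyNA(claimed_t)) break
    movers <- which(alive & !blocked)
    if (!length(movers)) {
      stop("unreplicable bins: ", sum(is.na(claimed_t)),
           " bins cannot be reached by any fork under the hard-stop trap model")
    }
    t_base <- (step - 1L) * dt
    for (f in movers) {
      if (!alive[f] || blocked[f]) next
      remaining <- dt
      while (remaining > eps / v) {
        dir <- forks$dir[f]
        sp <- local_speed(pmod(pos[f] + sgn[f] * eps, L), dir)
        cap <- sp * remaining
        # candidate events ahead: next midpoint, next speed boundary,
        # next blocking ter (not leaked), next waiting blocked fork
        mn <- mid_next(pos[f], dir)
        d_ev <- mn[1]; ev <- "mid"; ev_i <- mn[2]
        if (length(bnd[[dir]])) {
          db <- min(dist_ahead(pos[f], bnd[[dir]], dir))
          if (db < d_ev) { d_ev <- db; ev <- "bnd"; ev_i <- NA }
        }
        bt <- blocking[[dir]]
        if (class$tus_active && nrow(bt)) {
          keep <- !(bt$name %in% passed_ter[[f]])
          if (any(keep)) {
            db <- dist_ahead(pos[f], bt$position_bp[keep], dir)
            j <- which.min(db)
            if (db[j] < d_ev) { d_ev <- db[j]; ev <- "ter"; ev_i <- which(keep)[j] }
          }
        }
        waiting <- which(alive & blocked)
        waiting <- waiting[waiting != f]
        if (length(waiting)) {
          db <- dist_ahead(pos[f], pos[waiting], dir)
          j <- which.min(db)
          if (db[j] <= d_ev) { d_ev <- db[j]; ev <- "barrier"; ev_i <- waiting[j] }
        }
        if (d_ev > cap + eps) {  # no event within this step
          pos[f] <- pmod(pos[f] + sgn[f] * cap, L)
          remaining <- 0
          break
        }
        t_cross <- t_base + (dt - remaining) + d_ev / sp
        pos[f] <- pmod(pos[f] + sgn[f] * d_ev, L)
        remaining <- remaining - d_ev / sp
        if (ev == "mid") {
          i <- ev_i
          if (is.na(claimed_by[i])) {
            claimed_t[i] <- t_cross
            claimed_by[i] <- f
          } else if (claimed_by[i] == f || identical(claimed_by[i], -origin_of[f])) {
            # own claim (origin bin): pass through
          } else {
            alive[f] <- FALSE
            fusion_events[[length(fusion_events) + 1L]] <-
              data.frame(position = pos[f], time = t_cross)
            break
          }
        } else if (ev == "ter") {
          tn <- blocking[[dir]]$name[ev_i]
          if (params$ter_leakage > 0 && stats::runif(1) < params$ter_leakage) {
            passed_ter[[f]] <- c(passed_ter[[f]], tn)
          } else {
            blocked[f] <- TRUE
            block_events[[length(block_events) + 1L]] <-
              data.frame(ter = tn, fork = forks$id[f], time = t_cross,
                         position = pos[f], fusion_time = NA_real_,
                         stringsAsFactors = FALSE)
            break
          }
        } else if (ev == "barrier") {
          g <- ev_i
          alive[f] <- FALSE
          alive[g] <- FALSE
          fusion_events[[length(fusion_events) + 1L]] <-
            data.frame(position = pos[f], time = t_cross)
          break
        }
        # ev == "bnd": speed changes; loop continues
      }
    }
  }

  widx <- claimed_by
  widx[widx < 0] <- ocw[-widx[widx < 0]]
  structure(list(bin_size = bin_size, length_bp = L,
                 t = claimed_t, fork_id = forks$id[widx],
                 block_events = if (length(block_events)) do.call(rbind, block_events)
                   else data.frame(ter = character(), fork = character(),
                                   time = numeric(), position = numeric(),
                                   fusion_time = numeric()),
                 fusion_events = if (length(fusion_events)) do.call(rbind, fusion_events)
                   else data.frame(position = numeric(), time = numeric()),
                 class = class, params = params),
            class = "replication_schedule")
}
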