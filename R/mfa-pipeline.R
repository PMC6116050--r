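#' LOESS configuration for circular profile smoothing
#'
#' The smoother fits a local weighted second-order polynomial with tricube
#' weights to the nearest `span_fraction` of bins around each bin, with
#' periodic (circular) boundary conditions. At the default 10% span on the
#' full 4.64 Mb chromosome binned at 1 kb the window is ~460 kbp wide.
#'
#' @param span_fraction Fraction of bins in each local window (default 0.10).
#' @param degree Local polynomial degree (default 2).
#' @return An object of class `loess_config`.
#' @export
loess_config <- function(span_fraction = 0.10, degree = 2) {
  stopifnot(span_fraction > 0, span_fraction <= 1, degree %in% 0:2)
  structure(list(span_fraction = span_fraction, degree = degree,
                 weight_kernel = "tricube", periodic = TRUE),
            class = "loess_config")
}

#' Normalise sample counts against a stationary-phase control
#'
#' Per-bin ratio of read proportions,
#' `(sample_i / sample_total) / (control_i / control_total)`, which cancels
#' locus-specific coverage biases shared by the two libraries. Bins whose
#' control count falls below `control_floor` are masked (`NA`), as are any
#' bins in `extra_mask` (e.g. protein-occupancy artifact loci flagged with
#' [artifact_mask()]). The result is rescaled to mean 1 over unmasked bins.
#'
#' @param sample,control [binned_counts] on identical bins.
#' @param control_floor Minimum control count for a bin to be retained
#'   (default 10).
#' @param extra_mask Optional logical vector of additional bins to mask.
#' @return An [mfa_profile] (`source = "data"`).
#' @export
normalize_counts <- function(sample, control, control_floor = 10, extra_mask = NULL) {
  stopifnot(inherits(sample, "binned_counts"), inherits(control, "binned_counts"))
  if (!same_binning(sample, control)) stop("binning mismatch between sample and control")
  mask <- control$counts < control_floor
  if (!is.null(extra_mask)) {
    stopifnot(length(extra_mask) == length(mask))
    mask <- mask | extra_mask
  }
  ratio <- (sample$counts / sample$total) / (control$counts / control$total)
  ratio[mask] <- NA_real_
  if (all(is.na(ratio))) stop("all bins masked during normalisation")
  ratio <- ratio / mean(ratio, na.rm = TRUE)
  mfa_profile(ratio, sample$bin_size, sample$length_bp, source = "data",
              normalisation = sprintf(
                "ratio to control '%s', floor=%g, mean-scaled", control$label,
                control_floor))
}

# tricube weights for integer bin offsets -w..w
tricube_weights <- function(w) {
  d <- abs(-w:w) / w
  (1 - d^3)^3
}

#' Circular LOESS smoothing of a marker-frequency profile
#'
#' Local weighted polynomial regression on the circle: for every bin, the
#' nearest `span_fraction` of bins (by circular bin distance) is fitted with a
#' degree-`degree` polynomial under tricube weights scaled to the window
#' half-width, and the fit is evaluated at the bin itself. Masked (`NA`) bins
#' are excluded from all local fits but still receive smoothed values.
#'
#' Windows free of masked bins share identical regression weights, so the
#' smoother reduces to a circular convolution there (O(n k)); windows touching
#' masked bins fall back to an explicit weighted least-squares fit. Both
#' routes are checked against a brute-force per-point regression oracle in the
#' package tests.
#'
#' @param profile An [mfa_profile].
#' @param config A [loess_config].
#' @return A smoothed [mfa_profile]; the input mask is preserved as attribute
#'   `"mask"`.
#' @export
circular_loess <- function(profile, config = loess_config()) {
  y <- profile$values
  n <- length(y)
  k <- max(ceiling(config$span_fraction * n), config$degree + 2)
  if (k %% 2 == 0) k <- k + 1
  w <- (k - 1) / 2
  if (w < 2) stop("smoothing window too small for a local polynomial fit")
  if (k > n) stop("smoothing window exceeds the number of bins")
  wt <- tricube_weights(w)
  offs <- -w:w
  X <- stats::poly(offs, degree = max(config$degree, 1), raw = TRUE)
  X <- cbind(1, matrix(X[, seq_len(config$degree), drop = FALSE], nrow = k))

  nz <- wt > 0
  if (sum(nz) < config$degree + 1) stop("window too small for the requested degree")
  mask <- is.na(y)
  if (sum(!mask) < k) stop("fewer unmasked bins than the smoothing window")

  # fast path: projection coefficients shared by all clean windows
  XW <- X[nz, , drop = FALSE] * wt[nz]
  M <- solve(crossprod(X[nz, , drop = FALSE], XW))
  cvec <- numeric(k)
  cvec[nz] <- as.numeric(M[1, , drop = FALSE] %*% t(XW))
  y0 <- y
  y0[mask] <- 0
  sm <- as.numeric(stats::filter(y0, rev(cvec), method = "convolution",
                                 sides = 2, circular = TRUE))

  # windows containing masked bins: explicit WLS excluding them
  if (any(mask)) {
    touched <- unique(as.vector(outer(which(mask), offs, `+`)))
    touched <- ((touched - 1) %% n) + 1L
    for (i in touched) {
      idx <- ((i - 1 + offs) %% n) + 1L
      keep <- nz & !mask[idx]
      if (sum(keep) < config$degree + 2)
        stop("window too small after masking for a degree-", config$degree, " fit")
      fit <- stats::lm.wfit(X[keep, , drop = FALSE], y[idx][keep], wt[keep])
      sm[i] <- fit$coefficients[1]
    }
  }
  out <- mfa_profile(pmax(sm, 0), profile$bin_size, profile$length_bp,
                     source = profile$source,
                     normalisation = paste0(profile$normalisation,
                                            sprintf("; loess span=%g degree=%d",
                                                    config$span_fraction, config$degree)))
  attr(out, "mask") <- mask
  out
}

# circular running medians of `width` bins ending just left of / starting at
# each bin boundary b (boundary b sits before 1-based bin b+1)
boundary_medians <- function(y, width, side = c("left", "right"), offset = 0L) {
  side <- match.arg(side)
  n <- length(y)
  yy <- c(y, y, y)
  vapply(0:(n - 1L), function(b) {
    if (side == "left") idx <- (n + b - offset - width + 1L):(n + b - offset)
    else idx <- (n + b + offset + 1L):(n + b + offset + width)
    stats::median(yy[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Locate profile extrema
#'
#' Finds the global minimum of a (smoothed) profile and all local maxima whose
#' topographic prominence exceeds `prominence_frac` of the profile's dynamic
#' range, working on the circle.
#'
#' @param profile An [mfa_profile] (typically LOESS-smoothed).
#' @param prominence_frac Minimum peak prominence as a fraction of
#'   `max - min` (default 0.02).
#' @return A list with `low_point` (bp coordinate of the bin-midpoint minimum;
#'   `NA` for a flat profile), `flat` flag, and `peaks`
#'   (data.frame `position`, `height`, `prominence`).
#' @export
find_extrema <- function(profile, prominence_frac = 0.02) {
  y <- profile$values
  n <- length(y)
  mids <- bin_mids(profile$length_bp, profile$bin_size)
  rng <- range(y, na.rm = TRUE)
  if (diff(rng) < 1e-12)
    return(list(low_point = NA_real_, flat = TRUE,
                peaks = data.frame(position = numeric(), height = numeric(),
                                   prominence = numeric())))
  low_point <- mids[which.min(y)]

  prev <- c(n, 1:(n - 1)); nxt <- c(2:n, 1)
  cand <- which(!is.na(y) & y >= y[prev] & y >= y[nxt] &
                  (y > y[prev] | y > y[nxt]))
  prom <- vapply(cand, function(i) {
    lo <- c(Inf, Inf)
    for (s in 1:2) {
      stepv <- if (s == 1) -1 else 1
      j <- i; m <- y[i]
      for (q in seq_len(n - 1)) {
        j <- ((j - 1 + stepv) %% n) + 1
        if (is.na(y[j])) next
        if (y[j] > y[i]) break
        m <- min(m, y[j])
      }
      lo[s] <- m
    }
    y[i] - max(lo)
  }, numeric(1))
  keep <- prom >= prominence_frac * diff(rng)
  peaks <- data.frame(position = mids[cand[keep]], height = y[cand[keep]],
                      prominence = prom[keep])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  list(low_point = low_point, flat = FALSE, peaks = peaks)
}

#' Detect copy-number steps and free discontinuities
#'
#' Scans every circular bin boundary for a jump between the medians of the
#' flanking `flank`-bp windows. The raw flanking-median difference responds to
#' smooth copy-number gradients too, so by default it is trend-corrected with
#' a second pair of outer windows; candidate boundaries exceeding the
#' threshold are merged into runs and each run's breakpoint is refined by a
#' robust (least-absolute-deviation) two-segment split. Breakpoints within
#' `label_tol` of an annotated ter site are reported as ter steps (the
#' trap's signature); all others are free discontinuities — candidate gross
#' chromosomal rearrangements.
#'
#' @param profile An [mfa_profile] (raw normalised ratios localise steps
#'   sharply; heavily smoothed input smears them). Mask artifact loci first
#'   (see [process_counts()]): the depletion dip at a ter site otherwise
#'   mimics a small step at exactly the position where trap steps live.
#' @param map A [chrom_map] providing ter annotations.
#' @param threshold Absolute jump threshold; default
#'   `max(rel_threshold * IQR(values), noise_z * sd(statistic))`, where the
#'   statistic's sampling noise is estimated from the profile's
#'   high-frequency residual — jumps below their own measurement noise are
#'   not reportable.
#' @param flank Flanking window width in bp (default 50000).
#' @param rel_threshold Relative threshold (fraction of the profile IQR,
#'   default 0.10) used when `threshold` is `NULL`.
#' @param noise_z Noise-floor multiplier (default 3.5).
#' @param detrend Correct for local linear trend (default `TRUE`).
#' @param label_tol Max distance (bp) between a breakpoint and a ter site for
#'   labelling; default 5000 bp (breakpoints localise to ~1 bin on clean
#'   model profiles but only to a few bins at typical depth, especially with
#'   the artifact mask holes around ter sites).
#' @return List with data frames `steps` (`ter`, `position`, `magnitude`) and
#'   `discontinuities` (`position`, `jump`), plus the `threshold` used.
#' @export
detect_steps <- function(profile, map, threshold = NULL, flank = 50000,
                         rel_threshold = 0.10, noise_z = 3.5, detrend = TRUE,
                         label_tol = 5000) {
  y <- profile$values
  n <- length(y)
  b <- profile$bin_size
  fb <- max(3L, as.integer(round(flank / b)))
  if (2 * fb >= n) stop("flank too wide for the number of bins")
  m_l <- boundary_medians(y, fb, "left")
  m_r <- boundary_medians(y, fb, "right")
  D <- m_r - m_l
  if (detrend) {
    m_ll <- boundary_medians(y, fb, "left", offset = fb)
    m_rr <- boundary_medians(y, fb, "right", offset = fb)
    D <- D - ((m_rr - m_r) + (m_l - m_ll)) / 2
  }
  if (is.null(threshold)) {
    # robust per-bin noise from the high-frequency residual; the (detrended)
    # flanking-median difference of a continuous profile has sd ~ 1.73 times
    # the sd of one window median
    sigma_bin <- stats::mad(diff(y[!is.na(y)])) / sqrt(2)
    sigma_stat <- (if (detrend) sqrt(3) else sqrt(2)) * 1.253 * sigma_bin / sqrt(fb)
    threshold <- max(rel_threshold * stats::IQR(y, na.rm = TRUE),
                     noise_z * sigma_stat)
  }
  hit <- which(abs(D) >= threshold)
  res <- data.frame(position = numeric(), jump = numeric())
  if (length(hit)) {
    # merge circular runs of consecutive boundaries (allow gaps < fb/2)
    hs <- sort(hit)
    gap <- diff(hs) > fb / 2
    grp <- cumsum(c(TRUE, gap))
    if (length(hs) > 1 && (hs[1] + n - hs[length(hs)]) <= fb / 2)
      grp[grp == grp[length(grp)]] <- 1L  # wrap-around run
    for (g in unique(grp)) {
      bnds <- hs[grp == g]
      centre <- bnds[which.max(abs(D[bnds]))]
      refined <- refine_breakpoint(y, centre - 1L, fb)
      jump <- (m_r - m_l)[pmod(refined, n) + 1L]
      if (abs(jump) >= threshold)  # the refined jump must clear it too
        res <- rbind(res, data.frame(position = pmod(refined * b, profile$length_bp),
                                     jump = jump))
    }
  }
  if (nrow(res)) {
    # merge near-identical breakpoints from runs that refined to the same place
    res <- res[order(res$position), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(res$position) > fb / 2 * b))
    res <- do.call(rbind, lapply(split(res, grp), function(d)
      d[which.max(abs(d$jump)), , drop = FALSE]))
  }
  if (nrow(res)) {
    ter <- map$ter_sites
    lab <- vapply(res$position, function(p) {
      if (!nrow(ter)) return(NA_character_)
      d <- pmin(pmod(ter$position_bp - p, map$length_bp),
                pmod(p - ter$position_bp, map$length_bp))
      if (min(d) <= label_tol) ter$name[which.min(d)] else NA_character_
    }, character(1))
  } else lab <- character(0)
  list(steps = data.frame(ter = lab[!is.na(lab)],
                          position = res$position[!is.na(lab)],
                          magnitude = res$jump[!is.na(lab)],
                          stringsAsFactors = FALSE),
       discontinuities = data.frame(position = res$position[is.na(lab)],
                                    jump = res$jump[is.na(lab)]),
       threshold = threshold)
}

# L1-optimal two-segment split within +/- fb bins of boundary b0 (0-based
# boundary index); returns the refined 0-based boundary index.
refine_breakpoint <- function(y, b0, fb) {
  n <- length(y)
  idx <- ((b0 - fb):(b0 + fb - 1L)) %% n + 1L  # bins of the local window
  yy <- y[idx]
  splits <- seq_len(length(yy) - 1L)
  cost <- vapply(splits, function(s) {
    l <- yy[1:s]; r <- yy[(s + 1):length(yy)]
    sum(abs(l - stats::median(l, na.rm = TRUE)), na.rm = TRUE) +
      sum(abs(r - stats::median(r, na.rm = TRUE)), na.rm = TRUE)
  }, numeric(1))
  s <- splits[which.min(cost)]
  (b0 - fb + s) %% n
}

#' Relative origin activities from a smoothed profile
#'
#' Reads the smoothed profile value at each annotated origin and rescales so
#' the strongest origin is 1: in exponential populations the peak height at an
#' origin tracks how often that origin fires.
#'
#' @param profile A smoothed [mfa_profile].
#' @param map A [chrom_map].
#' @param origins Origin names to report (default: all in the map).
#' @return Named numeric vector of relative peak heights (max = 1).
#' @export
origin_activity <- function(profile, map, origins = map$origins$name) {
  idx <- match(origins, map$origins$name)
  if (anyNA(idx)) stop("unknown origin(s): ", paste(origins[is.na(idx)], collapse = ", "))
  bi <- bin_index(map$origins$position_bp[idx], profile$bin_size, profile$length_bp)
  h <- profile$values[bi]
  names(h) <- origins
  h / max(h, na.rm = TRUE)
}

#' One-call profile pipeline: normalise then smooth
#'
#' @param sample,control [binned_counts].
#' @param map [chrom_map] (for artifact masking).
#' @param control_floor See [normalize_counts()].
#' @param mask_artifacts Mask rrn/ter protein-occupancy artifact loci
#'   (default `TRUE`; see [artifact_mask()]).
#' @param config A [loess_config].
#' @return List with elements `raw` and `smooth` ([mfa_profile]s).
#' @export
process_counts <- function(sample, control, map, control_floor = 10,
                           mask_artifacts = TRUE, config = loess_config()) {
  em <- if (mask_artifacts) artifact_mask(map, sample$bin_size) else NULL
  raw <- normalize_counts(sample, control, control_floor = control_floor,
                          extra_mask = em)
  list(raw = raw, smooth = circular_loess(raw, config))
}
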