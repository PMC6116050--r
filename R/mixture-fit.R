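# Lawson-Hanson active-set non-negative least squares: minimise ||Ax - b||^2
# subject to x >= 0. Small-p problems only (class bases have a handful of
# columns), so the dense normal-equation solves are fine.
nnls_lh <- function(A, b, tol = NULL, max_iter = NULL) {
  p <- ncol(A)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(crossprod(A, b))) * p)
  max_iter <- max_iter %||% (3L * p + 30L)
  x <- numeric(p)
  P <- rep(FALSE, p)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      z <- numeric(p)
      Ap <- A[, P, drop = FALSE]
      z[P] <- drop(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Model profile basis for a set of cell classes
#'
#' One model marker-frequency profile per class on a common binning, each
#' mean-scaled to 1 so they are commensurable with a mean-scaled data
#' profile. The pre-scaling mean copy number of each class (needed to convert
#' fitted DNA shares back into cell fractions) is kept alongside.
#'
#' @param map A [chrom_map].
#' @param classes List of [cell_class] objects.
#' @param params A [sim_params].
#' @param bin_size Bin width in bp.
#' @param config Optional [loess_config]: smooth each basis profile the same
#'   way the observed profile was smoothed (smoothing is linear, so fitting
#'   smoothed-vs-smoothed preserves the weights).
#' @return List with `profiles` (list of [mfa_profile], mean 1), `means`
#'   (pre-scaling mean copy number per class), `schedules`, and `labels`.
#' @export
class_basis <- function(map, classes, params = sim_params(), bin_size = 1000,
                        config = NULL) {
  schedules <- lapply(classes, function(cl)
    replication_schedule(map, cl, params, bin_size))
  basis_from_schedules(schedules, params$tau, config)
}

basis_from_schedules <- function(schedules, tau, config = NULL) {
  profiles <- lapply(schedules, marker_frequency, tau = tau)
  if (!is.null(config)) profiles <- lapply(profiles, circular_loess, config = config)
  means <- vapply(profiles, function(p) mean(p$values), numeric(1))
  profiles <- Map(function(p, m) { p$values <- p$values / m; p }, profiles, means)
  list(profiles = profiles, means = means, schedules = schedules,
       labels = vapply(schedules, function(s) s$class$label, character(1)))
}

#' Fit subpopulation origin-usage weights to an observed profile
#'
#' Non-negative least squares of the observed (smoothed, mean-scaled) profile
#' on the model profiles of the candidate cell classes. Because a class whose
#' cells replicate more holds more DNA per cell, the NNLS solution on
#' mean-scaled profiles recovers each class's share of DNA; dividing by the
#' class mean copy number and renormalising converts this into the fraction
#' of cells, which is what the weights report. Optionally the
#' inter-initiation period tau is fitted by a grid search, refitting the
#' weights at every grid point.
#'
#' @param observed An [mfa_profile] (`source = "data"`), mean-scaled.
#' @param classes List of [cell_class] objects (the candidate basis).
#' @param map A [chrom_map].
#' @param params A [sim_params] (fork speed; `tau` used when `fit_tau =
#'   FALSE`).
#' @param config Optional [loess_config] applied to the basis (pass the one
#'   used on the observed profile).
#' @param fit_tau Grid-search tau? Default `FALSE`.
#' @param tau_grid Candidate tau values in minutes (default 15–40 by 1).
#' @param mask Optional logical vector of extra bins to exclude from the fit.
#' @return An object of class `mixture_model`: cell-fraction `weights`,
#'   DNA-share `weights_dna`, `rss`, fitted `tau`, `non_identifiable` flag.
#' @export
fit_mixture <- function(observed, classes, map, params = sim_params(),
                        config = NULL, fit_tau = FALSE, tau_grid = 15:40,
                        mask = NULL) {
  stopifnot(length(classes) >= 1)
  bin_size <- observed$bin_size
  schedules <- lapply(classes, function(cl)
    replication_schedule(map, cl, params, bin_size))

  use <- !is.na(observed$values)
  if (!is.null(mask)) use <- use & !mask
  if (sum(use) < length(classes) + 1) stop("too few unmasked bins to fit")

  fit_one <- function(tau) {
    basis <- basis_from_schedules(schedules, tau, config)
    A <- vapply(basis$profiles, function(p) p$values[use], numeric(sum(use)))
    A <- sweep(A, 2L, colMeans(A), "/")          # mean 1 on the fitted bins
    y <- observed$values[use]
    y <- y / mean(y)
    dup <- FALSE
    if (ncol(A) > 1) {
      for (i in 1:(ncol(A) - 1)) for (j in (i + 1):ncol(A))
        if (max(abs(A[, i] - A[, j])) < 1e-6) dup <- TRUE
    }
    x <- nnls_lh(A, y)
    rss <- sum((y - A %*% x)^2)
    mns <- vapply(basis$profiles, function(p) mean(p$values[use]) * 1, numeric(1))
    # basis profiles were globally mean-scaled; recover per-class copy-number
    # means on the fitted bins for the cell-fraction conversion
    raw_means <- basis$means * mns
    list(x = x, rss = rss, raw_means = raw_means, dup = dup,
         labels = basis$labels)
  }

  if (fit_tau) {
    fits <- lapply(tau_grid, fit_one)
    best <- which.min(vapply(fits, `[[`, numeric(1), "rss"))
    fit <- fits[[best]]
    tau <- tau_grid[best]
  } else {
    fit <- fit_one(params$tau)
    tau <- params$tau
  }
  if (fit$dup)
    warning("degenerate basis: two classes have identical model profiles; ",
            "weights are not identifiable")
  if (sum(fit$x) <= 0) stop("all fitted weights are zero")
  w_dna <- fit$x / sum(fit$x)
  w_cell <- w_dna / fit$raw_means
  w_cell <- w_cell / sum(w_cell)
  names(w_dna) <- names(w_cell) <- fit$labels
  structure(list(classes = classes, weights = w_cell, weights_dna = w_dna,
                 fit_rss = fit$rss, tau = tau,
                 non_identifiable = fit$dup),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("<mixture_model>\n")
  for (i in seq_along(x$weights))
    cat(sprintf("  %-20s %5.1f%% of cells (%5.1f%% of DNA)\n",
                names(x$weights)[i], 100 * x$weights[i], 100 * x$weights_dna[i]))
  cat(sprintf("  RSS %.4g, tau %g min%s\n", x$fit_rss, x$tau,
              if (x$non_identifiable) " [NON-IDENTIFIABLE]" else ""))
  invisible(x)
}
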