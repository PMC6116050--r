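#' Describe a gross chromosomal rearrangement
#'
#' An inversion or tandem duplication of the half-open segment
#' `[start_bp, end_bp)` given in reference coordinates. Segments wrapping the
#' origin of the coordinate system are not supported (neither of the studied
#' rearrangements wraps).
#'
#' @param kind `"inversion"` or `"duplication"`.
#' @param start_bp,end_bp Segment breakpoints (reference bp, half-open,
#'   `start_bp < end_bp`).
#' @param copies Tandem copy number for duplications (>= 2).
#' @return An object of class `rearrangement`.
#' @export
rearrangement <- function(kind = c("inversion", "duplication"),
                          start_bp, end_bp, copies = 2) {
  kind <- match.arg(kind)
  if (start_bp == end_bp) stop("zero-length rearrangement")
  if (start_bp > end_bp) stop("segments wrapping coordinate 0 are not supported")
  if (kind == "duplication" && copies < 2) stop("duplication needs copies >= 2")
  structure(list(kind = kind, start_bp = start_bp, end_bp = end_bp,
                 copies = if (kind == "duplication") as.integer(copies) else NA_integer_),
            class = "rearrangement")
}

#' @export
print.rearrangement <- function(x, ...) {
  cat(sprintf("<rearrangement> %s %s-%s (%s kb)%s\n", x$kind,
              format(x$start_bp, big.mark = ","), format(x$end_bp, big.mark = ","),
              round((x$end_bp - x$start_bp) / 1000),
              if (x$kind == "duplication") paste0(" x", x$copies) else ""))
  invisible(x)
}

reflect_point <- function(x, s, e) s + e - 1 - x
in_seg <- function(x, s, e) x >= s & x < e

#' Apply a rearrangement to a chromosome map
#'
#' Inversions reflect all contained features about the segment and reverse
#' their polarity: a ter site that blocked counter-clockwise forks blocks
#' clockwise forks afterwards ("flipped into permissive orientation" for the
#' fork it used to stop), and transcription directions reverse likewise.
#' Duplications repeat the segment in tandem, growing the chromosome by
#' `(copies - 1) * segment`; duplicated features get `.2`, `.3`, ... name
#' suffixes (duplicated origins are allowed but flagged with a message).
#' Features straddling a breakpoint are an error.
#'
#' @param map A [chrom_map].
#' @param r A [rearrangement].
#' @return The rearranged [chrom_map] (attribute `"rearrangement"` records
#'   `r`).
#' @export
apply_rearrangement <- function(map, r) {
  stopifnot(inherits(map, "chrom_map"), inherits(r, "rearrangement"))
  s <- r$start_bp; e <- r$end_bp
  L <- map$length_bp
  if (s < 0 || e > L) stop("breakpoints out of range")
  check_straddle <- function(a, b, what) {
    if (any((a < s & b > s) | (a < e & b > e)))
      stop("breakpoint falls inside ", what)
  }
  tf <- map$transcribed_features
  check_straddle(tf$start_bp, tf$end_bp, "a transcribed feature")
  ise <- map$is_elements
  check_straddle(ise$position_bp, ise$position_bp + ise$length_bp, "an IS element")

  if (r$kind == "inversion") {
    o <- map$origins
    o$position_bp <- ifelse(in_seg(o$position_bp, s, e),
                            reflect_point(o$position_bp, s, e), o$position_bp)
    t <- map$ter_sites
    flip <- in_seg(t$position_bp, s, e)
    t$position_bp[flip] <- reflect_point(t$position_bp[flip], s, e)
    t$blocks[flip] <- ifelse(t$blocks[flip] == "cw", "ccw", "cw")
    x <- tf
    fx <- in_seg(x$start_bp, s, e)
    ns <- s + e - x$end_bp[fx]; ne <- s + e - x$start_bp[fx]
    x$start_bp[fx] <- ns; x$end_bp[fx] <- ne
    x$direction[fx] <- ifelse(x$direction[fx] == "cw", "ccw", "cw")
    i <- ise
    fi <- in_seg(i$position_bp, s, e)
    i$position_bp[fi] <- s + e - (i$position_bp[fi] + i$length_bp[fi])
    out <- chrom_map(map$name, L, o, t, x, i)
  } else {
    seg <- e - s
    shift <- (r$copies - 1L) * seg
    dup_points <- function(df, poscol) {
      pos <- df[[poscol]]
      before <- df[pos < s, , drop = FALSE]
      inside <- df[in_seg(pos, s, e), , drop = FALSE]
      after <- df[pos >= e, , drop = FALSE]
      after[[poscol]] <- after[[poscol]] + shift
      copies <- lapply(seq_len(r$copies), function(k) {
        cp <- inside
        cp[[poscol]] <- cp[[poscol]] + (k - 1L) * seg
        if (k > 1 && nrow(cp)) cp$name <- paste0(cp$name, ".", k)
        cp
      })
      rbind(before, do.call(rbind, copies), after)
    }
    o <- dup_points(map$origins, "position_bp")
    if (nrow(o) > nrow(map$origins))
      message("duplication contains origin(s): ",
              paste(setdiff(o$name, map$origins$name), collapse = ", "))
    t <- dup_points(map$ter_sites, "position_bp")
    x <- tf
    xb <- x[x$start_bp < s, , drop = FALSE]
    xi <- x[in_seg(x$start_bp, s, e), , drop = FALSE]
    xa <- x[x$start_bp >= e, , drop = FALSE]
    xa$start_bp <- xa$start_bp + shift; xa$end_bp <- xa$end_bp + shift
    xc <- lapply(seq_len(r$copies), function(k) {
      cp <- xi
      cp$start_bp <- cp$start_bp + (k - 1L) * seg
      cp$end_bp <- cp$end_bp + (k - 1L) * seg
      if (k > 1 && nrow(cp)) cp$name <- paste0(cp$name, ".", k)
      cp
    })
    x <- rbind(xb, do.call(rbind, xc), xa)
    i <- dup_points(ise, "position_bp")
    out <- chrom_map(map$name, L + shift, o, t, x, i)
  }
  rownames(out$origins) <- rownames(out$ter_sites) <- NULL
  rownames(out$transcribed_features) <- rownames(out$is_elements) <- NULL
  attr(out, "rearrangement") <- r
  out
}

# shared bin-level projection; breakpoints must sit on the bin grid
seg_bins <- function(r, bin_size) {
  sb <- r$start_bp / bin_size
  eb <- r$end_bp / bin_size
  if (sb != round(sb) || eb != round(eb))
    stop("rearrangement breakpoints must align to the bin grid")
  list(sb = as.integer(sb), eb = as.integer(eb))
}

project_values <- function(values, r, bin_size, length_ref, inverse = FALSE) {
  g <- seg_bins(r, bin_size)
  if (r$kind == "inversion") {
    # reads from the inverted chromosome map back onto the reference with the
    # segment reversed; the operation is its own inverse
    idx <- (g$sb + 1L):g$eb
    values[idx] <- rev(values[idx])
    return(values)
  }
  seg <- g$eb - g$sb
  extra <- (r$copies - 1L) * seg
  n_ref <- n_bins(length_ref, bin_size)
  if (!inverse) {
    # rearranged (longer) -> reference: duplicated copies pile onto one locus
    if (length(values) != n_ref + extra) stop("length mismatch for duplication projection")
    head <- if (g$sb) values[1:g$sb] else numeric(0)
    copies <- sapply(seq_len(r$copies), function(k)
      values[(g$sb + (k - 1L) * seg + 1L):(g$sb + k * seg)])
    tail <- values[(g$sb + r$copies * seg + 1L):length(values)]
    c(head, rowSums(matrix(copies, nrow = seg)), tail)
  } else {
    # reference -> rearranged: split the pile-up evenly across copies
    if (length(values) != n_ref) stop("length mismatch for duplication projection")
    head <- if (g$sb) values[1:g$sb] else numeric(0)
    segv <- values[(g$sb + 1L):g$eb] / r$copies
    tail <- values[(g$eb + 1L):length(values)]
    c(head, rep(segv, r$copies), tail)
  }
}

#' Project a profile between rearranged and reference coordinates
#'
#' Models what read mapping does to a rearranged chromosome: reads from an
#' inverted segment map onto the reference with the segment reversed in
#' place, and reads from tandem-duplicated copies pile up on the single
#' reference copy (values summed). `inverse = TRUE` projects a
#' reference-coordinate profile onto the rearranged chromosome (for
#' inversions the operation is an involution; for duplications the pile-up is
#' split evenly across copies).
#'
#' @param profile An [mfa_profile] (on rearranged coordinates unless
#'   `inverse`).
#' @param r A [rearrangement] with bin-aligned breakpoints.
#' @param inverse Project reference -> rearranged instead.
#' @return An [mfa_profile] on the other coordinate system.
#' @export
project_profile <- function(profile, r, inverse = FALSE) {
  ref_len <- if (r$kind == "inversion") profile$length_bp
             else if (!inverse) profile$length_bp - (r$copies - 1L) * (r$end_bp - r$start_bp)
             else profile$length_bp
  vals <- project_values(profile$values, r, profile$bin_size, ref_len, inverse)
  out_len <- if (r$kind == "inversion") profile$length_bp
             else if (!inverse) ref_len
             else ref_len + (r$copies - 1L) * (r$end_bp - r$start_bp)
  mfa_profile(vals, profile$bin_size, out_len, source = profile$source,
              normalisation = paste0(profile$normalisation, "; projected ", r$kind))
}

#' @rdname project_profile
#' @param counts A [binned_counts] on rearranged coordinates.
#' @export
project_counts <- function(counts, r) {
  ref_len <- if (r$kind == "inversion") counts$length_bp
             else counts$length_bp - (r$copies - 1L) * (r$end_bp - r$start_bp)
  vals <- project_values(counts$counts, r, counts$bin_size, ref_len, inverse = FALSE)
  binned_counts(vals, counts$bin_size, ref_len, label = counts$label)
}

#' Profile continuity score at candidate breakpoints
#'
#' For each breakpoint, the squared difference between the medians of the two
#' flanking `flank`-bp windows, scaled by the local (median-detrended)
#' variance; summed over breakpoints. A continuous profile scores near the
#' noise floor (~the variance of a window median); a genuine coordinate
#' discontinuity scores far above it. Medians rather than means keep the
#' score robust to the rrn/ter depletion artifact.
#'
#' @param profile An [mfa_profile].
#' @param breakpoints Numeric vector of bp positions.
#' @param flank Flanking window width in bp (default 50000, >= one bin).
#' @return Non-negative score.
#' @export
continuity_score <- function(profile, breakpoints, flank = 50000) {
  y <- profile$values
  n <- length(y)
  b <- profile$bin_size
  if (flank < b) stop("flank must be at least one bin")
  fb <- max(2L, as.integer(round(flank / b)))
  yy <- c(y, y, y)
  sc <- vapply(breakpoints, function(p) {
    bd <- as.integer(round(pmod(p, profile$length_bp) / b))  # 0-based boundary
    l <- yy[(n + bd - fb + 1L):(n + bd)]
    r <- yy[(n + bd + 1L):(n + bd + fb)]
    ml <- stats::median(l, na.rm = TRUE); mr <- stats::median(r, na.rm = TRUE)
    vl <- stats::var(l - ml, na.rm = TRUE); vr <- stats::var(r - mr, na.rm = TRUE)
    (mr - ml)^2 / max((vl + vr) / 2, 1e-12)
  }, numeric(1))
  sum(sc)
}

#' Score a candidate rearrangement by restored continuity
#'
#' Computes the continuity score at the candidate's breakpoints before and
#' after applying the candidate's coordinate projection to the observed
#' profile. If the candidate is the rearrangement actually present in the
#' sequenced chromosome, the projection restores a continuous profile and
#' `score_after` collapses to the noise floor; wrong candidates leave (or
#' create) discontinuities.
#'
#' @param observed An [mfa_profile] in reference coordinates.
#' @param candidate A [rearrangement].
#' @param flank Flanking window width in bp.
#' @return List with `score_before`, `score_after` and their `ratio`.
#' @export
evaluate_candidate <- function(observed, candidate, flank = 50000) {
  bps <- c(candidate$start_bp, candidate$end_bp)
  before <- continuity_score(observed, bps, flank)
  if (candidate$kind == "inversion") {
    proj <- project_profile(observed, candidate)
    after_bps <- bps
  } else {
    proj <- project_profile(observed, candidate, inverse = TRUE)
    after_bps <- c(candidate$start_bp,
                   candidate$end_bp + (candidate$copies - 1L) *
                     (candidate$end_bp - candidate$start_bp))
  }
  after <- continuity_score(proj, after_bps, flank)
  list(score_before = before, score_after = after,
       ratio = after / max(before, 1e-12))
}

#' Enumerate IS-bounded rearrangement candidates
#'
#' Both inversions recovered in the study arose between homologous IS5
#' copies, so the default candidate search considers every ordered pair of
#' annotated IS elements.
#'
#' @param map A [chrom_map].
#' @param kind `"inversion"` or `"duplication"`.
#' @param bin_size Candidates are snapped to this bin grid.
#' @return List of [rearrangement] objects.
#' @export
enumerate_is_candidates <- function(map, kind = "inversion", bin_size = 1000) {
  pos <- sort(round(map$is_elements$position_bp / bin_size) * bin_size)
  if (length(pos) < 2) return(list())
  out <- list()
  for (i in seq_len(length(pos) - 1)) for (j in (i + 1):length(pos))
    out[[length(out) + 1L]] <- rearrangement(kind, pos[i], pos[j])
  out
}
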