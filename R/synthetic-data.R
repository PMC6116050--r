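#' Sequencing-noise specification
#'
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param depth Mean reads per bin (default 100, ~0.46 M reads per 4.64 Mb
#'   genome at 1 kb bins — deep enough for +/-0.05 mixture-weight recovery
#'   while staying desk-scale).
#' @param dispersion NB `size` parameter (NB -> Poisson as it grows).
#' @param seed Integer seed making every draw reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("poisson", "negative_binomial"),
                       depth = 100, dispersion = NULL, seed = 1) {
  family <- match.arg(family)
  stopifnot(depth > 0)
  if (family == "negative_binomial" &&
      (is.null(dispersion) || dispersion <= 0))
    stop("negative_binomial noise needs dispersion > 0")
  structure(list(family = family, depth = depth, dispersion = dispersion,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Protein-occupancy depletion artifact
#'
#' Column purification of genomic DNA under-recovers loci with tight or
#' frequent protein–DNA complexes (rrn operons, ter/Tus), depressing their
#' read counts; near rrnG this visibly lowers the adjacent oriX peak. The
#' generator emulates this by multiplying the expected depth by
#' `depletion_factor` inside the affected loci. The pipeline's counter-measure
#' is masking ([artifact_mask()]), not correction.
#'
#' @param map A [chrom_map]; default loci are all annotated rrn/GRP features
#'   and ter sites, each padded by `pad` bp.
#' @param depletion_factor Multiplier in (0, 1] (default 0.5; the real
#'   magnitude is not quantified, this is a documented placeholder).
#' @param pad Padding around each locus in bp (default 2000).
#' @param loci Optional explicit `data.frame(start_bp, end_bp)` overriding the
#'   default loci.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(map, depletion_factor = 0.5, pad = 2000, loci = NULL) {
  stopifnot(depletion_factor > 0, depletion_factor <= 1)
  if (is.null(loci)) {
    tf <- map$transcribed_features
    ts <- map$ter_sites
    loci <- rbind(
      if (nrow(tf)) data.frame(start_bp = tf$start_bp - pad, end_bp = tf$end_bp + pad),
      if (nrow(ts)) data.frame(start_bp = ts$position_bp - pad,
                               end_bp = ts$position_bp + pad))
    loci$start_bp <- pmod(loci$start_bp, map$length_bp)
    loci$end_bp <- pmin(loci$end_bp, loci$start_bp + map$length_bp)  # keep simple arcs
  }
  structure(list(loci = loci, depletion_factor = depletion_factor,
                 length_bp = map$length_bp), class = "artifact_spec")
}

# logical vector: bins whose midpoint falls in an artifact locus
artifact_spec_bins <- function(artifact, bin_size) {
  L <- artifact$length_bp
  mids <- bin_mids(L, bin_size)
  hit <- rep(FALSE, length(mids))
  for (k in seq_len(nrow(artifact$loci))) {
    s <- artifact$loci$start_bp[k]; e <- artifact$loci$end_bp[k]
    hit <- hit | if (e <= L) mids >= s & mids < e else mids >= s | mids < pmod(e, L)
  }
  hit
}

#' Flag artifact-prone bins of a map
#'
#' @param map A [chrom_map].
#' @param bin_size Bin width in bp.
#' @param pad Padding in bp around each rrn/ter locus.
#' @return Logical vector over bins, `TRUE` where the protein-occupancy
#'   depletion artifact is expected.
#' @export
artifact_mask <- function(map, bin_size, pad = 2000) {
  artifact_spec_bins(artifact_spec(map, pad = pad), bin_size)
}

#' Draw binned read counts from a model profile
#'
#' Each bin's count is Poisson (or negative binomial) with mean
#' `depth * profile_i`, times the artifact depletion factor inside artifact
#' loci. Reproducible given the seed in `noise`.
#'
#' @param profile An [mfa_profile] (model-derived expected copy number).
#' @param noise A [noise_spec].
#' @param artifact Optional [artifact_spec].
#' @param label Sample label.
#' @return A [binned_counts].
#' @export
simulate_counts <- function(profile, noise, artifact = NULL, label = "sample") {
  mu <- noise$depth * profile$values
  if (!is.null(artifact)) {
    hit <- artifact_spec_bins(artifact, profile$bin_size)
    if (length(hit) != length(mu)) stop("artifact binning mismatch")
    mu[hit] <- mu[hit] * artifact$depletion_factor
  }
  counts <- withr::with_seed(noise$seed, {
    if (noise$family == "poisson") stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = noise$dispersion)
  })
  binned_counts(counts, profile$bin_size, profile$length_bp, label = label)
}

#' Simulate a stationary-phase control library
#'
#' A non-replicating population has uniform copy number, so the control is a
#' flat-mean draw over the same bins.
#'
#' @param map A [chrom_map].
#' @param noise A [noise_spec].
#' @param bin_size Bin width in bp.
#' @return A [binned_counts] labelled `"stationary_control"`.
#' @export
simulate_control <- function(map, noise, bin_size = 1000) {
  flat <- mfa_profile(rep(1, n_bins(map$length_bp, bin_size)), bin_size,
                      map$length_bp, source = "model", normalisation = "flat")
  simulate_counts(flat, noise, artifact = NULL, label = "stationary_control")
}

scenario_names <- c("wild_type", "oriC_oriX", "oriC_oriX_dtus",
                    "doriC_oriX_inv820", "doriC_oriX_rpo_inv895",
                    "triple_origin_mix", "dup175")

#' Generate a named synthetic dataset bundle
#'
#' Builds the chromosome (applying the scenario's rearrangement where
#' relevant), simulates the class or mixture profile with the study's default
#' parameters (v = 1000 nt/s, tau = 25 min, depth 100 reads/bin, Poisson
#' noise, rrn/ter depletion artifact), projects rearranged-genome reads onto
#' reference coordinates, and returns counts plus a machine-readable truth
#' record. The one global seed fans out into independent substreams for the
#' sample and control draws.
#'
#' Scenarios: `wild_type` (oriC, tus+), `oriC_oriX` / `oriC_oriX_dtus`
#' (double origin, trap on/off), `doriC_oriX_inv820` (oriX only, 575–1394 kb
#' IS5 inversion flipping terA/D/E/H/I permissive: forks leave the terminus
#' and fuse near the oriX antipode), `doriC_oriX_rpo_inv895` (oriX
#' only, 1394–2288 kb inversion, trap on: the fork from oriX arrests at the
#' flipped terC after ~650 kb), `triple_origin_mix` (50% oriC+oriX,
#' 40% oriC+oriZ, 10% all three), `dup175` (oriX only, trap off, 175 kb
#' tandem duplication spanning rrnA and rrnB).
#'
#' @param name One of the scenario names above.
#' @param seed Integer master seed.
#' @param bin_size Bin width in bp.
#' @param depth Mean reads per bin.
#' @param params A [sim_params].
#' @param artifact Include the depletion artifact? Default `TRUE`.
#' @return List: `sample`, `control` ([binned_counts], reference
#'   coordinates), `profile_true` (noise-free reference-coordinate
#'   [mfa_profile]), `map_ref`, `map_sim`, and `truth` (scenario, seed,
#'   classes, weights, rearrangement breakpoints).
#' @export
generate_scenario <- function(name, seed = 1, bin_size = 1000, depth = 100,
                              params = sim_params(), artifact = TRUE) {
  if (!name %in% scenario_names)
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_names, collapse = ", "))
  map_ref <- mg1655_map()
  r <- NULL
  weights <- 1
  classes <- switch(
    name,
    wild_type = list(cell_class("oriC")),
    oriC_oriX = list(cell_class(c("oriC", "oriX"))),
    oriC_oriX_dtus = list(cell_class(c("oriC", "oriX"), tus_active = FALSE)),
    doriC_oriX_inv820 = {
      r <- rearrangement("inversion", 575000, 1394000)
      list(cell_class("oriX"))
    },
    doriC_oriX_rpo_inv895 = {
      r <- rearrangement("inversion", 1394000, 2288000)
      list(cell_class("oriX"))
    },
    triple_origin_mix = {
      weights <- c(0.5, 0.4, 0.1)
      list(cell_class(c("oriC", "oriX")), cell_class(c("oriC", "oriZ")),
           cell_class(c("oriC", "oriX", "oriZ")))
    },
    dup175 = {
      r <- rearrangement("duplication", 4030000, 4205000, copies = 2)
      list(cell_class("oriX", tus_active = FALSE))
    })
  map_sim <- if (is.null(r)) map_ref else apply_rearrangement(map_ref, r)

  profiles <- lapply(classes, function(cl)
    marker_frequency(replication_schedule(map_sim, cl, params, bin_size)))
  prof_sim <- if (length(profiles) == 1) profiles[[1]]
              else mixture_profile(profiles, weights)

  sub_seed <- function(k) as.integer((abs(seed) %% 1000000L) * 1000L + k)
  art <- if (artifact) artifact_spec(map_sim) else NULL
  sample <- simulate_counts(prof_sim, noise_spec(depth = depth, seed = sub_seed(1)),
                            artifact = art, label = name)
  if (!is.null(r)) sample <- project_counts(sample, r)
  control <- simulate_control(map_ref, noise_spec(depth = depth, seed = sub_seed(2)),
                              bin_size = bin_size)
  profile_true <- if (is.null(r)) prof_sim else {
    p <- project_profile(prof_sim, r)
    p
  }

  truth <- list(scenario = name, seed = seed, bin_size = bin_size, depth = depth,
                fork_speed = params$fork_speed, tau = params$tau,
                classes = lapply(classes, function(cl)
                  list(origins = cl$active_origins, tus_active = cl$tus_active)),
                weights = weights,
                rearrangement = if (is.null(r)) NULL else
                  list(kind = r$kind, start_bp = r$start_bp, end_bp = r$end_bp,
                       copies = r$copies))
  list(sample = sample, control = control, profile_true = profile_true,
       map_ref = map_ref, map_sim = map_sim, truth = truth)
}
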