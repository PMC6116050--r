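# Circular modulus that is always in [0, L).
pmod <- function(x, L) ((x %% L) + L) %% L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a circular chromosome map
#'
#' A `chrom_map` is the coordinate system every other module works on: a
#' circular chromosome of `length_bp` base pairs carrying annotated
#' replication origins, polar *ter* sites, highly transcribed features and IS
#' elements. Coordinates are 0-based; intervals are half-open `[start, end)`;
#' "clockwise" (cw) means increasing coordinate.
#'
#' @param name Chromosome name (used in BED/bedGraph output).
#' @param length_bp Chromosome length in bp (> 0).
#' @param origins `data.frame` with columns `name`, `position_bp`, `active`.
#' @param ter_sites `data.frame` with columns `name`, `position_bp`, `blocks`
#'   (`"cw"` or `"ccw"`: the travel direction of a fork that the site arrests;
#'   polarity belongs to the site, not the fork).
#' @param transcribed_features `data.frame` with columns `name`, `start_bp`,
#'   `end_bp`, `direction` (`"cw"`/`"ccw"`), `highly_transcribed`.
#' @param is_elements `data.frame` with columns `name`, `position_bp`,
#'   `length_bp`.
#' @return An object of class `chrom_map`.
#' @export
chrom_map <- function(name, length_bp,
                      origins = empty_origins(),
                      ter_sites = empty_ters(),
                      transcribed_features = empty_txn(),
                      is_elements = empty_is()) {
  map <- structure(
    list(name = name, length_bp = as.numeric(length_bp),
         origins = origins, ter_sites = ter_sites,
         transcribed_features = transcribed_features,
         is_elements = is_elements),
    class = "chrom_map")
  validate_chrom_map(map)
  map
}

empty_origins <- function() data.frame(name = character(), position_bp = numeric(),
                                       active = logical(), stringsAsFactors = FALSE)
empty_ters <- function() data.frame(name = character(), position_bp = numeric(),
                                    blocks = character(), stringsAsFactors = FALSE)
empty_txn <- function() data.frame(name = character(), start_bp = numeric(),
                                   end_bp = numeric(), direction = character(),
                                   highly_transcribed = logical(), stringsAsFactors = FALSE)
empty_is <- function() data.frame(name = character(), position_bp = numeric(),
                                  length_bp = numeric(), stringsAsFactors = FALSE)

validate_chrom_map <- function(map) {
  stopifnot(inherits(map, "chrom_map"))
  L <- map$length_bp
  if (!is.finite(L) || L <= 0) stop("length_bp must be > 0")
  in_range <- function(x) all(x >= 0 & x < L)
  if (!in_range(map$origins$position_bp)) stop("origin coordinates out of range [0, length_bp)")
  if (!in_range(map$ter_sites$position_bp)) stop("ter coordinates out of range [0, length_bp)")
  if (anyDuplicated(map$origins$name)) stop("origin names must be unique")
  if (anyDuplicated(map$ter_sites$name)) stop("ter site names must be unique")
  if (!all(map$ter_sites$blocks %in% c("cw", "ccw")))
    stop("ter `blocks` must be \"cw\" or \"ccw\"")
  tf <- map$transcribed_features
  if (nrow(tf)) {
    if (any(tf$start_bp == tf$end_bp)) stop("transcribed feature with start == end")
    if (!in_range(tf$start_bp) || !all(tf$end_bp > 0 & tf$end_bp <= L))
      stop("transcribed feature coordinates out of range")
    if (any(tf$highly_transcribed & !tf$direction %in% c("cw", "ccw")))
      stop("highly transcribed features must have a direction")
  }
  if (nrow(map$is_elements) && any(map$is_elements$length_bp <= 0))
    stop("IS element length must be > 0")
  invisible(map)
}

#' @export
print.chrom_map <- function(x, ...) {
  cat(sprintf("<chrom_map> %s: %s bp (circular)\n", x$name,
              format(x$length_bp, big.mark = ",")))
  cat(sprintf("  %d origins (%s), %d ter sites, %d transcribed features, %d IS elements\n",
              nrow(x$origins), paste(x$origins$name, collapse = ", "),
              nrow(x$ter_sites), nrow(x$transcribed_features), nrow(x$is_elements)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Default MG1655 fixture.
#
# The chromosome length is the U00096.3 reference (4,641,652 bp). Exact
# coordinates for oriC, ter A-J, the rrn operons and the ribosomal-protein
# gene cluster (GRP) are not part of the study being modelled; they are taken
# from the MG1655 reference annotation / primary literature (oriC midpoint of
# U00096.3 3,925,744..3,925,975; ter sites per the fork-trap literature; rrn
# operon spans per RegulonDB). Ectopic origins are placed on the standard
# genetic map: oriX in pheA at 59 min, oriY in malT at 76.5 min, oriZ
# lac-proximal at 7.4 min. Downstream tests treat these coordinates with
# +/- 5 kb tolerance.
# ---------------------------------------------------------------------------

MG1655_LENGTH <- 4641652

mg1655_tables <- function() {
  L <- MG1655_LENGTH
  origins <- data.frame(
    name = c("oriC", "oriX", "oriY", "oriZ"),
    position_bp = c(3925860,
                    round(59.0 / 100 * L),   # pheA, 59 min
                    round(76.5 / 100 * L),   # malT, 76.5 min
                    round(7.4 / 100 * L)),   # lac-proximal, 7.4 min
    active = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  # Polarity: the left-flank sites A, D, E, H, I arrest counter-clockwise
  # forks (they are passed by the clockwise fork entering the terminus); the
  # right-flank sites C, B, F, G, J arrest clockwise forks. The innermost
  # pair terA/terC faces the terminus from opposite sides: forks enter the
  # trap but cannot leave. terJ is the outermost right-flank site; its exact
  # coordinate is the least certain of the ten (see package vignette).
  ter <- data.frame(
    name = paste0("ter", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")),
    position_bp = c(1341427, 1682002, 1608788, 1278898, 1245961,
                    2312906, 2391360, 583532, 1096904, 2520000),
    blocks = c("ccw", "cw", "cw", "ccw", "ccw", "cw", "cw", "ccw", "ccw", "cw"),
    stringsAsFactors = FALSE)
  txn <- data.frame(
    name = c("rrnA", "rrnB", "rrnC", "rrnD", "rrnE", "rrnG", "rrnH", "GRP"),
    start_bp = c(4035153, 4166659, 3941808, 3423194, 4208147, 2729616, 223771, 3436000),
    end_bp   = c(4040906, 4172057, 3947213, 3428772, 4213594, 2735184, 229278, 3467000),
    direction = c("cw", "cw", "cw", "ccw", "cw", "ccw", "cw", "ccw"),
    highly_transcribed = TRUE,
    stringsAsFactors = FALSE)
  ise <- data.frame(
    name = c("IS5_575", "IS5_1394", "IS5_2288"),
    position_bp = c(575000, 1394000, 2288000),
    length_bp = 1195,
    stringsAsFactors = FALSE)
  list(origins = origins, ter = ter, txn = txn, ise = ise)
}

#' Default MG1655 chromosome map
#'
#' Builds the bundled *E. coli* K-12 MG1655 fixture: the 4,641,652 bp circular
#' chromosome with the native origin `oriC`, the ectopic origins `oriX`
#' (pheA, 59 min), `oriY` (malT, 76.5 min; inactive by default — the
#' integration could never be recovered intact) and `oriZ` (lac-proximal,
#' 7.4 min), the ten primary *ter* sites A–J in wild-type orientation, the
#' seven rrn operons (A–E, G, H) plus the ribosomal-protein gene cluster
#' (GRP), and the three IS5 elements at 575, 1394 and 2288 kb between which
#' the studied inversions arise.
#'
#' @return A [chrom_map].
#' @examples
#' m <- mg1655_map()
#' nrow(m$ter_sites)  # 10
#' @export
mg1655_map <- function() {
  tb <- mg1655_tables()
  chrom_map("MG1655", MG1655_LENGTH, origins = tb$origins, ter_sites = tb$ter,
            transcribed_features = tb$txn, is_elements = tb$ise)
}

#' Convert genetic-map minutes to bp
#'
#' The standard *E. coli* genetic map runs 0–100 minutes around the circle;
#' the conversion is linear (1 min = length/100).
#'
#' @param map A [chrom_map].
#' @param minutes Position in minutes, `0 <= minutes < 100`.
#' @return Integer-valued bp coordinate.
#' @export
minutes_to_bp <- function(map, minutes) {
  if (any(minutes < 0 | minutes >= 100)) stop("minutes must be in [0, 100)")
  pmod(round(minutes / 100 * map$length_bp), map$length_bp)
}

#' Directed arc distance on the circle
#'
#' Distance from `a` to `b` travelling only clockwise (increasing coordinate)
#' or only counter-clockwise. For `a != b`,
#' `arc_distance(a,b,"cw") + arc_distance(a,b,"ccw") == length_bp`.
#'
#' @param map A [chrom_map].
#' @param a,b Coordinates in bp.
#' @param direction `"cw"` or `"ccw"`.
#' @return Non-negative distance in bp (vectorised over `a`/`b`).
#' @export
arc_distance <- function(map, a, b, direction = c("cw", "ccw")) {
  direction <- match.arg(direction)
  L <- map$length_bp
  if (any(pmod(a, L) != a) || any(pmod(b, L) != b)) stop("coordinates out of range")
  if (direction == "cw") pmod(b - a, L) else pmod(a - b, L)
}

#' Midpoint of a circular arc
#'
#' Returns the coordinate equidistant from `a` and `b` along the arc that
#' contains `through` (there are two arcs between any two points of a circle;
#' `through` selects one). With `a == b` the "arc" is the whole circle and the
#' midpoint is the antipode of `a`.
#'
#' @param map A [chrom_map].
#' @param a,b Arc end coordinates (bp).
#' @param through A coordinate strictly inside the chosen arc.
#' @return Integer-valued bp coordinate.
#' @export
arc_midpoint <- function(map, a, b, through) {
  L <- map$length_bp
  if (through == a || through == b) stop("`through` must not coincide with an endpoint")
  # floor keeps the operation exactly equivariant under integer rotations
  if (a == b) return(pmod(floor(a + L / 2), L))
  d_cw <- pmod(b - a, L)
  d_thr <- pmod(through - a, L)
  mid <- if (d_thr > 0 && d_thr < d_cw) a + d_cw / 2 else b + pmod(a - b, L) / 2
  pmod(floor(mid), L)
}

# ---------------------------------------------------------------------------
# Annotation I/O: BED6-like text. The name column carries the feature type as
# "<type>:<name>" (type in origin/ter/txn/is); strand encodes direction or
# blocked direction ("+" = cw, "-" = ccw); score carries the active /
# highly_transcribed flag (1/0) or the IS length.
# ---------------------------------------------------------------------------

strand_of <- function(dir) ifelse(dir == "cw", "+", "-")
dir_of <- function(strand) ifelse(strand == "+", "cw", "ccw")

#' Write a chromosome map as BED6-like text
#'
#' @param map A [chrom_map].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map_bed <- function(map, path) {
  rows <- list()
  o <- map$origins
  if (nrow(o)) rows$o <- data.frame(chrom = map$name, start = o$position_bp,
                                    end = o$position_bp + 1,
                                    name = paste0("origin:", o$name),
                                    score = as.integer(o$active), strand = "+")
  t <- map$ter_sites
  if (nrow(t)) rows$t <- data.frame(chrom = map$name, start = t$position_bp,
                                    end = t$position_bp + 1,
                                    name = paste0("ter:", t$name),
                                    score = 0L, strand = strand_of(t$blocks))
  x <- map$transcribed_features
  if (nrow(x)) rows$x <- data.frame(chrom = map$name, start = x$start_bp,
                                    end = x$end_bp, name = paste0("txn:", x$name),
                                    score = as.integer(x$highly_transcribed),
                                    strand = strand_of(x$direction))
  i <- map$is_elements
  if (nrow(i)) rows$i <- data.frame(chrom = map$name, start = i$position_bp,
                                    end = i$position_bp + i$length_bp,
                                    name = paste0("is:", i$name),
                                    score = i$length_bp, strand = "+")
  bed <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# forktrap map: %s length_bp=%d", map$name,
                     as.integer(map$length_bp)), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome map from BED6-like text written by [write_map_bed()]
#'
#' @param path Input file.
#' @param length_bp Chromosome length; if `NULL`, taken from the header line.
#' @return A [chrom_map].
#' @export
read_map_bed <- function(path, length_bp = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(length_bp)) {
    m <- regmatches(first, regexpr("length_bp=[0-9]+", first))
    if (!length(m)) stop("no length_bp header in ", path, " and none supplied")
    length_bp <- as.numeric(sub("length_bp=", "", m))
  }
  bed <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           stringsAsFactors = FALSE)
  typ <- sub(":.*$", "", bed$name)
  nm <- sub("^[a-z]+:", "", bed$name)
  pick <- function(t) bed[typ == t, , drop = FALSE]
  o <- pick("origin"); t <- pick("ter"); x <- pick("txn"); i <- pick("is")
  chrom_map(
    name = bed$chrom[1], length_bp = length_bp,
    origins = data.frame(name = nm[typ == "origin"], position_bp = o$start,
                         active = o$score == 1, stringsAsFactors = FALSE),
    ter_sites = data.frame(name = nm[typ == "ter"], position_bp = t$start,
                           blocks = dir_of(t$strand), stringsAsFactors = FALSE),
    transcribed_features = data.frame(name = nm[typ == "txn"], start_bp = x$start,
                                      end_bp = x$end, direction = dir_of(x$strand),
                                      highly_transcribed = x$score == 1,
                                      stringsAsFactors = FALSE),
    is_elements = data.frame(name = nm[typ == "is"], position_bp = i$start,
                             length_bp = i$end - i$start, stringsAsFactors = FALSE))
}

# bin helpers shared by all modules -----------------------------------------

n_bins <- function(length_bp, bin_size) as.integer(ceiling(length_bp / bin_size))

bin_mids <- function(length_bp, bin_size) {
  n <- n_bins(length_bp, bin_size)
  starts <- (seq_len(n) - 1) * bin_size
  ends <- pmin(starts + bin_size, length_bp)
  (starts + ends) / 2
}

bin_index <- function(pos, bin_size, length_bp) {
  pmin(floor(pmod(pos, length_bp) / bin_size), n_bins(length_bp, bin_size) - 1L) + 1L
}
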