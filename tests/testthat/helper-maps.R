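# fixtures built in code: toy chromosomes and a random-map generator used by
# the property-style suites

toy_map <- function(L = 200000, origins = c(o1 = 10000),
                    ters = NULL, txn = NULL) {
  odf <- data.frame(name = names(origins), position_bp = unname(origins),
                    active = TRUE, stringsAsFactors = FALSE)
  tdf <- if (is.null(ters)) forktrap:::empty_ters() else ters
  xdf <- if (is.null(txn)) forktrap:::empty_txn() else txn
  chrom_map("toy", L, odf, tdf, xdf, forktrap:::empty_is())
}

# two origins 1000 kb apart on a 2.4 Mb circle (closed-form fusion checks)
two_origin_map <- function() toy_map(L = 2400000,
                                     origins = c(oA = 200000, oB = 1200000))

random_map <- function(seed) {
  set.seed(seed)
  L <- sample(80:200, 1) * 1000
  b <- 1000
  n_ori <- sample(1:3, 1)
  ob <- sample(0:(L / b - 1), n_ori)  # distinct bins, engines require it
  origins <- data.frame(name = paste0("o", seq_len(n_ori)),
                        position_bp = ob * b + sample(0:(b - 1), n_ori, replace = TRUE),
                        active = TRUE, stringsAsFactors = FALSE)
  n_ter <- sample(0:4, 1)
  ter <- if (n_ter) data.frame(name = paste0("t", seq_len(n_ter)),
                               position_bp = sample(0:(L - 1), n_ter),
                               blocks = sample(c("cw", "ccw"), n_ter, replace = TRUE),
                               stringsAsFactors = FALSE)
         else forktrap:::empty_ters()
  n_tf <- sample(0:2, 1)
  tf <- if (n_tf) {
    s <- sample(0:(L - 20000), n_tf)
    data.frame(name = paste0("g", seq_len(n_tf)), start_bp = s,
               end_bp = s + sample(3000:15000, n_tf),
               direction = sample(c("cw", "ccw"), n_tf, replace = TRUE),
               highly_transcribed = TRUE, stringsAsFactors = FALSE)
  } else forktrap:::empty_txn()
  chrom_map("rand", L, origins, ter, tf, forktrap:::empty_is())
}

# brute-force per-point circular weighted polynomial regression (independent
# LOESS oracle; deliberately naive)
loess_oracle <- function(y, span, degree = 2) {
  n <- length(y)
  k <- max(ceiling(span * n), degree + 2)
  if (k %% 2 == 0) k <- k + 1
  w <- (k - 1) / 2
  offs <- -w:w
  wt <- (1 - (abs(offs) / w)^3)^3
  vapply(seq_len(n), function(i) {
    idx <- ((i - 1 + offs) %% n) + 1
    keep <- wt > 0 & !is.na(y[idx])
    df <- data.frame(yy = y[idx][keep], x = offs[keep])
    fit <- if (degree == 2) stats::lm(yy ~ x + I(x^2), df, weights = wt[keep])
           else stats::lm(yy ~ x, df, weights = wt[keep])
    unname(stats::coef(fit)[1])
  }, numeric(1))
}
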