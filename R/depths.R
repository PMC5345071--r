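#' ddRAD-style read-depth model
#'
#' Per-cell (locus x individual) sequencing depths are negative binomial
#' around a configured mean (overdispersion is typical of reduced-
#' representation libraries); ALT-supporting reads are binomial within each
#' cell with success probability `(d/6) * (1 - eps) + (1 - d/6) * eps` for
#' true ALT dosage `d`, so the expected ALT read fraction is d/6 distorted
#' toward the center by the per-read error rate `eps`. Whole cells are
#' dropped as missing at a fixed rate, emulating failed genotyping calls.
#'
#' @param depth_mean mean quality read depth per data point (default 40).
#' @param depth_dispersion negative-binomial size parameter; larger is
#'   closer to Poisson.
#' @param error_rate per-read base miscall rate `eps` in `[0, 0.5)`.
#'   Default 0.002, the order of magnitude of filtered short-read data.
#' @param missing_rate probability a cell is reported missing
#'   (default 0.022, a typical ddRAD missing fraction after filtering).
#' @return an object of class `read_depth_model`.
#' @export
read_depth_model <- function(depth_mean = 40, depth_dispersion = 5,
                             error_rate = 0.002, missing_rate = 0.022) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop("depth_mean and depth_dispersion must be positive")
  structure(list(depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate, missing_rate = missing_rate),
            class = "read_depth_model")
}

#' Simulate per-genotype read depths from true dosages
#'
#' Produces the observable layer of the pipeline: a depth matrix of total
#' (DP), reference-supporting (RD) and variant-supporting (AD) read counts
#' per locus and individual, plus a missing mask.
#'
#' @param dosage integer matrix (loci x individuals) of true ALT dosages
#'   0-6, e.g. `simulate_s1_population()$dosage`.
#' @param model a `read_depth_model`.
#' @param seed integer seed.
#' @return an object of class `depth_matrix`: list of integer matrices
#'   `dp`, `rd`, `ad` and logical `missing`, all loci x individuals with
#'   the dimnames of `dosage`.
#' @export
simulate_read_depths <- function(dosage, model = read_depth_model(),
                                 seed = 1) {
  stopifnot(inherits(model, "read_depth_model"), is.matrix(dosage))
  if (any(dosage < 0 | dosage > 6)) stop("dosage entries must be in 0-6")
  set.seed(derive_seed(seed, 4))
  n <- length(dosage)
  dp <- matrix(stats::rnbinom(n, mu = model$depth_mean,
                              size = model$depth_dispersion),
               nrow(dosage), ncol(dosage))
  eps <- model$error_rate
  p_alt <- (dosage / 6) * (1 - eps) + (1 - dosage / 6) * eps
  ad <- matrix(stats::rbinom(n, dp, p_alt), nrow(dosage), ncol(dosage))
  rd <- dp - ad
  miss <- matrix(stats::runif(n) < model$missing_rate,
                 nrow(dosage), ncol(dosage))
  dimnames(dp) <- dimnames(rd) <- dimnames(ad) <- dimnames(miss) <-
    dimnames(dosage)
  new_depth_matrix(dp, rd, ad, miss)
}

new_depth_matrix <- function(dp, rd, ad, missing) {
  stopifnot(all(dim(dp) == dim(rd)), all(dim(dp) == dim(ad)),
            all(dim(dp) == dim(missing)))
  structure(list(dp = dp, rd = rd, ad = ad, missing = missing),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("depth_matrix: %d loci x %d individuals (%.1f%% missing)\n",
              nrow(x$dp), ncol(x$dp), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.depth_matrix <- function(x) dim(x$dp)

# subset a depth_matrix by locus index
subset_loci <- function(dm, idx) {
  new_depth_matrix(dm$dp[idx, , drop = FALSE], dm$rd[idx, , drop = FALSE],
                   dm$ad[idx, , drop = FALSE],
                   dm$missing[idx, , drop = FALSE])
}

#' Flip a fraction of dichotomized calls (validation utility)
#'
#' Injects genotyping errors at the call level: each non-missing call is
#' flipped (homozygous <-> not-homozygous) independently with probability
#' `rate`. Used to study how call errors inflate map length and how well
#' the map-based correction recovers them.
#'
#' @param calls integer matrix of dichotomized calls (0 = homozygous,
#'   1 = not-homozygous, NA = missing).
#' @param rate per-call flip probability.
#' @param seed integer seed.
#' @return list with `calls` (the corrupted matrix) and `flipped`
#'   (logical matrix marking injected errors).
#' @export
inject_call_errors <- function(calls, rate, seed = 1) {
  stopifnot(is.matrix(calls), rate >= 0, rate <= 1)
  set.seed(derive_seed(seed, 5))
  flip <- matrix(stats::runif(length(calls)) < rate,
                 nrow(calls), ncol(calls)) & !is.na(calls)
  out <- calls
  out[flip] <- 1L - out[flip]
  list(calls = out, flipped = flip)
}
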