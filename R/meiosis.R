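#' Autohexaploid meiosis model
#'
#' Parameters of gamete formation in an autohexaploid under random bivalent
#' pairing: at every meiosis the six homologs of each chromosome form three
#' disjoint bivalents drawn uniformly from the 15 possible pairings; within
#' a bivalent the transmitted chromatid is a mosaic of the two partners,
#' switching strand at crossover points whose count is Poisson with mean
#' `xo_rate * length_cM / 100` and whose positions are uniform on the cM
#' axis (no interference). Multivalents and double reduction are excluded:
#' every gamete receives exactly three homolog mosaics per chromosome, one
#' per bivalent, and each single homolog is transmitted with marginal
#' probability 1/2.
#'
#' @param xo_rate crossover intensity multiplier (1 = one expected
#'   crossover per 100 cM on the transmitted chromatid, i.e. distances on
#'   the simulated cM axis are genetic distances).
#' @return an object of class `meiosis_model`.
#' @export
meiosis_model <- function(xo_rate = 1) {
  stopifnot(xo_rate >= 0)
  structure(list(xo_rate = xo_rate, pairing = "random-bivalent",
                 double_reduction = 0), class = "meiosis_model")
}

# One gamete for one chromosome: 3 bivalents from a uniform pairing of the
# six homologs; returns a matrix (n_loci x 3) of the homolog id each
# bivalent's transmitted chromatid carries at each locus position.
gamete_chromosome <- function(pos_cM, length_cM, xo_rate) {
  perm <- sample.int(6L)
  hom_at <- matrix(0L, length(pos_cM), 3L)
  for (b in 1:3) {
    pair <- perm[c(2L * b - 1L, 2L * b)]
    n_xo <- stats::rpois(1L, xo_rate * length_cM / 100)
    switches <- if (n_xo > 0) sort(stats::runif(n_xo, 0, length_cM)) else numeric(0)
    n_sw <- findInterval(pos_cM, switches)
    start <- sample.int(2L, 1L)
    hom_at[, b] <- pair[((n_sw + start - 1L) %% 2L) + 1L]
  }
  hom_at
}

#' Simulate gametes of a founder (truth-level, for model checking)
#'
#' Draws independent gametes and reports, per locus, which three homologs
#' the gamete carries and the resulting ALT dosage (0-3). Mainly useful to
#' verify transmission genetics; population simulation fuses two such
#' gametes per individual.
#'
#' @param founder a `founder_genome`.
#' @param n_gametes number of gametes.
#' @param meiosis a `meiosis_model`.
#' @param seed integer seed.
#' @return list with `alt_dosage` (loci x gametes integer matrix) and
#'   `homologs` (loci x 3 x gametes integer array of carried homolog ids).
#' @export
simulate_gametes <- function(founder, n_gametes, meiosis = meiosis_model(),
                             seed = 1) {
  stopifnot(inherits(founder, "founder_genome"), n_gametes >= 1)
  set.seed(derive_seed(seed, 2))
  loci <- founder$loci
  n_loci <- nrow(loci)
  alt <- matrix(0L, n_loci, n_gametes, dimnames = list(loci$locus, NULL))
  homs <- array(0L, c(n_loci, 3L, n_gametes))
  by_chrom <- split(seq_len(n_loci), loci$chrom)
  for (g in seq_len(n_gametes)) {
    for (cc in seq_along(by_chrom)) {
      li <- by_chrom[[cc]]
      len <- founder$chromosomes$length_cM[cc]
      hom_at <- gamete_chromosome(loci$pos_cM[li], len, meiosis$xo_rate)
      homs[li, , g] <- hom_at
      carr <- founder$carriers[li, , drop = FALSE]
      idx <- seq_along(li)
      alt[li, g] <- carr[cbind(idx, hom_at[, 1])] +
        carr[cbind(idx, hom_at[, 2])] + carr[cbind(idx, hom_at[, 3])]
    }
  }
  list(alt_dosage = alt, homologs = homs)
}

#' Simulate an S1 population by selfing the founder
#'
#' Each individual is the fusion of two independent gametes of the same
#' founder. At a simplex locus the progeny ALT-dosage distribution is
#' 0:1:2 = 1:2:1 in expectation, so the homozygous-REF class has expected
#' frequency 1/4 — the 1:3 dichotomous ratio the mapping pipeline tests.
#'
#' @param founder a `founder_genome`.
#' @param n_individuals population size (default 142).
#' @param meiosis a `meiosis_model`.
#' @param seed integer seed.
#' @return an object of class `s1_truth`: list with `dosage` (loci x
#'   individuals integer matrix of true ALT dosages 0-6), `gamete_alt`
#'   (loci x individuals x 2 array of per-gamete ALT counts 0-3), `founder`
#'   and `params`.
#' @examples
#' fg <- simulate_founder(n_chrom = 1, loci_per_homolog = 4, seed = 1)
#' pop <- simulate_s1_population(fg, n_individuals = 50, seed = 2)
#' mean(pop$dosage[1, ] == 0)  # near 0.25 for a simplex locus
#' @export
simulate_s1_population <- function(founder, n_individuals = 142,
                                   meiosis = meiosis_model(), seed = 1) {
  stopifnot(inherits(founder, "founder_genome"))
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  set.seed(derive_seed(seed, 3))
  loci <- founder$loci
  n_loci <- nrow(loci)
  by_chrom <- split(seq_len(n_loci), loci$chrom)
  lens <- founder$chromosomes$length_cM
  carr <- founder$carriers

  gam <- array(0L, c(n_loci, n_individuals, 2L))
  for (ind in seq_len(n_individuals)) {
    for (g in 1:2) {
      for (cc in seq_along(by_chrom)) {
        li <- by_chrom[[cc]]
        hom_at <- gamete_chromosome(loci$pos_cM[li], lens[cc], meiosis$xo_rate)
        idx <- seq_along(li)
        cl <- carr[li, , drop = FALSE]
        gam[li, ind, g] <- cl[cbind(idx, hom_at[, 1])] +
          cl[cbind(idx, hom_at[, 2])] + cl[cbind(idx, hom_at[, 3])]
      }
    }
  }
  dosage <- gam[, , 1] + gam[, , 2]
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = n_loci)
  dimnames(dosage) <- list(loci$locus,
                           sprintf("S1_%03d", seq_len(n_individuals)))
  structure(list(dosage = dosage, gamete_alt = gam, founder = founder,
                 params = list(n_individuals = n_individuals, seed = seed,
                               xo_rate = meiosis$xo_rate)),
            class = "s1_truth")
}

#' @export
print.s1_truth <- function(x, ...) {
  cat(sprintf("S1 population truth: %d loci x %d individuals\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}
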