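#' Compute ALT allele frequencies
#'
#' The ALT allele frequency (AAF) of a locus is the fraction of reads
#' supporting the non-reference allele. In a hexaploid whose reads are
#' mapped onto a haploid relative, a locus where d of the six homologs
#' carry ALT has expected AAF d/6, so pooled AAFs over the population
#' concentrate at 1/6 ... 6/6 — the peak structure the dosage classifier
#' exploits. The pooled AAF of a locus is
#' `sum(AD) / sum(RD + AD)` over its non-missing cells; per-cell AAFs use
#' the same ratio within a cell.
#'
#' @param depths a `depth_matrix` (after filtering).
#' @param denominator `"ref_alt"` (default) divides ALT reads by
#'   `RD + AD`; `"dp"` divides by the caller's DP field instead. The two
#'   differ when DP counts reads supporting neither reported allele.
#' @return an object of class `aaf_profile`: list with `pooled` (named
#'   numeric per locus; `NaN` where a locus has no informative reads),
#'   `per_cell` (numeric matrix, `NaN` where a cell has no reads or is
#'   missing), `ref_total`, `alt_total` (pooled read counts per locus).
#' @examples
#' # the pooled AAF of a locus with 17391 REF and 5236 ALT reads is 0.231
#' 5236 / (17391 + 5236)
#' @export
compute_aaf <- function(depths, denominator = c("ref_alt", "dp")) {
  stopifnot(inherits(depths, "depth_matrix"))
  denominator <- match.arg(denominator)
  ad <- depths$ad; rd <- depths$rd
  ad[depths$missing] <- NA; rd[depths$missing] <- NA
  dp <- depths$dp; dp[depths$missing] <- NA
  alt_total <- rowSums(ad, na.rm = TRUE)
  ref_total <- rowSums(rd, na.rm = TRUE)
  den <- if (denominator == "ref_alt") ref_total + alt_total
         else rowSums(dp, na.rm = TRUE)
  pooled <- ifelse(den > 0, alt_total / den, NaN)
  cell_den <- if (denominator == "ref_alt") rd + ad else dp
  per_cell <- ifelse(!is.na(cell_den) & cell_den > 0, ad / cell_den, NaN)
  names(pooled) <- rownames(depths$dp)
  structure(list(pooled = pooled, per_cell = per_cell,
                 ref_total = ref_total, alt_total = alt_total,
                 denominator = denominator),
            class = "aaf_profile")
}

#' Double-simplex AAF selection windows
#'
#' Pooled-AAF windows isolating double-simplex loci: a simplex-REF locus
#' (one ALT-carrying homolog; genotype class `AAAAAa x AAAAAa` under
#' selfing) has expected pooled AAF 1/6, a simplex-ALT locus
#' (`Aaaaaa x Aaaaaa`) 5/6. The windows are half-open on the right and
#' placed midway to the neighbouring dosage peaks: `[0.0833, 0.2500)` and
#' `[0.7500, 0.9167)`.
#'
#' @param ds_ref_window numeric length-2, `[low, high)` for simplex-REF.
#' @param ds_alt_window numeric length-2, `[low, high)` for simplex-ALT.
#' @return an object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(ds_ref_window = c(0.0833, 0.2500),
                                 ds_alt_window = c(0.7500, 0.9167)) {
  chk <- function(w) length(w) == 2 && w[1] < w[2] && w[1] >= 0 && w[2] <= 1
  if (!chk(ds_ref_window) || !chk(ds_alt_window))
    stop("windows must be increasing length-2 vectors within [0, 1]")
  if (ds_ref_window[2] > ds_alt_window[1])
    stop("selection windows must be disjoint")
  structure(list(ds_ref_window = ds_ref_window,
                 ds_alt_window = ds_alt_window),
            class = "selection_thresholds")
}

#' Select double-simplex candidate loci from pooled AAFs
#'
#' Loci whose pooled AAF falls in the simplex-REF window are labelled
#' `"ds_ref"`, those in the simplex-ALT window `"ds_alt"`; all other loci
#' (duplex, triplex and their mirror classes, plus monomorphic-ALT loci at
#' AAF 1.0, which do not segregate) are discarded.
#'
#' @param aaf an `aaf_profile`.
#' @param thresholds a `selection_thresholds`.
#' @return data.frame with columns `locus`, `index` (row in the input),
#'   `class` (`"ds_ref"`/`"ds_alt"`), `aaf`.
#' @export
select_double_simplex <- function(aaf, thresholds = selection_thresholds()) {
  stopifnot(inherits(aaf, "aaf_profile"),
            inherits(thresholds, "selection_thresholds"))
  p <- aaf$pooled
  wr <- thresholds$ds_ref_window
  wa <- thresholds$ds_alt_window
  is_ref <- !is.na(p) & p >= wr[1] & p < wr[2]
  is_alt <- !is.na(p) & p >= wa[1] & p < wa[2]
  idx <- which(is_ref | is_alt)
  data.frame(locus = names(p)[idx] %||% as.character(idx), index = idx,
             class = ifelse(is_ref[idx], "ds_ref", "ds_alt"),
             aaf = unname(p[idx]), stringsAsFactors = FALSE)
}

#' Dichotomize individual genotypes at double-simplex loci
#'
#' Read depths in one individual cannot reliably separate dosage 1 from
#' dosage 2 (AAF 1/6 vs 2/6), so genotypes are collapsed into a dominant-
#' like dichotomy. For a `ds_ref` locus an individual with per-cell AAF of
#' exactly 0 is homozygous REF and anything above 0 is "not homozygous";
#' for a `ds_alt` locus, AAF exactly 1 is homozygous ALT, below 1 "not
#' homozygous". Both classes then segregate 1:3
#' (homozygous : not-homozygous) in S1 progeny.
#'
#' @param depths a `depth_matrix` restricted (or not) to selected loci.
#' @param class character vector per locus, `"ds_ref"` or `"ds_alt"`.
#' @param tolerance reads of the minority allele tolerated while still
#'   calling a cell homozygous (default 0, the literal AAF = 0 / 1 rule;
#'   raise to absorb rare sequencing errors at high depth).
#' @return integer matrix (loci x individuals): 0 = homozygous,
#'   1 = not-homozygous, NA = missing (masked cell or no reads).
#' @export
dichotomize <- function(depths, class, tolerance = 0) {
  stopifnot(inherits(depths, "depth_matrix"),
            length(class) == nrow(depths$dp),
            all(class %in% c("ds_ref", "ds_alt")), tolerance >= 0)
  minority <- depths$ad
  alt_rows <- class == "ds_alt"
  minority[alt_rows, ] <- depths$rd[alt_rows, , drop = FALSE]
  calls <- ifelse(minority <= tolerance, 0L, 1L)
  calls[depths$missing | (depths$rd + depths$ad) == 0] <- NA_integer_
  dimnames(calls) <- dimnames(depths$dp)
  calls
}

#' Chi-square test of the 1:3 double-simplex segregation ratio
#'
#' Tests each marker's homozygous : not-homozygous counts against the
#' expected 1:3 S1 ratio with a plain (uncorrected) one-degree-of-freedom
#' chi-square test; markers are kept when `p >= alpha` (default 1%), i.e.
#' when the observed segregation is compatible with double-simplex
#' inheritance.
#'
#' @param calls integer matrix from [dichotomize()].
#' @param alpha significance level below which a marker is dropped.
#' @return data.frame per marker: `locus`, `n_homo`, `n_nothomo`,
#'   `n_missing`, `chi2`, `p`, `keep` (FALSE for distorted markers;
#'   markers with no informative calls are dropped with `NA` statistics).
#' @export
chi_square_1_3 <- function(calls, alpha = 0.01) {
  stopifnot(is.matrix(calls), alpha >= 0, alpha <= 1)
  n_homo <- rowSums(calls == 0L, na.rm = TRUE)
  n_not <- rowSums(calls == 1L, na.rm = TRUE)
  n_miss <- rowSums(is.na(calls))
  n <- n_homo + n_not
  e_h <- n / 4; e_n <- 3 * n / 4
  chi2 <- ifelse(n > 0, (n_homo - e_h)^2 / e_h + (n_not - e_n)^2 / e_n, NA)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(locus = rownames(calls) %||% as.character(seq_len(nrow(calls))),
             n_homo = n_homo, n_nothomo = n_not, n_missing = n_miss,
             chi2 = chi2, p = p,
             keep = !is.na(p) & p >= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
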