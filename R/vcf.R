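#' Write a depth matrix as a VarScan-dialect VCF
#'
#' Emits a plain-text VCF 4.2 file whose per-genotype FORMAT fields carry
#' the read-depth triple under the VarScan names: `DP` (quality read
#' depth), `RD` (reference-supporting depth) and `AD` (variant-supporting
#' depth, a scalar — not the array-valued dialect of other callers).
#' `CHROM` is the scaffold id and `POS` the 1-based position within the
#' scaffold. Missing cells are written as `./.` with empty depth fields.
#'
#' @param depths a `depth_matrix`.
#' @param loci data.frame with one row per depth-matrix row: columns
#'   `locus`, `scaffold`, `scaf_pos`, `ref`, `alt` (as in
#'   `simulate_founder()$loci`).
#' @param path output path (plain text; bgzip-compatible).
#' @param scaffold_table optional scaffold data.frame (`scaffold`,
#'   `length`) used to emit `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(depths, loci, path, scaffold_table = NULL) {
  stopifnot(inherits(depths, "depth_matrix"))
  if (nrow(loci) != nrow(depths$dp))
    stop("loci table and depth matrix disagree on locus count")
  need <- c("locus", "scaffold", "scaf_pos", "ref", "alt")
  if (!all(need %in% names(loci)))
    stop("loci table must have columns: ", paste(need, collapse = ", "))

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hexmap-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Quality Read Depth of bases with Phred score >= 15\">",
    "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Depth of reference-supporting bases\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Depth of variant-supporting bases\">"
  )
  if (!is.null(scaffold_table)) {
    agg <- tapply(scaffold_table$length, scaffold_table$scaffold, sum)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(agg),
                          as.integer(agg)))
  }
  inds <- colnames(depths$dp) %||% sprintf("S1_%03d", seq_len(ncol(depths$dp)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", inds), collapse = "\t"))

  gt <- matrix("0/1", nrow(depths$dp), ncol(depths$dp))
  gt[depths$ad == 0 & !depths$missing] <- "0/0"
  gt[depths$rd == 0 & depths$ad > 0 & !depths$missing] <- "1/1"
  cells <- matrix(paste(gt, depths$dp, depths$rd, depths$ad, sep = ":"),
                  nrow(depths$dp), ncol(depths$dp))
  cells[depths$missing] <- "./.:.:.:."
  body <- paste(loci$scaffold, loci$scaf_pos, loci$locus, loci$ref,
                loci$alt, ".", "PASS", ".", "GT:DP:RD:AD",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a VarScan-dialect VCF into a depth matrix
#'
#' Parses a multi-sample VCF whose genotype fields carry DP/RD/AD depths
#' (scalar AD, the VarScan convention) and returns the locus table and the
#' `depth_matrix` the rest of the pipeline consumes. Only biallelic SNP
#' records are kept; indels and multi-allelic records are skipped with a
#' warning. A cell is missing when its genotype is `./.` or its depth
#' fields are absent.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return list with `loci` (data.frame: `locus` key `scaffold:pos`,
#'   `scaffold`, `pos`, `ref`, `alt`) and `depths` (a `depth_matrix`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  formats <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  have <- Reduce(intersect, formats)
  if (!all(c("DP", "RD", "AD") %in% have))
    stop("VCF FORMAT must carry DP, RD and AD genotype fields")

  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    warning(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(snp)) stop("no biallelic SNP records in ", path)

  num <- function(el) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    m[snp, , drop = FALSE]
  }
  dp <- num("DP"); rd <- num("RD"); ad <- num("AD")
  miss <- is.na(dp) | is.na(rd) | is.na(ad)
  dp[miss] <- 0L; rd[miss] <- 0L; ad[miss] <- 0L

  scaffold <- v@fix[snp, "CHROM"]
  pos <- as.integer(v@fix[snp, "POS"])
  id <- v@fix[snp, "ID"]
  key <- ifelse(is.na(id) | id == ".", paste(scaffold, pos, sep = ":"), id)
  if (anyDuplicated(key)) key <- make.unique(key, sep = "#")
  loci <- data.frame(locus = key, scaffold = scaffold, pos = pos,
                     ref = ref[snp], alt = alt[snp],
                     stringsAsFactors = FALSE)
  rownames(loci) <- key
  rn <- function(m) { dimnames(m) <- list(key, colnames(v@gt)[-1]); m }
  list(loci = loci,
       depths = new_depth_matrix(rn(dp), rn(rd), rn(ad), rn(miss)))
}

#' Hard-filter criteria for depth and missingness
#'
#' The two locus-selection filters applied before any dosage analysis:
#' every data point needs depth of coverage at or above `min_depth`
#' (default 10; cells below it become missing), and a locus is kept only
#' if its proportion of missing data is strictly below `max_missing`
#' (default 0.25).
#'
#' @param min_depth minimum per-cell DP (inclusive), `>= 1`.
#' @param max_missing maximum tolerated missing proportion per locus
#'   (exclusive bound), in `(0, 1]`.
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_depth = 10, max_missing = 0.25) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (max_missing <= 0 || max_missing > 1)
    stop("max_missing must be in (0, 1]")
  structure(list(min_depth = min_depth, max_missing = max_missing),
            class = "filter_criteria")
}

#' Mask cells below the depth threshold
#'
#' Cells with `DP < min_depth` are set missing; depth values of retained
#' cells are untouched and no loci are dropped at this stage.
#'
#' @param depths a `depth_matrix`.
#' @param criteria a `filter_criteria`.
#' @return the filtered `depth_matrix`.
#' @export
apply_depth_filter <- function(depths, criteria = filter_criteria()) {
  stopifnot(inherits(depths, "depth_matrix"),
            inherits(criteria, "filter_criteria"))
  miss <- depths$missing | depths$dp < criteria$min_depth
  new_depth_matrix(depths$dp, depths$rd, depths$ad, miss)
}

#' Drop loci with too much missing data
#'
#' Removes loci whose missing proportion is `>= max_missing` (the kept
#' side of the boundary is strict: a locus is retained only when its
#' missing fraction is below the threshold). Locus order is preserved.
#' Apply after `apply_depth_filter()` so low-depth cells count as missing.
#'
#' @param depths a `depth_matrix`.
#' @param criteria a `filter_criteria`.
#' @return list with `depths` (the locus subset) and `kept` (integer
#'   indices of retained loci in the input).
#' @export
apply_missing_filter <- function(depths, criteria = filter_criteria()) {
  stopifnot(inherits(depths, "depth_matrix"),
            inherits(criteria, "filter_criteria"))
  prop <- rowMeans(depths$missing)
  kept <- unname(which(prop < criteria$max_missing))
  list(depths = subset_loci(depths, kept), kept = kept)
}
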