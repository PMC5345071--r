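#' Simulate an autohexaploid founder genome and its fragmented reference
#'
#' Creates a single heterozygous hexaploid founder: `n_chrom` chromosomes,
#' each with six homologs, carrying biallelic SNP loci of configurable
#' dosage class (the number of ALT-carrying homologs, 1-6). Each locus is
#' "owned" by one homolog that always carries the ALT allele, so simplex
#' loci are spread over all six homologs of every chromosome; loci of
#' higher dosage add further carrier homologs at random. The physical axis
#' is coupled to the genetic axis proportionally (`bp_per_cM`) and is then
#' fragmented into scaffolds, emulating a draft reference assembly of a
#' diploid relative onto which reads were mapped.
#'
#' @param n_chrom number of basic chromosomes (the species in mind has 15;
#'   six homologs each, so `6 * n_chrom` homolog lineages segregate).
#' @param loci_per_homolog number of loci owned by each homolog of each
#'   chromosome; total loci per chromosome is `6 * loci_per_homolog`.
#' @param dosage_class_mix probability vector over dosage classes 1-6
#'   (number of ALT-carrying homologs). The default is all-simplex, the
#'   marker class the mapping pipeline retains.
#' @param chrom_length_cM genetic length of every chromosome in cM.
#' @param bp_per_cM physical bp per cM (default 10 kb/cM).
#' @param scaffold_n50_bp target mean scaffold length; chromosomes are cut
#'   at random breakpoints with exponentially distributed fragment sizes of
#'   this mean.
#' @param chimeric_fraction fraction of scaffolds fused pairwise across
#'   different chromosomes into chimeric scaffolds (assembly artifacts that
#'   anchor more linkage groups than the ploidy allows).
#' @param spacing `"even"`: each homolog's loci evenly spaced with a
#'   per-homolog phase offset (loci interleave, all positions distinct);
#'   `"uniform"`: positions drawn uniformly.
#' @param seed integer seed; the founder is deterministic given it.
#' @return an object of class `founder_genome`: a list with
#'   \describe{
#'     \item{loci}{data.frame: `locus` key, `chrom`, `homolog` (owner),
#'       `dosage`, `pos_cM`, `pos_bp`, `scaffold`, `scaf_pos` (1-based bp
#'       within scaffold), `ref`, `alt`.}
#'     \item{carriers}{logical matrix loci x 6, TRUE where that homolog
#'       carries ALT; row sums equal `loci$dosage`.}
#'     \item{chromosomes}{data.frame of per-chromosome genetic/physical
#'       lengths.}
#'     \item{scaffolds}{data.frame: `scaffold`, `chrom`, `start`, `end`
#'       (0-based half-open on the chromosome), `length`, `chimeric`.}
#'     \item{params}{the call parameters, seed included.}
#'   }
#' @examples
#' fg <- simulate_founder(n_chrom = 2, loci_per_homolog = 5, seed = 1)
#' table(fg$loci$dosage)
#' @export
simulate_founder <- function(n_chrom = 15, loci_per_homolog = 30,
                             dosage_class_mix = c(1, 0, 0, 0, 0, 0),
                             chrom_length_cM = 100, bp_per_cM = 1e4,
                             scaffold_n50_bp = 2e5, chimeric_fraction = 0,
                             spacing = c("even", "uniform"), seed = 1) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (loci_per_homolog < 1) stop("loci_per_homolog must be >= 1")
  if (chrom_length_cM <= 0 || bp_per_cM <= 0 || scaffold_n50_bp <= 0)
    stop("lengths must be positive")
  if (length(dosage_class_mix) != 6 || any(dosage_class_mix < 0) ||
      sum(dosage_class_mix) <= 0)
    stop("dosage_class_mix must be 6 non-negative weights over dosages 1-6")
  mix <- dosage_class_mix / sum(dosage_class_mix)

  set.seed(derive_seed(seed, 1))
  chrom_length_bp <- round(chrom_length_cM * bp_per_cM)
  n_per_chrom <- 6L * loci_per_homolog

  loci_list <- vector("list", n_chrom)
  for (cc in seq_len(n_chrom)) {
    if (spacing == "even") {
      hom <- rep(1:6, each = loci_per_homolog)
      idx <- rep(seq_len(loci_per_homolog), times = 6)
      pos <- (idx - 1 + (hom - 0.5) / 6) * chrom_length_cM / loci_per_homolog
    } else {
      hom <- sample(rep(1:6, length.out = n_per_chrom))
      pos <- sort(stats::runif(n_per_chrom, 0, chrom_length_cM))
    }
    o <- order(pos)
    loci_list[[cc]] <- data.frame(
      chrom = cc, homolog = hom[o], pos_cM = pos[o],
      dosage = sample.int(6, n_per_chrom, replace = TRUE, prob = mix)
    )
  }
  loci <- do.call(rbind, loci_list)
  n_loci <- nrow(loci)

  # owner homolog always carries ALT; extra carriers for dosage > 1
  carriers <- matrix(FALSE, n_loci, 6)
  carriers[cbind(seq_len(n_loci), loci$homolog)] <- TRUE
  extra <- which(loci$dosage > 1)
  for (i in extra) {
    others <- setdiff(1:6, loci$homolog[i])
    carriers[i, sample(others, loci$dosage[i] - 1L)] <- TRUE
  }

  loci$pos_bp <- pmax(1L, as.integer(round(loci$pos_cM * bp_per_cM)))
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, n_loci, replace = TRUE)
  loci$alt <- vapply(loci$ref, function(b) sample(setdiff(bases, b), 1), "")

  scaffolds <- fragment_scaffolds(n_chrom, chrom_length_bp, scaffold_n50_bp,
                                  chimeric_fraction)

  # map loci onto scaffolds (findInterval over each chromosome's breakpoints)
  loci$scaffold <- NA_character_
  loci$scaf_pos <- NA_integer_
  for (cc in seq_len(n_chrom)) {
    sc <- scaffolds[scaffolds$chrom == cc, ]
    sc <- sc[order(sc$start), ]
    li <- which(loci$chrom == cc)
    seg <- findInterval(loci$pos_bp[li] - 1L, sc$start)  # 0-based half-open
    loci$scaffold[li] <- sc$scaffold[seg]
    loci$scaf_pos[li] <- loci$pos_bp[li] - sc$start[seg] + sc$offset[seg] - 1L
  }
  loci$locus <- sprintf("L%02d_%05d", loci$chrom,
                        as.integer(round(loci$pos_bp)))
  if (anyDuplicated(loci$locus))
    loci$locus <- make.unique(loci$locus, sep = "b")
  rownames(loci) <- loci$locus
  rownames(carriers) <- loci$locus

  structure(list(
    loci = loci[, c("locus", "chrom", "homolog", "dosage", "pos_cM",
                    "pos_bp", "scaffold", "scaf_pos", "ref", "alt")],
    carriers = carriers,
    chromosomes = data.frame(chrom = seq_len(n_chrom),
                             length_cM = chrom_length_cM,
                             length_bp = chrom_length_bp),
    scaffolds = scaffolds[, c("scaffold", "chrom", "start", "end",
                              "length", "chimeric")],
    params = list(n_chrom = n_chrom, loci_per_homolog = loci_per_homolog,
                  dosage_class_mix = mix, chrom_length_cM = chrom_length_cM,
                  bp_per_cM = bp_per_cM, scaffold_n50_bp = scaffold_n50_bp,
                  chimeric_fraction = chimeric_fraction, spacing = spacing,
                  seed = seed)
  ), class = "founder_genome")
}

# Cut each chromosome at random breakpoints (exponential fragment sizes of
# the target mean) and optionally fuse scaffolds across chromosomes into
# chimeras. `offset` is the 1-based bp where a segment starts within its
# (possibly fused) scaffold.
fragment_scaffolds <- function(n_chrom, chrom_length_bp, n50_bp,
                               chimeric_fraction) {
  segs <- vector("list", n_chrom)
  for (cc in seq_len(n_chrom)) {
    cuts <- 0
    while (sum(cuts) < chrom_length_bp) {
      cuts <- c(cuts, pmax(1000, round(stats::rexp(5, 1 / n50_bp))))
    }
    b <- pmin(cumsum(cuts), chrom_length_bp)
    b <- unique(b)
    start <- b[-length(b)]
    end <- b[-1]
    segs[[cc]] <- data.frame(chrom = cc, start = start, end = end,
                             length = end - start)
  }
  sc <- do.call(rbind, segs)
  sc <- sc[sc$length > 0, ]
  sc$scaffold <- sprintf("scf%05d", seq_len(nrow(sc)))
  sc$offset <- 1L
  sc$chimeric <- FALSE

  if (chimeric_fraction > 0 && n_chrom >= 2) {
    n_fuse <- floor(chimeric_fraction * nrow(sc) / 2)
    avail <- seq_len(nrow(sc))
    for (k in seq_len(n_fuse)) {
      if (length(avail) < 2) break
      i <- sample(avail, 1)
      j_pool <- avail[sc$chrom[avail] != sc$chrom[i]]
      if (length(j_pool) == 0) break
      j <- if (length(j_pool) == 1) j_pool else sample(j_pool, 1)
      sc$scaffold[j] <- sc$scaffold[i]
      sc$offset[j] <- as.integer(sc$length[i] + 1L)
      sc$chimeric[c(i, j)] <- TRUE
      avail <- setdiff(avail, c(i, j))
    }
  }
  rownames(sc) <- NULL
  sc
}

#' @export
print.founder_genome <- function(x, ...) {
  cat("Autohexaploid founder genome\n")
  cat(sprintf("  chromosomes: %d (6 homologs each)\n", nrow(x$chromosomes)))
  cat(sprintf("  loci: %d  (dosage classes: %s)\n", nrow(x$loci),
              paste(names(table(x$loci$dosage)), table(x$loci$dosage),
                    sep = ":", collapse = " ")))
  cat(sprintf("  scaffolds: %d (%d chimeric)\n",
              length(unique(x$scaffolds$scaffold)),
              sum(x$scaffolds$chimeric)))
  invisible(x)
}

#' Write the simulated scaffold table
#'
#' Tab-separated columns: scaffold, chromosome, start, end (0-based
#' half-open bp on the source chromosome), length. Chimeric scaffolds
#' appear once per source segment.
#'
#' @param founder a `founder_genome`.
#' @param path output path.
#' @export
write_scaffold_table <- function(founder, path) {
  sc <- founder$scaffolds
  utils::write.table(sc[, c("scaffold", "chrom", "start", "end", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
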