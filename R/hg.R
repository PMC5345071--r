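#' Tally mapped SNPs per linkage group and scaffold
#'
#' Homologous groups are found physically: the six homolog linkage groups
#' of one basic chromosome anchor to the same reference scaffolds of a
#' diploid relative. This builds the LG x scaffold incidence — how many
#' mapped SNPs of each LG lie on each scaffold — and the per-scaffold set
#' of assigned LGs (those with at least `min_snps` SNPs on it).
#'
#' @param map a `genetic_map` (pass-2 map, typically).
#' @param snp_scaffolds named character vector: scaffold id per locus key
#'   (e.g. from the VCF `CHROM` column). Mapped SNPs without a scaffold
#'   are excluded with a warning.
#' @param min_snps minimum SNPs of an LG on a scaffold for assignment
#'   (default 1).
#' @param include_small include LGs below the reporting size (default
#'   FALSE).
#' @return an object of class `lg_scaffold_incidence`: list with `counts`
#'   (integer matrix LG x scaffold), `assigned` (logical matrix, counts >=
#'   min_snps), `min_snps`.
#' @export
build_incidence <- function(map, snp_scaffolds, min_snps = 1,
                            include_small = FALSE) {
  stopifnot(inherits(map, "genetic_map"))
  m <- map$map
  if (!include_small) {
    keep_lgs <- map$lgs$lg[!map$lgs$small]
    m <- m[m$lg %in% keep_lgs, ]
  }
  scaf <- snp_scaffolds[m$locus]
  unknown <- is.na(scaf)
  if (any(unknown)) {
    warning(sum(unknown), " mapped SNP(s) without a scaffold excluded")
    m <- m[!unknown, ]
    scaf <- scaf[!unknown]
  }
  if (nrow(m) == 0) {
    counts <- matrix(0L, 0, 0)
  } else {
    counts <- unclass(table(lg = m$lg, scaffold = scaf))
  }
  structure(list(counts = counts, assigned = counts >= min_snps,
                 min_snps = min_snps), class = "lg_scaffold_incidence")
}

#' Cluster linkage groups into homologous groups via shared scaffolds
#'
#' Builds a graph on LGs with edge weight equal to the number of
#' scaffolds assigned to both; edges below `min_shared_scaffolds` are
#' dropped, and connected components are the homologous groups. Scaffolds
#' assigned to more LGs than the ploidy (default > 6) are flagged
#' chimeric — a draft-assembly scaffold cannot legitimately anchor more
#' homologs than exist — and are excluded from edge weighting, so a
#' single mis-joined scaffold cannot bridge two true HGs.
#'
#' @param incidence an `lg_scaffold_incidence`.
#' @param min_shared_scaffolds minimum shared scaffolds for an edge
#'   (default 2; a lone chimeric or misassembled scaffold then cannot
#'   merge two HGs).
#' @param ploidy maximum legitimate LGs per scaffold (default 6).
#' @return an object of class `hg_partition`: list with `membership`
#'   (integer HG id per LG, named by LG id), `chimeric_scaffolds`
#'   (character), `edge_weights` (LG x LG shared-scaffold counts).
#' @export
cluster_hgs <- function(incidence, min_shared_scaffolds = 2, ploidy = 6) {
  stopifnot(inherits(incidence, "lg_scaffold_incidence"),
            min_shared_scaffolds >= 1)
  asg <- incidence$assigned
  if (nrow(asg) == 0)
    return(structure(list(membership = integer(0),
                          chimeric_scaffolds = character(0),
                          edge_weights = matrix(0, 0, 0)),
                     class = "hg_partition"))
  lgs_per_scaffold <- colSums(asg)
  chimeric <- colnames(asg)[lgs_per_scaffold > ploidy]
  use <- asg[, !(colnames(asg) %in% chimeric), drop = FALSE]
  w <- tcrossprod(use * 1)           # shared-scaffold counts per LG pair
  adj <- w >= min_shared_scaffolds
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  membership <- igraph::components(g)$membership
  names(membership) <- rownames(asg)
  structure(list(membership = membership, chimeric_scaffolds = chimeric,
                 edge_weights = w), class = "hg_partition")
}

#' @export
print.hg_partition <- function(x, ...) {
  cat(sprintf("hg_partition: %d LGs in %d HGs (%d chimeric scaffolds)\n",
              length(x$membership),
              length(unique(x$membership)),
              length(x$chimeric_scaffolds)))
  invisible(x)
}

#' Number homologous groups and linkage groups by map length
#'
#' HGs are labelled `HG01`, `HG02`, ... in order of decreasing total map
#' length; within each HG the member LGs are labelled `LG1`, `LG2`, ...
#' by decreasing length. Ties are broken by marker count, then by the
#' original group id, so the labelling is deterministic.
#'
#' @param partition an `hg_partition`.
#' @param map the `genetic_map` whose LG ids the partition uses.
#' @return data.frame, one row per LG: `hg` (label), `hg_id`, `lg_label`,
#'   `lg` (original integer id), `n_loci`, `n_bins`, `length_cM`, sorted
#'   in label order.
#' @export
number_groups <- function(partition, map) {
  stopifnot(inherits(partition, "hg_partition"),
            inherits(map, "genetic_map"))
  if (length(partition$membership) == 0) {
    return(data.frame(hg = character(), hg_id = integer(),
                      lg_label = character(), lg = integer(),
                      n_loci = integer(), n_bins = integer(),
                      length_cM = numeric()))
  }
  lg_ids <- as.integer(names(partition$membership))
  lgs <- map$lgs[match(lg_ids, map$lgs$lg), ]
  df <- data.frame(lg = lg_ids, hg_raw = unname(partition$membership),
                   n_loci = lgs$n_loci, n_bins = lgs$n_bins,
                   length_cM = lgs$length_cM)
  agg <- stats::aggregate(cbind(length_cM, n_loci) ~ hg_raw, df, sum)
  agg <- agg[order(-agg$length_cM, -agg$n_loci, agg$hg_raw), ]
  agg$hg_id <- seq_len(nrow(agg))
  df$hg_id <- agg$hg_id[match(df$hg_raw, agg$hg_raw)]
  df <- df[order(df$hg_id, -df$length_cM, -df$n_loci, df$lg), ]
  df$lg_label <- stats::ave(df$lg, df$hg_id,
                            FUN = function(v) seq_along(v))
  df$hg <- sprintf("HG%02d", df$hg_id)
  df$lg_label <- paste0("LG", df$lg_label)
  rownames(df) <- NULL
  df[, c("hg", "hg_id", "lg_label", "lg", "n_loci", "n_bins",
         "length_cM")]
}
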