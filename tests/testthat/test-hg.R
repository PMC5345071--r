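# a hand-built genetic_map stub: lg ids, marker lists, lengths
stub_map <- function(lgs, len_cM = NULL, n_loci = NULL) {
  map <- do.call(rbind, lapply(seq_along(lgs), function(i) {
    data.frame(locus = lgs[[i]], lg = rep(i, length(lgs[[i]])),
               bin = seq_along(lgs[[i]]), order = seq_along(lgs[[i]]),
               cM = seq(0, by = 1, length.out = length(lgs[[i]])))
  }))
  structure(list(
    map = map,
    lgs = data.frame(lg = seq_along(lgs),
                     n_loci = n_loci %||% lengths(lgs),
                     n_bins = lengths(lgs),
                     length_cM = len_cM %||% rep(10, length(lgs)),
                     small = FALSE),
    lg_data = list(), params = grouping_params()),
    class = "genetic_map")
}

test_that("incidence counts SNPs per LG and scaffold", {
  m <- stub_map(list(c("a1", "a2", "a3"), c("b1", "b2")))
  scafs <- c(a1 = "s1", a2 = "s1", a3 = "s2", b1 = "s2", b2 = "s3")
  inc <- build_incidence(m, scafs)
  expect_equal(unname(inc$counts["1", c("s1", "s2")]), c(2L, 1L))
  expect_equal(unname(inc$counts["2", c("s2", "s3")]), c(1L, 1L))
  # scaffold s2 is assigned to both LGs
  expect_equal(sum(inc$assigned[, "s2"]), 2)
  # unknown scaffolds are excluded with a warning
  scafs2 <- scafs[-1]
  expect_warning(inc2 <- build_incidence(m, scafs2), "without a scaffold")
  expect_equal(unname(inc2$counts["1", "s1"]), 1L)
})

test_that("empty maps give empty incidence and partitions", {
  m <- stub_map(list(character(0)))
  m$map <- m$map[0, ]
  inc <- build_incidence(m, character(0))
  expect_equal(dim(inc$counts), c(0L, 0L))
  part <- cluster_hgs(inc)
  expect_length(part$membership, 0)
})

test_that("shared-scaffold clustering separates true chromosomes", {
  s <- grp_sim()
  m <- build_map(s$kept_calls, grouping_params(lod = 7, min_size = 5),
                 tp = s$tp)
  scafs <- stats::setNames(s$founder$loci$scaffold, s$founder$loci$locus)
  inc <- build_incidence(m, scafs)
  part <- cluster_hgs(inc)
  expect_equal(length(unique(part$membership)), 2)
  # HG partition equals the true chromosome partition
  lg_chrom <- vapply(split(m$map$locus, m$map$lg), function(v)
    unique(s$founder$loci[v, "chrom"])[1], 1)
  tab <- table(part$membership, lg_chrom[names(part$membership)])
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("a single chimeric scaffold cannot bridge two HGs", {
  # two HGs of two LGs each; LGs within an HG share two scaffolds, the
  # chimera is the only scaffold shared across HGs -> weight 1 < 2
  m <- stub_map(list(paste0("a", 1:4), paste0("b", 1:4),
                     paste0("c", 1:4), paste0("d", 1:4)))
  scafs <- c(a1 = "s1", a2 = "s2", a3 = "chim", a4 = "s1",
             b1 = "s1", b2 = "s2", b3 = "s2", b4 = "s1",
             c1 = "s3", c2 = "s4", c3 = "chim", c4 = "s3",
             d1 = "s3", d2 = "s4", d3 = "s4", d4 = "s3")
  part <- cluster_hgs(build_incidence(m, scafs),
                      min_shared_scaffolds = 2)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(part$membership[["1"]], part$membership[["2"]])
  expect_false(part$membership[["1"]] == part$membership[["3"]])
})

test_that("scaffolds on more LGs than the ploidy are flagged chimeric", {
  lgs <- lapply(1:8, function(i) paste0("m", i, "_", 1:2))
  m <- stub_map(lgs)
  scafs <- stats::setNames(
    c(rbind(rep("busy", 8), paste0("own", 1:8))),
    unlist(lgs))
  part <- cluster_hgs(build_incidence(m, scafs), ploidy = 6)
  expect_equal(part$chimeric_scaffolds, "busy")
  # with the chimera excluded nothing links the LGs
  expect_equal(length(unique(part$membership)), 8)
})

test_that("LG isolated from all others forms a singleton HG", {
  m <- stub_map(list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")))
  scafs <- c(a1 = "s1", a2 = "s2", b1 = "s1", b2 = "s2",
             c1 = "s9", c2 = "s9")
  part <- cluster_hgs(build_incidence(m, scafs))
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(sum(part$membership == part$membership[["3"]]), 1)
})

test_that("raising the sharing threshold never merges components", {
  s <- grp_sim()
  m <- build_map(s$kept_calls, grouping_params(lod = 7, min_size = 5),
                 tp = s$tp)
  scafs <- stats::setNames(s$founder$loci$scaffold, s$founder$loci$locus)
  inc <- build_incidence(m, scafs)
  n_prev <- 0
  for (thr in 1:5) {
    n <- length(unique(cluster_hgs(inc, thr)$membership))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("HG and LG numbering follows map length with stated tie-breaks", {
  m <- stub_map(list("a1", "b1", "c1", "d1"),
                len_cM = c(100, 2734.7, 3409.2, 100),
                n_loci = c(5, 10, 10, 3))
  # LGs 1+3 together (3509.2 cM), LGs 2+4 together (2834.7 cM)
  part <- structure(list(
    membership = c(`1` = 1L, `2` = 2L, `3` = 1L, `4` = 2L),
    chimeric_scaffolds = character(0),
    edge_weights = matrix(0, 4, 4)), class = "hg_partition")
  tab <- number_groups(part, m)
  expect_equal(tab$hg[tab$lg == 3], "HG01")   # longest HG first
  expect_equal(tab$lg_label[tab$lg == 3], "LG1")
  expect_equal(tab$hg[tab$lg == 2], "HG02")
  # shorter members rank second within their HGs
  expect_equal(tab$lg_label[tab$lg == 1], "LG2")
  expect_equal(tab$lg_label[tab$lg == 4], "LG2")
  # invariant under permutation of the LG input order
  part2 <- part
  part2$membership <- part$membership[c(3, 1, 4, 2)]
  tab2 <- number_groups(part2, m)
  tab2 <- tab2[order(tab2$lg), ]
  tab_s <- tab[order(tab$lg), ]
  expect_equal(tab2$hg, tab_s$hg)
  expect_equal(tab2$lg_label, tab_s$lg_label)
})
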