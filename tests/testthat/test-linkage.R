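test_that("identical call vectors give r = 0 in coupling with maximal LOD", {
  set.seed(1)
  v <- sample(c(0L, 1L), 142, replace = TRUE, prob = c(1, 3) / 4)
  est <- two_point(v, v)
  expect_equal(est$r, 0)
  expect_equal(est$phase, "coupling")
  expect_gt(est$lod, 7)
  # no pair of the same n can exceed the perfect-cosegregation LOD
  w <- v; w[1:5] <- 1L - w[1:5]
  expect_lt(two_point(v, w)$lod, est$lod)
})

test_that("two_point matches the grid-search likelihood oracle", {
  set.seed(42)
  for (i in 1:200) {
    th <- stats::runif(1)
    n <- sample(40:142, 1)
    pr <- c((2 + th) / 4, (1 - th) / 4, (1 - th) / 4, th / 4)
    cnt <- as.vector(stats::rmultinom(1, n, pr))
    est <- two_point(rep(c(1L, 1L, 0L, 0L), cnt),
                     rep(c(1L, 0L, 1L, 0L), cnt))
    if (!est$informative) next
    oracle <- grid_two_point(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_lt(abs(est$r - oracle$r), 5e-4)
  }
})

test_that("LOD is zero at independence and never negative", {
  # a table whose MLE is exactly theta = 1/4 (perfect 9:3:3:1)
  est <- two_point(rep(c(1L, 1L, 0L, 0L), c(90, 30, 30, 10)),
                   rep(c(1L, 0L, 1L, 0L), c(90, 30, 30, 10)),
                   min_shared = 20)
  expect_equal(est$r, 0.5, tolerance = 1e-8)
  expect_equal(est$lod, 0, tolerance = 1e-8)
})

test_that("phase flips but r is preserved when one marker is inverted", {
  cnt <- c(80, 12, 12, 40)   # strongly coupled, symmetric off-diagonal
  i <- rep(c(1L, 1L, 0L, 0L), cnt)
  j <- rep(c(1L, 0L, 1L, 0L), cnt)
  a <- two_point(i, j)
  b <- two_point(i, 1L - j)
  expect_equal(a$phase, "coupling")
  expect_equal(b$phase, "repulsion")
  # balanced margins: inverted table counts are a permutation, theta maps
  # theta -> its mirror; r estimates agree closely
  expect_equal(b$r, two_point(1L - i, j)$r)
})

test_that("degenerate margins and low sharing are uninformative", {
  all1 <- rep(1L, 50)
  mixed <- rep(c(0L, 1L), 25)
  est <- two_point(all1, mixed)
  expect_false(est$informative)
  expect_equal(est$lod, 0)
  est2 <- two_point(mixed[1:10], mixed[1:10], min_shared = 20)
  expect_false(est2$informative)
})

test_that("vectorized all-pairs table agrees with the scalar estimator", {
  s <- small_sim()
  calls <- s$kept_calls[1:12, ]
  tp <- two_point_matrix(calls)
  for (i in c(1, 3, 7)) {
    for (j in c(2, 5, 11)) {
      est <- two_point(calls[i, ], calls[j, ])
      expect_equal(tp$r[i, j], est$r, tolerance = 1e-10)
      expect_equal(tp$lod[i, j], est$lod, tolerance = 1e-8)
      expect_equal(unname(tp$n[i, j]), est$n)
    }
  }
  expect_true(isSymmetric(tp$r))
  expect_true(all(tp$lod >= 0))
})

test_that("grouping is single-linkage with monotone threshold behaviour", {
  s <- grp_sim()
  sweep <- lod_sweep(s$tp, 3:10, grouping_params(min_size = 5))
  expect_equal(nrow(sweep), 8)
  # group count non-decreasing in the threshold (single-linkage splits)
  expect_true(all(diff(sweep$n_groups_all) >= 0))
  # effectively infinite threshold: all singletons
  gr_inf <- group_markers(s$tp, grouping_params(lod = 1e6, min_size = 5))
  expect_equal(length(gr_inf$groups), nrow(s$kept_calls))
  # at LOD 7 the partition equals the true (chromosome, homolog) lineages
  gr <- group_markers(s$tp, grouping_params(lod = 7, min_size = 5))
  truth <- paste(s$founder$loci[names(gr$membership), "chrom"],
                 s$founder$loci[names(gr$membership), "homolog"])
  tab <- table(gr$membership, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("co-segregation bins require exact equality including missing", {
  calls <- rbind(a = c(0L, 1L, 1L, NA), b = c(0L, 1L, 1L, NA),
                 c = c(0L, 1L, 0L, NA), d = c(0L, 1L, 1L, 0L))
  bins <- bin_cosegregating(calls)
  expect_equal(bins[["a"]], bins[["b"]])
  expect_false(bins[["a"]] == bins[["c"]])   # differ at one individual
  expect_false(bins[["a"]] == bins[["d"]])   # missing pattern differs
})

test_that("three-bin ordering is forced by additivity", {
  r <- matrix(c(0, 0.05, 0.10,
                0.05, 0, 0.05,
                0.10, 0.05, 0), 3, 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  lod <- matrix(10, 3, 3) - 10 * r
  ord <- order_markers(r, lod)
  expect_equal(ord[2], 2L)   # the middle marker is in the middle
  # reversal leaves the adjacent-r score unchanged
  expect_equal(hexmap:::sarf(ord, r), hexmap:::sarf(rev(ord), r))
})

test_that("ordering recovers the true locus order on one homolog", {
  s <- grp_sim()
  gr <- group_markers(s$tp, grouping_params(lod = 7, min_size = 5))
  members <- gr$groups[[which.max(lengths(gr$groups))]]
  sub <- two_point_matrix(s$kept_calls[members, ])
  ord <- order_markers(sub$r, sub$lod)
  true_pos <- s$founder$loci[members[ord], "pos_cM"]
  rho <- abs(stats::cor(seq_along(ord), true_pos, method = "spearman"))
  expect_gte(rho, 0.95)
})

test_that("map-distance conversion follows the Kosambi function", {
  expect_equal(rf_to_cm(0), 0)
  expect_equal(rf_to_cm(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(rf_to_cm(0.1), 2), 10.14)
  expect_equal(rf_to_cm(0.1, "haldane"), -50 * log(0.8))
  # capped near 0.5 rather than diverging
  expect_true(is.finite(rf_to_cm(0.5)))
  # cumulative positions are sums of adjacent distances
  r <- matrix(0.1, 3, 3); diag(r) <- 0
  cm <- assign_cm(1:3, r)
  expect_equal(cm, c(0, rf_to_cm(0.1), 2 * rf_to_cm(0.1)))
})

test_that("simulated coupling pairs at r = 0.1 are estimated unbiasedly", {
  # gamete-level truth: dominant alleles co-transmit with prob (1-r)/2
  set.seed(33)
  n <- 142; r <- 0.1; reps <- 500
  est <- numeric(reps)
  gam_pr <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)  # AB, Ab, aB, ab
  for (k in seq_len(reps)) {
    g1 <- sample(1:4, n, TRUE, gam_pr)
    g2 <- sample(1:4, n, TRUE, gam_pr)
    has_a <- function(g) g %in% c(1, 2)
    has_b <- function(g) g %in% c(1, 3)
    ci <- as.integer(has_a(g1) | has_a(g2))
    cj <- as.integer(has_b(g1) | has_b(g2))
    est[k] <- two_point(ci, cj)$r
  }
  expect_lt(abs(mean(est) - 0.1), 0.02)
})

test_that("markers on different chromosomes are essentially never linked", {
  s <- grp_sim()
  loci <- s$founder$loci[rownames(s$kept_calls), ]
  cross <- outer(loci$chrom, loci$chrom, "!=")
  lods <- s$tp$lod[cross & upper.tri(cross)]
  expect_gt(mean(lods < 3), 0.99)
  expect_true(all(lods < 7))
})
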