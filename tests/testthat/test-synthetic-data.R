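test_that("founder genome respects dosage, spacing and lineage invariants", {
  fg <- simulate_founder(n_chrom = 15, loci_per_homolog = 4, seed = 7)
  # dosage class equals the count of ALT-carrying homologs
  expect_equal(unname(rowSums(fg$carriers)), fg$loci$dosage)
  # all-simplex mix: exactly one carrier everywhere
  expect_true(all(fg$loci$dosage == 1))
  # 15 chromosomes x 6 homologs = 90 distinct carrier lineages
  lineages <- unique(paste(fg$loci$chrom, fg$loci$homolog))
  expect_length(lineages, 90)
  # genetic positions strictly increasing within each chromosome
  for (cc in split(fg$loci, fg$loci$chrom)) {
    expect_true(all(diff(cc$pos_cM) > 0))
  }
  # every locus maps to exactly one scaffold of its own chromosome
  expect_false(anyNA(fg$loci$scaffold))
  scaf_chrom <- fg$scaffolds$chrom[match(fg$loci$scaffold,
                                         fg$scaffolds$scaffold)]
  expect_equal(scaf_chrom, fg$loci$chrom)
  # scaffolds partition each chromosome without overlap
  for (sc in split(fg$scaffolds, fg$scaffolds$chrom)) {
    sc <- sc[order(sc$start), ]
    expect_equal(sc$start[1], 0)
    expect_equal(sc$start[-1], sc$end[-nrow(sc)])
    expect_true(all(sc$length > 0))
  }
})

test_that("founder generation is deterministic and validates inputs", {
  a <- simulate_founder(n_chrom = 2, loci_per_homolog = 5, seed = 42)
  b <- simulate_founder(n_chrom = 2, loci_per_homolog = 5, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_founder(n_chrom = 0), "n_chrom")
  expect_error(simulate_founder(chrom_length_cM = -1), "positive")
  expect_error(simulate_founder(dosage_class_mix = rep(0, 6)),
               "dosage_class_mix")
})

test_that("mixed dosage classes place the owner homolog among carriers", {
  fg <- simulate_founder(n_chrom = 1, loci_per_homolog = 50,
                         dosage_class_mix = rep(1 / 6, 6), seed = 9)
  expect_equal(unname(rowSums(fg$carriers)), fg$loci$dosage)
  expect_true(all(fg$carriers[cbind(seq_len(nrow(fg$loci)),
                                    fg$loci$homolog)]))
})

test_that("each homolog is transmitted to half the gametes", {
  fg <- simulate_founder(n_chrom = 1, loci_per_homolog = 2, seed = 3)
  g <- simulate_gametes(fg, n_gametes = 10000, seed = 5)
  # at the first locus position, membership of each homolog across gametes
  hom1 <- g$homologs[1, , ]           # 3 x n_gametes
  for (h in 1:6) {
    frac <- mean(colSums(hom1 == h) > 0)
    expect_gt(frac, 0.48)
    expect_lt(frac, 0.52)
  }
})

test_that("cross-homolog co-transmission matches the pairing enumeration", {
  # oracle: over the 15 uniform pairings, homologs 1 and 2 share a
  # bivalent in 3 (never co-transmitted), otherwise co-transmit 1/4
  pr <- all_pairings()
  co <- vapply(pr, function(m) {
    together <- any(vapply(m, function(p) all(c(1, 2) %in% p), TRUE))
    if (together) 0 else 0.25
  }, 1)
  expect_equal(mean(co), 0.2)

  fg <- simulate_founder(n_chrom = 1, loci_per_homolog = 1, seed = 11)
  # loci_per_homolog = 1 gives one locus per homolog; take the loci owned
  # by homologs 1 and 2 at nearly identical positions (0 cM apart matters
  # only for same-homolog loci; here we test carrier co-transmission at
  # each locus position)
  g <- simulate_gametes(fg, n_gametes = 20000, seed = 13)
  i1 <- which(fg$loci$homolog == 1)
  both <- mean(apply(g$homologs[i1, , ], 2,
                     function(m) all(c(1, 2) %in% m)))
  se <- sqrt(0.2 * 0.8 / 20000)
  expect_lt(abs(both - 0.2), 4 * se)
})

test_that("S1 selfing reproduces simplex segregation", {
  fg <- simulate_founder(n_chrom = 1, loci_per_homolog = 6, seed = 21)
  pop <- simulate_s1_population(fg, 4000, seed = 22)
  # dosage 0 : 1 : 2 = 1 : 2 : 1, so homozygous-REF frequency ~ 1/4
  frac0 <- rowMeans(pop$dosage == 0)
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(frac0 - 0.25) < 5 * se))
  expect_true(all(pop$dosage %in% 0:2))
})

test_that("loci 0 cM apart on one homolog always co-segregate", {
  fg <- simulate_founder(n_chrom = 1, loci_per_homolog = 2, seed = 31)
  # force two loci of homolog 1 onto the same genetic position
  idx <- which(fg$loci$homolog == 1)[1:2]
  fg$loci$pos_cM[idx[2]] <- fg$loci$pos_cM[idx[1]]
  pop <- simulate_s1_population(fg, 300, seed = 32)
  expect_equal(pop$dosage[idx[1], ], pop$dosage[idx[2], ])
})

test_that("read-depth model honours its boundary identities", {
  dos <- matrix(c(0L, 6L, 1L), 3, 50)
  dm <- simulate_read_depths(dos, read_depth_model(depth_mean = 60,
                                                   error_rate = 0,
                                                   missing_rate = 0),
                             seed = 4)
  expect_true(all(dm$ad[1, ] == 0))        # d = 0, eps = 0: no ALT reads
  expect_true(all(dm$rd[2, ] == 0))        # d = 6, eps = 0: no REF reads
  expect_true(all(dm$dp == dm$rd + dm$ad))
  # pooled ALT fraction at d = 1 approaches 1/6
  frac <- sum(dm$ad[3, ]) / sum(dm$dp[3, ])
  expect_lt(abs(frac - 1 / 6), 0.02)
  expect_error(read_depth_model(error_rate = 0.5), "error_rate")
  expect_error(read_depth_model(error_rate = -0.1), "error_rate")
  expect_error(simulate_read_depths(matrix(7L, 1, 1)), "0-6")
})

test_that("pooled AAF concentrates at d/6 for every dosage class", {
  dos <- matrix(rep(1:6, each = 200), 6, 200, byrow = TRUE)
  dm <- simulate_read_depths(dos, read_depth_model(depth_mean = 200,
                                                   error_rate = 0,
                                                   missing_rate = 0),
                             seed = 8)
  pooled <- compute_aaf(dm)$pooled
  expect_equal(unname(pooled), (1:6) / 6, tolerance = 0.01)
})

test_that("chimeric scaffolds span two chromosomes", {
  fg <- simulate_founder(n_chrom = 4, loci_per_homolog = 10,
                         scaffold_n50_bp = 1e5, chimeric_fraction = 0.3,
                         seed = 17)
  sc <- fg$scaffolds
  fused <- names(which(table(sc$scaffold) > 1))
  expect_gt(length(fused), 0)
  for (f in fused) {
    expect_gt(length(unique(sc$chrom[sc$scaffold == f])), 1)
  }
})
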