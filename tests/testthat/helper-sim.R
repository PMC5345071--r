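# Shared fixtures, memoized so expensive simulations run once per suite.
sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = sim_cache)) assign(key, force(expr), sim_cache)
  get(key, envir = sim_cache)
}

# hand-built depth matrix for unit fixtures
make_depths <- function(dp, rd, ad, missing = NULL) {
  if (is.null(missing)) missing <- matrix(FALSE, nrow(dp), ncol(dp))
  hexmap:::new_depth_matrix(dp, rd, ad, missing)
}

# simulate founder -> S1 -> depths -> dichotomized calls in one step
sim_calls <- function(n_chrom = 2, loci_per_homolog = 12, n_ind = 142,
                      depth_mean = 40, depth_dispersion = 5,
                      error_rate = 0, missing_rate = 0,
                      seed = 1, chrom_length_cM = 100) {
  fg <- simulate_founder(n_chrom = n_chrom,
                         loci_per_homolog = loci_per_homolog,
                         chrom_length_cM = chrom_length_cM, seed = seed)
  pop <- simulate_s1_population(fg, n_ind, seed = seed + 1)
  dm <- simulate_read_depths(
    pop$dosage,
    read_depth_model(depth_mean = depth_mean,
                     depth_dispersion = depth_dispersion,
                     error_rate = error_rate,
                     missing_rate = missing_rate),
    seed = seed + 2)
  mf <- apply_missing_filter(apply_depth_filter(dm))
  aaf <- compute_aaf(mf$depths)
  sel <- select_double_simplex(aaf)
  calls <- dichotomize(hexmap:::subset_loci(mf$depths, sel$index),
                       sel$class)
  seg <- chi_square_1_3(calls)
  list(founder = fg, pop = pop, depths = mf$depths, aaf = aaf, sel = sel,
       calls = calls, seg = seg, kept_calls = calls[seg$keep, ,
                                                    drop = FALSE])
}

# one chromosome, ds_ref-only, for quick dosage/linkage fixtures
small_sim <- function() {
  cached("small_sim", sim_calls(n_chrom = 1, loci_per_homolog = 8,
                                n_ind = 100, seed = 5))
}

# two chromosomes with the all-pairs two-point table attached
grp_sim <- function() {
  cached("grp_sim", {
    x <- sim_calls(n_chrom = 2, loci_per_homolog = 12, n_ind = 142,
                   seed = 19)
    x$tp <- two_point_matrix(x$kept_calls)
    x
  })
}

# dense two-chromosome map (1 cM bin spacing) for the clean-up module;
# depths high and tight so allele dropout (a simplex cell sampling zero
# ALT reads) is negligible and the calls are truly noise-free
imp_sim <- function() {
  cached("imp_sim", {
    x <- sim_calls(n_chrom = 2, loci_per_homolog = 60, n_ind = 142,
                   depth_mean = 100, depth_dispersion = 50,
                   seed = 55, chrom_length_cM = 30)
    x$map <- build_map(x$kept_calls, grouping_params(lod = 7,
                                                     min_size = 10))
    x
  })
}

# simulated dataset written to disk once for the pipeline tests
pipe_ds <- function() {
  cached("pipe_ds", {
    simulate_dataset(file.path(tempdir(), "hexmap_pipe_ds"),
                     n_chrom = 2, loci_per_homolog = 12,
                     n_individuals = 142,
                     depth_model = read_depth_model(error_rate = 0,
                                                    missing_rate = 0.01),
                     seed = 3)
  })
}

# the full-scale hexaploid study design: 15 chromosomes x 6 homologs,
# ~30 evenly spaced simplex loci per homolog, n = 142, no missing data,
# no sequencing error
full_sim <- function() {
  cached("full_sim", {
    s <- sim_calls(n_chrom = 15, loci_per_homolog = 30, n_ind = 142,
                   depth_mean = 100, depth_dispersion = 50, seed = 1)
    s$map <- build_map(s$kept_calls, grouping_params(lod = 7,
                                                     min_size = 20))
    s
  })
}

# independent likelihood oracle: grid search over r at the stated step,
# written directly from the dominant-dominant F2 class probabilities
grid_two_point <- function(n11, n10, n01, n00, step = 1e-4) {
  r <- seq(0, 0.5, by = step)
  ll_of_theta <- function(th) {
    lg <- function(w, x) {
      if (w > 0) w * log(pmax(x, 1e-300)) else rep(0, length(x))
    }
    lg(n11, (2 + th) / 4) + lg(n10 + n01, (1 - th) / 4) +
      lg(n00, th / 4)
  }
  llc <- ll_of_theta((1 - r)^2)
  llr <- ll_of_theta(r^2)
  ic <- which.max(llc)
  ir <- which.max(llr)
  if (llc[ic] >= llr[ir]) {
    list(r = r[ic], phase = "coupling", ll = llc[ic])
  } else {
    list(r = r[ir], phase = "repulsion", ll = llr[ir])
  }
}

# brute-force enumeration of the 15 bivalent pairings of six homologs
all_pairings <- function(v = 1:6) {
  if (length(v) == 0) return(list(list()))
  a <- v[1]
  out <- list()
  for (b in v[-1]) {
    for (m in all_pairings(setdiff(v, c(a, b)))) {
      out <- c(out, list(c(list(c(a, b)), m)))
    }
  }
  out
}
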