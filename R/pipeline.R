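#' Pipeline configuration
#'
#' Bundles every stage's parameters with their conventional defaults:
#' depth >= 10 per data point, missing proportion < 0.25 per locus,
#' double-simplex AAF windows [0.0833, 0.25) and [0.75, 0.9167),
#' 1:3 segregation chi-square at alpha = 0.01, grouping LOD 7 with
#' reporting size 20, imputation window 2 with max 33% missing, HG
#' clustering with >= 2 shared scaffolds and ploidy bound 6.
#'
#' @param filter a [filter_criteria()].
#' @param thresholds a [selection_thresholds()].
#' @param alpha segregation-test significance level (drop if p < alpha).
#' @param dichotomize_tolerance minority reads tolerated as homozygous.
#' @param grouping a [grouping_params()].
#' @param imputation an [imputation_params()].
#' @param min_shared_scaffolds,ploidy,min_snps HG-stage parameters, see
#'   [cluster_hgs()] and [build_incidence()].
#' @param seed master seed recorded in the manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_criteria(),
                            thresholds = selection_thresholds(),
                            alpha = 0.01, dichotomize_tolerance = 0,
                            grouping = grouping_params(),
                            imputation = imputation_params(),
                            min_shared_scaffolds = 2, ploidy = 6,
                            min_snps = 1, seed = 1) {
  structure(list(filter = filter, thresholds = thresholds, alpha = alpha,
                 dichotomize_tolerance = dichotomize_tolerance,
                 grouping = grouping, imputation = imputation,
                 min_shared_scaffolds = min_shared_scaffolds,
                 ploidy = ploidy, min_snps = min_snps, seed = seed),
            class = "pipeline_config")
}

#' Run the full mapping pipeline on a VCF
#'
#' Executes every stage in order — read, depth/missingness filters,
#' pooled AAF, double-simplex selection, dichotomization, 1:3 segregation
#' test, two-point grouping/ordering (pass 1), error correction and
#' imputation, regroup/reorder (pass 2), and homologous-group assignment
#' — writing tab-separated stage outputs and a JSON manifest recording
#' the marker attrition at each step. If no marker survives selection or
#' segregation testing the pipeline stops gracefully at that stage with
#' the partial outputs retained.
#'
#' @param vcf path to the VarScan-dialect VCF.
#' @param out_dir output directory (created if needed).
#' @param config a `pipeline_config`.
#' @param scaffold_table optional path to a scaffold table (tab-separated
#'   with `scaffold` and `length` columns) recorded in the manifest.
#' @return an object of class `pipeline_result`: list with `manifest`,
#'   `markers` (selection/segregation table), `map1`, `map2`, `hg_table`,
#'   `incidence`, `calls` (cleaned), `aaf`, `completed_stage`.
#' @export
run_pipeline <- function(vcf, out_dir, config = pipeline_config(),
                         scaffold_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    software = paste0("hexmap ",
                      as.character(utils::packageVersion("hexmap"))),
    seed = config$seed,
    inputs = list(vcf = vcf,
                  vcf_md5 = unname(tools::md5sum(vcf)),
                  scaffold_table = scaffold_table),
    config = config_snapshot(config),
    stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  vv <- read_vcf(vcf)
  note("read_vcf", n_loci = nrow(vv$depths$dp),
       n_individuals = ncol(vv$depths$dp))

  dm <- apply_depth_filter(vv$depths, config$filter)
  mf <- apply_missing_filter(dm, config$filter)
  dm <- mf$depths
  loci <- vv$loci[mf$kept, ]
  note("filter", n_candidate_loci = nrow(dm$dp))
  utils::write.table(loci[, c("locus", "scaffold", "pos")],
                     file.path(out_dir, "kept_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  aaf <- compute_aaf(dm)
  sel <- select_double_simplex(aaf, config$thresholds)
  note("select_double_simplex", n_ds_ref = sum(sel$class == "ds_ref"),
       n_ds_alt = sum(sel$class == "ds_alt"))
  result <- structure(list(manifest = manifest, aaf = aaf,
                           completed_stage = "select"),
                      class = "pipeline_result")
  if (nrow(sel) == 0) {
    message("no double-simplex candidates selected; stopping")
    write_manifest(manifest, out_dir)
    return(result)
  }

  ds <- subset_loci(dm, sel$index)
  calls <- dichotomize(ds, sel$class, config$dichotomize_tolerance)
  seg <- chi_square_1_3(calls, config$alpha)
  markers <- cbind(sel[, c("locus", "class", "aaf")],
                   loci[sel$index, c("scaffold", "pos")],
                   seg[, c("n_homo", "n_nothomo", "chi2", "p", "keep")])
  utils::write.table(markers, file.path(out_dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("segregation_test", n_tested = nrow(seg), n_kept = sum(seg$keep))
  result$markers <- markers
  result$completed_stage <- "segregation"
  if (sum(seg$keep) < 2) {
    message("fewer than two markers fit 1:3 segregation; stopping ",
            "before linkage")
    result$manifest <- manifest
    write_manifest(manifest, out_dir)
    return(result)
  }

  calls <- calls[seg$keep, , drop = FALSE]
  map1 <- build_map(calls, config$grouping)
  note("map_pass1", n_lgs = sum(!map1$lgs$small),
       n_small_groups = sum(map1$lgs$small),
       total_cM = round(map_length(map1), 1))

  rr <- rerun_map(calls, map1, config$imputation, config$grouping)
  map2 <- rr$map2
  note("impute_and_remap", n_corrected = sum(is.na(rr$log$after)),
       n_imputed = sum(!is.na(rr$log$after)),
       n_lgs = sum(!map2$lgs$small),
       total_cM = round(map_length(map2), 1))
  utils::write.table(rr$log, file.path(out_dir, "correction_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  snp_scaffolds <- stats::setNames(loci$scaffold, loci$locus)
  inc <- build_incidence(map2, snp_scaffolds, config$min_snps)
  part <- cluster_hgs(inc, config$min_shared_scaffolds, config$ploidy)
  hg_table <- number_groups(part, map2)
  note("hg_assign", n_hgs = length(unique(part$membership)),
       n_chimeric_scaffolds = length(part$chimeric_scaffolds))

  map_out <- map2$map
  hg_of_lg <- stats::setNames(hg_table$hg, hg_table$lg)
  map_out$hg <- hg_of_lg[as.character(map_out$lg)]
  map_out$scaffold <- loci$scaffold[match(map_out$locus, loci$locus)]
  map_out$pos <- loci$pos[match(map_out$locus, loci$locus)]
  utils::write.table(
    map_out[, c("hg", "lg", "order", "bin", "cM", "locus", "scaffold",
                "pos")],
    file.path(out_dir, "map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(hg_table, file.path(out_dir, "hg_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inc_long <- which(inc$counts > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(lg = rownames(inc$counts)[inc_long[, 1]],
               scaffold = colnames(inc$counts)[inc_long[, 2]],
               n_snps = inc$counts[inc_long]),
    file.path(out_dir, "incidence.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  result$calls <- rr$calls
  result$map1 <- map1
  result$map2 <- map2
  result$hg_table <- hg_table
  result$incidence <- inc
  result$partition <- part
  result$manifest <- manifest
  result$completed_stage <- "hg_assign"
  write_manifest(manifest, out_dir)
  result
}

config_snapshot <- function(config) {
  rapply(unclass(config), function(x) x, how = "list")
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (completed through stage:", x$completed_stage,
      ")\n")
  if (!is.null(x$map2)) print(x$map2)
  invisible(x)
}

#' Summary tables of a pipeline run
#'
#' Produces the standard report tables: the pooled-AAF histogram (the
#' six-peak dosage fingerprint), the LOD-sweep table of group counts, and
#' the HG x LG table of locus counts and map lengths with totals.
#'
#' @param result a `pipeline_result` that completed the mapping stages.
#' @param aaf_binwidth histogram bin width (default 0.005).
#' @param lods LOD thresholds for the sweep (default 3:10).
#' @param out_dir optional directory to write the tables to.
#' @return list: `aaf_hist` (data.frame `bin_low`, `count`), `lod_sweep`,
#'   `hg_lg` (HG x LG table with `total` row).
#' @export
report_tables <- function(result, aaf_binwidth = 0.005, lods = 3:10,
                          out_dir = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  p <- result$aaf$pooled
  p <- p[!is.na(p)]
  breaks <- seq(0, 1 + aaf_binwidth, by = aaf_binwidth)
  h <- hist(pmin(p, 1), breaks = breaks, plot = FALSE)
  aaf_hist <- data.frame(bin_low = h$breaks[-length(h$breaks)],
                         count = h$counts)

  sweep <- NULL
  hg_lg <- NULL
  if (!is.null(result$calls)) {
    tp <- two_point_matrix(result$calls,
                           result$map2$params$min_shared)
    sweep <- lod_sweep(tp, lods, result$map2$params)
  }
  if (!is.null(result$hg_table)) {
    ht <- result$hg_table
    hg_lg <- ht[, c("hg", "lg_label", "n_loci", "n_bins", "length_cM")]
    totals <- data.frame(hg = "total", lg_label = "",
                         n_loci = sum(ht$n_loci), n_bins = sum(ht$n_bins),
                         length_cM = sum(ht$length_cM))
    hg_lg <- rbind(hg_lg, totals)
  }
  out <- list(aaf_hist = aaf_hist, lod_sweep = sweep, hg_lg = hg_lg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]]))
        utils::write.table(out[[nm]],
                           file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Simulate a complete dataset to disk
#'
#' Convenience wrapper around the simulator: founder, S1 population, read
#' depths, VCF, scaffold table and truth files (true dosages and locus
#' truth), plus a JSON snapshot of all parameters and the seed.
#'
#' @param out_dir output directory.
#' @param n_chrom,loci_per_homolog,dosage_class_mix,chrom_length_cM,scaffold_n50_bp,chimeric_fraction
#'   founder parameters, see [simulate_founder()].
#' @param n_individuals S1 population size (default 142).
#' @param depth_model a [read_depth_model()].
#' @param seed master seed.
#' @return list with `vcf`, `scaffold_table`, `truth` file paths and the
#'   in-memory `founder`, `population`, `depths`.
#' @export
simulate_dataset <- function(out_dir, n_chrom = 15, loci_per_homolog = 30,
                             dosage_class_mix = c(1, 0, 0, 0, 0, 0),
                             chrom_length_cM = 100, scaffold_n50_bp = 2e5,
                             chimeric_fraction = 0, n_individuals = 142,
                             depth_model = read_depth_model(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  founder <- simulate_founder(
    n_chrom = n_chrom, loci_per_homolog = loci_per_homolog,
    dosage_class_mix = dosage_class_mix,
    chrom_length_cM = chrom_length_cM,
    scaffold_n50_bp = scaffold_n50_bp,
    chimeric_fraction = chimeric_fraction, seed = seed)
  pop <- simulate_s1_population(founder, n_individuals,
                                seed = derive_seed(seed, 11))
  depths <- simulate_read_depths(pop$dosage, depth_model,
                                 seed = derive_seed(seed, 12))
  vcf_path <- file.path(out_dir, "population.vcf")
  write_vcf(depths, founder$loci, vcf_path, founder$scaffolds)
  scaf_path <- file.path(out_dir, "scaffolds.tsv")
  write_scaffold_table(founder, scaf_path)
  truth_path <- file.path(out_dir, "truth_dosage.tsv")
  utils::write.table(pop$dosage, truth_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  loci_truth <- file.path(out_dir, "truth_loci.tsv")
  utils::write.table(founder$loci, loci_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_chrom = n_chrom,
         loci_per_homolog = loci_per_homolog,
         dosage_class_mix = dosage_class_mix,
         chrom_length_cM = chrom_length_cM,
         scaffold_n50_bp = scaffold_n50_bp,
         chimeric_fraction = chimeric_fraction,
         n_individuals = n_individuals,
         depth_model = unclass(depth_model)),
    file.path(out_dir, "simulation_params.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(vcf = vcf_path, scaffold_table = scaf_path, truth = truth_path,
       founder = founder, population = pop, depths = depths)
}
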