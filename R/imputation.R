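#' Map-based error-correction and imputation parameters
#'
#' Window rules driven by map order: within a dense map, a genotype that
#' disagrees with both flanking co-segregation bins implies a double
#' recombinant in a tiny interval — overwhelmingly a genotyping error —
#' so such singletons are masked; missing cells whose flanking bins agree
#' are filled with the consensus.
#'
#' @param window half-width w, in bins, searched on each side (default 2).
#' @param max_error maximum disagreements tolerated inside the window for
#'   a singleton to be masked (default 1, i.e. the target call must be the
#'   sole disagreement).
#' @param max_missing markers (bins) with a missing fraction above this
#'   are passed through untouched (default 0.33).
#' @return an object of class `imputation_params`.
#' @export
imputation_params <- function(window = 2, max_error = 1,
                              max_missing = 0.33) {
  if (window < 1) stop("window must be >= 1")
  stopifnot(max_error >= 1, max_missing > 0, max_missing <= 1)
  structure(list(window = window, max_error = max_error,
                 max_missing = max_missing), class = "imputation_params")
}

# shared walk over one individual's ordered bin calls; returns indices of
# singleton double-recombinant calls to mask
find_singletons <- function(v, w, max_error, eligible) {
  B <- length(v)
  out <- integer(0)
  if (B < 3) return(out)
  for (b in 2:(B - 1)) {
    if (!eligible[b]) next
    x <- v[b]
    if (is.na(x)) next
    left <- v[b - 1]; right <- v[b + 1]
    if (is.na(left) || is.na(right)) next
    if (left != right || left == x) next
    win <- max(1, b - w):min(B, b + w)
    disagree <- sum(v[win] != left, na.rm = TRUE)
    if (disagree <= max_error) out <- c(out, b)
  }
  out
}

#' Mask apparent genotyping errors along the map order
#'
#' For each individual, scans the ordered co-segregation bins of one
#' linkage group: a call that disagrees with both immediate flanking
#' bins' (agreeing, non-missing) calls, and is the sole disagreement
#' within `window` bins on each side (`<= max_error`), is set to missing.
#' Calls at group ends are left untouched (only one flank). No call is
#' ever flipped directly — changed cells are masked and may be re-filled
#' by [impute_missing()], so every change is auditable.
#'
#' @param bin_calls integer matrix (ordered bins x individuals) of one
#'   linkage group, 0/1/NA.
#' @param params an `imputation_params`.
#' @return list: `calls` (corrected matrix) and `log` (data.frame
#'   `marker`, `individual`, `before`, `after`, `reason`).
#' @export
correct_errors <- function(bin_calls, params = imputation_params()) {
  stopifnot(is.matrix(bin_calls), inherits(params, "imputation_params"))
  out <- bin_calls
  eligible <- rowMeans(is.na(bin_calls)) <= params$max_missing
  logs <- list()
  for (ind in seq_len(ncol(bin_calls))) {
    hits <- find_singletons(bin_calls[, ind], params$window,
                            params$max_error, eligible)
    if (length(hits)) {
      logs[[length(logs) + 1]] <- data.frame(
        marker = rownames(bin_calls)[hits] %||% as.character(hits),
        individual = colnames(bin_calls)[ind] %||% as.character(ind),
        before = bin_calls[hits, ind], after = NA_integer_,
        reason = "singleton_double_recombinant",
        stringsAsFactors = FALSE)
      out[hits, ind] <- NA_integer_
    }
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(marker = character(), individual = character(),
               before = integer(), after = integer(),
               reason = character(), stringsAsFactors = FALSE)
  list(calls = out, log = log_df)
}

#' Impute missing calls from agreeing flanking bins
#'
#' A missing cell whose nearest non-missing flanking calls — searched up
#' to `window` bins on each side — agree is set to that consensus call;
#' cells inside an apparent crossover interval (flanks disagree) or at a
#' group end with only one informative flank are left missing.
#'
#' @inheritParams correct_errors
#' @return list: `calls` (imputed matrix) and `log` (as in
#'   [correct_errors()], `reason = "flank_consensus"`).
#' @export
impute_missing <- function(bin_calls, params = imputation_params()) {
  stopifnot(is.matrix(bin_calls), inherits(params, "imputation_params"))
  out <- bin_calls
  B <- nrow(bin_calls)
  w <- params$window
  eligible <- rowMeans(is.na(bin_calls)) <= params$max_missing
  logs <- list()
  for (ind in seq_len(ncol(bin_calls))) {
    v <- bin_calls[, ind]
    miss <- which(is.na(v) & eligible)
    for (b in miss) {
      lw <- b - seq_len(min(w, b - 1))
      rw <- b + seq_len(min(w, B - b))
      left <- unname(v[lw][!is.na(v[lw])][1])
      right <- unname(v[rw][!is.na(v[rw])][1])
      if (!is.na(left) && !is.na(right) && left == right) {
        out[b, ind] <- left
        logs[[length(logs) + 1]] <- data.frame(
          marker = rownames(bin_calls)[b] %||% as.character(b),
          individual = colnames(bin_calls)[ind] %||% as.character(ind),
          before = NA_integer_, after = left,
          reason = "flank_consensus", stringsAsFactors = FALSE)
      }
    }
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(marker = character(), individual = character(),
               before = integer(), after = integer(),
               reason = character(), stringsAsFactors = FALSE)
  list(calls = out, log = log_df)
}

#' Clean a mapped call matrix and rebuild the map
#'
#' Applies [correct_errors()] then [impute_missing()] to every linkage
#' group of a pass-1 map, propagates the cleaned bin calls back to the
#' member markers, and runs a full second grouping/ordering pass on the
#' cleaned marker matrix with the same parameters. Residual genotyping
#' errors inflate a map (each masquerades as a double crossover), so the
#' pass-2 map of error-containing data is expected to be shorter.
#'
#' @param calls the pass-1 marker call matrix (loci x individuals).
#' @param map the pass-1 `genetic_map` built from `calls`.
#' @param imp_params an `imputation_params`.
#' @param map_params a `grouping_params` for the second pass (defaults to
#'   the pass-1 parameters).
#' @return list: `map2` (the pass-2 `genetic_map`), `calls` (cleaned
#'   marker matrix), `log` (combined correction/imputation log),
#'   `summary` (data.frame comparing the passes).
#' @export
rerun_map <- function(calls, map, imp_params = imputation_params(),
                      map_params = NULL) {
  stopifnot(is.matrix(calls), inherits(map, "genetic_map"))
  map_params <- map_params %||% map$params
  cleaned <- calls
  logs <- list()
  for (lg in seq_along(map$lg_data)) {
    ld <- map$lg_data[[lg]]
    bc <- ld$bin_calls
    corr <- correct_errors(bc, imp_params)
    imp <- impute_missing(corr$calls, imp_params)
    logs[[length(logs) + 1]] <- rbind(corr$log, imp$log)
    # bins carry identical vectors, so members inherit the cleaned bin row
    for (m in names(ld$bin_of_marker)) {
      cleaned[m, ] <- imp$calls[ld$bin_of_marker[[m]], ]
    }
  }
  map2 <- build_map(cleaned, map_params)
  log_df <- do.call(rbind, logs)
  summary <- data.frame(
    pass = c(1, 2),
    n_lgs = c(sum(!map$lgs$small), sum(!map2$lgs$small)),
    total_cM = c(map_length(map), map_length(map2)),
    missing_frac = c(mean(is.na(calls)), mean(is.na(cleaned))))
  list(map2 = map2, calls = cleaned, log = log_df, summary = summary)
}
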