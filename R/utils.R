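#' Convert a recombination fraction to map distance
#'
#' Map functions translate a recombination fraction `r` into additive
#' centimorgan distance. Kosambi, `d = 25 * log((1 + 2r) / (1 - 2r))`,
#' accounts for moderate crossover interference and is the conventional
#' default of plant linkage-mapping software; Haldane,
#' `d = -50 * log(1 - 2r)`, assumes none.
#'
#' @param r numeric vector of recombination fractions in `[0, 0.5]`.
#'   Values are capped at 0.4999 before the transform, which diverges at 0.5.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return numeric vector of distances in cM.
#' @examples
#' rf_to_cm(0.1)           # ~10.14 cM
#' rf_to_cm(0.1, "haldane")
#' @export
rf_to_cm <- function(r, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  stopifnot(is.numeric(r), all(r >= 0 | is.na(r)))
  r <- pmin(r, 0.4999)
  switch(map_function,
    kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
    haldane = -50 * log(1 - 2 * r)
  )
}

# Derive independent sub-seeds from one master seed so that each stage has
# its own reproducible stream. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
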