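# Two-point linkage of dichotomized double-simplex markers in an S1.
#
# A double-simplex pair whose rare alleles sit on the same homolog
# segregates exactly like a coupled heterozygous diploid pair scored
# dominantly at both loci: per gamete the dominant alleles co-transmit
# with probability (1-r)/2 each for AB/ab and r/2 for the recombinants.
# Fusing two independent gametes gives the classical F2 dominant-dominant
# class probabilities in theta = (1-r)^2 (coupling) or theta = r^2
# (repulsion):
#   P(1,1) = (2+theta)/4,  P(1,0) = P(0,1) = (1-theta)/4,  P(0,0) = theta/4
# where 1 = not-homozygous (carries the simplex allele), 0 = homozygous.
# The log-likelihood is maximized in closed form: d logL / d theta = 0 is
# the quadratic  n*theta^2 - (n11 - 2q - n00)*theta - 2*n00 = 0  with
# q = n10 + n01, whose positive root is the unconstrained MLE. theta > 1/4
# means coupling (r = 1 - sqrt(theta)), theta < 1/4 repulsion
# (r = sqrt(theta)); theta = 1/4 is independence (r = 0.5, LOD 0).

theta_mle <- function(n11, q, n00) {
  n <- n11 + q + n00
  b <- n11 - 2 * q - n00
  (b + sqrt(b^2 + 8 * n * n00)) / (2 * n)
}

loglik_theta <- function(theta, n11, q, n00) {
  safe <- function(w, x) ifelse(w > 0, w * log(pmax(x, 1e-300)), 0)
  safe(n11, (2 + theta) / 4) + safe(q, (1 - theta) / 4) +
    safe(n00, theta / 4)
}

#' Two-point recombination estimate for one marker pair
#'
#' Maximum-likelihood recombination fraction, linkage phase and LOD score
#' for a pair of dichotomized double-simplex markers in an S1 population
#' (dominant-dominant F2 model; see the source header for the class
#' probabilities). The LOD compares the maximized likelihood with
#' independence (r = 0.5). Pairs with fewer than `min_shared` jointly
#' non-missing individuals, or with a degenerate margin (one marker all
#' one class), are flagged uninformative and reported at r = 0.5, LOD 0.
#'
#' @param calls_i,calls_j integer call vectors (0/1/NA) of equal length.
#' @param min_shared minimum shared non-missing individuals (default 20).
#' @return list: `r`, `lod`, `phase` (`"coupling"`/`"repulsion"`), `n`
#'   (shared individuals), counts `n11`, `n10`, `n01`, `n00`,
#'   `informative`.
#' @export
two_point <- function(calls_i, calls_j, min_shared = 20) {
  stopifnot(length(calls_i) == length(calls_j))
  ok <- !is.na(calls_i) & !is.na(calls_j)
  i <- calls_i[ok]; j <- calls_j[ok]
  n11 <- sum(i == 1 & j == 1); n10 <- sum(i == 1 & j == 0)
  n01 <- sum(i == 0 & j == 1); n00 <- sum(i == 0 & j == 0)
  n <- n11 + n10 + n01 + n00
  out <- list(r = 0.5, lod = 0, phase = "coupling", n = n,
              n11 = n11, n10 = n10, n01 = n01, n00 = n00,
              informative = FALSE)
  if (n < min_shared) return(out)
  if (n11 + n10 == 0 || n01 + n11 == 0 || n10 + n00 == 0 || n01 + n00 == 0)
    return(out)  # a margin is fixed: no linkage information
  q <- n10 + n01
  th <- min(max(theta_mle(n11, q, n00), 0), 1)
  ll <- loglik_theta(th, n11, q, n00)
  ll0 <- loglik_theta(0.25, n11, q, n00)
  out$informative <- TRUE
  out$lod <- max(0, (ll - ll0) / log(10))
  if (th >= 0.25) {
    out$phase <- "coupling"; out$r <- 1 - sqrt(th)
  } else {
    out$phase <- "repulsion"; out$r <- sqrt(th)
  }
  out
}

#' All-pairs two-point estimates via matrix counting
#'
#' Computes the 2x2 joint-class counts for every marker pair with matrix
#' cross-products over the dichotomized call matrix and solves the
#' closed-form MLE vectorized, so thousands of markers complete in
#' seconds. Semantics per pair are identical to [two_point()].
#'
#' @param calls integer matrix (loci x individuals) of 0/1/NA calls.
#' @param min_shared minimum shared non-missing individuals per pair.
#' @return an object of class `two_point_table`: list of loci x loci
#'   matrices `r`, `lod`, `n`, logical `coupling` and `informative`;
#'   diagonal entries are uninformative by convention.
#' @export
two_point_matrix <- function(calls, min_shared = 20) {
  stopifnot(is.matrix(calls))
  A <- t(calls == 1L & !is.na(calls)) * 1  # individuals x loci
  B <- t(calls == 0L & !is.na(calls)) * 1
  N11 <- crossprod(A)
  N00 <- crossprod(B)
  D <- crossprod(A, B)        # D[i, j] = n10 for pair (i, j)
  rm(A, B)
  Q <- D + t(D)
  N <- N11 + Q + N00
  # degenerate margin: a marker all one class among the shared individuals
  margin_ok <- (N11 + D) > 0 & (t(D) + N00) > 0 &
    (N11 + t(D)) > 0 & (D + N00) > 0
  rm(D)
  informative <- N >= min_shared & margin_ok
  rm(margin_ok)

  th <- theta_mle(N11, Q, N00)
  th[!is.finite(th)] <- 0.25
  th <- pmin(pmax(th, 0), 1)
  ll <- loglik_theta(th, N11, Q, N00)
  ll0 <- loglik_theta(0.25, N11, Q, N00)
  lod <- (ll - ll0) / log(10)
  lod[lod < 0] <- 0
  rm(ll, ll0)
  r <- ifelse(th >= 0.25, 1 - sqrt(th), sqrt(th))
  coupling <- th >= 0.25
  rm(th, N11, N00, Q)
  r[!informative] <- 0.5
  lod[!informative] <- 0
  diag(informative) <- FALSE
  diag(lod) <- 0
  diag(r) <- 0
  keys <- rownames(calls)
  dimnames(r) <- dimnames(lod) <- dimnames(N) <-
    dimnames(coupling) <- dimnames(informative) <- list(keys, keys)
  structure(list(r = r, lod = lod, n = N, coupling = coupling,
                 informative = informative, min_shared = min_shared),
            class = "two_point_table")
}

#' @export
print.two_point_table <- function(x, ...) {
  cat(sprintf("two_point_table: %d markers, %d informative pairs\n",
              nrow(x$r), sum(x$informative[upper.tri(x$informative)])))
  invisible(x)
}

#' Grouping, ordering and mapping parameters
#'
#' @param lod LOD threshold for declaring linkage (default 7).
#' @param max_rf maximum recombination fraction for an edge (default 0.5).
#' @param min_size minimum markers for a group to be reported as a
#'   linkage group (default 20); smaller groups are listed separately.
#' @param min_shared minimum shared non-missing individuals for a pair to
#'   be informative (default 20).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @param ripple_window window size of the order-improvement ripple.
#' @return an object of class `grouping_params`.
#' @export
grouping_params <- function(lod = 7, max_rf = 0.5, min_size = 20,
                            min_shared = 20,
                            map_function = c("kosambi", "haldane"),
                            ripple_window = 4) {
  if (lod <= 0) stop("lod threshold must be positive")
  stopifnot(max_rf > 0, max_rf <= 0.5, min_size >= 1, ripple_window >= 2)
  structure(list(lod = lod, max_rf = max_rf, min_size = min_size,
                 min_shared = min_shared,
                 map_function = match.arg(map_function),
                 ripple_window = ripple_window),
            class = "grouping_params")
}

#' Group markers by transitive linkage
#'
#' Single-linkage grouping: markers are nodes, and an edge joins a pair
#' whose LOD is at or above the threshold with recombination fraction at
#' or below `max_rf`; connected components are the groups. In an
#' autohexaploid mapped with double-simplex markers, each homolog yields
#' its own group (coupling-phase linkage only), so about six groups per
#' basic chromosome are expected.
#'
#' @param tp a `two_point_table`.
#' @param params a `grouping_params`.
#' @return list: `membership` (named integer vector, group id per
#'   marker), `groups` (list of marker-key vectors, all sizes), `large`
#'   (indices of groups with `>= min_size` markers), `small` (the rest).
#' @export
group_markers <- function(tp, params = grouping_params()) {
  stopifnot(inherits(tp, "two_point_table"),
            inherits(params, "grouping_params"))
  adj <- tp$informative & tp$lod >= params$lod & tp$r <= params$max_rf
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- rownames(tp$r)
  groups <- split(names(membership), membership)
  sizes <- lengths(groups)
  list(membership = membership, groups = groups,
       large = which(sizes >= params$min_size),
       small = which(sizes < params$min_size))
}

#' Sweep the grouping LOD threshold
#'
#' Reports, for each LOD threshold, the number of groups with at least
#' `min_size` markers — the diagnostic used to pick a threshold whose
#' group count approaches the expected number of homolog linkage groups
#' (6 x basic chromosome number).
#'
#' @param tp a `two_point_table`.
#' @param lods thresholds to try (default 3:10).
#' @param params a `grouping_params` (its `lod` is overridden).
#' @return data.frame: `lod`, `n_groups` (>= min_size), `n_markers_in`
#'   (markers in those groups), `n_groups_all`.
#' @export
lod_sweep <- function(tp, lods = 3:10, params = grouping_params()) {
  rows <- lapply(lods, function(L) {
    params$lod <- L
    gr <- group_markers(tp, params)
    sizes <- lengths(gr$groups)
    data.frame(lod = L, n_groups = sum(sizes >= params$min_size),
               n_markers_in = sum(sizes[sizes >= params$min_size]),
               n_groups_all = length(sizes))
  })
  do.call(rbind, rows)
}

#' Assign co-segregation bin ids
#'
#' Markers with byte-identical call vectors — including the pattern of
#' missing cells — share a bin and are mapped as one point. Bin ids are
#' integers in order of first appearance.
#'
#' @param calls integer call matrix (loci x individuals).
#' @return integer vector of bin ids, one per marker, named by locus.
#' @export
bin_cosegregating <- function(calls) {
  stopifnot(is.matrix(calls))
  key <- apply(calls, 1, function(v) paste(ifelse(is.na(v), "M", v),
                                           collapse = ""))
  ids <- match(key, unique(key))
  names(ids) <- rownames(calls)
  ids
}

# all permutations of 1..n (n small), deterministic order
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

sarf <- function(ord, r_mat) sum(r_mat[cbind(ord[-length(ord)], ord[-1])])

#' Order markers (bins) within a linkage group
#'
#' Rapid-chain-delineation-style greedy ordering followed by local
#' improvement: the chain is seeded with the most strongly linked pair
#' (highest LOD; ties by lower r then key), unplaced bins are appended to
#' whichever chain end they are most strongly linked to, and a sliding
#' window ripple (all permutations of `window` consecutive bins) then
#' minimizes the sum of adjacent recombination fractions until stable.
#' Deterministic given the input and its stated tie-breaks.
#'
#' @param r_mat,lod_mat square matrices of pairwise r and LOD among the
#'   group's bins (e.g. from [two_point_matrix()] on bin representatives).
#' @param window ripple window (default 4).
#' @return integer vector: the ordered bin indices.
#' @export
order_markers <- function(r_mat, lod_mat, window = 4) {
  B <- nrow(r_mat)
  stopifnot(B >= 1, all(dim(lod_mat) == dim(r_mat)))
  if (B == 1) return(1L)
  keys <- rownames(r_mat) %||% sprintf("%06d", seq_len(B))

  # deterministic argmax over (lod desc, r asc, key asc)
  pick <- function(cand_i, cand_j) {
    o <- order(-lod_mat[cbind(cand_i, cand_j)],
               r_mat[cbind(cand_i, cand_j)], keys[cand_i], keys[cand_j])
    c(cand_i[o[1]], cand_j[o[1]])
  }
  ut <- which(upper.tri(r_mat), arr.ind = TRUE)
  seed <- pick(ut[, 1], ut[, 2])
  chain <- seed
  unplaced <- setdiff(seq_len(B), chain)
  while (length(unplaced) > 0) {
    ends <- c(chain[1], chain[length(chain)])
    cand_i <- rep(unplaced, times = 2)
    cand_j <- rep(ends, each = length(unplaced))
    best <- pick(cand_i, cand_j)
    if (best[2] == chain[1]) chain <- c(best[1], chain)
    else chain <- c(chain, best[1])
    unplaced <- setdiff(unplaced, best[1])
  }

  # ripple: permute sliding windows, accept strict improvements
  w <- min(window, B)
  pm <- perms(w)
  repeat {
    improved <- FALSE
    for (s in seq_len(B - w + 1)) {
      idx <- s:(s + w - 1)
      seg <- chain[idx]
      left <- if (s > 1) chain[s - 1] else NA
      right <- if (s + w <= B) chain[s + w] else NA
      score <- function(sg) {
        tot <- sum(r_mat[cbind(sg[-w], sg[-1])])
        if (!is.na(left)) tot <- tot + r_mat[left, sg[1]]
        if (!is.na(right)) tot <- tot + r_mat[sg[w], right]
        tot
      }
      base_sc <- score(seg)
      cand_sc <- apply(pm, 1, function(p) score(seg[p]))
      k <- which.min(cand_sc)
      if (cand_sc[k] < base_sc - 1e-12) {
        chain[idx] <- seg[pm[k, ]]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # canonical orientation: first key lexicographically <= last key
  if (keys[chain[1]] > keys[chain[length(chain)]]) chain <- rev(chain)
  chain
}

#' Convert an ordered group to cumulative cM positions
#'
#' Adjacent recombination fractions (capped at 0.4999) are transformed
#' with the chosen map function and accumulated from 0.
#'
#' @param ord integer order from [order_markers()].
#' @param r_mat pairwise r matrix among the same bins.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return numeric vector of cM positions along `ord`.
#' @export
assign_cm <- function(ord, r_mat, map_function = "kosambi") {
  if (length(ord) == 1) return(0)
  adj_r <- r_mat[cbind(ord[-length(ord)], ord[-1])]
  cumsum(c(0, rf_to_cm(adj_r, map_function)))
}

#' Build a genetic map from dichotomized calls
#'
#' Full mapping pass: all-pairs two-point estimation, single-linkage
#' grouping at the LOD threshold, co-segregation binning within groups,
#' ordering of bin representatives and cM assignment. Groups below
#' `min_size` markers are kept in the object (flagged small) but excluded
#' from the reported linkage groups.
#'
#' @param calls integer call matrix (loci x individuals).
#' @param params a `grouping_params`.
#' @param tp optional precomputed `two_point_table` for these calls.
#' @return an object of class `genetic_map`: list with
#'   \describe{
#'     \item{map}{data.frame per mapped marker: `locus`, `lg` (integer
#'       id), `bin`, `order`, `cM`.}
#'     \item{lgs}{data.frame per linkage group: `lg`, `n_loci`, `n_bins`,
#'       `length_cM`, `small`.}
#'     \item{lg_data}{per-LG list: ordered bin representative calls
#'       (`bin_calls`, bins x individuals in map order), `bin_of_marker`.}
#'     \item{params}{the `grouping_params` used.}
#'   }
#' @export
build_map <- function(calls, params = grouping_params(), tp = NULL) {
  stopifnot(is.matrix(calls))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("M%06d", seq_len(nrow(calls)))
  if (is.null(tp)) tp <- two_point_matrix(calls, params$min_shared)
  gr <- group_markers(tp, params)

  sizes <- lengths(gr$groups)
  ord_groups <- order(-sizes, vapply(gr$groups, min, ""))
  map_rows <- list()
  lg_rows <- list()
  lg_data <- list()
  lg_id <- 0L
  for (gi in ord_groups) {
    members <- gr$groups[[gi]]
    lg_id <- lg_id + 1L
    small <- length(members) < params$min_size
    gcalls <- calls[members, , drop = FALSE]
    bins <- bin_cosegregating(gcalls)
    reps <- members[!duplicated(bins)]
    bin_ids <- unique(bins)
    if (length(reps) >= 2) {
      sub_tp <- two_point_matrix(gcalls[reps, , drop = FALSE],
                                 params$min_shared)
      ord <- order_markers(sub_tp$r, sub_tp$lod, params$ripple_window)
      cm <- assign_cm(ord, sub_tp$r, params$map_function)
    } else {
      ord <- 1L
      cm <- 0
    }
    placed_bins <- bin_ids[ord]
    bin_pos <- stats::setNames(cm, placed_bins)
    bin_rank <- stats::setNames(seq_along(placed_bins), placed_bins)
    m_ord <- order(bin_rank[as.character(bins)], members)
    members_o <- members[m_ord]
    bins_o <- bins[m_ord]
    map_rows[[lg_id]] <- data.frame(
      locus = members_o, lg = lg_id,
      bin = unname(bin_rank[as.character(bins_o)]),
      order = seq_along(members_o),
      cM = unname(bin_pos[as.character(bins_o)]),
      stringsAsFactors = FALSE)
    lg_rows[[lg_id]] <- data.frame(
      lg = lg_id, n_loci = length(members), n_bins = length(bin_ids),
      length_cM = max(cm), small = small)
    lg_data[[lg_id]] <- list(
      bin_calls = gcalls[reps[ord], , drop = FALSE],
      bin_of_marker = stats::setNames(
        unname(bin_rank[as.character(bins_o)]), members_o))
  }
  structure(list(map = do.call(rbind, map_rows),
                 lgs = do.call(rbind, lg_rows),
                 lg_data = lg_data, params = params),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  big <- x$lgs[!x$lgs$small, ]
  cat(sprintf("genetic_map: %d LGs (>= %d markers), %d small groups\n",
              nrow(big), x$params$min_size, sum(x$lgs$small)))
  cat(sprintf("  %d markers in %d bins, total length %.1f cM (large LGs)\n",
              sum(big$n_loci), sum(big$n_bins), sum(big$length_cM)))
  invisible(x)
}

#' Total length of the reported linkage groups
#'
#' @param map a `genetic_map`.
#' @param include_small include groups below `min_size` (default FALSE).
#' @return total map length in cM.
#' @export
map_length <- function(map, include_small = FALSE) {
  stopifnot(inherits(map, "genetic_map"))
  lgs <- if (include_small) map$lgs else map$lgs[!map$lgs$small, ]
  sum(lgs$length_cM)
}
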