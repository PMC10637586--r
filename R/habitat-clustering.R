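## Habitat clustering: k-means on (intensity, entropy) voxel features, with
## consensus clustering over resampled voxels to choose the number of
## habitats, and per-patient segmentation at the chosen k with a
## deterministic cross-patient label alignment (ascending centroid
## intensity).

#' k-means with k-means++ seeding
#'
#' Lloyd's algorithm (via [stats::kmeans()]) started from k-means++ centres,
#' repeated over `nstart` seeded restarts; the restart with the lowest
#' within-cluster sum of squares wins.
#'
#' @param x numeric matrix (n x p) of features, n >= k
#' @param k number of clusters
#' @param seed integer seed
#' @param nstart number of restarts
#' @param iter_max Lloyd iteration cap
#' @return list with `labels`, `centroids`, `wcss`
#' @export
kmeans_voxels <- function(x, k, seed = 1L, nstart = 10L, iter_max = 300L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (n < k) stopf("fewer points (%d) than clusters (%d)", n, k)
  if (any(!is.finite(x))) stopf("features must be finite")
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1)
    return(list(labels = rep(1L, n), centroids = ctr,
                wcss = sum(sweep(x, 2, ctr[1, ])^2)))
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      init <- x[kmeanspp_init(x, k), , drop = FALSE]
      ## Lloyd can empty a cluster mid-run (or k-means++ can draw duplicate
      ## centres on degenerate data), which stats::kmeans treats as an
      ## error; such restarts are simply redrawn.
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = init, iter.max = iter_max,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
    }
  })
  if (is.null(best)) {
    distinct <- unique(x)
    if (nrow(distinct) <= k) {
      ## fewer distinct points than clusters: the optimum puts each
      ## distinct point in its own cluster
      labels <- match(apply(x, 1, paste, collapse = "\r"),
                      apply(distinct, 1, paste, collapse = "\r"))
      return(list(labels = as.integer(labels), centroids = distinct,
                  wcss = 0))
    }
    best <- with_seed(derive_seed(seed, "fallback"),
                      suppressWarnings(kmeans(x, centers = k,
                                              iter.max = iter_max,
                                              nstart = nstart)))
  }
  list(labels = as.integer(best$cluster),
       centroids = unname(best$centers), wcss = best$tot.withinss)
}

## k-means++ seeding: first centre uniform, then proportional to squared
## distance from the nearest chosen centre. Returns row indices.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- integer(k)
  centres[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centres[1], ])^2)
  for (c in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      centres[(c + 1):k] <- sample.int(n, k - c)
      break
    }
    centres[c + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centres[c + 1], ])^2))
  }
  centres
}

#' Consensus-clustering selection of the number of habitats
#'
#' For each candidate k, voxels are repeatedly subsampled (without
#' replacement, at `item_fraction`) and clustered; the consensus of a voxel
#' pair is the fraction of co-samplings in which they were co-clustered.
#' Stability is summarised two ways from the empirical CDF of the
#' upper-triangle consensus values: the area under the CDF with its
#' relative gain per k (the classical delta-area curve, whose "sharp
#' decrease" marks the loss of separability), and the proportion of
#' ambiguous clustering (PAC) — the CDF mass between `pac_window`. The
#' default rule picks k* as the last k of the first contiguous run of
#' unambiguous candidates (PAC at or below `pac_threshold`): consensus
#' entries of any k matching true structure concentrate at 0/1, PAC jumps
#' as soon as clusters start being split inconsistently, and restricting to
#' the first stable run guards against the spurious PAC dip at very large k
#' where most pairs are simply never co-clustered. `rule = "delta"` instead
#' applies the delta-area threshold directly.
#'
#' @param features n x 2 matrix/data.frame of z-scored voxel features
#' @param k_range candidate cluster numbers (default 2:10)
#' @param reps resampling replicates per k
#' @param item_fraction fraction of items sampled per replicate
#' @param seed integer seed
#' @param max_items cap on pooled items; larger inputs are subsampled (seeded)
#' @param rule `"pac"` (default) or `"delta"`
#' @param pac_threshold maximum PAC for a k to count as stable
#' @param pac_window consensus interval treated as ambiguous
#' @param delta_area_threshold relative area-gain cutoff for `rule="delta"`
#' @param nstart k-means restarts inside each replicate
#' @return a `consensus_result` with per-k consensus values, `areas`,
#'   `delta_area`, `pac` and the chosen `k_star`
#' @export
consensus_select_k <- function(features, k_range = 2:10, reps = 1000L,
                               item_fraction = 0.8, seed = 1L,
                               max_items = 5000L,
                               rule = c("pac", "delta"),
                               pac_threshold = 0.1,
                               pac_window = c(0.1, 0.9),
                               delta_area_threshold = 0.05,
                               nstart = 1L) {
  x <- as.matrix(features)
  rule <- match.arg(rule)
  if (reps < 2) stopf("reps must be >= 2")
  if (item_fraction <= 0 || item_fraction > 1)
    stopf("item_fraction must lie in (0, 1]")
  if (nrow(x) > max_items) {
    keep <- with_seed(derive_seed(seed, "item-cap"),
                      sample.int(nrow(x), max_items))
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x)
  m <- max(2L, round(item_fraction * n))
  n_pairs <- n * (n - 1) / 2
  areas <- pac <- numeric(length(k_range))
  cdfs <- vector("list", length(k_range))
  missing_any <- FALSE
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    M <- matrix(0, n, n)
    S <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      rs <- derive_seed(seed, "rep", k, r)
      idx <- with_seed(rs, sample.int(n, m))
      fit <- kmeans_voxels(x[idx, , drop = FALSE], min(k, m),
                           seed = derive_seed(rs, "km"), nstart = nstart,
                           iter_max = 50L)
      ord <- order(idx)
      cpp_consensus_accumulate(M, S, idx[ord] - 1L, fit$labels[ord])
    }
    seen <- which(S > 0)               # only the upper triangle is filled
    cons <- M[seen] / S[seen]
    if (length(seen) < n_pairs) missing_any <- TRUE
    cdfs[[ki]] <- cons
    areas[ki] <- cdf_area(cons)
    pac[ki] <- mean(cons > pac_window[1] & cons < pac_window[2])
  }
  if (missing_any)
    warning("some item pairs were never co-sampled; excluded from the CDF")
  if (any(diff(areas) < -1e-6))
    warning("consensus CDF area decreased with k; results may be unstable")
  delta <- c(areas[1], diff(areas) / pmax(areas[-length(areas)], 1e-12))
  k_star <- if (rule == "pac") {
    ## the last k of the FIRST contiguous stable run: at very large k most
    ## pairs are simply never co-clustered, consensus piles up near zero
    ## and PAC can dip back under the threshold spuriously
    stable <- pac <= pac_threshold
    if (any(stable)) {
      first <- which(stable)[1]
      run_end <- first
      while (run_end < length(stable) && stable[run_end + 1])
        run_end <- run_end + 1
      k_range[run_end]
    } else k_range[1]
  } else {
    big <- which(delta >= delta_area_threshold)
    if (length(big)) k_range[max(big)] else k_range[1]
  }
  structure(list(k_range = k_range, areas = areas, delta_area = delta,
                 pac = pac, k_star = k_star, consensus_values = cdfs,
                 n_items = n, reps = reps, item_fraction = item_fraction,
                 rule = rule, pac_threshold = pac_threshold,
                 delta_area_threshold = delta_area_threshold, seed = seed),
            class = "consensus_result")
}

## Area under the empirical CDF of consensus values over [0, 1].
cdf_area <- function(v) {
  if (!length(v)) return(NA_real_)
  g <- sort(unique(c(0, v, 1)))
  F <- ecdf(v)
  sum(diff(g) * F(g[-length(g)]))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k* = %d (items %d, reps %d)\n",
              x$k_star, x$n_items, x$reps))
  print(data.frame(k = x$k_range, area = round(x$areas, 4),
                   delta_area = round(x$delta_area, 4),
                   pac = round(x$pac, 4)), row.names = FALSE)
  invisible(x)
}

#' Segment one patient into habitats
#'
#' Runs per-patient k-means with `k_star` clusters on the z-scored
#' (intensity, entropy) features, then relabels the clusters so the habitat
#' index increases with the cluster's mean raw intensity — the deterministic
#' rule that makes "habitat h" comparable across patients.
#'
#' @param table the patient's voxel table
#' @param k_star number of habitats
#' @param transform cohort-level `voxel_zscore` transform
#' @param seed integer seed
#' @param dims grid dimensions for the output map
#' @return a `habitat_map`: integer array (0 background, 1..k habitats) with
#'   per-habitat voxel counts and feature-space centroids attached
#' @export
segment_patient <- function(table, k_star, transform, seed = 1L,
                            dims = NULL) {
  if (nrow(table) < k_star)
    stopf("patient %s has %d voxels, fewer than k = %d",
          table$patient_id[1], nrow(table), k_star)
  tz <- apply_voxel_zscore(table, transform)
  fit <- kmeans_voxels(as.matrix(tz[, c("z_intensity", "z_entropy")]),
                       k_star, seed = seed)
  mean_int <- vapply(seq_len(k_star), function(c)
    mean(table$intensity[fit$labels == c]), numeric(1))
  relabel <- match(seq_len(k_star), order(mean_int))
  labels <- relabel[fit$labels]
  if (is.null(dims)) dims <- c(max(table$i), max(table$j), max(table$k))
  map <- array(0L, dims)
  map[cbind(table$i, table$j, table$k)] <- labels
  structure(map,
            counts = tabulate(labels, k_star),
            centroids = fit$centroids[order(mean_int), , drop = FALSE],
            class = c("habitat_map", class(map)))
}
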