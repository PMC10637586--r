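## IBSI-style feature families. Each function turns a region's voxel values
## (continuous `x`, discretised `g` in 1..ng) or a texture matrix from the
## C++ kernels into a named numeric vector. Degenerate regions (a single
## gray level) take the conventional limits noted inline, so matrices never
## emit NaN.

feps <- .Machine$double.eps

#' First-order intensity statistics of a region
#'
#' The 18 standard first-order features; `Entropy` and `Uniformity` use the
#' fixed-bin-width discretisation shared with the texture families.
#'
#' @param x numeric vector of region voxel values
#' @param g integer vector of discretised gray levels (1..ng)
#' @param ng number of gray levels
#' @param voxel_volume physical voxel volume in mm^3
#' @return named numeric vector
#' @export
firstorder_features <- function(x, g, ng, voxel_volume = 1) {
  p <- tabulate(g, ng) / length(g)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  rx <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p + feps)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rx - mean(rx))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' Morphological (shape) features of a binary region
#'
#' Voxel-based shape descriptors. Surface area uses a Crofton-corrected
#' boundary-face estimator (sum of exposed face areas scaled by 2/3), which
#' converges to the true area for smooth bodies where the raw face count
#' overestimates by ~3/2; volume is voxel-count volume. Axis lengths come
#' from the principal components of the voxel-centre coordinates.
#'
#' @param mask logical 3D array
#' @param spacing voxel spacing in mm
#' @return named numeric vector of 14 features
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  n <- sum(mask)
  if (n == 0) stopf("empty region")
  vv <- prod(spacing)
  V <- n * vv
  d <- dim(mask)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  A_faces <- 0
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    idx <- vector("list", 3)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    src <- idx
    src[[axis]] <- pmin(pmax(idx[[axis]] + s, 1L), d[axis])
    nb <- mask[src[[1]], src[[2]], src[[3]]]
    edge <- idx[[axis]] + s < 1L | idx[[axis]] + s > d[axis]
    if (any(edge)) {
      sl <- idx
      sl[[axis]] <- which(edge)
      tmp <- array(FALSE, d)
      tmp[sl[[1]], sl[[2]], sl[[3]]] <- TRUE
      nb[tmp] <- FALSE
    }
    A_faces <- A_faces + sum(mask & !nb) * face_area[axis]
  }
  A <- A_faces * 2 / 3
  coords <- which_voxels(mask)
  mm <- sweep(coords, 2, c(1, 1, 1)) * rep(spacing, each = nrow(coords))
  bnd <- mask & boundary_voxels(mask)
  bc <- which_voxels(if (any(bnd)) bnd else mask)
  bmm <- sweep(bc, 2, c(1, 1, 1)) * rep(spacing, each = nrow(bc))
  if (nrow(bmm) > 2000) {
    keep <- unique(round(seq(1, nrow(bmm), length.out = 2000)))
    bmm <- bmm[keep, , drop = FALSE]
  }
  max_d <- function(pts) {
    if (nrow(pts) < 2) return(0)
    max(dist(pts))
  }
  by_plane <- function(fixed_axis) {
    ## largest in-plane diameter across all planes orthogonal to fixed_axis
    groups <- split.data.frame(bmm, bc[seq_len(nrow(bmm)), fixed_axis])
    max(vapply(groups, function(p)
      max_d(p[, -fixed_axis, drop = FALSE]), numeric(1)))
  }
  ev <- if (nrow(mm) > 1) {
    e <- eigen(stats::cov(mm), symmetric = TRUE, only.values = TRUE)$values
    pmax(e, 0)
  } else c(0, 0, 0)
  R_equiv <- (3 * V / (4 * pi))^(1 / 3)
  c(VoxelVolume = V,
    MeshVolume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = (pi^(1 / 3) * (6 * V)^(2 / 3)) / A,
    Maximum3DDiameter = max_d(bmm),
    Maximum2DDiameterSlice = by_plane(3),
    Maximum2DDiameterColumn = by_plane(2),
    Maximum2DDiameterRow = by_plane(1),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

## GLCM features for one normalised co-occurrence matrix P (ng x ng).
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  ## diagonal/cross-diagonal distributions
  pxmy <- vapply(0:(ng - 1), function(kk) sum(P[abs(i - j) == kk]),
                 numeric(1))          # |i-j| = 0..ng-1
  pxpy <- vapply(2:(2 * ng), function(kk) sum(P[i + j == kk]), numeric(1))
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  DA <- sum(kd * pxmy)
  HXY <- -sum(P * log2(P + feps))
  pxpy_ij <- outer(px, py)
  HXY1 <- -sum(P * log2(pxpy_ij + feps))
  HXY2 <- -sum(pxpy_ij * log2(pxpy_ij + feps))
  HX <- -sum(px * log2(px + feps)); HY <- -sum(py * log2(py + feps))
  corr <- if (sx > 0 && sy > 0)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  mcc <- glcm_mcc(P, px, py)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  offd <- abs(i - j) > 0
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(pxmy * log2(pxmy + feps)),
    DifferenceVariance = sum((kd - DA)^2 * pxmy),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offd] / (i - j)[offd]^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * pxpy),
    SumEntropy = -sum(pxpy * log2(pxpy + feps)),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc)
}

## Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
## Q(i,j) = sum_k P(i,k) P(j,k) / (px_i py_k). 1 for degenerate matrices.
glcm_mcc <- function(P, px, py) {
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  Pk <- P[keep, keep, drop = FALSE]
  pxk <- px[keep]; pyk <- py[keep]
  Q <- matrix(0, nrow(Pk), nrow(Pk))
  for (kk in seq_len(ncol(Pk))) {
    if (pyk[kk] <= 0) next
    Q <- Q + outer(Pk[, kk] / pxk, Pk[, kk]) / pyk[kk]
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2) return(1)
  sqrt(pmax(min(ev[2], 1), 0))
}

#' @rdname extract_region
#' @keywords internal
glcm_features <- function(cube) {
  ng <- dim(cube)[1]
  dirs <- dim(cube)[3]
  acc <- NULL; used <- 0
  for (d in seq_len(dirs)) {
    P <- matrix(cube[, , d], ng, ng)
    tot <- sum(P)
    if (tot <= 0) next
    f <- glcm_features_one(P / tot)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  if (used == 0) return(glcm_features_one(matrix(1, 1, 1)) * 0)
  acc / used
}

## Shared run-length / size-zone style statistics: counts matrix R with gray
## level on rows, run length (or zone size / dependence) on columns.
rl_stats <- function(R, np, prefix_small, prefix_large, size_name) {
  nr <- sum(R)
  if (nr == 0) return(NULL)
  ii <- row(R); jj <- col(R)
  p <- R / nr
  gl <- rowSums(R); sz <- colSums(R)
  mu_i <- sum(ii * p); mu_j <- sum(jj * p)
  out <- c(
    sum(R / jj^2) / nr,                       # small/short emphasis
    sum(R * jj^2) / nr,                       # large/long emphasis
    sum(gl^2) / nr,                           # gray-level non-uniformity
    sum(gl^2) / nr^2,                         # ... normalised
    sum(sz^2) / nr,                           # size non-uniformity
    sum(sz^2) / nr^2,                         # ... normalised
    nr / np,                                  # percentage
    sum((ii - mu_i)^2 * p),                   # gray-level variance
    sum((jj - mu_j)^2 * p),                   # size variance
    -sum(p * log2(p + feps)),                 # entropy
    sum(R / ii^2) / nr,                       # low gray-level emphasis
    sum(R * ii^2) / nr,                       # high gray-level emphasis
    sum(R / (ii^2 * jj^2)) / nr,
    sum(R * ii^2 / jj^2) / nr,
    sum(R * jj^2 / ii^2) / nr,
    sum(R * ii^2 * jj^2) / nr)
  names(out) <- c(paste0(prefix_small, "Emphasis"),
                  paste0(prefix_large, "Emphasis"),
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  paste0(size_name, "NonUniformity"),
                  paste0(size_name, "NonUniformityNormalized"),
                  paste0(size_name, "Percentage"),
                  "GrayLevelVariance", paste0(size_name, "Variance"),
                  paste0(size_name, "Entropy"),
                  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                  paste0(prefix_small, "LowGrayLevelEmphasis"),
                  paste0(prefix_small, "HighGrayLevelEmphasis"),
                  paste0(prefix_large, "LowGrayLevelEmphasis"),
                  paste0(prefix_large, "HighGrayLevelEmphasis"))
  out
}

#' @keywords internal
glrlm_features <- function(cube, np) {
  dirs <- dim(cube)[3]
  acc <- NULL; used <- 0
  for (d in seq_len(dirs)) {
    R <- matrix(cube[, , d], dim(cube)[1], dim(cube)[2])
    f <- rl_stats(R, np, "ShortRun", "LongRun", "RunLength")
    if (is.null(f)) next
    names(f)[names(f) == "RunLengthPercentage"] <- "RunPercentage"
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  acc / max(used, 1)
}

#' @keywords internal
glszm_features <- function(zones, ng, np) {
  if (!length(zones$gray)) return(NULL)
  maxs <- max(zones$size)
  R <- matrix(0, ng, maxs)
  for (q in seq_along(zones$gray))
    R[zones$gray[q], zones$size[q]] <- R[zones$gray[q], zones$size[q]] + 1
  f <- rl_stats(R, np, "SmallArea", "LargeArea", "Zone")
  names(f)[names(f) == "ZonePercentage"] <- "ZonePercentage"
  f
}

#' @keywords internal
gldm_features <- function(D) {
  nz <- sum(D)
  ii <- row(D); jj <- col(D)   # jj = dependence + 1
  p <- D / nz
  gl <- rowSums(D); dep <- colSums(D)
  mu_i <- sum(ii * p); mu_j <- sum(jj * p)
  c(SmallDependenceEmphasis = sum(D / jj^2) / nz,
    LargeDependenceEmphasis = sum(D * jj^2) / nz,
    GrayLevelNonUniformity = sum(gl^2) / nz,
    DependenceNonUniformity = sum(dep^2) / nz,
    DependenceNonUniformityNormalized = sum(dep^2) / nz^2,
    GrayLevelVariance = sum((ii - mu_i)^2 * p),
    DependenceVariance = sum((jj - mu_j)^2 * p),
    DependenceEntropy = -sum(p * log2(p + feps)),
    LowGrayLevelEmphasis = sum(D / ii^2) / nz,
    HighGrayLevelEmphasis = sum(D * ii^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (ii^2 * jj^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * ii^2 / jj^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * jj^2 / ii^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * ii^2 * jj^2) / nz)
}

#' @keywords internal
ngtdm_features <- function(s, n) {
  N <- sum(n)
  p <- n / N
  lev <- seq_along(p)
  act <- p > 0
  ngp <- sum(act)
  ps <- sum(p * s)
  pair_i <- rep(lev[act], each = ngp)
  pair_j <- rep(lev[act], times = ngp)
  p_i <- p[pair_i]; p_j <- p[pair_j]
  contrast <- if (ngp > 1)
    (sum(p_i * p_j * (pair_i - pair_j)^2) / (ngp * (ngp - 1))) * (sum(s) / N)
  else 0
  busy_den <- sum(abs(pair_i * p_i - pair_j * p_j))
  complexity <- sum(abs(pair_i - pair_j) *
                      (p_i * s[pair_i] + p_j * s[pair_j]) / (p_i + p_j)) / N
  strength_num <- sum((p_i + p_j) * (pair_i - pair_j)^2)
  c(Coarseness = if (ps > 0) 1 / ps else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) ps / busy_den else 0,
    Complexity = complexity,
    Strength = if (sum(s) > 0) strength_num / sum(s) else 0)
}
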