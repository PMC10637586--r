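test_that("first-order statistics match direct computation on masked voxels", {
  ph <- generate_phantom(small_phantom_spec(seed = 19))
  nv <- normalize_grayscale(ph$volume, ph$mask)
  f <- extract_region(nv, ph$mask,
                      extraction_config(families = "firstorder",
                                        filters = "original"))
  x <- nv$data[ph$mask]
  expect_equal(f[["original_firstorder_Mean"]], mean(x), tolerance = 1e-9)
  expect_equal(f[["original_firstorder_Median"]], median(x),
               tolerance = 1e-9)
  expect_equal(f[["original_firstorder_Minimum"]], min(x), tolerance = 1e-9)
  expect_equal(f[["original_firstorder_Maximum"]], max(x), tolerance = 1e-9)
  expect_equal(f[["original_firstorder_Variance"]],
               mean((x - mean(x))^2), tolerance = 1e-9)
  expect_equal(f[["original_firstorder_Energy"]], sum(x^2), tolerance = 1e-6)
})

test_that("constant regions degenerate exactly", {
  x <- array(0, c(8, 8, 4))
  m <- array(FALSE, c(8, 8, 4)); m[3:6, 3:6, 2:3] <- TRUE
  x[m] <- 42
  f <- extract_region(volume(x), m,
                      extraction_config(families = c("firstorder", "glcm"),
                                        filters = "original"))
  expect_equal(f[["original_firstorder_Variance"]], 0)
  expect_equal(f[["original_firstorder_Entropy"]], 0, tolerance = 1e-9)
  expect_equal(f[["original_glcm_Contrast"]], 0)
  expect_equal(f[["original_glcm_JointEntropy"]], 0, tolerance = 1e-9)
})

test_that("GLCM joint entropy matches exhaustive pair counting on a fixture", {
  ## 3 x 3 x 1 region with printed values; bin width 1 keeps levels distinct
  vals <- matrix(c(1, 2, 2,
                   3, 1, 1,
                   2, 3, 1), 3, 3, byrow = TRUE)
  x <- array(0, c(3, 3, 1)); x[, , 1] <- vals
  m <- array(TRUE, c(3, 3, 1))
  f <- extract_region(volume(x), m,
                      extraction_config(bin_width = 1, families = "glcm",
                                        filters = "original", min_region = 1))
  ## brute-force: enumerate ordered co-occurrences over the 13 direction
  ## pairs (symmetric), per direction, then average the per-direction
  ## joint entropies
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1),
                c(0,1,-1), c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  g <- vals  # already 1..3
  ents <- c()
  for (d in seq_len(nrow(dirs))) {
    counts <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      ii <- i + dirs[d, 1]; jj <- j + dirs[d, 2]
      if (dirs[d, 3] != 0) next
      if (ii >= 1 && ii <= 3 && jj >= 1 && jj <= 3) {
        a <- g[i, j]; b <- g[ii, jj]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
    if (sum(counts) == 0) next
    P <- counts / sum(counts)
    ents <- c(ents, -sum(P[P > 0] * log2(P[P > 0])))
  }
  expect_equal(f[["original_glcm_JointEntropy"]], mean(ents),
               tolerance = 1e-10)
})

test_that("sphericity of a discretised sphere approaches 1", {
  d <- c(41, 41, 41)
  ctr <- (d - 1) / 2
  ax <- lapply(1:3, function(a) seq_len(d[a]) - 1 - ctr[a])
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  mask <- sqrt(X^2 + Y^2 + Z^2) <= 15
  sh <- shape_features(mask, c(1, 1, 1))
  expect_lt(abs(sh[["Sphericity"]] - 1), 0.05)
  expect_equal(sh[["VoxelVolume"]], sum(mask))
  expect_equal(sh[["Maximum3DDiameter"]], 30, tolerance = 0.1)
  expect_equal(sh[["Elongation"]], 1, tolerance = 0.05)
})

test_that("texture features are shift-invariant under fixed-bin-width", {
  ph <- generate_phantom(small_phantom_spec(seed = 20))
  nv <- normalize_grayscale(ph$volume, ph$mask)
  cfg <- extraction_config(families = c("glcm", "glrlm", "glszm",
                                        "ngtdm", "gldm"),
                           filters = "original")
  f1 <- extract_region(nv, ph$mask, cfg)
  f2 <- extract_region(volume(nv$data + 100, nv$spacing), ph$mask, cfg)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("wavelet decomposition yields 8 sub-bands and LoG adds columns", {
  ph <- generate_phantom(small_phantom_spec(seed = 21))
  nv <- normalize_grayscale(ph$volume, ph$mask)
  wl <- wavelet_decompose(nv$data)
  expect_length(wl, 8)
  expect_setequal(names(wl), c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH",
                               "LHH", "HHH"))
  expect_identical(dim(wl$HHH), dim(nv$data))

  base <- extract_region(nv, ph$mask,
                         extraction_config(families = c("firstorder", "glcm"),
                                           filters = "original"))
  one_sig <- extract_region(nv, ph$mask,
                            extraction_config(families = c("firstorder",
                                                           "glcm"),
                                              filters = c("original", "log"),
                                              log_sigmas = 2))
  two_sig <- extract_region(nv, ph$mask,
                            extraction_config(families = c("firstorder",
                                                           "glcm"),
                                              filters = c("original", "log"),
                                              log_sigmas = c(2, 3)))
  per_image <- length(base)   # non-shape features per filter image
  expect_equal(length(one_sig) - length(base), per_image)
  expect_equal(length(two_sig) - length(one_sig), per_image)
})

test_that("cohort extraction is deterministic with aligned rows", {
  co <- generate_cohort(cohort_spec(n_train = 3, n_test = 2, seed = 3),
                        small_phantom_spec())
  cfg <- extraction_config(families = c("firstorder", "glcm"),
                           filters = "original")
  prep <- lapply(co$cases, function(case) {
    nv <- normalize_grayscale(case$volume, case$mask)
    tab <- build_voxel_table(nv, entropy_map(nv, case$mask), case$mask,
                             case$id)
    list(id = case$id, volume = nv, mask = case$mask,
         mask_r2 = case$mask_r2, table = tab)
  })
  tr <- fit_voxel_zscore(lapply(prep, `[[`, "table"))
  maps <- lapply(prep, function(p)
    segment_patient(p$table, 3, tr, seed = 1, dims = dim(p$volume$data)))
  mats <- extract_cohort(prep, maps, 3, cfg)
  expect_named(mats, c("whole", "habitat1", "habitat2", "habitat3"))
  for (mname in names(mats)) expect_equal(nrow(mats[[mname]]), 5)
  expect_equal(rownames(mats$whole), rownames(mats$habitat2))
  prov <- attr(mats$habitat1, "provenance")
  expect_true(all(prov$family %in% c("firstorder", "glcm", "shape")))
  expect_false(any(duplicated(prov$column)))

  mats2 <- extract_cohort(prep, maps, 3, cfg)
  expect_identical(mats$whole, mats2$whole)
  expect_identical(mats$habitat3, mats2$habitat3)
})

test_that("undersized regions are skipped with a recorded reason", {
  ph <- generate_phantom(small_phantom_spec(seed = 5))
  nv <- normalize_grayscale(ph$volume, ph$mask)
  tiny <- array(FALSE, dim(ph$mask))
  tiny[which(ph$mask)[1:4]] <- TRUE
  expect_error(extract_region(nv, tiny, extraction_config()), "below")
  expect_error(extract_region(nv, array(FALSE, dim(ph$mask)),
                              extraction_config()), "empty")
})
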