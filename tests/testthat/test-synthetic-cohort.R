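test_that("phantom generation honours the spec's distributional parameters", {
  sds <- c(5, 5, 5)
  spec <- small_phantom_spec(seed = 11, habitat_intensity_sds = sds,
                             habitat_smoothness = c(0, 0, 0))
  ph <- generate_phantom(spec)
  expect_true(all(ph$truth[ph$mask] %in% 1:3))
  expect_true(all(ph$truth[!ph$mask] == 0))
  for (h in 1:3) {
    v <- ph$volume$data[ph$truth == h]
    n <- length(v)
    expect_gt(n, 50)
    expect_lt(abs(mean(v) - spec$habitat_intensity_means[h]),
              3 * sds[h] / sqrt(n))
  }
  ## fractions close to 1/3 each (quantile cuts are voxel-granular)
  frac <- tabulate(ph$truth[ph$mask], 3) / sum(ph$mask)
  expect_true(all(abs(frac - 1 / 3) < 0.05))
})

test_that("degenerate single-habitat, zero-noise phantom is constant", {
  spec <- small_phantom_spec(n_habitats = 1, habitat_fractions = 1,
                             habitat_intensity_means = 120,
                             habitat_intensity_sds = 0,
                             habitat_smoothness = 0)
  ph <- generate_phantom(spec)
  expect_true(all(ph$volume$data[ph$mask] == 120))
  expect_true(all(ph$truth[ph$mask] == 1L))
})

test_that("identical spec and seed give bit-identical phantoms", {
  a <- generate_phantom(small_phantom_spec(seed = 5))
  b <- generate_phantom(small_phantom_spec(seed = 5))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(small_phantom_spec(seed = 6))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("a tumour larger than the grid is rejected", {
  expect_error(small_phantom_spec(tumour_axes = c(50, 50, 50)), "larger")
  expect_error(small_phantom_spec(habitat_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(small_phantom_spec(habitat_intensity_sds = c(-1, 5, 5)),
               ">= 0")
})

test_that("habitat truth maps are spatially contiguous shells", {
  ph <- generate_phantom(small_phantom_spec(seed = 2))
  ## shells: habitat index must be monotone in ellipsoid radius
  geo <- (function(spec) {
    d <- spec$grid_shape; sp <- spec$voxel_spacing
    ctr <- (d - 1) * sp / 2
    ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a] - ctr[a])
    X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
    Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    sqrt((X / spec$tumour_axes[1])^2 + (Y / spec$tumour_axes[2])^2 +
           (Z / spec$tumour_axes[3])^2)
  })(small_phantom_spec(seed = 2))
  r1 <- range(geo[ph$truth == 1])
  r3 <- range(geo[ph$truth == 3])
  expect_lt(r1[2], r3[1] + 1e-9)   # core radii all below rim radii
})

test_that("dice coefficient matches brute-force voxel counting", {
  set.seed(42)
  for (rep in 1:5) {
    a <- array(runif(4 * 4 * 3) > 0.5, c(4, 4, 3))
    b <- array(runif(4 * 4 * 3) > 0.5, c(4, 4, 3))
    inter <- 0
    for (i in 1:4) for (j in 1:4) for (k in 1:3)
      inter <- inter + (a[i, j, k] && b[i, j, k])
    expected <- if (sum(a) + sum(b) == 0) 1 else
      2 * inter / (sum(a) + sum(b))
    expect_equal(dice_coefficient(a, b), expected)
  }
  expect_equal(dice_coefficient(array(FALSE, c(2, 2, 2)),
                                array(FALSE, c(2, 2, 2))), 1)
})

test_that("mask perturbation is bounded and seeded", {
  ph <- generate_phantom(phantom_spec(seed = 3))  # 30 mm default tumour
  expect_identical(perturb_mask(ph$mask, 0), ph$mask)
  m1 <- perturb_mask(ph$mask, 1, seed = 9, spacing = c(1, 1, 3))
  expect_gt(dice_coefficient(ph$mask, m1), 0.9)
  expect_false(identical(m1, ph$mask))
  m2 <- perturb_mask(ph$mask, 2, seed = 9, spacing = c(1, 1, 3))
  expect_gte(dice_coefficient(ph$mask, m2), 0.85)
  expect_identical(perturb_mask(ph$mask, 1, seed = 9, spacing = c(1, 1, 3)),
                   m1)
  expect_error(perturb_mask(array(FALSE, c(3, 3, 3)), 1), "empty")
})

test_that("cohort generation is reproducible with conserved prevalence", {
  cs <- cohort_spec(n_train = 12, n_test = 6, label_prevalence = 0.5,
                    seed = 21)
  co <- generate_cohort(cs, small_phantom_spec())
  expect_length(co$cases, 18)
  expect_equal(sum(co$clinical$cohort == "train"), 12)
  expect_identical(
    co$clinical$label,
    generate_cohort(cs, small_phantom_spec())$clinical$label)
  ## prevalence within binomial noise (4 SD)
  expect_lt(abs(mean(co$clinical$label) - 0.5), 4 * sqrt(0.25 / 18))
  ## label-positive patients carry the planted shift in the signal habitat
  pos <- which(co$clinical$label == 1)[1]
  neg <- which(co$clinical$label == 0)[1]
  expect_true(!is.na(pos) && !is.na(neg))
})

test_that("cohort file tree round-trips through NIfTI", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(n_train = 2, n_test = 1, seed = 4)
  co <- generate_cohort(cs, small_phantom_spec(), dir = dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "spec.json")))
  p1 <- file.path(dir, co$clinical$patient_id[1])
  for (f in c("img.nii.gz", "mask_r1.nii.gz", "mask_r2.nii.gz",
              "truth.nii.gz"))
    expect_true(file.exists(file.path(p1, f)))
  case <- load_case(file.path(p1, "img.nii.gz"),
                    file.path(p1, "mask_r1.nii.gz"))
  expect_equal(case$volume$data, co$cases[[1]]$volume$data,
               tolerance = 1e-6)
  expect_equal(case$mask$data > 0, co$cases[[1]]$mask)
  expect_equal(case$volume$spacing, c(1, 1, 3))
})

test_that("angular-sector geometry partitions the mask into sectors", {
  spec <- small_phantom_spec(seed = 3, geometry = "sectors")
  ph <- generate_phantom(spec)
  frac <- tabulate(ph$truth[ph$mask], 3) / sum(ph$mask)
  expect_true(all(abs(frac - 1 / 3) < 0.05))
  ## sectors: habitat index is monotone in azimuth, not radius
  idx <- which(ph$mask, arr.ind = TRUE)
  ctr <- (dim(ph$mask) - 1) / 2 + 1
  theta <- atan2((idx[, 2] - ctr[2]) * 1, (idx[, 1] - ctr[1]) * 1)
  lab <- ph$truth[ph$mask]
  expect_lt(max(theta[lab == 1]), min(theta[lab == 3]) + 1e-9)
  expect_identical(ph$truth,
                   generate_phantom(small_phantom_spec(
                     seed = 3, geometry = "sectors"))$truth)
})
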