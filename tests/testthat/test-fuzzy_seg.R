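manual_stats <- function(mean, sd) {
  structure(list(mode = mean, mean = mean, sd = sd, bin_width = 1,
                 n_voxels = 1L), class = "wmh_stats")
}

test_that("seed detection keeps exactly the voxels at or above mean + k SD", {
  arr <- array(100, c(3, 3, 1))
  arr[1, 1, 1] <- 129
  arr[3, 3, 1] <- 131
  flair <- wmh_volume(arr)
  brain <- wmh_mask(array(TRUE, c(3, 3, 1)))
  seeds <- detect_seeds(flair, brain, manual_stats(100, 10), k = 3)
  expect_equal(seeds$threshold_used, 130)
  expect_equal(seeds$index, which(arr == 131))
  # at k = 2.5 the 129 voxel still fails but nothing above 125 does
  seeds25 <- detect_seeds(flair, brain, manual_stats(100, 10), k = 2.5)
  expect_setequal(seeds25$index, which(arr >= 125))
})

test_that("separated bright lesions yield separate seed labels", {
  ph <- ph_bright(noise_sd = 0)
  st <- compute_stats(ph$flair, ph$brain_mask)
  seeds <- detect_seeds(ph$flair, ph$brain_mask, st, k = 3)
  expect_gt(length(seeds$index), 0)
  expect_equal(max(seeds$label), 2L)  # two lesion spheres
  expect_setequal(seeds$index, which(ph$lesion_truth$data))
  # oracle: labelling matches flood fill on the seed voxel set
  sel <- array(FALSE, dim(ph$flair$data))
  sel[seeds$index] <- TRUE
  lab <- r_label_components(sel, 26L)
  expect_equal(max(lab), 2L)
})

test_that("seed voxels sit at connectivity 1 and the field stays in [0, 1]", {
  ph <- ph_bright(noise_sd = 5)
  st <- compute_stats(ph$flair, ph$brain_mask)
  seeds <- detect_seeds(ph$flair, ph$brain_mask, st, k = 3)
  conn <- fuzzy_connectivity(ph$flair, ph$brain_mask, seeds)
  expect_true(all(conn[seeds$index] == 1))
  expect_true(all(conn >= 0 & conn <= 1))
  expect_true(all(conn[!ph$brain_mask$data] == 0))
})

test_that("a neighbour at the kernel centre has affinity and connectivity 1", {
  arr <- array(c(100, 100), c(2, 1, 1))
  flair <- wmh_volume(arr)
  brain <- wmh_mask(array(TRUE, c(2, 1, 1)))
  seeds <- detect_seeds(flair, brain, manual_stats(90, 1), k = 1)
  conn <- fuzzy_connectivity(flair, brain, seeds, mu = 100, sigma = 10)
  expect_equal(as.vector(conn), c(1, 1))
})

test_that("a weak middle link caps the far end of a chain at its affinity", {
  # 1D chain, seed at one end; the two middle steps are built to have
  # affinity exactly 0.2 at mu = 100, sigma = 10, all other steps 1
  x <- 100 + 2 * sqrt(2 * 10^2 * log(5))
  arr <- array(c(100, 100, x, 100, 100), c(5, 1, 1))
  flair <- wmh_volume(arr)
  brain <- wmh_mask(array(TRUE, c(5, 1, 1)))
  seeds <- structure(list(coords = matrix(c(1L, 1L, 1L), 1),
                          label = 1L, index = 1L, threshold_used = 100),
                     class = "wmh_seeds")
  conn <- fuzzy_connectivity(flair, brain, seeds, mu = 100, sigma = 10)
  expect_equal(conn[3, 1, 1], 0.2, tolerance = 1e-12)
  expect_equal(conn[4, 1, 1], 0.2, tolerance = 1e-12)
  expect_equal(conn[5, 1, 1], 0.2, tolerance = 1e-12)
  expect_equal(conn[2, 1, 1], 1, tolerance = 1e-12)
  # oracle: exhaustive path enumeration on the chain
  oracle <- r_fuzzy_conn_enumerate(arr, array(TRUE, dim(arr)), 1L,
                                   mu = 100, sigma = 10, connectivity = 26)
  expect_equal(as.vector(conn), as.vector(oracle), tolerance = 1e-12)
})

test_that("best-first propagation equals exhaustive max-min enumeration on tiny grids", {
  set.seed(55)
  shapes <- list(c(2, 2, 2), c(3, 3, 1), c(2, 3, 1), c(4, 2, 1))
  for (trial in 1:12) {
    d <- shapes[[(trial - 1) %% length(shapes) + 1]]
    arr <- array(stats::runif(prod(d), 80, 120), d)
    region <- array(TRUE, d)
    region[sample(prod(d), 1)] <- trial %% 3 == 0  # sometimes knock one out
    seed_pool <- which(region)
    s <- sample(seed_pool, sample(1:2, 1))
    seeds <- structure(list(coords = arrayInd(s, d), label = seq_along(s),
                            index = s, threshold_used = 0),
                       class = "wmh_seeds")
    flair <- wmh_volume(arr)
    brain <- wmh_mask(region)
    conn <- fuzzy_connectivity(flair, brain, seeds, mu = 100, sigma = 15)
    oracle <- r_fuzzy_conn_enumerate(arr, region, s, 100, 15, 26)
    expect_equal(as.vector(conn), as.vector(oracle), tolerance = 1e-12)
  }
})

test_that("best-first propagation matches the spanning-tree bottleneck oracle on 3x3x3 grids", {
  skip_if_not_installed("igraph")
  set.seed(66)
  for (trial in 1:100) {
    d <- c(sample(2:3, 1), sample(2:3, 1), sample(2:3, 1))
    arr <- array(stats::runif(prod(d), 80, 120), d)
    region <- array(TRUE, d)
    s <- sample(prod(d), sample(1:3, 1))
    seeds <- structure(list(coords = arrayInd(s, d), label = seq_along(s),
                            index = s, threshold_used = 0),
                       class = "wmh_seeds")
    conn <- fuzzy_connectivity(wmh_volume(arr), wmh_mask(region), seeds,
                               mu = 100, sigma = 12)
    oracle <- r_fuzzy_conn_mst(arr, region, s, 100, 12, 26)
    expect_equal(as.vector(conn), as.vector(oracle), tolerance = 1e-10)
  }
})

test_that("bright well-defined lesions are recovered by the fuzzy segmenter", {
  ph <- ph_bright(noise_sd = 5)
  st <- compute_stats(ph$flair, ph$brain_mask)
  # lesions sit well beyond the mean + 3 SD seed bar
  expect_gt(2.6 * 100, seed_threshold(st, 3))
  res <- segment_fuzzy(ph$flair, ph$brain_mask)
  ov <- overlap(res$mask, ph$lesion_truth)
  expect_gte(ov$overlap_pct, 80)
  # all lesion-core voxels (above the seed threshold) are included
  core <- ph$lesion_truth$data & ph$flair$data >= res$threshold_used
  expect_true(all(res$mask$data[core]))
})

test_that("an image with nothing above mean + 3 SD yields an empty mask", {
  ph <- ph_noise_free(factor = 1.8)   # lesions at 180 < mean + 3 SD (~186)
  st <- compute_stats(ph$flair, ph$brain_mask)
  expect_lt(180, seed_threshold(st, 3))
  res <- segment_fuzzy(ph$flair, ph$brain_mask)
  expect_equal(n_voxels(res$mask), 0L)
  expect_equal(nrow(res$iterations), 0L)
})

test_that("lowering the seed bar never removes seeds and never shrinks the mask", {
  for (seed in c(1, 2, 3)) {
    ph <- ph_bright(noise_sd = 20, seed = seed, n_flow = 40)
    st <- compute_stats(ph$flair, ph$brain_mask)
    s30 <- detect_seeds(ph$flair, ph$brain_mask, st, k = 3.0)
    s25 <- detect_seeds(ph$flair, ph$brain_mask, st, k = 2.5)
    expect_true(all(s30$index %in% s25$index))
    f30 <- segment_fuzzy(ph$flair, ph$brain_mask, affinity_params(k_sd = 3.0))
    f25 <- segment_fuzzy(ph$flair, ph$brain_mask, affinity_params(k_sd = 2.5))
    expect_gte(n_voxels(f25$mask), n_voxels(f30$mask))
  }
})

test_that("with bright artifacts, the looser seed bar grows the mask but loses accuracy", {
  ph <- ph_bright(noise_sd = 20, seed = 1, n_flow = 40)
  f30 <- segment_fuzzy(ph$flair, ph$brain_mask, affinity_params(k_sd = 3.0))
  f25 <- segment_fuzzy(ph$flair, ph$brain_mask, affinity_params(k_sd = 2.5))
  expect_gt(n_voxels(f25$mask), n_voxels(f30$mask))
  o30 <- overlap(f30$mask, ph$lesion_truth)$overlap_pct
  o25 <- overlap(f25$mask, ph$lesion_truth)$overlap_pct
  expect_lt(o25, o30)
})

test_that("a small low-contrast lesion is missed by fuzzy growth but caught by thresholding", {
  shape <- 48
  ctr <- (shape + 1) / 2
  sp <- phantom_spec(shape = rep(shape, 3),
                     lesions = list(lesion_spec(rep(ctr, 3), 2.5, 1.55)),
                     noise_sd = 2, seed = 9)
  ph <- generate_phantom(sp)
  fuzzy <- segment_fuzzy(ph$flair, ph$brain_mask)
  expect_equal(n_voxels(fuzzy$mask), 0L)
  thr <- segment_threshold(ph$flair, ph$brain_mask)
  ov <- overlap(thr$mask, ph$lesion_truth)
  expect_gt(ov$overlap_pct, 90)
})

test_that("iteration is capped with a warning and the partial mask returned", {
  ph <- ph_bright(noise_sd = 20, seed = 3, n_flow = 40)
  expect_warning(
    res <- segment_fuzzy(ph$flair, ph$brain_mask,
                         affinity_params(max_iterations = 1)),
    "max_iterations")
  expect_s3_class(res$mask, "wmh_mask")
  expect_lte(nrow(res$iterations), 1L)
})

test_that("the iteration log accounts for every segmented voxel", {
  ph <- ph_bright(noise_sd = 10, seed = 5)
  res <- segment_fuzzy(ph$flair, ph$brain_mask)
  expect_equal(sum(res$iterations$n_added), n_voxels(res$mask))
  expect_true(all(diff(res$iterations$iteration) == 1))
  expect_lte(nrow(res$iterations), n_voxels(ph$brain_mask))
})

test_that("degenerate images and empty seed sets are rejected", {
  flat <- wmh_volume(array(50, c(6, 6, 6)))
  brain <- wmh_mask(array(TRUE, c(6, 6, 6)))
  expect_error(segment_fuzzy(flat, brain), "degenerate")
  empty_seeds <- structure(list(coords = matrix(integer(), 0, 3),
                                label = integer(), index = integer(),
                                threshold_used = 10),
                           class = "wmh_seeds")
  expect_error(fuzzy_connectivity(flat, brain, empty_seeds), "empty seed")
})
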