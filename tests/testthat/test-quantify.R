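test_that("nuclei counting handles blank, clean and touching cases", {
  # blank / constant image -> zero, not an error
  expect_equal(count_nuclei(matrix(5, 64, 64))$count, 0L)
  expect_equal(count_nuclei(matrix(0, 64, 64))$count, 0L)

  # 50 well-separated noiseless nuclei are enumerated exactly
  fld <- generate_field(monolayer_spec(n_cells = 50L, nucleus_radius_px = 6L,
                                       noise_sd = 0, seed = 4))
  nr <- count_nuclei(fld$images$nuclei)
  expect_equal(nr$count, 50L)
  expect_equal(nrow(nr$centers), 50L)
  expect_equal(max(nr$label_grid), 50L)

  # two blobs merged into one component are split by the distance-transform
  # watershed; oracle: the noiseless distance transform has two local maxima
  img <- matrix(0, 64, 64)
  for (ctr in list(c(32, 26), c(32, 38))) {
    for (r in 1:64) for (cl in 1:64) {
      img[r, cl] <- img[r, cl] +
        1000 * exp(-((r - ctr[1])^2 + (cl - ctr[2])^2) / (2 * 4^2))
    }
  }
  xs <- EBImage::gblur(EBImage::Image(img / max(img)), sigma = 2)
  mask <- EBImage::imageData(xs) > EBImage::otsu(xs, range = c(0, 1))
  expect_equal(max(EBImage::bwlabel(EBImage::Image(mask * 1))), 1)  # merged
  expect_equal(count_nuclei(img)$count, 2L)
})

test_that("grown band of an isolated pixel is the exact 317-point digital disk", {
  # brute-force lattice enumeration oracle
  n317 <- 0L
  for (dx in -10:10) for (dy in -10:10) {
    if (dx^2 + dy^2 <= 100) n317 <- n317 + 1L
  }
  expect_equal(n317, 317L)
  expect_equal(sum(disk_brush(10)), n317)

  m <- matrix(FALSE, 41, 41)
  m[21, 21] <- TRUE
  band <- tjscreen:::dilate_mask(m, disk_brush(10))
  expect_equal(sum(band), n317)
  # exactly the enumerated offsets
  got <- which(band, arr.ind = TRUE)
  expect_true(all((got[, 1] - 21)^2 + (got[, 2] - 21)^2 <= 100))
})

test_that("band across a straight membrane segment is 21 px thick", {
  m <- matrix(FALSE, 64, 64)
  m[32, ] <- TRUE
  band <- tjscreen:::dilate_mask(m, disk_brush(10))
  mid_cols <- 20:44
  expect_true(all(colSums(band)[mid_cols] == 21))
})

test_that("a single cell filling the field has no inter-cell outline", {
  fld <- generate_field(small_spec(seed = 2, n_cells = 1L, noise_sd = 0))
  nr <- count_nuclei(fld$images$nuclei)
  expect_equal(nr$count, 1L)
  seg <- segment_membranes(fld$images$cellmask, nr)
  expect_false(any(seg$outline_mask))
  expect_false(any(seg$band_mask))
  expect_false(seg$warning_flag)
})

test_that("zero nuclei yields an empty flagged segmentation", {
  seg <- segment_membranes(matrix(1000, 32, 32),
                           count_nuclei(matrix(0, 32, 32)))
  expect_true(seg$warning_flag)
  expect_false(any(seg$band_mask))
})

test_that("watershed labels and outline match ground truth on noiseless fields", {
  for (s in 1:3) {
    fld <- generate_field(noiseless_spec(seed = s, n_cells = 6L))
    nr <- count_nuclei(fld$images$nuclei)
    expect_equal(nr$count, 6L)
    seg <- segment_membranes(fld$images$cellmask, nr)
    near_boundary <- tjscreen:::dilate_mask(fld$truth$membrane_skeleton,
                                            disk_brush(2))
    agree <- label_agreement(fld$truth$cell_label_grid, seg$cell_label_grid,
                             exclude = near_boundary)
    expect_gte(agree, 0.99)
    # detected 1-px outline lies within 1 px (8-neighbour) of the skeleton
    expect_lte(max_chebyshev_to(seg$outline_mask, fld$truth$membrane_skeleton), 1)
  }
})

test_that("junction mask is empty on background and covers the skeleton at full integrity", {
  expect_false(any(junction_band(matrix(100, 64, 64))))

  fld <- generate_field(noiseless_spec(seed = 8, junction_integrity = 1))
  jb <- junction_band(fld$images$junction)
  grown_truth <- tjscreen:::dilate_mask(fld$truth$membrane_skeleton, disk_brush(10))
  expect_gte(sum(jb & grown_truth) / sum(grown_truth), 0.95)

  # morphology monotonicity: band never exceeds the dilated threshold mask
  mask <- tjscreen:::otsu_mask(fld$images$junction)
  expect_lte(sum(jb), sum(tjscreen:::dilate_mask(mask, disk_brush(10))))
})

test_that("metrics are invariant to intensity rescaling and covariant with pixel size", {
  fld <- generate_field(small_spec(seed = 12))
  m0 <- field_metrics(fld$images)

  scaled <- fld$images
  scaled$nuclei <- scaled$nuclei * 3.7
  scaled$cellmask <- scaled$cellmask * 3.7
  scaled$junction <- scaled$junction * 3.7
  m1 <- field_metrics(scaled)
  expect_equal(m1$nuclei_count, m0$nuclei_count)
  expect_equal(m1$membrane_area_um2, m0$membrane_area_um2)
  expect_equal(m1$junction_at_membrane_area_um2, m0$junction_at_membrane_area_um2)

  halved <- fld$images
  halved$pixel_size_um <- fld$images$pixel_size_um / 2
  m2 <- field_metrics(halved)
  expect_equal(m2$membrane_area_um2, m0$membrane_area_um2 / 4)
  expect_equal(m2$junction_at_membrane_area_um2,
               m0$junction_at_membrane_area_um2 / 4)
})

test_that("junction overlap area is bounded by the band area", {
  fld <- generate_field(small_spec(seed = 13, junction_integrity = 0.6))
  px2 <- fld$images$pixel_size_um^2
  nr <- count_nuclei(fld$images$nuclei)
  seg <- segment_membranes(fld$images$cellmask, nr)
  m <- field_metrics(fld$images)
  expect_lte(m$junction_at_membrane_area_um2, sum(seg$band_mask) * px2 + 1e-9)
  expect_gte(m$junction_at_membrane_area_um2, 0)
})

test_that("well aggregation follows the ratio-of-means convention", {
  fm <- function(count, mem, jun) {
    structure(list(nuclei_count = count, membrane_area_um2 = mem,
                   junction_at_membrane_area_um2 = jun, warning_flag = FALSE),
              class = "field_metrics")
  }
  # idempotent on identical fields
  w <- aggregate_well(rep(list(fm(5, 10, 4)), 16))
  expect_equal(w$mean_nuclei_count, 5)
  expect_equal(w$membrane_area_per_cell_um2, 2)
  expect_equal(w$junction_area_per_cell_um2, 0.8)
  expect_equal(w$n_fields, 16L)

  # arithmetic: areas {10, 20}, counts {5, 5} -> 15/5 = 3
  w2 <- aggregate_well(list(fm(5, 10, 10), fm(5, 20, 20)))
  expect_equal(w2$membrane_area_per_cell_um2, 3)

  # permutation symmetry
  fl <- list(fm(3, 9, 3), fm(7, 21, 14), fm(5, 10, 5))
  expect_equal(aggregate_well(fl), aggregate_well(rev(fl)))

  # mean-of-ratios alternative
  w3 <- aggregate_well(list(fm(2, 10, 2), fm(10, 10, 10)),
                       normalization = "mean_of_ratios")
  expect_equal(w3$membrane_area_per_cell_um2, mean(c(5, 1)))

  # zero-cell well is flagged, not silently NaN
  expect_warning(w4 <- aggregate_well(list(fm(0, 1, 1))), "undefined")
  expect_true(w4$undefined_per_cell)
  expect_true(is.na(w4$junction_area_per_cell_um2))
})

test_that("measured junction area tracks ground-truth integrity", {
  ratios <- vapply(1:4, function(s) {
    full <- field_metrics(generate_field(monolayer_spec(seed = s,
                                                        junction_integrity = 1))$images)
    half <- field_metrics(generate_field(monolayer_spec(seed = s,
                                                        junction_integrity = 0.5))$images)
    half$junction_at_membrane_area_um2 / full$junction_at_membrane_area_um2
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.1)
})
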