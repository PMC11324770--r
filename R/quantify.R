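#' Parameters of the image quantification pipeline
#'
#' Defaults follow the assay's published workflow: Gaussian smoothing and a
#' parameter-free Otsu threshold for nuclei; nuclei-seeded segmentation of
#' the *inverted* whole-cell channel to a 1-px membrane outline; outline
#' growth by a Euclidean disk of radius `grow_halfwidth_px` ("10 pixels on
#' either side of the identified membrane"); and a thickened junction mask
#' built threshold -> skeletonize -> dilate, mirroring the membrane
#' pipeline. Thresholds operate on max-normalised intensities and are
#' therefore invariant to rescaling all intensities by a positive constant.
#'
#' @param smooth_sigma_px Gaussian smoothing SD for the nuclei channel
#' @param min_area_px,max_area_px nuclei component area bounds (px)
#' @param min_separation_px local-maximum neighbourhood radius used when
#'   splitting touching nuclei on the distance transform
#' @param grow_halfwidth_px band half-width grown on either side of the
#'   1-px membrane outline (disk radius, px)
#' @param junction_min_area_px speck-removal threshold for the junction mask
#' @param junction_floor_mads robust background floor for the junction
#'   threshold, in median-absolute-deviations above the channel median;
#'   prevents the global threshold from collapsing into background noise on
#'   fields with little or no junction signal
#' @param junction_mode "skeletonize" (threshold -> skeletonize -> dilate,
#'   default) or "dilate" (threshold -> dilate); the source workflow is
#'   ambiguous between the two
#' @param normalization per-well normalisation convention,
#'   "ratio_of_means" (default; robust when a field has few cells) or
#'   "mean_of_ratios"
#' @param include_border whether image-border pixels of cells count as
#'   membrane outline (default FALSE: only inter-cell boundaries carry
#'   tight junctions)
#' @param propagate_lambda regularisation of the seeded region growing on
#'   the inverted whole-cell channel (small = intensity-driven)
#' @return list of class `quantify_params`
#' @export
quantify_params <- function(smooth_sigma_px = 2, min_area_px = 20,
                            max_area_px = 2000, min_separation_px = 3,
                            grow_halfwidth_px = 10L,
                            junction_min_area_px = 10,
                            junction_floor_mads = 8,
                            junction_mode = c("skeletonize", "dilate"),
                            normalization = c("ratio_of_means", "mean_of_ratios"),
                            include_border = FALSE,
                            propagate_lambda = 1e-4) {
  structure(list(
    smooth_sigma_px = smooth_sigma_px, min_area_px = min_area_px,
    max_area_px = max_area_px, min_separation_px = min_separation_px,
    grow_halfwidth_px = as.integer(grow_halfwidth_px),
    junction_min_area_px = junction_min_area_px,
    junction_floor_mads = junction_floor_mads,
    junction_mode = match.arg(junction_mode),
    normalization = match.arg(normalization),
    include_border = include_border,
    propagate_lambda = propagate_lambda), class = "quantify_params")
}

#' Segment and enumerate nuclei
#'
#' Gaussian smooth, global Otsu threshold, removal of components outside the
#' area bounds, then splitting of touching blobs by a distance-transform
#' watershed. An all-constant image yields count 0 (not an error).
#'
#' @param nuclei_channel intensity matrix
#' @param params a [quantify_params()]
#' @return list with `count`, `label_grid`, `centers` (n x 2 row/col)
#' @export
count_nuclei <- function(nuclei_channel, params = quantify_params()) {
  stopifnot(is.matrix(nuclei_channel), all(is.finite(nuclei_channel)))
  h <- nrow(nuclei_channel); w <- ncol(nuclei_channel)
  empty <- list(count = 0L, label_grid = matrix(0L, h, w),
                centers = matrix(numeric(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))))
  mx <- max(nuclei_channel)
  if (mx <= 0 || mx == min(nuclei_channel)) return(empty)
  xs <- EBImage::gblur(EBImage::Image(nuclei_channel / mx),
                       sigma = params$smooth_sigma_px)
  xs <- matrix(EBImage::imageData(xs), h, w)
  mask <- otsu_mask(xs)
  labm <- filter_components(mask, params$min_area_px, params$max_area_px)
  if (!any(labm > 0L)) return(empty)
  dm <- EBImage::distmap(EBImage::Image((labm > 0L) * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = params$min_separation_px)
  labm <- relabel(matrix(as.integer(EBImage::imageData(ws)), h, w))
  centers <- label_centroids(labm)
  list(count = max(labm), label_grid = labm, centers = centers)
}

#' Membrane segmentation from the inverted whole-cell channel
#'
#' Inverts the whole-cell intensity (max - value) so the dim membrane
#' ridges become bright, floods it from the nuclei labels by
#' marker-controlled region growing, extracts the 1-px inter-label outline
#' and grows it by a Euclidean disk of radius `grow_halfwidth_px`.
#' With zero nuclei an empty segmentation is returned with `warning_flag`
#' set (no membranes definable).
#'
#' @param cellmask_channel intensity matrix
#' @param nuclei result of [count_nuclei()]
#' @param grow_halfwidth_px band half-width (overrides `params`)
#' @param params a [quantify_params()]
#' @return list with `cell_label_grid`, `outline_mask`, `band_mask`,
#'   `warning_flag`
#' @export
segment_membranes <- function(cellmask_channel, nuclei,
                              grow_halfwidth_px = NULL,
                              params = quantify_params()) {
  stopifnot(is.matrix(cellmask_channel), all(is.finite(cellmask_channel)))
  h <- nrow(cellmask_channel); w <- ncol(cellmask_channel)
  grow <- grow_halfwidth_px %||% params$grow_halfwidth_px
  if (nuclei$count < 1) {
    return(list(cell_label_grid = matrix(0L, h, w),
                outline_mask = matrix(FALSE, h, w),
                band_mask = matrix(FALSE, h, w), warning_flag = TRUE))
  }
  stopifnot(all(dim(nuclei$label_grid) == c(h, w)))
  inv <- max(cellmask_channel) - cellmask_channel
  mx <- max(inv)
  if (mx > 0) inv <- inv / mx
  seg <- EBImage::propagate(EBImage::Image(inv),
                            EBImage::Image(nuclei$label_grid),
                            lambda = params$propagate_lambda)
  labm <- matrix(as.integer(EBImage::imageData(seg)), h, w)
  outline <- label_boundaries(labm, include_border = params$include_border)
  band <- dilate_mask(outline, disk_brush(grow))
  list(cell_label_grid = labm, outline_mask = outline, band_mask = band,
       warning_flag = FALSE)
}

#' Thickened junction mask
#'
#' The junction channel is specific enough that no inversion is needed:
#' global Otsu threshold, removal of specks below `junction_min_area_px`,
#' skeletonization to 1-px curves and growth by the same Euclidean disk used
#' for the membrane band ("assessed in a similar manner"). Set
#' `junction_mode = "dilate"` in `params` to grow the thresholded mask
#' directly without skeletonizing.
#'
#' @param junction_channel intensity matrix
#' @param params a [quantify_params()]
#' @param grow_halfwidth_px band half-width (overrides `params`)
#' @return logical matrix
#' @export
junction_band <- function(junction_channel, params = quantify_params(),
                          grow_halfwidth_px = NULL) {
  stopifnot(is.matrix(junction_channel), all(is.finite(junction_channel)))
  grow <- grow_halfwidth_px %||% params$grow_halfwidth_px
  mask <- otsu_mask(junction_channel)
  # junction staining is high-contrast ("significantly more specific"), so
  # guard the global threshold against collapsing into background noise
  # when a field carries little or no junction signal: foreground must also
  # clear a robust background floor (scale-invariant, like the threshold)
  floor_level <- stats::median(junction_channel) +
    params$junction_floor_mads * stats::mad(junction_channel)
  mask <- mask & (junction_channel > floor_level)
  labm <- filter_components(mask, params$junction_min_area_px)
  mask <- labm > 0L
  if (!any(mask)) return(mask)
  if (params$junction_mode == "skeletonize") mask <- thin_mask(mask)
  dilate_mask(mask, disk_brush(grow))
}

#' Per-field quantification
#'
#' Counts nuclei, segments membranes, builds the thickened junction mask and
#' reports (i) the stained membrane area inside the grown membrane band and
#' (ii) the junction staining area overlapping that band, both in square
#' microns, as totals over all cells in the image.
#'
#' @param images a `field_images` object
#' @param params a [quantify_params()]
#' @return list of class `field_metrics`: `nuclei_count`,
#'   `membrane_area_um2`, `junction_at_membrane_area_um2`, `warning_flag`
#' @export
field_metrics <- function(images, params = quantify_params()) {
  stopifnot(inherits(images, "field_images"))
  px2 <- images$pixel_size_um^2
  nuc <- count_nuclei(images$nuclei, params)
  seg <- segment_membranes(images$cellmask, nuc, params = params)
  jb <- junction_band(images$junction, params)
  stain <- otsu_mask(images$cellmask)
  structure(list(
    nuclei_count = nuc$count,
    membrane_area_um2 = sum(stain & seg$band_mask) * px2,
    junction_at_membrane_area_um2 = sum(jb & seg$band_mask) * px2,
    warning_flag = seg$warning_flag), class = "field_metrics")
}

#' Aggregate field metrics to the well level
#'
#' Mean areas and the mean nuclei count over fields; per-cell metrics are
#' the ratio of mean area to mean nuclei count by default ("the mean of all
#' images normalized to the number of cells counted"), or the mean of
#' per-field ratios when `normalization = "mean_of_ratios"`.
#' A well whose mean nuclei count is zero has undefined per-cell metrics:
#' values are NA and `undefined_per_cell` is flagged.
#'
#' @param fields list of [field_metrics()] results
#' @param normalization "ratio_of_means" or "mean_of_ratios"
#' @return list of class `well_metrics`
#' @export
aggregate_well <- function(fields,
                           normalization = c("ratio_of_means", "mean_of_ratios")) {
  normalization <- match.arg(normalization)
  stopifnot(length(fields) >= 1)
  cnt <- vapply(fields, function(f) as.numeric(f$nuclei_count), numeric(1))
  mem <- vapply(fields, function(f) f$membrane_area_um2, numeric(1))
  jun <- vapply(fields, function(f) f$junction_at_membrane_area_um2, numeric(1))
  mean_cnt <- mean(cnt)
  undefined <- mean_cnt == 0
  if (normalization == "ratio_of_means") {
    mpc <- if (undefined) NA_real_ else mean(mem) / mean_cnt
    jpc <- if (undefined) NA_real_ else mean(jun) / mean_cnt
  } else {
    ok <- cnt > 0
    if (!any(ok)) {
      undefined <- TRUE
      mpc <- jpc <- NA_real_
    } else {
      mpc <- mean(mem[ok] / cnt[ok])
      jpc <- mean(jun[ok] / cnt[ok])
    }
  }
  if (undefined) {
    warning("well has zero mean nuclei count; per-cell metrics undefined")
  }
  structure(list(
    mean_nuclei_count = mean_cnt,
    mean_membrane_area_um2 = mean(mem),
    mean_junction_area_um2 = mean(jun),
    membrane_area_per_cell_um2 = mpc,
    junction_area_per_cell_um2 = jpc,
    n_fields = length(fields),
    undefined_per_cell = undefined), class = "well_metrics")
}

#' Simulate and quantify a plate field-by-field
#'
#' Streaming combination of [simulate_plate()] and [analyze_plate()]: each
#' field is generated, quantified and discarded, so whole plates at full
#' field counts run in constant memory. Produces the same per-well table as
#' [analyze_plate()] on an in-memory plate with the same seed.
#'
#' @inheritParams simulate_plate
#' @param params a [quantify_params()]
#' @return list with data.frames `field_table` and `well_table`
#' @export
simulate_and_analyze_plate <- function(layout, pharmacology, base_spec,
                                       fields_per_well = 16L, seed = 1L,
                                       params = quantify_params(),
                                       plate_id = "P1") {
  stopifnot(is.data.frame(layout))
  if (!any(layout$role == "vehicle")) {
    stop("plate layout must contain at least one vehicle well")
  }
  ph <- pharmacology
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    wl <- layout[i, ]
    if (wl$role == "vehicle") {
      integ <- 1; loss <- 0
    } else {
      integ <- hill_fraction(wl$concentration_um, ph$junction_ic50_um,
                             ph$junction_hill %||% 1)
      loss <- 1 - hill_fraction(wl$concentration_um, ph$viability_ec50_um,
                                ph$viability_hill %||% 1)
    }
    fm <- vector("list", fields_per_well)
    for (f in seq_len(fields_per_well)) {
      spec_f <- base_spec
      spec_f$junction_integrity <- integ
      spec_f$cell_loss_fraction <- loss
      spec_f$seed <- derive_seed(seed, i, f)
      fld <- generate_field(spec_f)
      fm[[f]] <- field_metrics(fld$images, params)
    }
    wm <- aggregate_well(fm, normalization = params$normalization)
    rows[[i]] <- data.frame(
      plate = plate_id, well = wl$well_id, compound = wl$compound_id,
      concentration_um = wl$concentration_um, role = wl$role,
      n_fields = fields_per_well,
      mean_nuclei_count = wm$mean_nuclei_count,
      membrane_area_per_cell_um2 = wm$membrane_area_per_cell_um2,
      junction_area_per_cell_um2 = wm$junction_area_per_cell_um2,
      stringsAsFactors = FALSE)
  }
  list(well_table = do.call(rbind, rows))
}

#' Analyze a whole plate of fields
#'
#' Accepts either the in-memory result of [simulate_plate()] or a manifest
#' data.frame whose `path_*` columns point at TIFF triplets written by
#' [write_field()]. Returns per-field and per-well metric tables.
#'
#' @param plate result of [simulate_plate()], or NULL when `manifest` rows
#'   carry file paths
#' @param manifest manifest data.frame (taken from `plate` if NULL)
#' @param params a [quantify_params()]
#' @param pixel_size_um pixel scale used when reading fields from disk
#' @return list with data.frames `field_table` and `well_table`
#' @export
analyze_plate <- function(plate = NULL, manifest = NULL,
                          params = quantify_params(), pixel_size_um = 0.325) {
  manifest <- manifest %||% plate$manifest
  stopifnot(is.data.frame(manifest),
            all(c("plate", "well", "field", "concentration_um", "role") %in% names(manifest)))
  n <- nrow(manifest)
  fm <- vector("list", n)
  for (i in seq_len(n)) {
    key <- sprintf("%s_f%02d", manifest$well[i], manifest$field[i])
    if (!is.null(plate) && key %in% names(plate$fields)) {
      img <- plate$fields[[key]]$images
    } else {
      stem <- sub("_nuc\\.tif$", "", basename(manifest$path_nuc[i]))
      img <- read_field(dirname(manifest$path_nuc[i]), stem, pixel_size_um)
    }
    fm[[i]] <- field_metrics(img, params)
  }
  field_table <- data.frame(
    plate = manifest$plate, well = manifest$well, field = manifest$field,
    compound = manifest$compound, concentration_um = manifest$concentration_um,
    role = manifest$role,
    nuclei_count = vapply(fm, function(f) as.numeric(f$nuclei_count), numeric(1)),
    membrane_area_um2 = vapply(fm, function(f) f$membrane_area_um2, numeric(1)),
    junction_at_membrane_area_um2 =
      vapply(fm, function(f) f$junction_at_membrane_area_um2, numeric(1)),
    stringsAsFactors = FALSE)
  wells <- unique(manifest[, c("plate", "well", "compound", "concentration_um", "role")])
  wm <- vector("list", nrow(wells))
  for (j in seq_len(nrow(wells))) {
    sel <- which(manifest$plate == wells$plate[j] & manifest$well == wells$well[j])
    wm[[j]] <- aggregate_well(fm[sel], normalization = params$normalization)
  }
  well_table <- cbind(
    wells,
    data.frame(
      n_fields = vapply(wm, function(x) x$n_fields, numeric(1)),
      mean_nuclei_count = vapply(wm, function(x) x$mean_nuclei_count, numeric(1)),
      membrane_area_per_cell_um2 =
        vapply(wm, function(x) x$membrane_area_per_cell_um2, numeric(1)),
      junction_area_per_cell_um2 =
        vapply(wm, function(x) x$junction_area_per_cell_um2, numeric(1)),
      stringsAsFactors = FALSE),
    row.names = NULL)
  list(field_table = field_table, well_table = well_table)
}
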