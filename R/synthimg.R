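#' Specification of a synthetic epithelial monolayer field
#'
#' Defines the geometry, staining levels and degradation state of one
#' simulated three-channel microscopy field. The monolayer is a confluent
#' Voronoi ("cobblestone") tessellation seeded at nucleus centers with a
#' minimum center separation of twice the nucleus radius. Junction staining
#' occupies a randomly chosen, spatially contiguous subset of cell-cell
#' membrane segments whose total length is the fraction
#' `junction_integrity` of the skeleton length, so partial integrity
#' produces patch-wise gaps as in a degrading epithelium. Cytotoxic cell
#' loss removes whole cells before tessellation. Defaults emulate confluent
#' alveolar epithelial cells (~18 um across, ~6 um nuclei) imaged at 40x on
#' a fine camera grid (0.16 um/px) in a 256 px field, so that cell bodies
#' are large relative to the 10 px analysis band.
#'
#' @param image_height_px,image_width_px field size in pixels
#' @param n_cells nominal number of cells at full viability
#' @param pixel_size_um microns per pixel
#' @param junction_integrity fraction in [0,1] of membrane length carrying
#'   junction signal
#' @param cell_loss_fraction fraction in [0,1) of cells lost to cytotoxicity
#' @param noise_sd additive Gaussian noise SD (intensity units), applied last
#'   with negative values clipped to zero
#' @param background_level,cytoplasm_level,membrane_dip,junction_level,nucleus_level
#'   staining intensity levels. Membranes are rendered as *dim ridges*: the
#'   whole-cell channel is `cytoplasm_level` inside cells, reduced by
#'   `membrane_dip` along the 1-px membrane skeleton, so the analysis
#'   pipeline's inversion step is meaningful.
#' @param nucleus_radius_px nucleus blob radius in pixels; the minimum
#'   nucleus center separation is twice this value
#' @param seed integer RNG seed; identical spec + seed is bit-identical
#' @return an object of class `monolayer_spec`
#' @export
monolayer_spec <- function(image_height_px = 256L, image_width_px = 256L,
                           n_cells = 5L, pixel_size_um = 0.16,
                           junction_integrity = 1, cell_loss_fraction = 0,
                           noise_sd = 100,
                           background_level = 200, cytoplasm_level = 2000,
                           membrane_dip = 1200, junction_level = 3000,
                           nucleus_level = 3000, nucleus_radius_px = 18L,
                           seed = 1L) {
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_cells = as.integer(n_cells), pixel_size_um = pixel_size_um,
    junction_integrity = junction_integrity,
    cell_loss_fraction = cell_loss_fraction, noise_sd = noise_sd,
    background_level = background_level, cytoplasm_level = cytoplasm_level,
    membrane_dip = membrane_dip, junction_level = junction_level,
    nucleus_level = nucleus_level,
    nucleus_radius_px = as.integer(nucleus_radius_px),
    seed = as.integer(seed))
  class(spec) <- "monolayer_spec"
  validate_monolayer_spec(spec)
  spec
}

validate_monolayer_spec <- function(spec) {
  stopifnot(
    spec$image_height_px >= 8, spec$image_width_px >= 8,
    spec$n_cells >= 1, spec$pixel_size_um > 0,
    spec$junction_integrity >= 0, spec$junction_integrity <= 1,
    spec$cell_loss_fraction >= 0, spec$cell_loss_fraction < 1,
    spec$noise_sd >= 0, spec$background_level >= 0,
    spec$cytoplasm_level >= 0, spec$membrane_dip >= 0,
    spec$junction_level >= 0, spec$nucleus_level >= 0,
    spec$nucleus_radius_px >= 1)
  n_eff <- effective_cell_count(spec)
  if (n_eff < 1) {
    stop("effective cell count (n_cells adjusted for cell loss) is 0")
  }
  invisible(spec)
}

#' @rdname monolayer_spec
#' @param spec a `monolayer_spec`
#' @export
effective_cell_count <- function(spec) {
  as.integer(round(spec$n_cells * (1 - spec$cell_loss_fraction)))
}

#' @export
print.monolayer_spec <- function(x, ...) {
  cat(sprintf(
    "monolayer_spec: %dx%d px (%.3f um/px), %d cells (%d effective)\n",
    x$image_height_px, x$image_width_px, x$pixel_size_um, x$n_cells,
    effective_cell_count(x)))
  cat(sprintf("  junction integrity %.3f, cell loss %.3f, noise sd %.1f, seed %d\n",
              x$junction_integrity, x$cell_loss_fraction, x$noise_sd, x$seed))
  invisible(x)
}

# Rejection-sample n centers with pairwise separation >= min_sep, uniform in
# the field interior (margin of one nucleus radius). Errors out when the
# requested packing is impossible to place.
sample_centers <- function(n, h, w, min_sep, margin, max_tries = 200L) {
  cent <- matrix(NA_real_, n, 2)
  k <- 0L
  tries_left <- max_tries * n
  while (k < n) {
    if (tries_left <= 0L) {
      stop(sprintf(
        "cannot place %d cell centers with minimum separation %.1f px in a %dx%d field",
        n, min_sep, h, w))
    }
    p <- c(stats::runif(1, 1 + margin, h - margin),
           stats::runif(1, 1 + margin, w - margin))
    tries_left <- tries_left - 1L
    if (k == 0L ||
        min((cent[seq_len(k), 1] - p[1])^2 + (cent[seq_len(k), 2] - p[2])^2) >= min_sep^2) {
      k <- k + 1L
      cent[k, ] <- p
    }
  }
  colnames(cent) <- c("row", "col")
  cent
}

# Nearest-center (Euclidean) assignment of every pixel -> Voronoi labels.
voronoi_labels <- function(centers, h, w) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  best <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  for (k in seq_len(nrow(centers))) {
    d <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2
    m <- d < best
    lab[m] <- k
    best[m] <- d[m]
  }
  lab
}

# Spatially clustered selection of cell-cell edges totalling ~target of the
# skeleton length. Junction loss in a degrading epithelium is patchy, so the
# *retained* set is grown as contiguous patches over the edge-adjacency
# graph (edges are adjacent when they share a cell): a random seed edge is
# extended by randomly drawn frontier edges until the target length is
# reached (the crossing edge is included only if that lands closer to the
# target). Growth order is a deterministic function of the RNG state, so
# for a fixed seed a higher integrity keeps a superset of the edges kept at
# a lower integrity.
select_junction_edges <- function(keys, lens, edge_cells, integrity) {
  total <- sum(lens)
  target <- integrity * total
  if (target <= 0) return(character(0))
  n <- length(keys)
  # map cell -> incident edge indices
  cells <- sort(unique(unlist(edge_cells)))
  incident <- lapply(cells, function(cl) {
    which(vapply(edge_cells, function(e) cl %in% e, logical(1)))
  })
  names(incident) <- as.character(cells)
  kept <- logical(n)
  infront <- logical(n)
  frontier <- integer(0)
  cum <- 0
  order_draw <- sample.int(n)  # tie-break stream for seeds of new patches
  oi <- 1L
  repeat {
    if (length(frontier) == 0L) {
      while (oi <= n && kept[order_draw[oi]]) oi <- oi + 1L
      if (oi > n) break
      nxt <- order_draw[oi]
    } else {
      pick <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
      nxt <- frontier[pick]
      frontier <- frontier[-pick]
    }
    infront[nxt] <- FALSE
    if (kept[nxt]) next
    if (abs(cum + lens[nxt] - target) > abs(cum - target)) break
    kept[nxt] <- TRUE
    cum <- cum + lens[nxt]
    if (cum >= target) break
    nbr <- unique(unlist(incident[as.character(edge_cells[[nxt]])]))
    nbr <- nbr[!kept[nbr] & !infront[nbr]]
    infront[nbr] <- TRUE
    frontier <- c(frontier, nbr)
  }
  keys[kept]
}

# Assign each skeleton pixel to the cell-cell edge (unordered label pair) it
# separates, under the same right/down half-boundary convention used to
# build the skeleton.
skeleton_segments <- function(lab, sk) {
  h <- nrow(lab); w <- ncol(lab)
  idx <- which(sk)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  a <- lab[idx]
  right <- ifelse(cc < w, lab[idx + h], a)
  down <- ifelse(rr < h, lab[idx + 1L], a)
  b <- ifelse(right != a, right, down)
  key <- paste(pmin(a, b), pmax(a, b))
  list(idx = idx, key = key)
}

#' Generate one synthetic three-channel field with ground truth
#'
#' Renders the nuclei, whole-cell ("cell mask") and junction channels of a
#' confluent epithelial monolayer together with its pixel-level ground
#' truth. Nuclei are Gaussian blobs at cell centers; the whole-cell channel
#' is uniform cytoplasm with dim 1-px ridges along the inter-cell membrane
#' skeleton; the junction channel carries signal on a spatially clustered
#' segment-wise subset of the skeleton (dilated by 1 px) totalling
#' `junction_integrity` of the skeleton length. Gaussian noise is added
#' last and negatives clipped.
#'
#' @param spec a [monolayer_spec()]
#' @return a list with elements `images` (class `field_images`: matrices
#'   `nuclei`, `cellmask`, `junction` and `pixel_size_um`) and `truth`
#'   (class `field_truth`: `cell_label_grid`, `nucleus_centers`,
#'   `membrane_skeleton`, `true_junction_mask`)
#' @export
generate_field <- function(spec) {
  validate_monolayer_spec(spec)
  h <- spec$image_height_px; w <- spec$image_width_px
  n_eff <- effective_cell_count(spec)
  rad <- spec$nucleus_radius_px
  with_seed(spec$seed, {
    centers <- sample_centers(n_eff, h, w, min_sep = 2 * rad, margin = rad)
    lab <- voronoi_labels(centers, h, w)
    sk <- label_boundaries(lab)

    # segment-wise junction dropout
    seg <- skeleton_segments(lab, sk)
    jmask <- matrix(FALSE, h, w)
    if (spec$junction_integrity > 0 && length(seg$idx)) {
      keys <- unique(seg$key)
      lens <- tabulate(factor(seg$key, levels = keys))
      edge_cells <- lapply(strsplit(keys, " ", fixed = TRUE), as.integer)
      chosen <- select_junction_edges(keys, lens, edge_cells,
                                      spec$junction_integrity)
      jmask[seg$idx[seg$key %in% chosen]] <- TRUE
    }
    true_junction <- dilate_mask(jmask, disk_brush(1))

    # nuclei channel: Gaussian blobs
    nuc <- matrix(spec$background_level, h, w)
    sig <- rad / 2
    win <- -(2 * rad + 1):(2 * rad + 1)
    for (k in seq_len(n_eff)) {
      r0 <- round(centers[k, 1]); c0 <- round(centers[k, 2])
      ri <- r0 + win; ci <- c0 + win
      okr <- ri >= 1 & ri <= h; okc <- ci >= 1 & ci <= w
      g <- exp(-outer(win[okr]^2, win[okc]^2, "+") / (2 * sig^2))
      nuc[ri[okr], ci[okc]] <- nuc[ri[okr], ci[okc]] + spec$nucleus_level * g
    }

    # whole-cell channel: uniform cytoplasm with dim membrane ridges
    cm <- matrix(spec$cytoplasm_level, h, w)
    cm[sk] <- max(spec$cytoplasm_level - spec$membrane_dip, 0)

    # junction channel
    jc <- matrix(spec$background_level, h, w)
    jc[true_junction] <- jc[true_junction] + spec$junction_level

    if (spec$noise_sd > 0) {
      nuc <- pmax(nuc + stats::rnorm(h * w, 0, spec$noise_sd), 0)
      cm <- pmax(cm + stats::rnorm(h * w, 0, spec$noise_sd), 0)
      jc <- pmax(jc + stats::rnorm(h * w, 0, spec$noise_sd), 0)
    }

    images <- structure(
      list(nuclei = nuc, cellmask = cm, junction = jc,
           pixel_size_um = spec$pixel_size_um),
      class = "field_images")
    truth <- structure(
      list(cell_label_grid = lab, nucleus_centers = centers,
           membrane_skeleton = sk, true_junction_mask = true_junction),
      class = "field_truth")
    list(images = images, truth = truth)
  })
}

#' @export
print.field_images <- function(x, ...) {
  cat(sprintf("field_images: %dx%d px, %.3f um/px, channels nuclei/cellmask/junction\n",
              nrow(x$nuclei), ncol(x$nuclei), x$pixel_size_um))
  invisible(x)
}

#' Hill occupancy: fraction of baseline remaining at concentration c
#'
#' `1 / (1 + (c / ec50)^hill)`; the midpoint (c = ec50) gives 0.5 and the
#' zero-concentration limit gives 1.
#' @param conc_um concentration (same units as `ec50_um`)
#' @param ec50_um midpoint concentration
#' @param hill Hill coefficient
#' @export
hill_fraction <- function(conc_um, ec50_um, hill = 1) {
  1 / (1 + (conc_um / ec50_um)^hill)
}

#' Default screening plate layout
#'
#' Nine-point, 3-fold concentration series from 100 uM down to 15 nM with
#' replicate treated wells and vehicle wells, mirroring a 96-well screening
#' plate design.
#'
#' @param compound_id compound label
#' @param concentrations_um concentration series (uM)
#' @param replicates treated wells per concentration
#' @param n_vehicle number of vehicle wells
#' @return data.frame with columns well_id, compound_id, concentration_um,
#'   role ("treated"/"vehicle"), replicate
#' @export
plate_layout <- function(compound_id = "CPD1",
                         concentrations_um = 100 / 3^(0:8),
                         replicates = 2L, n_vehicle = 2L) {
  stopifnot(all(concentrations_um > 0), replicates >= 1, n_vehicle >= 1)
  conc <- sort(concentrations_um, decreasing = TRUE)
  treated <- expand.grid(replicate = seq_len(replicates),
                         concentration_um = conc)
  treated <- treated[order(-treated$concentration_um, treated$replicate), ]
  n_t <- nrow(treated)
  layout <- data.frame(
    well_id = sprintf("W%02d", seq_len(n_t + n_vehicle)),
    compound_id = compound_id,
    concentration_um = c(treated$concentration_um, rep(NA_real_, n_vehicle)),
    role = c(rep("treated", n_t), rep("vehicle", n_vehicle)),
    replicate = c(treated$replicate, seq_len(n_vehicle)),
    stringsAsFactors = FALSE)
  layout
}

#' Simulate a full screening plate
#'
#' For a well at concentration c, the generator's junction integrity follows
#' `1/(1 + (c/junction_ic50_um)^junction_hill)` and the cell-loss fraction
#' `1 - 1/(1 + (c/viability_ec50_um)^viability_hill)`; vehicle wells use
#' integrity 1 and loss 0. Per-well and per-field seeds are derived
#' deterministically from the master seed (see [derive_seed()]), so any
#' single field is regenerable in isolation.
#'
#' @param layout a [plate_layout()] data.frame
#' @param pharmacology list with `junction_ic50_um`, `junction_hill`,
#'   `viability_ec50_um`, `viability_hill`
#' @param base_spec a [monolayer_spec()] providing geometry and staining
#'   levels (its `junction_integrity`, `cell_loss_fraction` and `seed` are
#'   overridden per well/field)
#' @param fields_per_well images per well
#' @param seed master seed
#' @param directory if non-NULL, write TIFF triplets and ground truth there
#'   (see [write_field()]) and record paths in the manifest
#' @param plate_id plate label recorded in the manifest
#' @return list with `fields` (named list of `generate_field()` results,
#'   names `<well>_f<field>`) and `manifest` (data.frame: plate, well,
#'   field, compound, concentration_um, role, path_nuc, path_mask,
#'   path_junc)
#' @export
simulate_plate <- function(layout, pharmacology, base_spec,
                           fields_per_well = 16L, seed = 1L,
                           directory = NULL, plate_id = "P1") {
  stopifnot(is.data.frame(layout),
            all(c("well_id", "concentration_um", "role") %in% names(layout)))
  if (!any(layout$role == "vehicle")) {
    stop("plate layout must contain at least one vehicle well")
  }
  ph <- pharmacology
  stopifnot(ph$junction_ic50_um > 0, ph$viability_ec50_um > 0)
  fields <- list()
  rows <- vector("list", nrow(layout) * fields_per_well)
  ri <- 0L
  for (i in seq_len(nrow(layout))) {
    wl <- layout[i, ]
    if (wl$role == "vehicle") {
      integ <- 1
      loss <- 0
    } else {
      integ <- hill_fraction(wl$concentration_um, ph$junction_ic50_um, ph$junction_hill %||% 1)
      loss <- 1 - hill_fraction(wl$concentration_um, ph$viability_ec50_um, ph$viability_hill %||% 1)
    }
    for (f in seq_len(fields_per_well)) {
      spec_f <- base_spec
      spec_f$junction_integrity <- integ
      spec_f$cell_loss_fraction <- loss
      spec_f$seed <- derive_seed(seed, i, f)
      fld <- generate_field(spec_f)
      key <- sprintf("%s_f%02d", wl$well_id, f)
      fields[[key]] <- fld
      paths <- c(path_nuc = NA_character_, path_mask = NA_character_,
                 path_junc = NA_character_)
      if (!is.null(directory)) {
        p <- write_field(fld$images, fld$truth, directory,
                         basename = sprintf("%s_%s", plate_id, key))
        paths <- c(path_nuc = p$nuc, path_mask = p$mask, path_junc = p$junc)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        plate = plate_id, well = wl$well_id, field = f,
        compound = wl$compound_id %||% NA_character_,
        concentration_um = wl$concentration_um, role = wl$role,
        path_nuc = paths[["path_nuc"]], path_mask = paths[["path_mask"]],
        path_junc = paths[["path_junc"]], stringsAsFactors = FALSE)
    }
  }
  list(fields = fields, manifest = do.call(rbind, rows[seq_len(ri)]))
}

write_channel_tiff <- function(grid, path) {
  if (max(grid) > 65535) {
    stop("intensity exceeds the 16-bit range (65535); refusing to clip silently")
  }
  q <- round(grid)
  tiff::writeTIFF(q / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write a field to disk as 16-bit grayscale TIFFs plus ground truth
#'
#' Channels are quantized by rounding to the nearest integer grey level and
#' stored as uint16; a round-trip read reproduces the rounded grids exactly.
#' Intensities above 65535 are an error, never silently clipped. Ground
#' truth is written alongside as a label-grid TIFF and a centers CSV.
#'
#' @param images,truth a `field_images` / `field_truth` pair
#' @param directory output directory (created if missing)
#' @param basename file stem; files are `<basename>_nuc.tif`,
#'   `<basename>_mask.tif`, `<basename>_junc.tif`, `<basename>_labels.tif`,
#'   `<basename>_centers.csv`
#' @return invisible list of written paths
#' @export
write_field <- function(images, truth, directory, basename) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    nuc = file.path(directory, paste0(basename, "_nuc.tif")),
    mask = file.path(directory, paste0(basename, "_mask.tif")),
    junc = file.path(directory, paste0(basename, "_junc.tif")),
    labels = file.path(directory, paste0(basename, "_labels.tif")),
    centers = file.path(directory, paste0(basename, "_centers.csv")))
  write_channel_tiff(images$nuclei, p$nuc)
  write_channel_tiff(images$cellmask, p$mask)
  write_channel_tiff(images$junction, p$junc)
  if (!is.null(truth)) {
    write_channel_tiff(truth$cell_label_grid, p$labels)
    utils::write.csv(as.data.frame(truth$nucleus_centers), p$centers,
                     row.names = FALSE)
  }
  invisible(p)
}

read_channel_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Read a field written by [write_field()]
#'
#' @param directory,basename as given to [write_field()]
#' @param pixel_size_um pixel scale to attach (not stored in the TIFFs)
#' @return a `field_images` object (integer-valued grids)
#' @export
read_field <- function(directory, basename, pixel_size_um = 0.325) {
  structure(
    list(nuclei = read_channel_tiff(file.path(directory, paste0(basename, "_nuc.tif"))),
         cellmask = read_channel_tiff(file.path(directory, paste0(basename, "_mask.tif"))),
         junction = read_channel_tiff(file.path(directory, paste0(basename, "_junc.tif"))),
         pixel_size_um = pixel_size_um),
    class = "field_images")
}
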