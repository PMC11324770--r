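# Internal helpers shared across modules: seeded RNG scoping, digital disk
# brushes, boundary extraction and binary thinning on (row, col) matrices.
# Conventions (stated once, used everywhere): coordinates are (row, col),
# 1-based in R; boundary tests use 4-connectivity, connected components
# 8-connectivity.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generation never leaks
#' RNG state into the caller.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Counter-based seed splitting: master seed -> per-well -> per-field
#'
#' Deterministic arithmetic scheme so any single field is regenerable in
#' isolation; results stay in the positive 32-bit integer range.
#' @param master integer master seed
#' @param ... non-negative integer counters (e.g. well index, field index)
#' @return an integer seed
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

#' Digital disk: lattice points with dx^2 + dy^2 <= r^2
#'
#' @param radius_px non-negative integer radius
#' @return logical (2r+1) x (2r+1) matrix (the structuring element)
#' @export
disk_brush <- function(radius_px) {
  stopifnot(radius_px >= 0)
  d <- -radius_px:radius_px
  outer(d^2, d^2, "+") <= radius_px^2
}

# Dilate a logical matrix by an arbitrary logical kernel (odd dimensions).
dilate_mask <- function(mask, kernel) {
  if (!any(mask)) return(mask)
  out <- EBImage::dilate(EBImage::Image(mask * 1), kernel * 1)
  matrix(EBImage::imageData(out) > 0.5, nrow(mask), ncol(mask))
}

# 1-px inter-label boundary under the half-boundary convention: a pixel is a
# boundary pixel when its label differs from its right or down 4-neighbour.
# Gives single-pixel curves (each shared edge marked on one side only).
label_boundaries <- function(lab, include_border = FALSE) {
  h <- nrow(lab); w <- ncol(lab)
  b <- matrix(FALSE, h, w)
  if (w > 1) b[, -w] <- lab[, -w] != lab[, -1]
  if (h > 1) b[-h, ] <- b[-h, ] | (lab[-h, ] != lab[-1, ])
  if (include_border) {
    b[1, ] <- TRUE; b[h, ] <- TRUE; b[, 1] <- TRUE; b[, w] <- TRUE
  }
  b
}

# Pad-shifted copy of a logical matrix (dr, dc in {-1,0,1}), padding FALSE.
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Zhang-Suen binary thinning to a 1-px skeleton
#'
#' Iterative two-subpass thinning of a logical matrix; vectorised over the
#' whole grid per pass. Used to reduce thresholded junction staining to
#' 1-px curves before band growth.
#' @param mask logical matrix
#' @return logical matrix of the same shape
#' @export
thin_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # 8-neighbours in circular order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      p2 <- shift_mask(m, -1, 0);  p3 <- shift_mask(m, -1, 1)
      p4 <- shift_mask(m, 0, 1);   p5 <- shift_mask(m, 1, 1)
      p6 <- shift_mask(m, 1, 0);   p7 <- shift_mask(m, 1, -1)
      p8 <- shift_mask(m, 0, -1);  p9 <- shift_mask(m, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0->1 transitions in the circular sequence
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Otsu threshold mask on a non-negative intensity matrix. Normalises by the
# image maximum first so the mask is invariant to multiplying all
# intensities by a positive constant. A constant image yields an empty mask.
otsu_mask <- function(x, levels = 256L) {
  mx <- max(x)
  if (!is.finite(mx) || mx <= 0 || mx == min(x)) {
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  xn <- x / mx
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = levels)
  xn > th
}

# Remove 8-connected components with area outside [min_area, max_area].
# Returns the filtered label matrix (labels re-enumerated 1..K).
filter_components <- function(mask, min_area = 0, max_area = Inf) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  drop <- which(areas < min_area | areas > max_area)
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  if (length(drop)) labm[labm %in% drop] <- 0L
  relabel(labm)
}

# Re-enumerate nonzero labels to 1..K preserving order of first appearance
# by original label id.
relabel <- function(labm) {
  u <- sort(unique(labm[labm > 0L]))
  if (!length(u)) return(labm)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  labm[labm > 0L] <- map[labm[labm > 0L]]
  labm
}

# Per-label centroids of a label matrix, as an n x 2 (row, col) matrix
# ordered by label id.
label_centroids <- function(labm) {
  idx <- which(labm > 0L)
  if (!length(idx)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  lab <- labm[idx]
  h <- nrow(labm)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  out <- cbind(row = tapply(rr, lab, mean), col = tapply(cc, lab, mean))
  out[order(as.integer(rownames(out))), , drop = FALSE]
}
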