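# Small-field helpers shared across tests. Fields are deliberately miniature
# (128 px, few cells) so that the suite stays fast; geometry-critical tests
# build their own specs.

small_spec <- function(seed = 1L, ...) {
  args <- list(image_height_px = 128L, image_width_px = 128L, n_cells = 4L,
               nucleus_radius_px = 10L, pixel_size_um = 0.2, seed = seed)
  do.call(monolayer_spec, utils::modifyList(args, list(...)))
}

noiseless_spec <- function(seed = 1L, ...) {
  small_spec(seed = seed, noise_sd = 0, ...)
}

# chebyshev (8-neighbour) distance from each TRUE pixel of `from` to the
# nearest TRUE pixel of `to`, as a maximum; Inf when `to` is empty
max_chebyshev_to <- function(from, to) {
  if (!any(from)) return(0)
  if (!any(to)) return(Inf)
  fi <- which(from, arr.ind = TRUE)
  ti <- which(to, arr.ind = TRUE)
  mx <- 0
  for (i in seq_len(nrow(fi))) {
    d <- pmax(abs(ti[, 1] - fi[i, 1]), abs(ti[, 2] - fi[i, 2]))
    mx <- max(mx, min(d))
  }
  mx
}

# fraction of non-boundary pixels on which a segmentation agrees with the
# ground-truth labels, under the best per-truth-label assignment
label_agreement <- function(truth_lab, seg_lab, exclude) {
  nb <- !exclude
  tab <- table(truth_lab[nb], seg_lab[nb])
  sum(apply(tab, 1, max)) / sum(nb)
}
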