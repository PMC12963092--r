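# Per-frame stone segmentation. The reference implementation is a
# classical pipeline (intensity threshold, morphological opening then
# closing, connected-component area filter); a learned text-prompted
# segmenter can stand behind the same backend contract
# (frame -> binary mask of identical shape).

#' Segment one frame with the reference segmenter
#'
#' Thresholds the frame at `config$threshold` (Otsu by default), opens
#' then closes the binary image with a disc of radius
#' `config$morph_radius` (opening first, so dust speckle is removed
#' before stone holes are sealed), and keeps only connected components
#' with area at least `config$min_area` pixels. Deterministic; an
#' all-FALSE mask is a legal output.
#'
#' @param frame numeric matrix with intensities in \[0, 1\].
#' @param config a [segment_config()].
#' @return Logical mask of the same shape.
#' @export
segment_frame <- function(frame, config = segment_config()) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    ft_input_error("frame must be a numeric matrix")
  }
  tau <- if (identical(config$threshold, "otsu")) {
    # Otsu needs spread; a constant frame thresholds to nothing
    if (max(frame) - min(frame) < 1e-8) Inf
    else EBImage::otsu(EBImage::Image(pmin(pmax(frame, 0), 1)))
  } else {
    config$threshold
  }
  bw <- frame >= tau
  if (config$morph_radius > 0 && any(bw)) {
    kern <- EBImage::makeBrush(2L * config$morph_radius + 1L, shape = "disc")
    bw <- EBImage::closing(EBImage::opening(bw * 1, kern), kern) > 0.5
  }
  if (any(bw)) {
    lab <- EBImage::bwlabel(bw * 1)
    areas <- tabulate(as.integer(lab[lab > 0]))
    keep <- which(areas >= config$min_area)
    bw <- matrix(as.integer(lab) %in% keep, nrow(frame), ncol(frame))
  }
  bw
}

#' Segment every frame of a sequence
#'
#' Frames are processed independently. `backend` is any function
#' mapping a frame matrix to a strictly binary mask of identical
#' shape; the default wraps [segment_frame()]. A backend returning the
#' wrong shape or non-binary values violates the contract and errors.
#'
#' @param frames a [frame_sequence()].
#' @param backend `NULL` for the reference segmenter, or a function
#'   `frame -> logical matrix`.
#' @param config a [segment_config()] (used by the reference backend).
#' @return A [mask_sequence()].
#' @export
segment_sequence <- function(frames, backend = NULL,
                             config = segment_config()) {
  if (!inherits(frames, "frame_sequence")) {
    ft_input_error("segment_sequence() needs a frame_sequence")
  }
  fn <- if (is.null(backend)) {
    function(f) segment_frame(f, config)
  } else {
    if (!is.function(backend)) ft_contract_error("backend must be a function")
    backend
  }
  masks <- lapply(frames$frames, function(f) {
    m <- fn(f)
    if (is.numeric(m)) {
      if (!all(m %in% c(0, 1))) {
        ft_contract_error("segmenter backend returned non-binary values")
      }
      m <- m > 0.5
    }
    if (!is.matrix(m) || !is.logical(m) || !all(dim(m) == dim(f))) {
      ft_contract_error("segmenter backend must return a binary mask of frame shape")
    }
    m
  })
  mask_sequence(masks)
}

#' Backend that replays precomputed masks
#'
#' Adapter for externally produced segmentations (e.g. a fine-tuned
#' neural segmenter thresholded at probability 0.5): returns each mask
#' of `masks` in order, one per call.
#'
#' @param masks a [mask_sequence()].
#' @return A function usable as `backend` in [segment_sequence()].
#' @export
mask_replay_backend <- function(masks) {
  i <- 0L
  function(frame) {
    i <<- i + 1L
    if (i > masks$n_frames) ft_contract_error("mask backend exhausted")
    masks$masks[[i]]
  }
}
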