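# On-disk frame and mask I/O. Frames live as a directory of PNG images
# in lexicographic order; masks as one binary PNG per frame. Color
# input is converted to grayscale on load by Rec.601 luma weighting.

.luma <- c(0.299, 0.587, 0.114)

.read_png_gray <- function(file) {
  img <- tryCatch(png::readPNG(file),
                  error = function(e) ft_input_error("cannot read %s: %s",
                                                    file, conditionMessage(e)))
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    if (nc >= 3) {
      img <- .luma[1] * img[, , 1] + .luma[2] * img[, , 2] + .luma[3] * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

.list_frame_files <- function(path) {
  files <- list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                      full.names = TRUE)
  sort(files, method = "radix")
}

#' Read a frame sequence from disk
#'
#' @param path directory of lexicographically ordered PNG images.
#' @param frame_rate frames per second of the recording (default 30).
#' @return A [frame_sequence()] with grayscale intensities in \[0, 1\].
#' @export
read_frames <- function(path, frame_rate = 30) {
  if (!dir.exists(path)) {
    ft_input_error("frame directory not found: %s", path)
  }
  files <- .list_frame_files(path)
  if (length(files) == 0) ft_input_error("no PNG frames in %s", path)
  frames <- lapply(files, .read_png_gray)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ft_format_error("inconsistent frame shapes in %s", path)
  }
  ft_log("read %d frames (%dx%d) from %s", length(frames),
         dims[1, 1], dims[2, 1], path)
  frame_sequence(frames, frame_rate = frame_rate)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param frames a [frame_sequence()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(frames$n_frames)) {
    f <- pmin(pmax(frames$frames[[i]], 0), 1)
    png::writePNG(f, file.path(path, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(path)
}

#' Read a mask sequence from a directory of binary PNG files
#'
#' @param path directory of per-frame binary PNG masks in
#'   lexicographic order.
#' @return A [mask_sequence()].
#' @export
read_masks <- function(path) {
  if (!dir.exists(path)) ft_input_error("mask directory not found: %s", path)
  files <- .list_frame_files(path)
  if (length(files) == 0) ft_input_error("no PNG masks in %s", path)
  masks <- lapply(files, function(f) .read_png_gray(f) > 0.5)
  mask_sequence(masks)
}

#' Write a mask sequence as numbered binary PNG files
#'
#' @param masks a [mask_sequence()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(masks$n_frames)) {
    m <- masks$masks[[i]] * 1.0
    png::writePNG(m, file.path(path, sprintf("mask_%06d.png", i - 1L)))
  }
  invisible(path)
}
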