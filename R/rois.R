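#' Detect presynaptic-terminal ROIs from a recording stack
#'
#' Segments regions of interest (single cone terminals) from the temporal
#' standard-deviation projection of an imaging stack: pixels whose
#' SD-over-time exceeds `sd_threshold` are labeled into connected
#' components, which are then filtered for size (2-5 square micrometers by
#' default) and roundness (best-fit-ellipse major/minor axis ratio below
#' `max_elongation`, i.e. "< 150% elongation").
#'
#' The absolute SD threshold depends on detector gain and is therefore
#' configuration-driven; `sd_threshold` may also be given as a function of
#' the SD image (e.g. for adaptive thresholds).
#'
#' @param stack Numeric array, height x width x frames (>= 2 frames).
#' @param pixel_size Pixel side length in micrometers.
#' @param sd_threshold Threshold on the temporal-SD image (numeric scalar,
#'   or a function receiving the SD image and returning a scalar/matrix).
#' @param area_bounds ROI area bounds in square micrometers.
#' @param max_elongation Maximal major/minor axis ratio.
#' @return An `roi_set`: list with `masks` (list of pixel-index matrices),
#'   `area_um2`, `elongation`, `labels` (labeled image), `n`. An empty set
#'   is valid.
#' @export
detect_rois <- function(stack, pixel_size, sd_threshold,
                        area_bounds = c(2, 5), max_elongation = 1.5) {
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    stop("`stack` must be a height x width x frames array with >= 2 frames",
         call. = FALSE)
  stopifnot(pixel_size > 0)
  sd_img <- apply(stack, c(1, 2), stats::sd)
  thr <- if (is.function(sd_threshold)) sd_threshold(sd_img) else sd_threshold
  bin <- sd_img > thr
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  nlab <- max(lab)
  keep <- integer(0)
  areas <- elong <- numeric(0)
  if (nlab > 0) {
    mom <- EBImage::computeFeatures.moment(lab)
    mom <- matrix(mom, ncol = ncol(mom),
                  dimnames = list(NULL, colnames(mom)))
    labm <- EBImage::imageData(lab)
    px_counts <- tabulate(labm[labm > 0], nbins = nlab)
    for (k in seq_len(nlab)) {
      a <- px_counts[k] * pixel_size^2
      ecc <- mom[k, "m.eccentricity"]
      el <- if (is.finite(ecc) && ecc < 1) 1 / sqrt(1 - ecc^2) else Inf
      if (px_counts[k] <= 2) el <- 1  # too few pixels for an ellipse
      if (a >= area_bounds[1] && a <= area_bounds[2] && el < max_elongation) {
        keep <- c(keep, k)
        areas <- c(areas, a)
        elong <- c(elong, el)
      }
    }
  }
  masks <- lapply(keep, function(k) which(EBImage::imageData(lab) == k,
                                          arr.ind = TRUE))
  structure(list(masks = masks, area_um2 = areas, elongation = elong,
                 labels = lab, n = length(keep)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs", x$n))
  if (x$n) cat(sprintf(" (area %.2g-%.2g um^2)", min(x$area_um2),
                       max(x$area_um2)))
  cat("\n")
  invisible(x)
}

#' Extract the mean trace of an ROI from a stack
#'
#' @param stack Height x width x frames array.
#' @param roi_set A [detect_rois()] result.
#' @param roi ROI index.
#' @return Numeric trace (mean over mask pixels per frame).
#' @export
roi_trace <- function(stack, roi_set, roi) {
  m <- roi_set$masks[[roi]]
  vapply(seq_len(dim(stack)[3]), function(f) {
    mean(stack[cbind(m, f)])
  }, 0)
}

#' Read an imaging stack from a TIFF file
#'
#' Thin reader returning a height x width x frames array; requires the
#' `tiff` package.
#'
#' @param path TIFF file path.
#' @return Numeric array.
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the `tiff` package", call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) == 3) f <- f[, , 1]
    arr[, , i] <- f
  }
  arr
}
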