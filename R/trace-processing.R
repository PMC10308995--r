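#' Per-cell fluorescence trace
#'
#' Container for one cell's dye intensity time series on a uniform time
#' grid. `laser_index` is the 1-based index of the first post-laser frame;
#' frames before it are the pre-laser background used for photobleaching
#' correction and noise estimation.
#'
#' @param times Acquisition times in seconds, uniformly spaced, increasing.
#' @param intensities Fluorescence intensities (AU), same length as `times`.
#' @param laser_index 1-based index of the first frame after laser onset.
#' @param cell_id Identifier.
#' @return Object of class `fluor_trace`.
#' @export
fluor_trace <- function(times, intensities, laser_index = 101L, cell_id = "cell") {
  stopifnot(length(times) == length(intensities), length(times) >= 3)
  dts <- diff(times)
  if (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("times must be strictly increasing with uniform spacing")
  laser_index <- as.integer(laser_index)
  if (laser_index < 2L || laser_index > length(times))
    stop("laser_index must lie inside the trace with at least one background frame")
  structure(list(times = as.numeric(times), intensities = as.numeric(intensities),
                 laser_index = laser_index, frame_interval = dts[1],
                 cell_id = cell_id),
            class = "fluor_trace")
}

#' Extract per-cell traces from an image stack
#'
#' Computes, for each label in the mask, the per-frame mean pixel intensity
#' within that label's region. Labels are processed in ascending order.
#'
#' @param stack Numeric array height x width x frames.
#' @param mask Integer matrix of label ids (0 = background); same spatial
#'   shape as the stack.
#' @param frame_interval Seconds per frame (default 1).
#' @param laser_index 1-based index of the first post-laser frame.
#' @param labels Optional subset of label ids to extract; an id with no
#'   pixels raises an error naming it.
#' @return List of [fluor_trace()] objects, one per label, ascending id.
#' @export
extract_traces <- function(stack, mask, frame_interval = 1, laser_index = 101L,
                           labels = NULL) {
  stopifnot(length(dim(stack)) == 3, is.matrix(mask),
            all(dim(stack)[1:2] == dim(mask)))
  present <- sort(unique(mask[mask > 0]))
  if (is.null(labels)) labels <- present
  if (length(labels) == 0) stop("mask contains no labeled regions")
  labels <- sort(as.integer(labels))
  n_frames <- dim(stack)[3]
  flat <- matrix(stack, ncol = n_frames)   # pixels x frames
  lapply(labels, function(lab) {
    idx <- which(mask == lab)
    if (length(idx) == 0) stop(sprintf("label %d has no pixels in the mask", lab))
    fluor_trace(times = (seq_len(n_frames) - 1) * frame_interval,
                intensities = colMeans(flat[idx, , drop = FALSE]),
                laser_index = laser_index, cell_id = lab)
  })
}

#' Linear photobleaching correction
#'
#' Fits an ordinary-least-squares line `F(frame) = F0 + s * frame` to the
#' pre-laser background frames only, extrapolates it over the whole trace,
#' and divides the intensities by it (multiplicative bleaching model). The
#' corrected relative intensity has background mean 1; the resting level is
#' the fitted intercept `F0` (value of the bleach line at the first frame).
#'
#' @param trace A [fluor_trace()].
#' @return Object of class `corrected_trace` with fields `times`,
#'   `rel_intensity`, `resting_intensity`, `bleach_slope` (AU/frame),
#'   `laser_index`, `frame_interval`, `cell_id`.
#' @export
bleach_correct <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  n <- length(trace$intensities)
  bg <- seq_len(trace$laser_index - 1L)
  if (length(bg) < 2) stop("need at least 2 background frames for the bleach fit")
  frame <- seq_len(n) - 1L
  fit <- lm(trace$intensities[bg] ~ frame[bg])
  f0 <- unname(coef(fit)[1]); s <- unname(coef(fit)[2])
  baseline <- f0 + s * frame
  if (any(baseline <= 0))
    stop("extrapolated bleach baseline is non-positive; linear correction invalid")
  structure(list(times = trace$times,
                 rel_intensity = trace$intensities / baseline,
                 resting_intensity = f0, bleach_slope = s,
                 laser_index = trace$laser_index,
                 frame_interval = trace$frame_interval,
                 cell_id = trace$cell_id),
            class = "corrected_trace")
}

# Re-correct a corrected trace (used by the idempotence property): treat the
# relative series as intensities on the same grid.
recorrect <- function(ct) {
  bleach_correct(fluor_trace(ct$times, ct$rel_intensity, ct$laser_index, ct$cell_id))
}

#' Classify a cell as perforated from its corrected trace
#'
#' The background noise level `sigma` is the sample sd of the relative
#' intensity over the pre-laser frames. A cell is called perforated when the
#' minimum over the dip-search window falls strictly below
#' `1 - k_sigma * sigma` (less a 1e-9 numerical floor, so that floating-point
#' residue on exactly noiseless traces never triggers a call; any real dip
#' is many orders of magnitude deeper). The dip depth is one minus that
#' minimum.
#'
#' The dip search is confined to the first `dip_window` frames after laser
#' onset: a poration dip is laser-synchronised, with its minimum at onset,
#' whereas far-extrapolation error of the bleach baseline grows linearly
#' with distance from the fitted background frames and would otherwise
#' dominate the false-positive rate at any noise level.
#'
#' @param ct A [bleach_correct()] output.
#' @param k_sigma Detection threshold in background-noise sigmas (default 5).
#' @param dip_window Number of post-laser frames searched for the dip
#'   minimum (default 30; the dip minimum physically occurs within a frame
#'   or two of onset).
#' @return List with `perforated` (logical) and `dip_depth`.
#' @export
classify_perforated <- function(ct, k_sigma = 5, dip_window = 30L) {
  stopifnot(inherits(ct, "corrected_trace"), k_sigma >= 0, dip_window >= 1)
  n <- length(ct$rel_intensity)
  bg <- seq_len(ct$laser_index - 1L)
  sigma <- sd(ct$rel_intensity[bg])
  win <- ct$laser_index:min(ct$laser_index + dip_window - 1L, n)
  post_min <- min(ct$rel_intensity[win])
  list(perforated = post_min < 1 - k_sigma * sigma - 1e-9,
       dip_depth = 1 - post_min)
}

#' Membrane resealing time from a corrected trace
#'
#' Implements the 90-percent recovery rule: starting at the post-laser
#' minimum, find the first frame whose relative intensity reaches
#' `threshold` and stays there for `confirm_frames` consecutive frames
#' (truncated at the end of the trace), then linearly interpolate the
#' crossing between the bracketing frames. The returned time is measured
#' from laser onset. `NA` (with a `reason` attribute) is returned when the
#' trace never recovers within the observation window.
#'
#' @param ct A [bleach_correct()] output.
#' @param threshold Recovery threshold relative to resting level (default 0.9).
#' @param confirm_frames Frames the trace must stay above threshold (default 3).
#' @param dip_window Post-laser frames searched for the dip minimum the
#'   recovery starts from (default 30, as in [classify_perforated()]).
#' @return Resealing time in seconds, or `NA_real_` if unresealed.
#' @export
resealing_time <- function(ct, threshold = 0.90, confirm_frames = 3L,
                           dip_window = 30L) {
  stopifnot(inherits(ct, "corrected_trace"), threshold > 0, threshold < 1,
            confirm_frames >= 1)
  n <- length(ct$rel_intensity)
  rel <- ct$rel_intensity
  li <- ct$laser_index
  post <- li:min(li + dip_window - 1L, n)
  dip_idx <- post[which.min(rel[post])]
  cross <- NA_integer_
  for (j in dip_idx:n) {
    if (rel[j] >= threshold) {
      upto <- min(j + confirm_frames - 1L, n)
      if (all(rel[j:upto] >= threshold)) { cross <- j; break }
    }
  }
  if (is.na(cross)) {
    out <- NA_real_
    attr(out, "reason") <- "unresealed within observation window"
    return(out)
  }
  if (cross == dip_idx) {
    # never fell below threshold after the dip frame: report the dip frame time
    return(max(0, (cross - li) * ct$frame_interval))
  }
  frac <- (threshold - rel[cross - 1L]) / (rel[cross] - rel[cross - 1L])
  ((cross - 1L - li) + frac) * ct$frame_interval
}

#' Full per-trace analysis: correction, classification, resealing time
#'
#' @param trace A [fluor_trace()].
#' @param threshold Recovery threshold (default 0.9).
#' @param k_sigma Perforation detection threshold (default 5).
#' @param confirm_frames Confirmation window (default 3).
#' @return One-row data frame: `cell_id`, `perforated`, `dip_depth`,
#'   `resealing_time_s`, `resting_intensity`, `bleach_slope`.
#' @export
analyze_trace <- function(trace, threshold = 0.90, k_sigma = 5, confirm_frames = 3L) {
  ct <- bleach_correct(trace)
  cls <- classify_perforated(ct, k_sigma = k_sigma)
  rt <- if (cls$perforated) resealing_time(ct, threshold, confirm_frames) else NA_real_
  data.frame(cell_id = as.character(trace$cell_id), perforated = cls$perforated,
             dip_depth = cls$dip_depth, resealing_time_s = as.numeric(rt),
             resting_intensity = ct$resting_intensity,
             bleach_slope = ct$bleach_slope,
             stringsAsFactors = FALSE)
}

#' @rdname analyze_trace
#' @param traces List of [fluor_trace()] objects.
#' @param ... Passed to [analyze_trace()].
#' @return `analyze_traces`: data frame with one row per trace.
#' @export
analyze_traces <- function(traces, ...) {
  do.call(rbind, lapply(traces, analyze_trace, ...))
}
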