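#' Specification of a synthetic fluorescence trace
#'
#' Describes one per-cell voltage-sensitive-dye intensity time series as
#' acquired in a photoporation experiment: a resting baseline with linear
#' photobleaching drift, and — for perforated cells — a laser-synchronised
#' dip that recovers exponentially toward baseline. The recovery time
#' constant is chosen so that the noiseless trace crosses 90 percent of the
#' resting level exactly at `true_resealing_time` seconds after laser onset.
#'
#' @param resting_intensity Resting fluorescence level (arbitrary units).
#' @param bleach_slope Photobleaching drift in AU per frame (typically <= 0).
#' @param n_background_frames Number of pre-laser frames (default 100).
#' @param n_post_frames Number of post-laser frames (default 380).
#' @param frame_interval Seconds between frames (default 1).
#' @param perforated Logical; does the cell porate?
#' @param dip_fraction Minimum of F/F_rest immediately after the laser pulse,
#'   in (0, 1). Must be < 0.9 for a finite resealing time to be defined.
#' @param true_resealing_time Seconds after laser onset at which the
#'   noiseless relative intensity crosses 0.9. Required when `perforated`.
#' @param noise_sd Standard deviation of additive Gaussian noise (AU).
#' @param seed RNG seed (integer) or `NULL`.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(resting_intensity = 1000,
                       bleach_slope = -0.5,
                       n_background_frames = 100L,
                       n_post_frames = 380L,
                       frame_interval = 1.0,
                       perforated = TRUE,
                       dip_fraction = 0.6,
                       true_resealing_time = if (perforated) 60 else NA_real_,
                       noise_sd = 0,
                       seed = NULL) {
  stopifnot(n_background_frames >= 2, n_post_frames >= 1, frame_interval > 0,
            resting_intensity > 0, noise_sd >= 0)
  if (perforated) {
    if (!is.finite(dip_fraction) || dip_fraction <= 0 || dip_fraction >= 1)
      stop("dip_fraction must lie in (0, 1) for perforated traces")
    if (dip_fraction >= 0.9)
      stop("dip_fraction >= 0.9: the 90% recovery crossing is undefined")
    if (!is.finite(true_resealing_time) || true_resealing_time <= 0)
      stop("perforated traces need true_resealing_time > 0")
  }
  structure(list(resting_intensity = resting_intensity,
                 bleach_slope = bleach_slope,
                 n_background_frames = as.integer(n_background_frames),
                 n_post_frames = as.integer(n_post_frames),
                 frame_interval = frame_interval,
                 perforated = isTRUE(perforated),
                 dip_fraction = dip_fraction,
                 true_resealing_time = true_resealing_time,
                 noise_sd = noise_sd,
                 seed = seed),
            class = "trace_spec")
}

#' Generate one synthetic fluorescence trace
#'
#' The noiseless construction is `F(frame) = (resting + slope * frame) * g(t)`
#' with `g = 1` before laser onset. For perforated cells `g` drops to
#' `dip_fraction` at onset and recovers as
#' `g(t) = 1 - (1 - dip_fraction) * exp(-t / tau)` with
#' `tau = true_resealing_time / log((1 - dip_fraction) / 0.1)`, which places
#' the 0.9 crossing exactly at `true_resealing_time`. Independent Gaussian
#' noise is added afterwards.
#'
#' @param spec A [trace_spec()].
#' @param cell_id Identifier stored on the trace.
#' @return A list with elements `trace` (a `fluor_trace`: `times`,
#'   `intensities`, `laser_index`, `frame_interval`, `cell_id`) and `truth`
#'   (perforated flag and true resealing time).
#' @export
make_trace <- function(spec, cell_id = "cell_1") {
  stopifnot(inherits(spec, "trace_spec"))
  n_bg <- spec$n_background_frames
  n <- n_bg + spec$n_post_frames
  frames <- seq_len(n) - 1L                      # 0-based frame index
  laser_index <- n_bg + 1L                       # first post-laser frame (1-based)
  baseline <- spec$resting_intensity + spec$bleach_slope * frames
  if (any(baseline <= 0))
    stop("bleach_slope drives the baseline non-positive within the trace")
  g <- rep(1, n)
  if (spec$perforated) {
    d <- spec$dip_fraction
    tau <- spec$true_resealing_time / log((1 - d) / 0.1)
    t_post <- (frames[laser_index:n] - (laser_index - 1L)) * spec$frame_interval
    g[laser_index:n] <- 1 - (1 - d) * exp(-t_post / tau)
  }
  noiseless <- baseline * g
  intensities <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, function() noiseless + rnorm(n, sd = spec$noise_sd))
  } else noiseless
  trace <- fluor_trace(times = frames * spec$frame_interval,
                       intensities = intensities,
                       laser_index = laser_index,
                       cell_id = cell_id)
  list(trace = trace,
       truth = list(cell_id = cell_id, perforated = spec$perforated,
                    true_resealing_time = if (spec$perforated) spec$true_resealing_time else NA_real_))
}

#' Specification of a synthetic image stack
#'
#' @param frame_shape Integer `c(height, width)` in pixels.
#' @param cells List of cells, each `list(center = c(row, col), radius, spec)`
#'   where `spec` is a [trace_spec()].
#' @param psf_sigma Gaussian blur sigma in pixels (0 = no blur).
#' @param background_level Constant background intensity (AU).
#' @param seed RNG seed used to derive per-cell trace seeds when the trace
#'   specs carry none.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(frame_shape = c(64L, 64L), cells, psf_sigma = 0,
                       background_level = 100, seed = NULL) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 4), psf_sigma >= 0,
            background_level >= 0, length(cells) >= 1)
  for (cl in cells) {
    stopifnot(length(cl$center) == 2, cl$radius > 0, inherits(cl$spec, "trace_spec"))
    if (cl$center[1] - cl$radius < 1 || cl$center[1] + cl$radius > frame_shape[1] ||
        cl$center[2] - cl$radius < 1 || cl$center[2] + cl$radius > frame_shape[2])
      stop("cell disk extends beyond the frame bounds")
  }
  if (length(cells) > 1) {
    for (i in seq_len(length(cells) - 1)) for (j in seq(i + 1, length(cells))) {
      dist <- sqrt(sum((cells[[i]]$center - cells[[j]]$center)^2))
      if (dist <= cells[[i]]$radius + cells[[j]]$radius)
        stop(sprintf("cell disks %d and %d overlap; ROI truth would be ambiguous", i, j))
    }
  }
  structure(list(frame_shape = as.integer(frame_shape), cells = cells,
                 psf_sigma = psf_sigma, background_level = background_level,
                 seed = seed),
            class = "stack_spec")
}

# Separable Gaussian blur with replicate-edge padding; kernel truncated at
# 3 sigma. Only used when psf_sigma > 0.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    top <- m[rep(1L, half), , drop = FALSE]
    bot <- m[rep(nrow(m), half), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Render a synthetic image stack with label mask and ground truth
#'
#' Each frame is `background_level` plus, per cell, a (optionally blurred)
#' disk whose uniform intensity equals that cell's [make_trace()] value at
#' the frame, so the ROI mean inside the unblurred mask recovers the cell's
#' trace (exactly when `psf_sigma = 0`).
#'
#' @param spec A [stack_spec()].
#' @return List with `stack` (array height x width x frames), `mask`
#'   (integer matrix, 0 = background), `truth` (data frame), and `traces`
#'   (the underlying `fluor_trace` objects).
#' @export
make_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  n_cells <- length(spec$cells)
  masks <- vector("list", n_cells)
  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cl <- spec$cells[[i]]
    tspec <- cl$spec
    if (is.null(tspec$seed) && !is.null(spec$seed))
      tspec$seed <- derive_seed(spec$seed, "stack_cell", i)
    made <- make_trace(tspec, cell_id = sprintf("cell_%d", i))
    traces[[i]] <- made$trace
    truth[[i]] <- data.frame(cell_id = i, perforated = made$truth$perforated,
                             true_resealing_time = made$truth$true_resealing_time)
    masks[[i]] <- (rows - cl$center[1])^2 + (cols - cl$center[2])^2 <= cl$radius^2
  }
  n_frames <- length(traces[[1]]$intensities)
  stack <- array(spec$background_level, dim = c(h, w, n_frames))
  kernels <- lapply(masks, function(m) {
    k <- matrix(0, h, w); k[m] <- 1
    gaussian_blur(k, spec$psf_sigma)
  })
  for (f in seq_len(n_frames)) {
    frame <- matrix(spec$background_level, h, w)
    for (i in seq_len(n_cells)) frame <- frame + kernels[[i]] * traces[[i]]$intensities[f]
    stack[, , f] <- frame
  }
  mask <- matrix(0L, h, w)
  for (i in seq_len(n_cells)) mask[masks[[i]]] <- i
  list(stack = stack, mask = mask, truth = do.call(rbind, truth), traces = traces)
}

#' Write / read a stack as multi-frame 16-bit TIFF
#'
#' Intensities are stored as unsigned 16-bit samples; values must lie in
#' `[0, 65535]` and are rounded to integers on write.
#'
#' @param stack Numeric array height x width x frames.
#' @param path Output file path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns the array restored to the 0..65535 scale.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  if (min(stack) < 0 || max(stack) > 65535)
    stop("stack intensities must lie in [0, 65535] for 16-bit TIFF output")
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2], length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]] * 65535
  arr
}

#' Write / read a label mask as 16-bit TIFF
#' @param mask Integer matrix of label ids (0 = background).
#' @param path File path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Design of a synthetic photoporation experiment
#'
#' The ground-truth resealing time at each fluence is the exponential
#' calibration `a * exp(fluence / b) + c`; per-cell times add Gaussian
#' jitter of sd `jitter_sd` (truncated at zero, resampled if non-positive).
#'
#' @param fluences Laser fluences in J/cm^2, strictly positive and
#'   increasing. Defaults to the six experimental levels.
#' @param mol_weights Tracer molecular weights in kDa.
#' @param cells_per_condition Perforated cells generated per fluence.
#' @param unperforated_per_condition Additional flat-trace cells per fluence.
#' @param truth_curve Numeric `c(a, b, c)` of the fluence-to-resealing-time
#'   relation used as ground truth (defaults to the measured calibration
#'   `y = 106.3 exp(x / 2.7) - 80.6`).
#' @param jitter_sd Between-cell sd of true resealing times (s). The
#'   default is a small value suited to exact end-to-end verification;
#'   realistic biological scatter is several seconds.
#' @param trace Template [trace_spec()] whose perforation fields are
#'   overwritten per cell. The default carries no additive noise, again the
#'   exact-verification regime; pass `trace_spec(noise_sd = 10)` or similar
#'   for a realistic 1 percent acquisition noise level.
#' @param seed Master RNG seed for the design.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(fluences = c(0.064, 0.32, 0.64, 0.96, 1.28, 1.6),
                              mol_weights = c(5, 10, 40, 70, 100),
                              cells_per_condition = 10L,
                              unperforated_per_condition = 2L,
                              truth_curve = c(a = 106.3, b = 2.7, c = -80.6),
                              jitter_sd = 0.1,
                              trace = trace_spec(),
                              seed = 1L) {
  stopifnot(length(fluences) >= 1, all(fluences > 0),
            all(diff(fluences) > 0), cells_per_condition >= 1,
            unperforated_per_condition >= 0, length(truth_curve) == 3,
            jitter_sd >= 0, inherits(trace, "trace_spec"))
  structure(list(fluences = fluences, mol_weights = mol_weights,
                 cells_per_condition = as.integer(cells_per_condition),
                 unperforated_per_condition = as.integer(unperforated_per_condition),
                 truth_curve = setNames(as.numeric(truth_curve), c("a", "b", "c")),
                 jitter_sd = jitter_sd, trace = trace, seed = seed),
            class = "experiment_design")
}

#' Generate a full synthetic experiment: traces plus truth table
#'
#' @param design An [experiment_design()].
#' @return List with `traces` (list of `fluor_trace`) and `truth`
#'   (data frame: cell_id, fluence_J_cm2, mw_kDa, perforated,
#'   true_resealing_time_s, seed).
#' @export
make_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  tc <- design$truth_curve
  base_times <- tc["a"] * exp(design$fluences / tc["b"]) + tc["c"]
  bad <- which(base_times <= 0)
  if (length(bad))
    stop(sprintf("truth curve predicts non-positive resealing time at fluence %s J/cm2",
                 paste(design$fluences[bad], collapse = ", ")))
  mw <- if (length(design$mol_weights)) design$mol_weights[min(2L, length(design$mol_weights))] else NA_real_
  traces <- list(); rows <- list(); id <- 0L
  for (fi in seq_along(design$fluences)) {
    f <- design$fluences[fi]
    for (ci in seq_len(design$cells_per_condition + design$unperforated_per_condition)) {
      id <- id + 1L
      cell_seed <- derive_seed(design$seed, "experiment_cell", id)
      perf <- ci <= design$cells_per_condition
      tspec <- design$trace
      tspec$seed <- cell_seed
      tspec$perforated <- perf
      if (perf) {
        tt <- with_seed(cell_seed, function() {
          repeat {
            cand <- base_times[fi] + rnorm(1, sd = design$jitter_sd)
            if (cand > 0) return(cand)
          }
        })
        tspec$true_resealing_time <- tt
      } else tspec$true_resealing_time <- NA_real_
      made <- make_trace(tspec, cell_id = sprintf("cell_%03d", id))
      traces[[id]] <- made$trace
      rows[[id]] <- data.frame(cell_id = made$trace$cell_id,
                               fluence_J_cm2 = f, mw_kDa = mw,
                               perforated = perf,
                               true_resealing_time_s = if (perf) tspec$true_resealing_time else NA_real_,
                               seed = cell_seed)
    }
  }
  list(traces = traces, truth = do.call(rbind, rows))
}
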