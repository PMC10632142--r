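# build a roi_traces table directly from a T x n matrix of fluorescence
# values (one column per ROI), via a 1 x n movie with single-pixel masks
traces_from_matrix <- function(mat, frame_rate_hz = 4, roi_names = NULL) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  stack <- array(0, dim = c(nrow(mat), 1, n))
  for (j in seq_len(n)) stack[, 1, j] <- mat[, j]
  movie <- ca_movie(stack, frame_rate_hz = frame_rate_hz)
  masks <- lapply(seq_len(n), function(j) {
    m <- matrix(FALSE, 1, n)
    m[1, j] <- TRUE
    m
  })
  names(masks) <- roi_names %||% as.character(seq_len(n))
  extract_traces(movie, masks)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal 2-epoch schedule for hand-built traces
tiny_schedule <- function(t_first_s = 25, n_trials = 1,
                          directions = c(0, 90), speed = 500) {
  stim_schedule(directions_deg = directions, speed_um_s = speed,
                n_trials = n_trials, t_first_s = t_first_s, seed = 1)
}

# standard small movie settings used across tests (coarse field for speed)
fast_movie <- function(cells, sched, noise_sd = 0, seed = 1, ...) {
  synth_movie(cells, sched, px_per_um = 64 / 220, noise_sd = noise_sd,
              seed = seed, ...)
}

# run the trace pipeline on a bundle and return tuning profiles
bundle_profiles <- function(bundle, rois = NULL) {
  rois <- rois %||% truth_rois(bundle$cells, bundle$movie)
  tr <- extract_traces(bundle$movie, rois)
  tr <- subtract_background(tr, rep(bundle$background_f, dim(bundle$movie$stack)[1]))
  tr <- compute_dff(tr, bundle$schedule)
  resp <- epoch_responses(tr, bundle$schedule)
  tuning_profiles(resp, traces = tr, schedule = bundle$schedule)
}
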