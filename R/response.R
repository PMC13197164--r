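#' Construct a visuomotor response trace
#'
#' A response trace is a force (difference) signal on a regular time grid
#' whose zero is the instant the visual perturbation was actually
#' presented.
#'
#' @param time time from visual presentation, s (regular grid).
#' @param force force (or force difference), N.
#' @param experiment optional experiment label (1 or 2).
#' @param participant,condition optional identifiers carried through the
#'   pipeline.
#' @return Object of class `"response_trace"` (a data frame with columns
#'   `time`, `force`).
#' @export
response_trace <- function(time, force, experiment = NA_integer_,
                           participant = NA_character_,
                           condition = NA_character_) {
  stopifnot(length(time) == length(force))
  out <- data.frame(time = time, force = force)
  attr(out, "experiment") <- experiment
  attr(out, "participant") <- participant
  attr(out, "condition") <- condition
  class(out) <- c("response_trace", "data.frame")
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' 5th-order Butterworth with a 14 Hz cutoff, applied forward and
#' backward (`signal::filtfilt`) so the output is zero-phase; the
#' effective magnitude response is the square of the single-pass
#' response. Length is preserved.
#'
#' @param x numeric trace.
#' @param sample_rate sampling rate in Hz; must exceed twice the cutoff.
#' @param order filter order.
#' @param cutoff cutoff frequency, Hz.
#' @return Filtered trace of the same length.
#' @export
lowpass <- function(x, sample_rate, order = 5L, cutoff = 14) {
  if (sample_rate <= 2 * cutoff)
    stop("sample_rate must exceed twice the cutoff frequency", call. = FALSE)
  if (length(x) < 3L * (order + 1L))
    stop("trace too short for the filter warm-up", call. = FALSE)
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  n <- length(x)
  # remove the line through the endpoints and odd-reflect both edges so
  # the zero-initial-condition double pass has no edge transient; the
  # line is added back unchanged (it is in the passband)
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - line
  npad <- min(n - 1L, ceiling(3 * sample_rate / cutoff))
  pre <- 2 * r[1] - r[(npad + 1):2]
  post <- 2 * r[n] - r[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, r, post)))
  line + y[npad + seq_len(n)]
}

#' Re-time a trace to the visual presentation instant
#'
#' Shifts the time axis so that zero falls at the jump command time plus
#' the display latency (the LCD presented visual feedback 42 ms after the
#' command). No resampling is performed.
#'
#' @param trace a [response_trace()] (or data frame with `time`).
#' @param jump_command_time time of the jump command on the trace's
#'   current axis, s.
#' @param display_delay display latency, s.
#' @return The trace with a shifted time axis.
#' @export
align_trace <- function(trace, jump_command_time, display_delay = 0.042) {
  t0 <- jump_command_time + display_delay
  if (t0 < min(trace$time) || t0 > max(trace$time))
    stop("alignment point lies outside the trace", call. = FALSE)
  trace$time <- trace$time - t0
  trace
}

#' Visuomotor feedback response from left/right probe forces
#'
#' Per-participant probe forces are averaged within jump direction and
#' differenced: Experiment 1 (cursor jumps) uses mean(left) -
#' mean(right); Experiment 2 (target jumps) uses mean(right) -
#' mean(left). Inputs must share one aligned time grid.
#'
#' @param left_probe_forces,right_probe_forces numeric matrix (trials x
#'   samples) or vector of forces on a common aligned time grid.
#' @param time the common time grid (s from presentation).
#' @param experiment 1 or 2.
#' @return A [response_trace()].
#' @export
visuomotor_response <- function(left_probe_forces, right_probe_forces,
                                time, experiment = 1L) {
  as_mat <- function(f) if (is.matrix(f)) f else matrix(f, nrow = 1L)
  L <- as_mat(left_probe_forces); R <- as_mat(right_probe_forces)
  if (ncol(L) != ncol(R) || ncol(L) != length(time))
    stop("left and right probe forces must share the time grid",
         call. = FALSE)
  d <- colMeans(L) - colMeans(R)
  if (experiment == 2L) d <- -d
  response_trace(time, d, experiment = as.integer(experiment))
}

#' Epoch means of a visuomotor response trace
#'
#' Means over the involuntary (180-230 ms), semi-involuntary (230-300
#' ms) and voluntary (300-400 ms) windows after visual presentation.
#' Windows are half-open `[start, end)` on the sample grid.
#'
#' @param resp a [response_trace()].
#' @param windows named list of `c(start, end)` windows in s.
#' @return List with numeric fields `involuntary`, `semi_involuntary`,
#'   `voluntary` (N).
#' @export
epoch_means <- function(resp,
                        windows = list(involuntary = c(0.180, 0.230),
                                       semi_involuntary = c(0.230, 0.300),
                                       voluntary = c(0.300, 0.400))) {
  tmax <- max(vapply(windows, `[`, numeric(1), 2L))
  if (min(resp$time) > 0 || max(resp$time) < tmax - 1e-9)
    stop("response trace must cover 0-", round(tmax * 1000), " ms",
         call. = FALSE)
  lapply(windows, function(w) {
    sel <- resp$time >= w[1] - 1e-9 & resp$time < w[2] - 1e-9
    mean(resp$force[sel])
  })
}

#' Final lateral hand deviation
#'
#' Voluntary correction metric for perturbation trials: the difference
#' between the average final lateral hand position on non-perturbation
#' trials and on perturbation trials, with left-jump trials mirrored
#' about the midline first (sign-folded) so that corrections in the
#' direction opposing the jump accumulate positively.
#'
#' @param nonpert_final_x numeric final lateral positions of
#'   non-perturbation trials, m.
#' @param pert_final_x numeric final lateral positions of perturbation
#'   trials, m.
#' @param pert_direction character vector (`"left"`/`"right"`) matching
#'   `pert_final_x`; left trials are mirrored before averaging.
#' @param fold logical; set `FALSE` to skip sign-folding.
#' @return Scalar deviation in m.
#' @export
final_lateral_deviation <- function(nonpert_final_x, pert_final_x,
                                    pert_direction = NULL, fold = TRUE) {
  if (!length(nonpert_final_x) || !length(pert_final_x))
    stop("need at least one trial of each type", call. = FALSE)
  base <- mean(nonpert_final_x)
  if (fold && !is.null(pert_direction)) {
    stopifnot(length(pert_direction) == length(pert_final_x))
    mirror <- pert_direction == "left"
    pert_final_x[mirror] <- 2 * base - pert_final_x[mirror]
  }
  base - mean(pert_final_x)
}
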