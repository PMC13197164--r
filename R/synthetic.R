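# cache for model-derived condition effects (one entry per hypothesis x
# experiment under default parameters)
.effect_cache <- new.env(parent = emptyenv())

#' Model-predicted involuntary epoch mean for a hypothesis and condition
#'
#' Runs a noise-free probe batch of the dynamic game model (once per
#' hypothesis and experiment; results are cached for the session) and
#' returns the involuntary-epoch (180-230 ms) visuomotor feedback
#' response the model predicts for the given condition, optionally
#' scaled. These values anchor the synthetic dataset generator so that
#' synthetic condition structure follows the model predictions.
#'
#' @param hypothesis one of [hypotheses()].
#' @param condition one of [conditions()], or `NULL` for the named
#'   vector over all four conditions.
#' @param experiment 1 or 2.
#' @param params a [model_params()] object (defaults are cached; custom
#'   parameter sets are recomputed each call).
#' @param scale multiplicative scale applied to the model value.
#' @return Expected involuntary epoch mean(s) in N.
#' @export
effect_model <- function(hypothesis, condition = NULL, experiment = 1L,
                         params = NULL, scale = 1) {
  hypothesis <- match.arg(hypothesis, hypotheses())
  default_params <- is.null(params)
  if (default_params) params <- model_params()
  key <- paste0(hypothesis, ".exp", experiment)
  if (default_params && !is.null(.effect_cache[[key]])) {
    eff <- .effect_cache[[key]]
  } else {
    batch <- run_batch(hypothesis, conditions(), params,
                       n_trials = 1L, experiment = experiment, noise = FALSE)
    eff <- vapply(batch, `[[`, numeric(1), "involuntary_mean")
    if (default_params) .effect_cache[[key]] <- eff
  }
  eff <- eff * scale
  if (is.null(condition)) eff else unname(eff[match.arg(condition, conditions())])
}

#' Noise and effect-scale parameters of the synthetic dataset generator
#'
#' @param between_participant_sd SD of the per-participant, per-condition
#'   deviation of the true involuntary epoch mean from the condition
#'   effect, N. The default was chosen once so that synthetic effect
#'   sizes (theta-hat) for the planned comparisons fall in the empirical
#'   60-90 range at n = 48.
#' @param trial_amplitude_sd SD of the per-trial multiplicative response
#'   amplitude jitter (fraction of the participant's mean response).
#' @param trace_noise_sd white measurement noise SD on each 1000 Hz force
#'   sample, N.
#' @param final_sd SD of final lateral hand positions, m.
#' @param deviation_relevant,deviation_irrelevant mean corrective final
#'   lateral hand deviation on perturbation trials for a self-relevant /
#'   self-irrelevant target, m.
#' @return List of class `"synth_noise"`.
#' @export
synth_noise <- function(between_participant_sd = 0.21,
                        trial_amplitude_sd = 0.15,
                        trace_noise_sd = 0.25,
                        final_sd = 0.004,
                        deviation_relevant = 0.025,
                        deviation_irrelevant = 0.003) {
  structure(list(between_participant_sd = between_participant_sd,
                 trial_amplitude_sd = trial_amplitude_sd,
                 trace_noise_sd = trace_noise_sd,
                 final_sd = final_sd,
                 deviation_relevant = deviation_relevant,
                 deviation_irrelevant = deviation_irrelevant),
            class = "synth_noise")
}

# condition label of a participant given own/partner target relevance
.cond_label <- function(self_relevant, partner_relevant) {
  paste0(ifelse(partner_relevant, "pr", "pi"), "/",
         ifelse(self_relevant, "sr", "si"))
}

# smooth response template: 0 before ~140 ms, smoothstep rise, plateau 1
# from 180 ms on, so the involuntary/semi-involuntary/voluntary epoch
# means of the noiseless template are exactly 1
.response_template <- function(time, rise_start = 0.140, rise_end = 0.180) {
  u <- pmin(pmax((time - rise_start) / (rise_end - rise_start), 0), 1)
  u * u * (3 - 2 * u)
}

#' Generate per-participant involuntary epoch means (fast path)
#'
#' Draws the participant-level involuntary epoch table directly from the
#' effect model plus between-participant Gaussian variability, without
#' synthesizing force traces. This is the table the full trace pipeline
#' recovers (up to trial-level noise) and is used for power studies.
#'
#' @param effect named numeric vector of condition effects (N), as from
#'   [effect_model()].
#' @param noise a [synth_noise()] object.
#' @param n_participants number of participants.
#' @param seed integer seed.
#' @return Data frame, participants x conditions (columns
#'   [conditions()]).
#' @export
generate_epoch_table <- function(effect, noise = synth_noise(),
                                 n_participants = 48L, seed = 1L) {
  stopifnot(all(conditions() %in% names(effect)))
  set.seed(seed)
  tab <- sapply(conditions(), function(cond) {
    effect[[cond]] + stats::rnorm(n_participants, 0,
                                  noise$between_participant_sd)
  })
  as.data.frame(tab, check.names = FALSE)
}

#' Generate a synthetic paired dataset
#'
#' Emulates the structure of the two-experiment study: `n_pairs` pairs,
#' four blocked 2x2 target-relevance conditions per pair, and per block
#' one lead-in non-perturbation trial plus 10 randomized sets of 15
#' trials (8 non-perturbation, 2 left + 2 right perturbation, 1 left + 1
#' right + 1 null force-channel probe), i.e. 151 trials per block: 81
#' non-perturbation, 40 perturbation and 30 probe trials. Probe trials
#' carry 1000 Hz lateral-force traces whose involuntary epoch means
#' follow the condition effect plus between-participant variability;
#' non-perturbation and perturbation trials carry final lateral hand
#' positions.
#'
#' @param effect named numeric vector of condition effects (N) or a
#'   hypothesis label (resolved via [effect_model()], which requires
#'   solving the model once).
#' @param noise a [synth_noise()] object; pass SDs of 0 for a noiseless
#'   dataset.
#' @param n_pairs number of pairs.
#' @param experiment 1 or 2 (sets the force sign convention of the probe
#'   traces).
#' @param seed integer seed; fixed seeds give identical datasets.
#' @param sample_rate force trace sampling rate, Hz.
#' @param trace_window time window of the probe traces relative to
#'   visual presentation, s.
#' @return Object of class `"pair_dataset"`: list with `trials` (trial
#'   sequence and final positions), `trace_meta` + `traces` (one row per
#'   probe trace), `trace_time`, `participant_effects` (the true
#'   per-participant epoch means), `experiment` and `manifest`.
#' @export
generate_dataset <- function(effect = "rep_weighted", noise = synth_noise(),
                             n_pairs = 24L, experiment = 1L, seed = 1L,
                             sample_rate = 1000,
                             trace_window = c(-0.1, 0.5)) {
  if (is.character(effect) && length(effect) == 1L)
    effect <- effect_model(effect, experiment = experiment)
  stopifnot(all(conditions() %in% names(effect)))
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  set.seed(seed)

  time <- seq(trace_window[1], trace_window[2], by = 1 / sample_rate)
  template <- .response_template(time)
  # sign applied to a participant's force on a left-jump probe such that
  # the experiment's differencing convention recovers + (epoch mean)
  left_sign <- if (experiment == 1L) 1 else -1

  set_types <- c(rep("non_perturbation", 8L),
                 rep("perturbation", 4L), rep("probe", 2L), "null_probe")
  set_dirs <- c(rep("none", 8L), "left", "left", "right", "right",
                "left", "right", "none")
  blocks <- list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE),
                 c(TRUE, TRUE))   # (self-relevance of A, of B)

  trials <- list(); meta <- list(); traces <- list()
  effects <- list()
  ti <- 0L
  for (pr in seq_len(n_pairs)) {
    pid <- c(sprintf("P%02dA", pr), sprintf("P%02dB", pr))
    block_order <- sample(4L)
    for (bi in seq_along(block_order)) {
      rel <- blocks[[block_order[bi]]]
      cond <- c(.cond_label(rel[1], rel[2]), .cond_label(rel[2], rel[1]))
      mu <- vapply(1:2, function(j) {
        effect[[cond[j]]] +
          stats::rnorm(1, 0, noise$between_participant_sd)
      }, numeric(1))
      effects[[length(effects) + 1L]] <- data.frame(
        pair = pr, participant = pid, condition = cond,
        epoch_mean = mu)
      # trial sequence: lead-in + 10 randomized sets of 15
      seq_type <- "non_perturbation"; seq_dir <- "none"
      for (s in seq_len(10L)) {
        ord <- sample(length(set_types))
        seq_type <- c(seq_type, set_types[ord])
        seq_dir <- c(seq_dir, set_dirs[ord])
      }
      for (k in seq_along(seq_type)) {
        ti <- ti + 1L
        type <- seq_type[k]; dir <- seq_dir[k]
        for (j in 1:2) {
          self_rel <- rel[j]
          final_x <- NA_real_
          if (type %in% c("non_perturbation", "perturbation")) {
            dev <- if (type == "non_perturbation") 0 else
              if (self_rel) noise$deviation_relevant else
                noise$deviation_irrelevant
            sgn <- switch(dir, left = 1, right = -1, 0)
            final_x <- 0.13 + sgn * dev +
              stats::rnorm(1, 0, noise$final_sd)
          }
          trials[[length(trials) + 1L]] <- data.frame(
            pair = pr, participant = pid[j], condition = cond[j],
            block = bi, trial = k, type = type, direction = dir,
            final_x = final_x)
          if (type %in% c("probe", "null_probe")) {
            amp <- if (type == "null_probe") 0 else {
              s_dir <- if (dir == "left") left_sign else -left_sign
              s_dir * (mu[j] / 2) *
                (1 + stats::rnorm(1, 0, noise$trial_amplitude_sd))
            }
            f <- amp * template +
              stats::rnorm(length(time), 0, noise$trace_noise_sd)
            meta[[length(meta) + 1L]] <- data.frame(
              pair = pr, participant = pid[j], condition = cond[j],
              block = bi, trial = k, type = type, direction = dir)
            traces[[length(traces) + 1L]] <- f
          }
        }
      }
    }
  }
  structure(list(
    trials = do.call(rbind, trials),
    trace_meta = do.call(rbind, meta),
    traces = do.call(rbind, traces),
    trace_time = time,
    participant_effects = do.call(rbind, effects),
    experiment = as.integer(experiment),
    manifest = list(seed = seed, n_pairs = n_pairs,
                    experiment = as.integer(experiment),
                    effect = as.list(effect), noise = unclass(noise),
                    sample_rate = sample_rate)),
    class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("Synthetic pair dataset: experiment %d, %d pairs, %d trials, %d probe traces\n",
              x$experiment, x$manifest$n_pairs, nrow(x$trials),
              nrow(x$trace_meta)))
  invisible(x)
}
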