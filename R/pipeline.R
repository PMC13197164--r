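#' Turn a dataset's probe traces into per-participant epoch tables
#'
#' For every participant and condition: averages the left-jump and
#' right-jump probe force traces within direction, low-pass filters the
#' averages (5th-order zero-phase Butterworth, 14 Hz), forms the
#' visuomotor feedback response with the experiment's differencing
#' convention, and computes the involuntary, semi-involuntary and
#' voluntary epoch means.
#'
#' @param ds a [generate_dataset()] result (or a dataset loaded with
#'   [load_trial_table()]).
#' @param filter logical; apply the Butterworth filter (disable to check
#'   exact recovery identities on noiseless data).
#' @return Object of class `"epoch_tables"`: list of three data frames
#'   (`involuntary`, `semi_involuntary`, `voluntary`), each participants
#'   x conditions with a `participant` column.
#' @export
analyze_dataset <- function(ds, filter = TRUE) {
  stopifnot(inherits(ds, "pair_dataset"))
  meta <- ds$trace_meta
  sample_rate <- 1 / mean(diff(ds$trace_time))
  participants <- unique(meta$participant)
  epochs <- c("involuntary", "semi_involuntary", "voluntary")
  tabs <- lapply(epochs, function(e) {
    d <- as.data.frame(matrix(NA_real_, length(participants),
                              length(conditions())))
    names(d) <- conditions()
    d
  })
  names(tabs) <- epochs
  for (i in seq_along(participants)) {
    for (cond in conditions()) {
      selL <- meta$participant == participants[i] & meta$condition == cond &
        meta$type == "probe" & meta$direction == "left"
      selR <- meta$participant == participants[i] & meta$condition == cond &
        meta$type == "probe" & meta$direction == "right"
      if (!any(selL) || !any(selR))
        stop("participant ", participants[i], " lacks probe trials in ",
             cond, call. = FALSE)
      mL <- colMeans(ds$traces[selL, , drop = FALSE])
      mR <- colMeans(ds$traces[selR, , drop = FALSE])
      if (filter) {
        mL <- lowpass(mL, sample_rate)
        mR <- lowpass(mR, sample_rate)
      }
      resp <- visuomotor_response(mL, mR, ds$trace_time,
                                  experiment = ds$experiment)
      em <- epoch_means(resp)
      for (e in epochs) tabs[[e]][i, cond] <- em[[sub("semi_involuntary",
                                                      "semi_involuntary", e)]]
    }
  }
  for (e in epochs) tabs[[e]] <- cbind(participant = participants, tabs[[e]])
  structure(tabs, class = "epoch_tables", experiment = ds$experiment)
}

#' Full statistical report for a set of epoch tables
#'
#' Runs, per epoch, the 2x2 repeated-measures ANOVA (self, partner,
#' interaction) and the planned paired bootstrap comparisons with
#' Holm-Bonferroni correction and common-language effect sizes.
#'
#' @param tables an [analyze_dataset()] result, or a single epoch table.
#' @param n_boot bootstrap resamples per comparison.
#' @param seed integer seed for the bootstrap.
#' @return List with data frames `anova` and `comparisons`, each with an
#'   `epoch` column.
#' @export
dataset_statistics <- function(tables, n_boot = 1e6, seed = 1L) {
  if (!inherits(tables, "epoch_tables"))
    tables <- structure(list(involuntary = tables), class = "epoch_tables")
  an <- list(); cmp <- list()
  for (e in names(tables)) {
    tab <- tables[[e]][, conditions(), drop = FALSE]
    a <- rm_anova_2x2(tab)
    a$epoch <- e
    an[[e]] <- a
    cc <- epoch_comparisons(tab, n_boot = n_boot, seed = seed)
    cc$epoch <- e
    cmp[[e]] <- cc
  }
  list(anova = do.call(rbind, c(an, make.row.names = FALSE)),
       comparisons = do.call(rbind, c(cmp, make.row.names = FALSE)))
}

# canonical columns of the long probe-trace interchange format
.trace_columns <- c("pair", "participant", "condition", "block", "trial",
                    "type", "direction", "t", "force")

#' Write a dataset to plain-text tables
#'
#' Writes `trials.csv` (trial sequence with final lateral positions),
#' `probes.csv` (long format, one row per probe force sample) and
#' `manifest.json` (seed and generation parameters) into a directory.
#'
#' @param ds a `"pair_dataset"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_trial_table <- function(ds, dir) {
  stopifnot(inherits(ds, "pair_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  nt <- length(ds$trace_time)
  long <- ds$trace_meta[rep(seq_len(nrow(ds$trace_meta)), each = nt), ]
  long$t <- rep(ds$trace_time, times = nrow(ds$trace_meta))
  long$force <- as.vector(t(ds$traces))
  utils::write.csv(long, file.path(dir, "probes.csv"), row.names = FALSE)
  jsonlite::write_json(c(ds$manifest, list(experiment = ds$experiment)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset from column-mapped tabular files
#'
#' Adapter for externally recorded (or previously written) data. Reads a
#' long-format probe-force table (one row per sample) plus an optional
#' trial-sequence table and maps the file's column names onto the
#' canonical fields `pair`, `participant`, `condition`, `block`,
#' `trial`, `type`, `direction`, `t` (s), `force` (N). All probe traces
#' must share one regular time grid. Units are expected in m/s/N.
#'
#' @param path directory containing `probes.csv` (and optionally
#'   `trials.csv`), or the path of the probe-sample CSV itself.
#' @param column_mapping named character vector mapping canonical field
#'   names to the file's column names; canonical names missing from the
#'   mapping are assumed to be literal column names.
#' @param experiment 1 or 2.
#' @return A `"pair_dataset"`.
#' @export
load_trial_table <- function(path, column_mapping = NULL, experiment = 1L) {
  probe_file <- if (dir.exists(path)) file.path(path, "probes.csv") else path
  if (!file.exists(probe_file))
    stop("no such file: ", probe_file, call. = FALSE)
  raw <- utils::read.csv(probe_file, check.names = FALSE)
  mapped <- function(field) {
    nm <- if (!is.null(column_mapping) && field %in% names(column_mapping))
      column_mapping[[field]] else field
    if (!nm %in% names(raw))
      stop("schema error: required column '", field, "' (file column '",
           nm, "') not found", call. = FALSE)
    raw[[nm]]
  }
  d <- data.frame(pair = mapped("pair"), participant = mapped("participant"),
                  condition = mapped("condition"), block = mapped("block"),
                  trial = mapped("trial"), type = mapped("type"),
                  direction = mapped("direction"),
                  t = mapped("t"), force = mapped("force"))
  bad <- !d$condition %in% conditions()
  if (any(bad))
    stop("malformed rows (unknown condition) at file row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  key <- interaction(d$pair, d$participant, d$condition, d$block, d$trial,
                     d$direction, d$type, drop = TRUE)
  time <- sort(unique(d$t))
  ord <- order(key, d$t)
  d <- d[ord, ]
  nt <- length(time)
  ntr <- nrow(d) / nt
  if (ntr != round(ntr))
    stop("probe traces do not share a common time grid", call. = FALSE)
  traces <- matrix(d$force, nrow = ntr, ncol = nt, byrow = TRUE)
  meta <- d[seq(1, nrow(d), by = nt),
            c("pair", "participant", "condition", "block", "trial",
              "type", "direction")]
  rownames(meta) <- NULL
  trials_file <- if (dir.exists(path)) file.path(path, "trials.csv") else ""
  trials <- if (nzchar(trials_file) && file.exists(trials_file))
    utils::read.csv(trials_file, check.names = FALSE) else meta
  structure(list(trials = trials, trace_meta = meta, traces = traces,
                 trace_time = time,
                 participant_effects = NULL,
                 experiment = as.integer(experiment),
                 manifest = list(source = normalizePath(probe_file))),
            class = "pair_dataset")
}

#' Run a configured analysis pipeline end to end
#'
#' Executes one or more stages and writes their outputs (plus a
#' `manifest.json` recording the configuration, seed and package
#' version) into `config$out_dir`. Stages:
#' \describe{
#'   \item{`simulate`}{model probe batches for `config$hypotheses` x
#'     [conditions()]; writes `model_vfr.csv` of involuntary epoch
#'     means.}
#'   \item{`synth`}{synthetic dataset via [generate_dataset()]; written
#'     with [write_trial_table()].}
#'   \item{`analyze`}{epoch tables from the dataset in
#'     `config$data_dir` (or the one just generated); writes
#'     `epochs_<epoch>.csv`.}
#'   \item{`stats`}{ANOVA + bootstrap report from the epoch tables;
#'     writes `anova.csv` and `comparisons.csv`.}
#' }
#'
#' @param config named list; recognized fields: `stages`, `out_dir`,
#'   `experiment`, `hypotheses`, `effect` (named list of condition
#'   effects in N), `n_pairs`, `n_trials`, `n_boot`, `seed`,
#'   `data_dir`. A path to a YAML file is also accepted.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% c("synth", "analyze", "stats")
  bad <- setdiff(stages, c("simulate", "synth", "analyze", "stats"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  hyps <- config$hypotheses %||% "rep_weighted"
  if (!all(hyps %in% hypotheses()))
    stop("unknown hypothesis label(s): ",
         paste(setdiff(hyps, hypotheses()), collapse = ", "), call. = FALSE)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  experiment <- config$experiment %||% 1L
  res <- list()

  if ("simulate" %in% stages) {
    rows <- list()
    for (h in hyps) {
      b <- run_batch(h, conditions(), n_trials = config$n_trials %||% 100L,
                     seed = seed, experiment = experiment)
      for (cond in names(b))
        rows[[paste(h, cond)]] <- data.frame(
          hypothesis = h, condition = cond,
          involuntary_vfr = b[[cond]]$involuntary_mean)
    }
    res$simulate <- do.call(rbind, c(rows, make.row.names = FALSE))
    utils::write.csv(res$simulate, file.path(out_dir, "model_vfr.csv"),
                     row.names = FALSE)
  }
  if ("synth" %in% stages) {
    eff <- if (!is.null(config$effect)) unlist(config$effect) else
      hyps[[1]]
    res$dataset <- generate_dataset(effect = eff,
                                    n_pairs = config$n_pairs %||% 24L,
                                    experiment = experiment, seed = seed)
    write_trial_table(res$dataset, file.path(out_dir, "dataset"))
  }
  if ("analyze" %in% stages) {
    ds <- res$dataset %||% load_trial_table(config$data_dir,
                                            experiment = experiment)
    res$epochs <- analyze_dataset(ds)
    for (e in names(res$epochs))
      utils::write.csv(res$epochs[[e]],
                       file.path(out_dir, paste0("epochs_", e, ".csv")),
                       row.names = FALSE)
  }
  if ("stats" %in% stages) {
    tabs <- res$epochs
    if (is.null(tabs)) {
      files <- list.files(out_dir %||% config$data_dir, "^epochs_.*\\.csv$",
                          full.names = TRUE)
      if (!length(files)) stop("no epoch tables for the stats stage",
                               call. = FALSE)
      tabs <- lapply(files, utils::read.csv, check.names = FALSE)
      names(tabs) <- sub("^epochs_(.*)\\.csv$", "\\1", basename(files))
      class(tabs) <- "epoch_tables"
    }
    res$stats <- dataset_statistics(tabs, n_boot = config$n_boot %||% 1e6,
                                    seed = seed)
    utils::write.csv(res$stats$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(res$stats$comparisons,
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("dyadgame")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
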