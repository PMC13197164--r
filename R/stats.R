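#' 2x2 repeated-measures ANOVA on an epoch table
#'
#' Fits the standard fully within-subject 2 (self relevance) x 2
#' (partner relevance) ANOVA via `stats::aov` with `Error` strata and
#' returns the two main effects and the interaction. For a complete
#' design with n participants every effect has df = (1, n - 1).
#'
#' @param table data frame with one row per participant and columns
#'   named as in [conditions()] (`pi/si`, `pr/si`, `pi/sr`, `pr/sr`), or
#'   a matrix with those column names.
#' @return Data frame with columns `effect` (`self`, `partner`,
#'   `interaction`), `F`, `df1`, `df2`, `p`.
#' @examples
#' set.seed(1)
#' tab <- matrix(rnorm(48 * 4), 48, dimnames = list(NULL, conditions()))
#' rm_anova_2x2(tab)
#' @export
rm_anova_2x2 <- function(table) {
  table <- as.data.frame(table, check.names = FALSE)
  miss <- setdiff(conditions(), names(table))
  if (length(miss))
    stop("epoch table is missing condition column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(table[conditions()]))
    stop("epoch table has missing cells", call. = FALSE)
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)

  long <- data.frame(
    id = factor(rep(seq_len(n), times = 4L)),
    self = factor(rep(c("irrelevant", "irrelevant", "relevant", "relevant"),
                      each = n)),
    partner = factor(rep(c("irrelevant", "relevant", "irrelevant", "relevant"),
                         each = n)),
    value = c(table[["pi/si"]], table[["pr/si"]],
              table[["pi/sr"]], table[["pr/sr"]]))
  fit <- stats::aov(value ~ self * partner + Error(id / (self * partner)),
                    data = long)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(term, trimws(rownames(tab)))
    data.frame(effect = sub("self:partner", "interaction",
                            sub("^self$", "self",
                                sub("^partner$", "partner", term))),
               F = tab[i, "F value"],
               df1 = tab[i, "Df"],
               df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
               p = tab[i, "Pr(>F)"])
  }
  out <- rbind(grab("id:self", "self"),
               grab("id:partner", "partner"),
               grab("id:self:partner", "self:partner"))
  rownames(out) <- NULL
  out
}

#' Non-parametric paired bootstrap test for a mean difference
#'
#' Resamples the participant-level paired differences, recentered to
#' mean zero, with replacement; the two-tailed p-value is the proportion
#' of resampled means at least as extreme (in absolute value) as the
#' observed mean, with a +1 continuity correction on numerator and
#' denominator.
#'
#' @param a,b paired per-participant values (equal length, n >= 2).
#' @param n_boot number of bootstrap resamples (the analysis default is
#'   1,000,000).
#' @param seed optional integer seed.
#' @return Two-tailed p-value.
#' @export
bootstrap_paired <- function(a, b, n_boot = 1e6, seed = NULL) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  if (length(a) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  .boot_paired_p(as.numeric(a - b), as.integer(n_boot))
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param alpha significance threshold for the returned decisions.
#' @return List with `adjusted` p-values (monotone step-down) and
#'   logical `reject` at level `alpha`.
#' @examples
#' holm_bonferroni(c(0.010, 0.020, 0.040))$adjusted  # 0.030 0.040 0.040
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}

#' Common-language effect size for paired data
#'
#' The percentage of participants whose paired difference `a - b` lies in
#' the hypothesized direction (that `a` exceeds `b`), with ties given
#' half weight: `theta = 100 (count(a > b) + 0.5 count(a == b)) / n`. On
#' tie-free data with n participants, theta is a multiple of 100/n.
#'
#' @param a,b paired per-participant values; `a` is the condition
#'   hypothesized to be larger.
#' @return Effect size in percent (0-100).
#' @examples
#' common_language_effect_size(2:49, rep(1, 48))  # 100
#' @export
common_language_effect_size <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  n <- length(a)
  if (n == 0L) stop("need n >= 1 pairs", call. = FALSE)
  d <- a - b
  100 * (sum(d > 0) + 0.5 * sum(d == 0)) / n
}

#' Planned pairwise comparisons of an epoch table
#'
#' Runs the two planned follow-up comparisons on one epoch table
#' (partner-relevant/self-irrelevant vs partner-irrelevant/
#' self-irrelevant, and partner-irrelevant/self-relevant vs
#' partner-relevant/self-relevant), each as a paired bootstrap test with
#' Holm-Bonferroni correction and a common-language effect size in the
#' direction hypothesized larger by the weighted-joint-cost model.
#'
#' @param table epoch table as in [rm_anova_2x2()].
#' @param n_boot bootstrap resamples per comparison.
#' @param seed integer seed.
#' @return Data frame with columns `comparison`, `larger`, `smaller`,
#'   `p`, `p_holm`, `theta`.
#' @export
epoch_comparisons <- function(table, n_boot = 1e6, seed = 1L) {
  table <- as.data.frame(table, check.names = FALSE)
  plan <- list(c("pr/si", "pi/si"), c("pi/sr", "pr/sr"))
  set.seed(seed)
  p <- vapply(plan, function(cmp) {
    .boot_paired_p(as.numeric(table[[cmp[1]]] - table[[cmp[2]]]),
                   as.integer(n_boot))
  }, numeric(1))
  theta <- vapply(plan, function(cmp) {
    common_language_effect_size(table[[cmp[1]]], table[[cmp[2]]])
  }, numeric(1))
  data.frame(
    comparison = vapply(plan, paste, character(1), collapse = " vs "),
    larger = vapply(plan, `[`, character(1), 1L),
    smaller = vapply(plan, `[`, character(1), 2L),
    p = p,
    p_holm = holm_bonferroni(p)$adjusted,
    theta = theta)
}

#' Monte-Carlo type-I error of the paired bootstrap under a normal null
#'
#' Draws `n_tests` independent samples of `n` standard-normal paired
#' differences and bootstraps each; returns the rejection rate at
#' `alpha` and the raw p-values.
#'
#' @param n_tests number of simulated tests.
#' @param n sample size per test.
#' @param n_boot bootstrap resamples per test.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return List with `rate` and `p`.
#' @export
bootstrap_type1_study <- function(n_tests = 5000L, n = 48L, n_boot = 10000L,
                                  alpha = 0.05, seed = 1L) {
  set.seed(seed)
  p <- .boot_null_study(as.integer(n_tests), as.integer(n),
                        as.integer(n_boot))
  list(rate = mean(p < alpha), p = p)
}
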