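# Two-group continuous sample-size estimation (normal approximation, common
# standard deviation) and scenario simulation propagating effect-size
# uncertainty into a distribution of required sample sizes and power-shortfall
# probabilities.

#' Inputs for two-group continuous sample-size estimation
#'
#' @param mean1,mean2 The two group means.
#' @param sd Common standard deviation (> 0).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param target_power Target power in (0, 1); default 0.80.
#' @param sides `"two"` (default) or `"one"`.
#' @return A `sample_size_inputs` list.
#' @export
sample_size_inputs <- function(mean1, mean2, sd, alpha = 0.05,
                               target_power = 0.80, sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(is.finite(mean1), is.finite(mean2), sd > 0,
            alpha > 0, alpha < 1, target_power > 0, target_power < 1)
  structure(list(mean1 = mean1, mean2 = mean2, sd = sd, alpha = alpha,
                 target_power = target_power, sides = sides),
            class = "sample_size_inputs")
}

z_alpha <- function(inputs) {
  a <- if (inputs$sides == "two") inputs$alpha / 2 else inputs$alpha
  stats::qnorm(1 - a)
}

#' Required per-group sample size for a fixed effect
#'
#' Normal-approximation closed form for a two-group comparison of a
#' continuous outcome with common standard deviation:
#' \deqn{n = \lceil 2 \sigma^2 (z_{1-\alpha^*} + z_{power})^2 / \Delta^2 \rceil}
#' per group, with \eqn{\alpha^* = \alpha/2} for a two-sided test, and a
#' floor of 2 per group.
#'
#' @param inputs A [sample_size_inputs()]; `mean1` must differ from `mean2`.
#' @param delta Optional override of the absolute mean difference.
#' @return Integer per-group sample size.
#' @export
required_n_fixed <- function(inputs, delta = NULL) {
  stopifnot(inherits(inputs, "sample_size_inputs"))
  delta <- abs(delta %||% (inputs$mean1 - inputs$mean2))
  if (delta == 0)
    stop("zero effect size: required sample size is unbounded", call. = FALSE)
  z_a <- z_alpha(inputs)
  z_b <- stats::qnorm(inputs$target_power)
  n <- ceiling(2 * inputs$sd^2 * (z_a + z_b)^2 / delta^2)
  max(as.integer(n), 2L)
}

#' Achieved power at a given per-group sample size
#'
#' Normal-approximation power (dominant tail):
#' \deqn{power = \Phi(|\Delta| / (\sigma \sqrt{2/n}) - z_{1-\alpha^*})}
#' For a zero effect this reduces to the test size \eqn{\alpha^*}.
#'
#' @param inputs A [sample_size_inputs()].
#' @param n Per-group sample size (>= 2).
#' @param delta Optional override of the absolute mean difference.
#' @return Power in (0, 1).
#' @export
achieved_power <- function(inputs, n, delta = NULL) {
  stopifnot(inherits(inputs, "sample_size_inputs"), n >= 2)
  delta <- abs(delta %||% (inputs$mean1 - inputs$mean2))
  stats::pnorm(delta / (inputs$sd * sqrt(2 / n)) - z_alpha(inputs))
}

#' Scenario simulation of sample size under effect-size uncertainty
#'
#' Uncertainty about the effect size is expressed as bounds on a
#' multiplicative shrinkage factor in (0, 1] applied to the stated mean
#' difference. Scenario multipliers are drawn uniformly between the bounds
#' (or equally spaced in `"grid"` mode); each scenario's required per-group
#' sample size is computed with [required_n_fixed()], summarised by
#' minimum / median / mean / maximum, and converted into a table of
#' power-shortfall probabilities: for each candidate sample size, the
#' fraction of scenarios whose achieved power falls below `power_threshold`
#' (90% by default).
#'
#' @param inputs A [sample_size_inputs()].
#' @param lower,upper Bounds on the effect multiplier, 0 < lower <= upper <= 1
#'   (a lower bound of exactly 0 is rejected: a zero multiplier means zero
#'   effect and an unbounded sample size).
#' @param n_scenarios Number of scenarios (>= 1).
#' @param mode `"uniform_random"` (default) or `"grid"`.
#' @param power_threshold Power threshold for the shortfall table; default 0.90.
#' @param seed Integer seed (used in `uniform_random` mode).
#' @return A `sample_size_scenario_result` list: `lower`, `upper`,
#'   `n_scenarios`, `scenario_multipliers`, `scenario_effects`, `scenario_n`,
#'   `summary` (min/median/mean/max of per-group n), `power_table`
#'   (data frame `n`, `prob_power_below`), `power_threshold`, `seed`.
#' @export
scenario_sample_sizes <- function(inputs, lower, upper, n_scenarios = 100,
                                  mode = c("uniform_random", "grid"),
                                  power_threshold = 0.90, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(inputs, "sample_size_inputs"), n_scenarios >= 1)
  if (lower <= 0)
    stop("lower bound must be > 0: a zero effect multiplier gives a zero ",
         "effect size and an unbounded sample size", call. = FALSE)
  if (!(lower <= upper && upper <= 1))
    stop("bounds must satisfy 0 < lower <= upper <= 1", call. = FALSE)
  base_delta <- abs(inputs$mean1 - inputs$mean2)
  if (base_delta == 0)
    stop("zero effect size: mean1 equals mean2", call. = FALSE)
  mult <- if (mode == "grid") {
    if (n_scenarios == 1) (lower + upper) / 2
    else seq(lower, upper, length.out = n_scenarios)
  } else {
    with_seed(seed, stats::runif(n_scenarios, lower, upper))
  }
  effects <- mult * base_delta
  ns <- vapply(effects, function(d) required_n_fixed(inputs, delta = d), 0L)
  smry <- list(minimum = min(ns), median = stats::median(ns),
               mean = mean(ns), maximum = max(ns))
  res <- structure(list(lower = lower, upper = upper,
                        n_scenarios = as.integer(n_scenarios),
                        scenario_multipliers = mult,
                        scenario_effects = effects, scenario_n = ns,
                        summary = smry, power_table = NULL,
                        power_threshold = power_threshold,
                        seed = as.integer(seed)),
                   class = "sample_size_scenario_result")
  res$power_table <- power_probability_table(res, inputs)
  res
}

#' Power-shortfall probability table
#'
#' For each candidate per-group sample size, the fraction of uncertainty
#' scenarios in which the achieved power falls below the threshold. The
#' default candidate list is the deciles of the scenario sample sizes
#' (rounded, deduplicated, ascending). Fractions are non-increasing in the
#' candidate size because power is increasing in n.
#'
#' @param result A `sample_size_scenario_result`.
#' @param inputs The [sample_size_inputs()] the scenarios came from.
#' @param candidate_ns Optional integer candidate sizes (all >= 2).
#' @return Data frame with columns `n` and `prob_power_below`.
#' @export
power_probability_table <- function(result, inputs, candidate_ns = NULL) {
  stopifnot(inherits(result, "sample_size_scenario_result"),
            inherits(inputs, "sample_size_inputs"))
  if (length(result$scenario_n) == 0)
    stop("empty scenario set", call. = FALSE)
  if (is.null(candidate_ns)) {
    candidate_ns <- unique(round(stats::quantile(result$scenario_n,
                                                 probs = seq(0, 1, by = 0.1),
                                                 type = 7, names = FALSE)))
    candidate_ns <- sort(pmax(candidate_ns, 2L))
    candidate_ns <- unique(as.integer(candidate_ns))
  }
  if (any(candidate_ns < 2)) stop("candidate sizes must be >= 2", call. = FALSE)
  frac <- vapply(candidate_ns, function(n) {
    pw <- vapply(result$scenario_effects,
                 function(d) achieved_power(inputs, n, delta = d), 0.0)
    mean(pw < result$power_threshold)
  }, 0.0)
  data.frame(n = as.integer(candidate_ns), prob_power_below = frac)
}

#' @export
print.sample_size_scenario_result <- function(x, ...) {
  cat(sprintf("<sample_size_scenario_result> %d scenarios, multiplier in [%.3g, %.3g]\n",
              x$n_scenarios, x$lower, x$upper))
  cat(sprintf("  per-group n: min %d, median %.1f, mean %.1f, max %d\n",
              x$summary$minimum, x$summary$median, x$summary$mean,
              x$summary$maximum))
  invisible(x)
}
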