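# One-group and two-group analyses of validated cohorts: frequency/chi-square
# for discrete variables, summary/boxplot/t-test for continuous variables,
# Kaplan-Meier estimation and log-rank comparison for time-to-event variables.
# All test statistics are computed from first principles; base-R and survival
# equivalents serve only as independent oracles in the test suite.

new_test_result <- function(test_name, statistic, df = NA_real_, p_value,
                            effect_summary = list()) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 degrees_of_freedom = df, p_value = p_value,
                 effect_summary = effect_summary),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$test_name))
  cat(sprintf("  statistic = %.6g, df = %s, p = %.6g\n", x$statistic,
              format(x$degrees_of_freedom), x$p_value))
  invisible(x)
}

discrete_counts <- function(ch, variable, levels = NULL) {
  v <- get_variable(ch, variable, "discrete")
  lv <- levels %||% sort(unique(v))
  tab <- vapply(lv, function(l) sum(v == l), 0L)
  stats::setNames(tab, lv)
}

#' One-group discrete analysis: frequencies and chi-square goodness of fit
#'
#' Level frequencies plus the Pearson chi-square goodness-of-fit test of the
#' observed counts against `expected_probs` (default: equal proportions over
#' the observed levels), with df = levels - 1.
#'
#' @param ch A [cohort()].
#' @param variable A discrete variable with >= 2 observed levels.
#' @param expected_probs Optional named per-level probabilities summing to 1;
#'   levels must cover the observed levels.
#' @return `list(frequencies = named counts, proportions, test = test_result)`.
#' @export
one_group_discrete <- function(ch, variable, expected_probs = NULL) {
  counts <- discrete_counts(ch, variable)
  k <- length(counts)
  if (k < 2 && is.null(expected_probs))
    stop("chi-square goodness of fit undefined for a single observed level",
         call. = FALSE)
  if (is.null(expected_probs)) {
    probs <- rep(1 / k, k)
  } else {
    if (abs(sum(expected_probs) - 1) > 1e-8)
      stop("expected_probs must sum to 1", call. = FALSE)
    missing_lv <- setdiff(names(counts), names(expected_probs))
    if (length(missing_lv))
      stop("expected_probs missing level(s): ",
           paste(missing_lv, collapse = ", "), call. = FALSE)
    counts <- counts[names(expected_probs)]
    counts[is.na(counts)] <- 0L
    names(counts) <- names(expected_probs)
    probs <- as.numeric(expected_probs)
    k <- length(counts)
  }
  n <- sum(counts)
  expected <- n * probs
  stat <- sum((counts - expected)^2 / expected)
  df <- k - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(frequencies = counts, proportions = counts / n,
       test = new_test_result("chi-square goodness of fit", stat, df, p,
                              effect_summary = list(expected = expected)))
}

#' Two-group discrete analysis: contingency table and chi-square test
#'
#' Pearson chi-square test of homogeneity on the group x level contingency
#' table; levels are the union of the levels observed in either group
#' (absent levels enter with count 0); df = levels - 1. The Yates continuity
#' correction is off by default so the 2x2 closed form
#' N(ad-bc)^2 / (r1 r2 c1 c2) holds exactly.
#'
#' @param a,b The two [cohort()] groups.
#' @param variable A discrete variable name.
#' @param continuity_correction Apply the Yates correction (2x2 tables only).
#' @return `list(table = 2 x L counts, test = test_result)`.
#' @export
two_group_discrete <- function(a, b, variable, continuity_correction = FALSE) {
  va <- get_variable(a, variable, "discrete")
  vb <- get_variable(b, variable, "discrete")
  if (length(va) == 0 || length(vb) == 0)
    stop("both groups need at least one complete record", call. = FALSE)
  lv <- sort(union(unique(va), unique(vb)))
  if (length(lv) < 2)
    stop("chi-square test undefined: a single level overall", call. = FALSE)
  tab <- rbind(a = discrete_counts(a, variable, lv),
               b = discrete_counts(b, variable, lv))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected <= 0))
    stop("degenerate table: expected cell count of zero", call. = FALSE)
  dev <- abs(tab - expected)
  if (continuity_correction && identical(dim(tab), c(2L, 2L)))
    dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- length(lv) - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(table = tab,
       test = new_test_result("chi-square test of homogeneity", stat, df, p,
                              effect_summary = list(
                                proportions_a = tab[1, ] / sum(tab[1, ]),
                                proportions_b = tab[2, ] / sum(tab[2, ]))))
}

#' Two-group continuous analysis: two-sample t-test
#'
#' Two-sided two-sample t-test of the mean difference, Welch by default
#' (Satterthwaite degrees of freedom) with a pooled-variance mode for
#' textbook comparisons. The effect summary carries the mean difference
#' (a - b) and its standard error.
#'
#' @param a,b The two [cohort()] groups.
#' @param variable A continuous variable; >= 2 complete rows per group.
#' @param variance_mode `"welch"` or `"pooled"`.
#' @return A `test_result`.
#' @export
two_group_continuous <- function(a, b, variable,
                                 variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  xa <- get_variable(a, variable, "continuous")
  xb <- get_variable(b, variable, "continuous")
  if (length(xa) < 2 || length(xb) < 2)
    stop("need at least 2 complete rows per group", call. = FALSE)
  na <- length(xa); nb <- length(xb)
  va <- stats::var(xa); vb <- stats::var(xb)
  diff <- mean(xa) - mean(xb)
  if (va == 0 && vb == 0) {
    if (diff == 0) stop("both groups constant and equal: t-test undefined",
                        call. = FALSE)
    stop("both groups constant: t-test degenerate (zero variance)",
         call. = FALSE)
  }
  if (variance_mode == "welch") {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  new_test_result(sprintf("two-sample t-test (%s)", variance_mode),
                  t_stat, df, p,
                  effect_summary = list(mean_difference = diff,
                                        se = se, mean_a = mean(xa),
                                        mean_b = mean(xb)))
}

tte_columns <- function(ch, variable) {
  idx <- match(variable, ch$variables$name)
  if (is.na(idx)) stop("unknown variable: ", variable, call. = FALSE)
  if (ch$variables$kind[idx] != "time_to_event")
    stop(sprintf("variable '%s' is not time_to_event", variable), call. = FALSE)
  ev <- ch$variables$event_indicator[idx]
  cc <- complete_cases(ch, variable)
  list(time = cc$data[[variable]], event = cc$data[[ev]])
}

#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival estimate \eqn{\hat S(t) = \prod_{t_i \le t}
#' (1 - d_i / n_i)} over distinct event times, with \eqn{d_i} events among
#' \eqn{n_i} at risk. Records censored at an event time are counted at risk
#' for that time (events processed before censorings). Censoring times are
#' retained for tick marks on plots.
#'
#' @param ch A [cohort()].
#' @param variable A time-to-event variable (with its event indicator).
#' @return A `km_estimate` list: `event_times`, `at_risk`, `events`,
#'   `survival`, `censoring_times`, `n`.
#' @export
km_estimate <- function(ch, variable) {
  d <- tte_columns(ch, variable)
  time <- d$time; event <- d$event
  if (any(time < 0)) stop("negative time", call. = FALSE)
  if (any(!event %in% c(0, 1))) stop("event indicator outside {0, 1}", call. = FALSE)
  et <- sort(unique(time[event == 1]))
  at_risk <- vapply(et, function(t) sum(time >= t), 0L)
  d_i <- vapply(et, function(t) sum(time == t & event == 1), 0L)
  surv <- cumprod(1 - d_i / at_risk)
  structure(list(event_times = et, at_risk = at_risk, events = d_i,
                 survival = surv,
                 censoring_times = sort(time[event == 0]),
                 n = length(time)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d event times, %d censored\n",
              x$n, length(x$event_times), length(x$censoring_times)))
  invisible(x)
}

# evaluate a km_estimate as a right-continuous step function
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    k <- sum(km$event_times <= tt)
    if (k == 0) 1 else km$survival[k]
  }, 0.0)
}

#' Two-group time-to-event analysis: Kaplan-Meier curves and log-rank test
#'
#' Per-group product-limit curves plus the two-group log-rank (Mantel-Cox)
#' chi-square statistic with 1 degree of freedom: at each distinct event
#' time the observed events in group a are compared with the hypergeometric
#' expectation given the risk sets, and
#' \eqn{X^2 = (O_a - E_a)^2 / \sum_j V_j}.
#'
#' @param a,b The two [cohort()] groups.
#' @param variable A time-to-event variable name (same encoding in both).
#' @return `list(km_a, km_b, test = test_result)`; the effect summary
#'   carries observed and expected event counts per group.
#' @export
two_group_tte <- function(a, b, variable) {
  da <- tte_columns(a, variable)
  db <- tte_columns(b, variable)
  if (sum(da$event) + sum(db$event) < 1)
    stop("no events in either group: log-rank test undefined", call. = FALSE)
  time <- c(da$time, db$time)
  event <- c(da$event, db$event)
  grp <- rep(c(1L, 2L), c(length(da$time), length(db$time)))
  et <- sort(unique(time[event == 1]))
  o_a <- e_a <- v_sum <- 0
  for (t in et) {
    n_j <- sum(time >= t)
    n1_j <- sum(time >= t & grp == 1L)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & grp == 1L)
    o_a <- o_a + d1_j
    e_a <- e_a + n1_j * d_j / n_j
    if (n_j > 1)
      v_sum <- v_sum + n1_j * (n_j - n1_j) * d_j * (n_j - d_j) /
        (n_j^2 * (n_j - 1))
  }
  if (v_sum == 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (o_a - e_a)^2 / v_sum
    p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  list(km_a = km_estimate(a, variable), km_b = km_estimate(b, variable),
       test = new_test_result("log-rank (Mantel-Cox) test", stat, 1, p,
                              effect_summary = list(
                                observed_a = o_a, expected_a = e_a,
                                observed_b = sum(event) - o_a,
                                expected_b = sum(event) - e_a)))
}

#' One-group continuous analysis: summary and boxplot statistics
#'
#' Descriptive summary (mean, sd, min, max) plus Tukey boxplot statistics of
#' one continuous variable, following the same conventions as the validation
#' views.
#'
#' @param ch A [cohort()].
#' @param variable A continuous variable with >= 1 complete row.
#' @return `list(summary = one-row data frame, boxplot = boxplot_stats)`.
#' @export
one_group_continuous <- function(ch, variable) {
  v <- get_variable(ch, variable, "continuous")
  if (length(v) < 1)
    stop("no complete rows for ", variable, call. = FALSE)
  smry <- data.frame(variable = variable, n = length(v), mean = mean(v),
                     sd = if (length(v) > 1) stats::sd(v) else 0,
                     min = min(v), max = max(v), stringsAsFactors = FALSE)
  list(summary = smry, boxplot = boxplot_stats(ch, variable))
}
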