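# Seeded generation of paired real/virtual cohorts with known ground truth.
# Real and virtual cohorts use disjoint sub-streams derived from one seed, so
# changing n_real never perturbs the virtual draw.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# two independent 31-bit sub-seeds derived from one master seed
derive_subseeds <- function(seed, k = 2L) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Specification of a synthetic real/virtual cohort pair
#'
#' Declares the ground-truth generative model: a multivariate-normal block of
#' continuous features with stated mean and covariance, optional independent
#' categorical features, and an optional censored exponential time-to-event
#' variable (event time ~ Exp(rate), censoring time ~ Exp(censor_rate),
#' observed time = their minimum, indicator 1 iff the event came first). The
#' virtual cohort is drawn from a perturbed model: mean `mean + mean_shift`,
#' covariance `covariance * covariance_scale`.
#'
#' @param n_real,n_virtual Record counts (> 0).
#' @param mean Numeric p-vector of continuous-feature means (names optional;
#'   default variable names are `x1..xp`).
#' @param covariance p x p symmetric positive-definite matrix.
#' @param discrete_levels Optional named list: variable name -> named
#'   probability vector over levels (each sums to 1).
#' @param tte Optional list `list(rate = , censor_rate = )` with
#'   `rate > 0`, `censor_rate >= 0`.
#' @param mean_shift Numeric p-vector added to the virtual mean (default 0).
#' @param covariance_scale Positive scalar multiplying the virtual covariance.
#' @param seed Integer master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_real, n_virtual, mean, covariance,
                           discrete_levels = NULL, tte = NULL,
                           mean_shift = NULL, covariance_scale = 1,
                           seed = 1L) {
  p <- length(mean)
  covariance <- as.matrix(covariance)
  stopifnot(n_real >= 1, n_virtual >= 1, p >= 1,
            nrow(covariance) == p, ncol(covariance) == p,
            covariance_scale > 0)
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance must be positive definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  if (is.null(mean_shift)) mean_shift <- rep(0, p)
  stopifnot(length(mean_shift) == p)
  if (!is.null(discrete_levels)) {
    stopifnot(is.list(discrete_levels), !is.null(names(discrete_levels)))
    for (nm in names(discrete_levels)) {
      pr <- discrete_levels[[nm]]
      if (is.null(names(pr)) || any(pr < 0) || abs(sum(pr) - 1) > 1e-12)
        stop(sprintf("level probabilities for '%s' must be named, nonnegative, and sum to 1",
                     nm), call. = FALSE)
    }
  }
  if (!is.null(tte)) {
    stopifnot(is.list(tte), tte$rate > 0, tte$censor_rate >= 0)
  }
  nm <- names(mean) %||% paste0("x", seq_len(p))
  structure(list(n_real = as.integer(n_real), n_virtual = as.integer(n_virtual),
                 mean = stats::setNames(as.numeric(mean), nm),
                 covariance = covariance,
                 discrete_levels = discrete_levels, tte = tte,
                 mean_shift = as.numeric(mean_shift),
                 covariance_scale = as.numeric(covariance_scale),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# MVN sampler via Cholesky factor of the covariance
rmvn_chol <- function(n, mean, covariance) {
  p <- length(mean)
  L <- chol(covariance)  # upper triangular: cov = t(L) %*% L
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  sweep(z %*% L, 2, mean, `+`)
}

sample_one_cohort <- function(n, mean, covariance, discrete_levels, tte,
                              provenance, subseed) {
  with_seed(subseed, {
    x <- rmvn_chol(n, mean, covariance)
    colnames(x) <- names(mean)
    df <- as.data.frame(x)
    kinds <- stats::setNames(rep("continuous", length(mean)), names(mean))
    ev_map <- NULL
    if (!is.null(discrete_levels)) {
      for (nm in names(discrete_levels)) {
        pr <- discrete_levels[[nm]]
        df[[nm]] <- sample(names(pr), n, replace = TRUE, prob = pr)
        kinds[nm] <- "discrete"
      }
    }
    if (!is.null(tte)) {
      t_event <- stats::rexp(n, rate = tte$rate)
      t_cens <- if (tte$censor_rate > 0) stats::rexp(n, rate = tte$censor_rate)
                else rep(Inf, n)
      df$time <- pmin(t_event, t_cens)
      df$event <- as.numeric(t_event <= t_cens)
      kinds["time"] <- "time_to_event"
      ev_map <- c(time = "event")
    }
    cohort(df, kinds = kinds, provenance = provenance,
           event_indicators = ev_map)
  })
}

#' Generate a paired real/virtual cohort from a synthetic specification
#'
#' The real cohort is drawn from the base model, the virtual cohort from the
#' perturbed model (`mean + mean_shift`, `covariance * covariance_scale`).
#' Fully reproducible: the same spec (same seed) yields bit-identical cohorts,
#' and the two cohorts use disjoint random sub-streams.
#'
#' @param spec A [synthetic_spec()].
#' @return `list(real = cohort, virtual = cohort)`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sub <- derive_subseeds(spec$seed, 2L)
  real <- sample_one_cohort(spec$n_real, spec$mean, spec$covariance,
                            spec$discrete_levels, spec$tte, "real", sub[1])
  vmean <- spec$mean + spec$mean_shift
  vcov <- spec$covariance * spec$covariance_scale
  virtual <- sample_one_cohort(spec$n_virtual, vmean, vcov,
                               spec$discrete_levels, spec$tte, "virtual", sub[2])
  list(real = real, virtual = virtual)
}

#' Sample mean vector and covariance matrix of continuous variables
#'
#' Complete-case sample moments with covariance divisor n - 1.
#'
#' @param ch A [cohort()].
#' @param variables Continuous variable names.
#' @return `list(mean = named vector, covariance = matrix, n = rows used)`.
#' @export
sample_moments <- function(ch, variables) {
  stopifnot(inherits(ch, "cohort"), length(variables) >= 1)
  cc <- complete_cases(ch, variables)
  if (cc$n < 2) stop("need at least 2 complete rows", call. = FALSE)
  x <- as.matrix(cc$data[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  list(mean = colMeans(x), covariance = stats::cov(x), n = cc$n)
}
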