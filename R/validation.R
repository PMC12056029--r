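# Validation views comparing a virtual cohort against a real cohort:
# univariate descriptives, Spearman correlation matrices, Mahalanobis-type
# quadratic forms against a chi-squared reference, and a bootstrap pointwise
# confidence band on kernel density estimates.

#' Side-by-side univariate descriptive comparison
#'
#' Mean, standard deviation (divisor n - 1), minimum and maximum of each
#' continuous variable, computed per cohort on complete cases per variable.
#'
#' @param real,virtual [cohort()] objects.
#' @param variables Continuous variable names.
#' @return A `univariate_summary` data frame with columns `variable`,
#'   `cohort`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_univariate <- function(real, virtual, variables) {
  one <- function(ch, label) {
    rows <- lapply(variables, function(nm) {
      v <- get_variable(ch, nm, "continuous")
      if (length(v) < 2)
        stop(sprintf("variable '%s' has fewer than 2 complete rows in the %s cohort",
                     nm, label), call. = FALSE)
      data.frame(variable = nm, cohort = label, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one(real, "real"), one(virtual, "virtual"))
  if (is.null(out))
    out <- data.frame(variable = character(0), cohort = character(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0),
                      min = numeric(0), max = numeric(0))
  class(out) <- c("univariate_summary", "data.frame")
  out
}

#' Tukey boxplot statistics for one continuous variable
#'
#' Quartiles by linear-interpolation quantiles (type 7); whiskers extend to
#' the most extreme data points within 1.5 IQR of the quartiles; points
#' beyond the whiskers are outliers.
#'
#' @param ch A [cohort()].
#' @param variable A continuous variable name.
#' @return A `boxplot_stats` list: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
boxplot_stats <- function(ch, variable) {
  v <- get_variable(ch, variable, "continuous")
  if (length(v) < 1) stop("no complete rows for ", variable, call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = sort(v[v < lo_fence | v > hi_fence]),
                 n = length(v)),
            class = "boxplot_stats")
}

#' Scatter-plot point sets for all variable pairs
#'
#' For every unordered pair of the named continuous variables, the (x, y)
#' points per cohort, using pairwise-complete records (a record missing on
#' one member of a pair is excluded from that pair only).
#'
#' @param real,virtual [cohort()] objects.
#' @param variables At least 2 continuous variable names.
#' @return A `scatter_pairs` list; one element per pair with `x_var`,
#'   `y_var`, `real` and `virtual` (two-column matrices).
#' @export
scatter_pairs <- function(real, virtual, variables) {
  if (length(variables) < 2)
    stop("need at least 2 variables for scatter pairs", call. = FALSE)
  pts <- function(ch, vx, vy) {
    x <- ch$data[[vx]]; y <- ch$data[[vy]]
    ok <- !is.na(x) & !is.na(y)
    cbind(x = x[ok], y = y[ok])
  }
  for (nm in variables) { get_variable(real, nm, "continuous"); get_variable(virtual, nm, "continuous") }
  combs <- utils::combn(variables, 2, simplify = FALSE)
  out <- lapply(combs, function(pr)
    list(x_var = pr[1], y_var = pr[2],
         real = pts(real, pr[1], pr[2]),
         virtual = pts(virtual, pr[1], pr[2])))
  structure(out, class = "scatter_pairs")
}

# Spearman rho for one matrix, pairwise complete, average ranks for ties;
# constant-variable pairs are NA (undefined), never silently 0.
spearman_matrix <- function(df, variables) {
  p <- length(variables)
  m <- matrix(NA_real_, p, p, dimnames = list(variables, variables))
  diag(m) <- 1
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    x <- df[[variables[i]]]; y <- df[[variables[j]]]
    ok <- !is.na(x) & !is.na(y)
    rx <- rank(x[ok]); ry <- rank(y[ok])
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) next  # undefined
    m[i, j] <- m[j, i] <- stats::cor(rx, ry)
  }
  m
}

#' Spearman correlation matrices for real and virtual cohorts
#'
#' Rank-based correlation (average ranks for ties) between all named
#' variables, computed separately per cohort on pairwise-complete records,
#' with the element-wise difference matrix (virtual - real). Pairs involving
#' a constant variable are reported as `NA` (correlation undefined).
#'
#' @param real,virtual [cohort()] objects.
#' @param variables At least 2 continuous variable names.
#' @return A `correlation_result` list: `variables`, `real_matrix`,
#'   `virtual_matrix`, `difference_matrix`, `undefined_pairs`.
#' @export
spearman_matrices <- function(real, virtual, variables) {
  if (length(variables) < 2)
    stop("need at least 2 variables", call. = FALSE)
  for (nm in variables) {
    if (length(get_variable(real, nm, "continuous")) < 3 ||
        length(get_variable(virtual, nm, "continuous")) < 3)
      stop("need at least 3 complete rows per cohort (variable ", nm, ")",
           call. = FALSE)
  }
  rm_ <- spearman_matrix(real$data, variables)
  vm_ <- spearman_matrix(virtual$data, variables)
  und <- which(is.na(rm_) | is.na(vm_), arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  structure(list(variables = variables, real_matrix = rm_,
                 virtual_matrix = vm_, difference_matrix = vm_ - rm_,
                 undefined_pairs = unname(apply(und, 1, function(ij)
                   paste(variables[ij], collapse = ":")))),
            class = "correlation_result")
}

# quadratic forms d_i = (x_i - xbar)' S^{-1} (x_i - xbar) for one matrix
quadratic_forms_one <- function(x) {
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop(sprintf("need n > p complete rows (n = %d, p = %d)", n, p),
                   call. = FALSE)
  xb <- colMeans(x)
  S <- stats::cov(x)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS) || rcond_from_chol(cS) < 1e-12) {
    cm <- suppressWarnings(abs(stats::cor(x)))
    cm[!is.finite(cm)] <- 1
    diag(cm) <- 0
    idx <- which(cm > 1 - 1e-8, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pairs <- if (nrow(idx)) paste(apply(idx, 1, function(ij)
      paste(colnames(x)[ij], collapse = " ~ ")), collapse = "; ") else "unidentified"
    stop("sample covariance is singular or near-singular; collinear variables: ",
         pairs, call. = FALSE)
  }
  cen <- sweep(x, 2, xb)
  # d_i = || L^{-T} (x_i - xbar) ||^2 with S = L'L (chol upper)
  z <- backsolve(cS, t(cen), transpose = TRUE)
  colSums(z^2)
}

rcond_from_chol <- function(cU) {
  d <- diag(cU)^2
  min(d) / max(d)
}

#' Multivariate comparison via standardized quadratic forms
#'
#' Each record is standardized against its own cohort: the per-cohort sample
#' mean is subtracted and the result is scaled by the inverse of the
#' per-cohort sample covariance (divisor n - 1), giving the quadratic form
#' \eqn{d_i = (x_i - \bar x)' S^{-1} (x_i - \bar x)}. Under multivariate
#' normality these approximately follow a chi-squared distribution; the
#' reference degrees of freedom default to `p - 1` (`df_mode = "paper"`,
#' mirroring the original environment's documentation) with the classical
#' asymptotic `df = p` available via `df_mode = "classical"`. The d values
#' of the two cohorts are paired by matching linear-interpolation quantiles
#' on a common probability grid for QQ display, and common-break histograms
#' are attached.
#'
#' @param real,virtual [cohort()] objects.
#' @param variables p >= 1 continuous variable names.
#' @param df_mode `"paper"` (df = p - 1, the degrees of freedom the original
#'   environment documents; degenerate for p = 1) or `"classical"` (df = p,
#'   the standard asymptotic for Mahalanobis squared distances).
#' @return A `quadratic_form_result` list: `d_real`, `d_virtual`, `p`, `df`,
#'   `df_mode`, `qq_pairs` (matrix with columns `prob`, `real`, `virtual`),
#'   `histogram` (common `breaks`, per-cohort `counts`).
#' @export
quadratic_forms <- function(real, virtual, variables,
                            df_mode = c("paper", "classical")) {
  df_mode <- match.arg(df_mode)
  stopifnot(length(variables) >= 1)
  xr <- as.matrix(complete_cases(real, variables)$data[, variables, drop = FALSE])
  xv <- as.matrix(complete_cases(virtual, variables)$data[, variables, drop = FALSE])
  storage.mode(xr) <- "double"; storage.mode(xv) <- "double"
  d_real <- quadratic_forms_one(xr)
  d_virtual <- quadratic_forms_one(xv)
  p <- length(variables)
  df <- if (df_mode == "paper") p - 1L else p
  probs <- stats::ppoints(min(length(d_real), length(d_virtual)))
  qq <- cbind(prob = probs,
              real = stats::quantile(d_real, probs, type = 7, names = FALSE),
              virtual = stats::quantile(d_virtual, probs, type = 7, names = FALSE))
  breaks <- pretty(range(c(d_real, d_virtual)), n = 30)
  hr <- graphics::hist(d_real, breaks = breaks, plot = FALSE)
  hv <- graphics::hist(d_virtual, breaks = breaks, plot = FALSE)
  structure(list(d_real = d_real, d_virtual = d_virtual, p = p, df = df,
                 df_mode = df_mode, qq_pairs = qq,
                 histogram = list(breaks = breaks, counts_real = hr$counts,
                                  counts_virtual = hv$counts)),
            class = "quadratic_form_result")
}

#' Chi-squared reference quantiles
#'
#' Quantiles of the chi-squared distribution for overlay on quadratic-form
#' histograms and QQ displays.
#'
#' @param df Degrees of freedom (>= 1).
#' @param probs Probabilities strictly inside (0, 1).
#' @return Numeric vector of quantiles.
#' @export
chi2_reference <- function(df, probs) {
  if (!is.numeric(df) || length(df) != 1 || df < 1)
    stop("df must be a number >= 1", call. = FALSE)
  if (any(probs <= 0) || any(probs >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  stats::qchisq(probs, df = df)
}

# Silverman rule-of-thumb bandwidth: 0.9 * min(sd, IQR/1.34) * n^(-1/5)
silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- diff(stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE))
  spread <- min(s, iqr / 1.34)
  if (spread <= 0) spread <- s
  if (spread <= 0) spread <- abs(mean(x)) * 1e-3 + 1e-8  # degenerate data
  0.9 * spread * n^(-1 / 5)
}

kde_on_grid <- function(x, grid, bw) {
  d <- stats::density(x, bw = bw, kernel = "gaussian",
                      from = grid[1], to = grid[length(grid)],
                      n = length(grid))
  d$y
}

#' Bootstrap pointwise confidence band on density estimates
#'
#' The real cohort is taken as the reference distribution; `B` bootstrap
#' samples of size n_virtual are drawn with replacement from the virtual
#' values. Each replicate's Gaussian-kernel density (Silverman rule-of-thumb
#' bandwidth, re-estimated per replicate) is evaluated on a common grid of
#' 512 points spanning the pooled data range extended by 3 bandwidths; the
#' pointwise band is the ((1-level)/2, 1-(1-level)/2) percentile envelope
#' across replicates. The real-data density is computed once on the same
#' grid; `outside_fraction` is the fraction of grid points at which it falls
#' outside the band, reported as the bootstrap p-value, and a model deviation
#' is flagged when that fraction exceeds `deviation_threshold`.
#'
#' @param real,virtual [cohort()] objects.
#' @param variable A continuous variable with >= 10 complete rows per cohort.
#' @param B Bootstrap replicates (>= 100).
#' @param level Band coverage level in (0, 1); default 0.95.
#' @param deviation_threshold Out-of-band fraction above which a deviation is
#'   declared; default 0.05.
#' @param seed Integer seed; the whole result is a pure function of
#'   (inputs, seed).
#' @return A `density_band_result` list: `grid`, `band_lower`, `band_upper`,
#'   `density_real`, `density_virtual`, `B`, `level`, `bandwidth_real`,
#'   `bandwidth_virtual`, `outside_fraction`, `p_value`,
#'   `deviation_detected`, `deviation_threshold`, `seed`.
#' @export
bootstrap_density_band <- function(real, virtual, variable, B = 500,
                                   level = 0.95, deviation_threshold = 0.05,
                                   seed = 1L) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  xr <- get_variable(real, variable, "continuous")
  xv <- get_variable(virtual, variable, "continuous")
  if (length(xr) < 10 || length(xv) < 10)
    stop("need at least 10 complete rows per cohort", call. = FALSE)
  bw_r <- silverman_bw(xr)
  bw_v <- silverman_bw(xv)
  pad <- 3 * max(bw_r, bw_v)
  rng <- range(c(xr, xv))
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 512)
  dens_r <- kde_on_grid(xr, grid, bw_r)
  dens_v <- kde_on_grid(xv, grid, bw_v)
  nB <- length(xv)
  boot <- with_seed(seed, {
    m <- matrix(NA_real_, nrow = B, ncol = length(grid))
    for (b in seq_len(B)) {
      xs <- sample(xv, nB, replace = TRUE)
      m[b, ] <- kde_on_grid(xs, grid, silverman_bw(xs))
    }
    m
  })
  alpha <- (1 - level) / 2
  band_lower <- apply(boot, 2, stats::quantile, probs = alpha, type = 7, names = FALSE)
  band_upper <- apply(boot, 2, stats::quantile, probs = 1 - alpha, type = 7, names = FALSE)
  outside <- dens_r < band_lower | dens_r > band_upper
  frac <- mean(outside)
  structure(list(grid = grid, band_lower = band_lower, band_upper = band_upper,
                 density_real = dens_r, density_virtual = dens_v,
                 B = as.integer(B), level = level,
                 bandwidth_real = bw_r, bandwidth_virtual = bw_v,
                 outside_fraction = frac, p_value = frac,
                 deviation_detected = frac > deviation_threshold,
                 deviation_threshold = deviation_threshold,
                 seed = as.integer(seed)),
            class = "density_band_result")
}

#' @export
print.density_band_result <- function(x, ...) {
  cat(sprintf("<density_band_result> B = %d, level = %.2f\n", x$B, x$level))
  cat(sprintf("  outside fraction (bootstrap p-value): %.4f\n", x$outside_fraction))
  cat(sprintf("  deviation detected: %s (threshold %.2f)\n",
              x$deviation_detected, x$deviation_threshold))
  invisible(x)
}
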