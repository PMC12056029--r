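# Shared fixture builders. Everything is generated in code at test time.

cont_cohort <- function(..., provenance = "unspecified") {
  cohort(data.frame(...), provenance = provenance)
}

tte_cohort <- function(time, event, provenance = "unspecified") {
  cohort(data.frame(t = time, e = event),
         kinds = c(t = "time_to_event"),
         event_indicators = c(t = "e"),
         provenance = provenance)
}

disc_cohort <- function(values, provenance = "unspecified") {
  cohort(data.frame(g = values), kinds = c(g = "discrete"),
         provenance = provenance)
}

# random cohort with continuous + discrete columns and injected missingness,
# for round-trip and property tests
random_cohort <- function(n, p_cont, p_disc = 1, missing_prob = 0.1) {
  df <- as.data.frame(matrix(rnorm(n * p_cont), nrow = n, ncol = p_cont))
  names(df) <- paste0("c", seq_len(p_cont))
  if (n > 0) {
    for (j in seq_len(p_cont))
      df[[j]][runif(n) < missing_prob] <- NA
    for (k in seq_len(p_disc)) {
      lv <- c("lo", "hi", 'odd "level"', "with,comma")
      v <- sample(lv, n, replace = TRUE)
      v[runif(n) < missing_prob] <- NA
      df[[paste0("d", k)]] <- v
    }
  } else {
    for (k in seq_len(p_disc)) df[[paste0("d", k)]] <- character(0)
  }
  kinds <- c(stats::setNames(rep("continuous", p_cont), paste0("c", seq_len(p_cont))),
             stats::setNames(rep("discrete", p_disc), paste0("d", seq_len(p_disc))))
  cohort(df, kinds = kinds)
}

# equicorrelation covariance matrix
equicov <- function(p, rho = 0.3, var = 1) {
  m <- matrix(rho * var, p, p); diag(m) <- var; m
}
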