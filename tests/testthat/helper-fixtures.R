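# Shared fixtures and independent oracles used across the test files.

# Brute-force evaluation of the ACF / INT definition: explicit double loop
# over (t, k) with the full-series variance in the denominator, honoring a
# retain mask via pairwise-complete products. Deliberately O(T*K) and
# independent of the vectorized implementation.
acf_bruteforce <- function(y, max_lag, mask = rep(TRUE, length(y))) {
  ybar <- mean(y[mask])
  denom <- sum((y[mask] - ybar)^2)
  tt <- length(y)
  sapply(seq_len(max_lag), function(k) {
    s <- 0
    for (t in (k + 1):tt)
      if (mask[t] && mask[t - k]) s <- s + (y[t] - ybar) * (y[t - k] - ybar)
    s / denom
  })
}

int_bruteforce <- function(y, tr, max_lag, mask = rep(TRUE, length(y))) {
  a <- acf_bruteforce(y, max_lag, mask)
  i <- which(a <= 0)
  n <- if (length(i)) i[1] - 1 else max_lag
  if (n < 1) 0 else tr * sum(a[seq_len(n)])
}

# Small hand-built patient cohort with controllable symptom scores.
make_cohort <- function(n_patients, n_controls = 0, n_sites = 2, seed = 1) {
  set.seed(seed)
  n <- n_patients + n_controls
  scores <- matrix(sample(0:5, n * 7, replace = TRUE), n, 7,
                   dimnames = list(NULL, symptom_items()))
  scores[seq_len(n) > n_patients, ] <- 0
  cohort_table(data.frame(
    diagnosis = rep(c(1L, 0L), c(n_patients, n_controls)),
    scores,
    age = round(runif(n, 20, 60), 1),
    gender = rbinom(n, 1, 0.5),
    mean_fd = round(runif(n, 0.05, 0.3), 3),
    site = factor(sample(paste0("site", seq_len(n_sites)), n, replace = TRUE))
  ))
}

# Independent M1 + M2 oracle: plain lm() per parcel, then an lm() on the
# long (symptom, level, system) table, returning the per-system gradient and
# interaction t-statistics by explicit contrasts of the fitted coefficients.
oracle_gradient_t <- function(int_matrix, cohort, hierarchies,
                              symptoms = c("hallucinations", "delusions")) {
  pat <- cohort[cohort$diagnosis == 1L, ]
  ts <- sapply(colnames(int_matrix), function(p) {
    df <- data.frame(int = int_matrix[cohort$diagnosis == 1L, p], pat)
    f <- stats::as.formula(paste("int ~", paste(symptom_items(), collapse = "+"),
                                 "+ age + gender + mean_fd",
                                 if (nlevels(droplevels(pat$site)) > 1) "+ site"))
    summary(stats::lm(f, data = df))$coefficients[symptoms, "t value"]
  })
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1, dimnames = list(symptoms, colnames(int_matrix)))
  rows <- do.call(rbind, lapply(names(hierarchies), function(sys) {
    a <- hierarchies[[sys]]$assignment
    do.call(rbind, lapply(symptoms, function(sym)
      data.frame(t = ts[sym, names(a)], symptom = sym,
                 level = as.numeric(a), system = sys)))
  }))
  out <- c()
  one_sys <- length(hierarchies) == 1L
  for (sys in names(hierarchies)) {
    dat <- transform(rows,
                     symptom = stats::relevel(factor(symptom, levels = symptoms),
                                              symptoms[1]),
                     system = stats::relevel(factor(system,
                                                    levels = names(hierarchies)),
                                             sys))
    m <- if (one_sys) stats::lm(t ~ symptom * level, data = dat)
         else stats::lm(t ~ symptom * level * system, data = dat)
    sm <- summary(m)$coefficients
    out[paste0("grad_", symptoms[1], "_", sys)] <- sm["level", "t value"]
    out[paste0("grad_", symptoms[2], "_", sys)] <-
      oracle_contrast_t(m, c(level = 1, `symptomdelusions:level` = 1))
    out[paste0("interact_", sys)] <- sm["symptomdelusions:level", "t value"]
  }
  out
}

# t-statistic of a named linear combination of lm coefficients
oracle_contrast_t <- function(fit, weights) {
  beta <- stats::coef(fit)
  cv <- stats::setNames(rep(0, length(beta)), names(beta))
  cv[names(weights)] <- weights
  v <- stats::vcov(fit)
  sum(cv * beta) / sqrt(drop(t(cv) %*% v %*% cv))
}

# All permutations of 1..n as a list (tiny n only).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(sub, as.integer(n), after = pos)
  out
}

# Fast scaled-down settings for network simulations used in several tests.
sim_args_small <- function() {
  list(n_reps = 1L, duration = 90, dt = 1e-3, record_dt = 2e-3,
       tr_out = 2, burn_in = 10)
}
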