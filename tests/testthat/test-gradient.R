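hier3 <- winning_hierarchies()

test_that("a planted symptom effect dominates the parcel-wise regression", {
  cohort <- make_cohort(80, seed = 1)
  pat <- cohort$diagnosis == 1L
  set.seed(2)
  int <- matrix(rnorm(80 * 3, sd = 0.01), 80, 3,
                dimnames = list(NULL, c("p1", "p2", "p3")))
  int[, "p2"] <- int[, "p2"] + 2 * cohort$hallucinations
  m1 <- fit_parcelwise_glm(int, cohort, "M1_primary")
  expect_gt(m1$tstats["hallucinations", "p2"], 50)
  others <- setdiff(symptom_items(), "hallucinations")
  expect_lt(max(abs(m1$tstats[others, "p2"])), 5)
})

test_that("type-I error of the parcel-wise t is near nominal", {
  cohort <- make_cohort(100, seed = 3)
  set.seed(4)
  int <- matrix(rnorm(100 * 300), 100, 300)
  m1 <- fit_parcelwise_glm(int, cohort, "M1_primary")
  tcrit <- qt(0.975, m1$df)
  frac <- mean(abs(m1$tstats["hallucinations", ]) > tcrit)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})

test_that("parcel-wise coefficients equal the normal-equation oracle", {
  cohort <- make_cohort(6, n_controls = 4, n_sites = 1, seed = 5)
  set.seed(6)
  int <- matrix(rnorm(30), 10, 3)
  m1 <- fit_parcelwise_glm(int, cohort, "M1_exploratory")
  X <- m1$X
  oracle <- solve(t(X) %*% X) %*% t(X) %*% int
  expect_equal(unname(m1$coefficients), unname(oracle), tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear column named", {
  cohort <- make_cohort(40, seed = 7)
  cohort$mean_fd <- cohort$age    # exact collinearity
  int <- matrix(rnorm(40 * 2), 40, 2)
  expect_error(fit_parcelwise_glm(int, cohort, "M1_primary"),
               "collinear columns")
})

fake_effects <- function(tstats) {
  structure(list(tstats = tstats, design = "M1_primary"),
            class = "parcel_effects")
}

all_parcels <- unique(unlist(lapply(hier3, function(h) names(h$assignment))))

test_that("planted opposing gradients give exact simple slopes and df 42", {
  ts <- matrix(0, 2, length(all_parcels),
               dimnames = list(c("hallucinations", "delusions"), all_parcels))
  for (sys in names(hier3)) {
    a <- hier3[[sys]]$assignment
    ts["hallucinations", names(a)] <- -a
    ts["delusions", names(a)] <- a
  }
  g <- suppressWarnings(fit_gradient_glm(fake_effects(ts), hier3))
  expect_equal(nrow(g$data), 54L)
  expect_equal(nrow(g$coefficients), 12L)
  expect_equal(g$df, 42L)
  for (sys in names(hier3)) {
    expect_equal(g$effects[paste0("grad_hallucinations_", sys), "estimate"],
                 -1, tolerance = 1e-10)
    expect_equal(g$effects[paste0("grad_delusions_", sys), "estimate"],
                 1, tolerance = 1e-10)
    expect_equal(g$effects[paste0("interact_", sys), "estimate"],
                 2, tolerance = 1e-10)
  }
})

test_that("constant t-values give zero slopes and interactions", {
  ts <- matrix(1.7, 2, length(all_parcels),
               dimnames = list(c("hallucinations", "delusions"), all_parcels))
  g <- suppressWarnings(fit_gradient_glm(fake_effects(ts), hier3))
  expect_equal(g$effects$estimate, rep(0, nrow(g$effects)), tolerance = 1e-10)
})

test_that("gradient model coefficients match an independent normal-equation solve", {
  set.seed(8)
  ts <- matrix(rnorm(2 * length(all_parcels)), 2, length(all_parcels),
               dimnames = list(c("hallucinations", "delusions"), all_parcels))
  g <- fit_gradient_glm(fake_effects(ts), hier3)
  # independent design construction: treatment dummies and products
  d <- g$data
  S <- as.integer(d$symptom == "delusions")
  Y1 <- as.integer(d$system == "visual")
  Y2 <- as.integer(d$system == "somatosensory")
  L <- d$level
  X <- cbind(1, S, L, Y1, Y2, S * L, S * Y1, S * Y2, L * Y1, L * Y2,
             S * L * Y1, S * L * Y2)
  beta <- solve(t(X) %*% X, t(X) %*% d$t)
  expect_equal(sort(unname(coef(g$fit))), sort(unname(drop(beta))),
               tolerance = 1e-8)
  expect_equal(g$df, 42L)
  # single-symptom and dual-system variants reproduce the reduced designs
  g1 <- fit_gradient_glm(fake_effects(ts), hier3, symptoms = "hallucinations")
  expect_equal(g1$df, 27L - 6L)
  g2 <- fit_gradient_glm(fake_effects(ts), hier3[c("auditory", "visual")])
  expect_equal(g2$df, 36L - 8L)
})

test_that("missing design cells are reported", {
  ts <- matrix(0, 2, 3, dimnames = list(c("hallucinations", "delusions"),
                                        c("A1", "LBelt", "MBelt")))
  expect_error(fit_gradient_glm(fake_effects(ts), hier3["auditory"]),
               "missing \\(symptom, level, system\\) cells")
})

test_that("joint permutation matches exhaustive enumeration on a small toy", {
  cohort <- make_cohort(18, n_sites = 1, seed = 9)
  set.seed(10)
  parc <- names(hier3$auditory$assignment)
  int <- matrix(rnorm(18 * 9, sd = 0.3), 18, 9,
                dimnames = list(NULL, parc)) +
    outer(cohort$hallucinations, -0.05 * hier3$auditory$assignment)
  # surrogates permuting the symptom rows of five chosen patients
  base <- 1:18
  perms <- t(sapply(combinat_perms(5), function(p) {
    q <- base; q[3:7] <- (3:7)[p]; q
  }))
  res <- permutation_null_gradient(int, cohort, hier3["auditory"],
                                   permutations = perms)
  expect_equal(res$n_perm, 120L)

  # independent oracle over the same surrogate set
  oracle_obs <- oracle_gradient_t(int, cohort, hier3["auditory"])
  term <- "interact_auditory"
  oracle_null <- apply(perms, 1L, function(q) {
    ch <- cohort
    ch[symptom_items()] <- cohort[q, symptom_items()]
    oracle_gradient_t(int, ch, hier3["auditory"])[term]
  })
  expect_equal(unname(res$observed[term]), unname(oracle_obs[term]),
               tolerance = 1e-8)
  expect_equal(unname(res$null[, term]), unname(oracle_null),
               tolerance = 1e-8)
  p_oracle <- (1 + sum(abs(oracle_null) >= abs(oracle_obs[term]) - 1e-12)) / 121
  expect_equal(unname(res$p[term]), p_oracle, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical permutation results", {
  sim <- sim_cohort(n_patients = 40, n_controls = 0, n_parcels = 30, seed = 2)
  a <- permutation_null_gradient(sim$int, sim$cohort, sim$hierarchies,
                                 n_perm = 30, seed = 99)
  b <- permutation_null_gradient(sim$int, sim$cohort, sim$hierarchies,
                                 n_perm = 30, seed = 99)
  expect_identical(a$p, b$p)
  expect_identical(a$null, b$null)
})

test_that("joint row permutation preserves the symptom correlation matrix", {
  cohort <- make_cohort(50, seed = 11)
  sym <- as.matrix(cohort[symptom_items()])
  set.seed(12)
  perm <- sample.int(50)
  expect_equal(cor(sym[perm, ]), cor(sym), tolerance = 1e-12)
})

test_that("a planted strong interaction attains the minimal permutation p", {
  sim <- sim_cohort(n_patients = 127, n_controls = 0, hall_slope = -0.008,
                    del_slope = 0.0064, n_parcels = 25, seed = 13)
  res <- permutation_null_gradient(sim$int, sim$cohort, sim$hierarchies,
                                   terms = "interact_auditory",
                                   n_perm = 1000, seed = 14)
  expect_equal(unname(res$p["interact_auditory"]), 1 / 1001)
})

test_that("set-level p approximates the product rule for independent terms", {
  set.seed(15)
  null <- cbind(a = rnorm(4000), b = rnorm(4000))
  obs <- c(a = 5, b = 5)
  perm <- structure(list(null = null, observed = obs, n_perm = 4000),
                    class = "gradient_perm")
  res <- set_level_test(perm, list(
    list(terms = "a", sign = +1, k = 1),
    list(terms = "b", sign = +1, k = 1)))
  expect_equal(res$p, 0.025^2, tolerance = 0.3)  # Monte-Carlo, relative
  expect_true(res$observed_satisfied)

  # a clause satisfied by every surrogate pushes p to 1
  res2 <- set_level_test(perm, list(list(terms = "a", sign = +1, k = 0)))
  expect_equal(res2$p, 1, tolerance = 0.001)
  expect_error(
    set_level_test(perm, list(list(terms = "zz", sign = 1, k = 1))),
    "unknown terms")
})

test_that("BCa core: symmetric limit and exhaustive textbook enumeration", {
  set.seed(16)
  draws <- rnorm(4000)
  jk <- rnorm(30)
  ci <- bca_interval(draws, median(draws), jackknife = c(jk, -jk))  # exactly symmetric
  pct <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 6)
  expect_equal(c(ci$lower, ci$upper), pct, tolerance = 0.05)
  expect_lt(abs(ci$z0), 0.05)

  # exhaustive bootstrap of the mean of a printed 4-vector
  x <- c(1.2, 3.4, 2.2, 8.9)
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  draws2 <- rowMeans(matrix(x[idx], ncol = 4))
  obs <- mean(x)
  jack <- sapply(1:4, function(i) mean(x[-i]))
  ci2 <- bca_interval(draws2, obs, jack)
  # textbook computation written out independently
  z0 <- qnorm(mean(draws2 < obs) + 0.5 * mean(draws2 == obs))
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  al <- pnorm(z0 + (z0 + qnorm(c(0.025, 0.975))) /
                (1 - a * (z0 + qnorm(c(0.025, 0.975)))))
  expect_equal(c(ci2$lower, ci2$upper),
               quantile(draws2, al, names = FALSE, type = 6),
               tolerance = 1e-12)
  expect_equal(ci2$z0, z0, tolerance = 1e-12)
  expect_equal(ci2$accel, a, tolerance = 1e-12)

  # degenerate draws collapse to a flagged point interval
  ci3 <- bca_interval(rep(2, 100), 2)
  expect_true(ci3$degenerate)
  expect_equal(ci3$lower, 2)
})

test_that("pipeline BCa intervals exclude zero for a planted interaction", {
  sim <- sim_cohort(n_patients = 60, n_controls = 0, hall_slope = -0.02,
                    del_slope = 0.02, noise_sd = 0.02, subject_sd = 0.02,
                    n_parcels = 25, seed = 17)
  bca <- bca_ci(sim$int, sim$cohort, sim$hierarchies,
                terms = "interact_auditory", n_boot = 200, seed = 18)
  expect_gt(bca$intervals["interact_auditory", "lower"], 0)
})

test_that("BCa achieves near-nominal coverage for a planted coefficient", {
  # generic BCa core on an OLS slope with known truth
  beta_true <- 0.7
  n <- 60
  cover <- sapply(1:200, function(s) {
    set.seed(s)
    x <- rnorm(n)
    y <- beta_true * x + (rexp(n) - 1)   # skewed homoskedastic errors
    slope <- function(idx) coef(lm.fit(cbind(1, x[idx]), y[idx]))[2]
    obs <- slope(seq_len(n))
    draws <- sapply(1:399, function(b) slope(sample.int(n, replace = TRUE)))
    jack <- sapply(seq_len(n), function(i) slope(setdiff(seq_len(n), i)))
    ci <- bca_interval(draws, obs, jack)
    ci$lower <= beta_true && beta_true <= ci$upper
  })
  expect_equal(mean(cover), 0.95,
               tolerance = 1.96 * sqrt(0.95 * 0.05 / 200) / 0.95 + 0.02)
})

test_that("exemplary profiles are linear and additive in the coefficients", {
  sim <- sim_cohort(n_patients = 50, n_controls = 0, n_parcels = 25, seed = 19)
  m1 <- fit_parcelwise_glm(sim$int, sim$cohort, "M1_primary")
  prof <- exemplary_profiles(m1, sim$hierarchies$auditory)
  expect_equal(unname(prof$delta[, "none"]), rep(0, 9))
  expect_equal(prof$delta[, "both"],
               prof$delta[, "hallucinations_only"] +
                 prof$delta[, "delusions_only"], tolerance = 1e-10)
  # deltas are 5x the fitted symptom coefficients, exactly
  parc <- prof$parcels
  expect_equal(unname(prof$delta[, "hallucinations_only"]),
               unname(5 * m1$coefficients["hallucinations", parc]),
               tolerance = 1e-10)

  # a single hand-set coefficient propagates as 5 * 0.02 at its level only
  m1z <- m1
  m1z$coefficients[symptom_items(), ] <- 0
  m1z$coefficients["hallucinations", "A1"] <- 0.02
  profz <- exemplary_profiles(m1z, sim$hierarchies$auditory)
  expect_equal(unname(profz$delta["A1", "hallucinations_only"]), 0.1)
  expect_equal(unname(profz$delta["LBelt", "hallucinations_only"]), 0)
  expect_equal(max(abs(profz$delta[, "delusions_only"])), 0)
})

test_that("rank-binned control bins, averages and detects monotone gradients", {
  set.seed(20)
  ref <- runif(600)
  tmono <- 3 * ref + rnorm(600, sd = 1e-6)
  rb <- rank_binned_profile(cbind(hallucinations = tmono,
                                  delusions = -tmono), ref, n_bins = 10)
  expect_equal(rb$bin_size, 60L)
  expect_true(all(diff(rb$bin_means[, "hallucinations"]) > 0))
  expect_equal(nrow(rb$gradient$data), 20L)

  # constant t: zero slope
  rb2 <- rank_binned_profile(rep(2, 600), ref, n_bins = 10)
  expect_equal(unname(rb2$slopes), 0, tolerance = 1e-12)

  expect_warning(rank_binned_profile(rnorm(605), runif(605), 10), "leftover")
  expect_error(rank_binned_profile(rnorm(5), runif(5), 10), "more bins")
})

test_that("diagnosis overall test counts suppressed INT parcels", {
  sim <- sim_cohort(n_patients = 60, n_controls = 60, diagnosis_pct = -5,
                    n_parcels = 60, seed = 21)
  res <- diagnosis_overall_test(sim$int, sim$cohort, n_perm = 99, seed = 22)
  expect_gt(sum(res$tstats < 0), 30)   # majority of parcels negative
  expect_lt(res$p, 0.05)
})

test_that("PANSS rescaling subtracts one and merges the top levels", {
  expect_identical(rescale_panss(1:7), c(0L, 1L, 2L, 3L, 4L, 5L, 5L))
  expect_error(rescale_panss(0), "1..7")
})
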