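test_that("connectivity container enforces FLN/SLN invariants", {
  fln <- matrix(c(0, 1, 0.5, 0), 2, 2, byrow = TRUE)
  expect_error(connectivity_data(fln), "sum to 1")
  fln[2, ] <- c(1, 0)
  sln <- matrix(c(NA, 0.2, 1.4, NA), 2, 2, byrow = TRUE)
  expect_error(connectivity_data(fln, sln), "0, 1")
  expect_s3_class(connectivity_data(fln, abs(sln) / 2), "connectivity_data")
})

test_that("hierarchy estimation recovers the generating values from SLN", {
  sc <- sim_connectivity(h = setNames(c(0, .3, .45, .7, 1), paste0("n", 1:5)),
                         sln_noise = 0, seed = 2)
  hv <- build_hierarchy_from_tracing(sc$conn)
  expect_equal(cor(hv$h, sc$h, method = "spearman"), 1)
  # noiseless logistic link: recovery is exact up to affine normalization
  expect_equal(unname(hv$h), unname((sc$h - min(sc$h)) / diff(range(sc$h))),
               tolerance = 1e-6)
})

test_that("two reciprocally connected nodes give the closed-form logit gap", {
  fln <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("lo", "hi"),
                                                     c("lo", "hi")))
  sln <- matrix(c(NA, 0.12, 0.88, NA), 2, 2, byrow = TRUE,
                dimnames = dimnames(fln))  # SLN(lo -> hi) = 0.88
  hv <- build_hierarchy_from_tracing(connectivity_data(fln, sln))
  expect_equal(unname(hv$h_raw["hi"] - hv$h_raw["lo"]),
               qlogis(0.88), tolerance = 1e-6)
})

test_that("flat SLN yields a flagged flat hierarchy; disconnection errors", {
  fln <- matrix(1/2, 3, 3); diag(fln) <- 0
  fln <- fln / rowSums(fln)
  sln <- matrix(0.5, 3, 3); diag(sln) <- NA
  expect_warning(hv <- build_hierarchy_from_tracing(connectivity_data(fln, sln)),
                 "flat")
  expect_equal(unname(hv$h), rep(0, 3))

  fln4 <- matrix(0, 4, 4)
  fln4[1, 2] <- fln4[2, 1] <- 1
  fln4[3, 4] <- fln4[4, 3] <- 1
  sln4 <- matrix(0.6, 4, 4); diag(sln4) <- NA
  expect_error(build_hierarchy_from_tracing(connectivity_data(fln4, sln4)),
               "disconnected")
})

test_that("background calibration hits the printed operating point exactly", {
  # isolated nodes: closed-form currents
  fln <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  mod <- calibrate_background(rate_model(connectivity_data(fln),
                                         c(a = 0, b = 1)))
  p <- rate_model_params()
  for (i in 1:2) {
    h <- c(0, 1)[i]
    expect_equal(unname(mod$iext_e[i]),
                 10 / p$beta_e - (1 + p$eta * h) * p$w_ee * 10 + p$w_ei * 35,
                 tolerance = 1e-10)
    expect_equal(unname(mod$iext_i[i]),
                 35 / p$beta_i - (1 + p$eta * h) * p$w_ie * 10 + p$w_ii * 35,
                 tolerance = 1e-10)
  }
  ss <- steady_state(mod)
  expect_equal(unname(ss$v_e), rep(10, 2), tolerance = 1e-10)
  expect_equal(unname(ss$v_i), rep(35, 2), tolerance = 1e-10)

  # currents are linear in the target rates
  mod2 <- calibrate_background(rate_model(connectivity_data(fln),
                                          c(a = 0, b = 1)),
                               target_e = 20, target_i = 70)
  expect_equal(mod2$iext_e, 2 * mod$iext_e, tolerance = 1e-10)
  expect_equal(mod2$iext_i, 2 * mod$iext_i, tolerance = 1e-10)
})

sc0 <- sim_connectivity(seed = 1)
mod0 <- calibrate_background(rate_model(sc0$conn, sc0$h))

test_that("the calibrated full network relaxes to 10/35 Hz and is stable", {
  st <- model_stability(mod0)
  expect_true(st$stable)
  ss <- steady_state(mod0)
  sim <- simulate_network(mod0, duration = 16, dt = 5e-4, noise_sd = 0,
                          init = list(v_e = ss$v_e * 1.3, v_i = ss$v_i * 0.8))
  tail_rates_e <- colMeans(sim$rates_e[14000:16000, ])
  tail_rates_i <- colMeans(sim$rates_i[14000:16000, ])
  expect_true(all(abs(tail_rates_e - 10) < 0.1))
  expect_true(all(abs(tail_rates_i - 35) < 0.1))
})

test_that("noiseless simulation from the fixed point stays there", {
  sim <- simulate_network(mod0, duration = 10, dt = 5e-4, noise_sd = 0)
  expect_lt(max(abs(sim$rates_e - 10)), 1e-6)
  expect_lt(max(abs(sim$rates_i - 35)), 1e-6)
})

test_that("simulation guards its preconditions", {
  expect_error(simulate_network(mod0, duration = 5), "at least 10")
  expect_error(simulate_network(mod0, duration = 20, dt = 0.01),
               "tau_i / 10")
  sc <- sim_connectivity(seed = 1)
  expect_error(simulate_network(rate_model(sc$conn, sc$h), duration = 20),
               "not calibrated")
})

test_that("identical nodes with eta = 0 produce exchangeable trajectories", {
  fln <- matrix(1/2, 3, 3); diag(fln) <- 0; fln <- fln / rowSums(fln)
  dimnames(fln) <- list(paste0("n", 1:3), paste0("n", 1:3))
  par0 <- rate_model_params(eta = 0, noise_sd = 1e-5)
  m <- calibrate_background(rate_model(connectivity_data(fln),
                                       setNames(c(0, 0.5, 1), paste0("n", 1:3)),
                                       params = par0))
  sim <- simulate_network(m, duration = 60, dt = 5e-4, seed = 3, burn_in = 5)
  vars <- apply(sim$rates_e, 2, var)
  expect_lt(max(vars) / min(vars), 1.5)
  expect_lt(max(abs(colMeans(sim$rates_e) - 10)), 0.01)
})

test_that("simulated autocovariance matches the Lyapunov-equation oracle", {
  fln <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- calibrate_background(rate_model(connectivity_data(fln), c(a = 0.2, b = 0.6)))
  noise_sd <- 1e-5
  sim <- simulate_network(m, duration = 400, dt = 2e-4, seed = 4,
                          record_dt = 1e-3, burn_in = 10, noise_sd = noise_sd)
  x <- cbind(sim$rates_e, sim$rates_i)
  emp <- cov(x)

  st <- model_stability(m)
  J <- st$jacobian
  p <- m$params
  q <- diag(c(rep((noise_sd / p$tau_e)^2, 2), rep((noise_sd / p$tau_i)^2, 2)))
  n <- nrow(J)
  C <- matrix(solve(kronecker(diag(n), J) + kronecker(J, diag(n)),
                    -as.vector(q)), n, n)
  expect_equal(unname(diag(emp)), diag(C), tolerance = 0.1)
})

test_that("the E/I triangle profile has the stated endpoints and additivity", {
  nl <- mod0$node_levels
  pb <- ei_perturbation(1, 20, 0)
  d <- ei_delta_profile(pb, nl)
  expect_equal(unname(d["V1"]), 20)
  expect_equal(unname(d["8l"]), 0)            # furthest free level, D = 7
  expect_equal(unname(d["V4"]), 20 * (1 - 3 / 7), tolerance = 1e-12)
  expect_equal(unname(d["46d"]), 0)           # fixed node

  p2 <- ei_perturbation(8, 4, 0)
  d12 <- ei_delta_profile(list(pb, p2), nl)
  expect_equal(d12, d + ei_delta_profile(p2, nl), tolerance = 1e-12)

  # identity when both magnitudes are zero
  m_id <- apply_ei_perturbation(mod0, ei_perturbation(3, 0, 0))
  expect_equal(unname(rep_len(m_id$params$w_ie, 9)),
               rep(mod0$params$w_ie, 9))

  expect_error(ei_perturbation(9, 10), "1..8")
  expect_error(ei_perturbation(1, 50), "0, 40")
  expect_error(ei_perturbation(1, 10, -40), "-30, 40")
  expect_error(
    apply_ei_perturbation(mod0, list(ei_perturbation(1, 40, 40),
                                     ei_perturbation(2, 40, 40),
                                     ei_perturbation(3, 40, 40))),
    "nonphysical")
})

hemo0 <- hemodynamic_params()

test_that("BOLD coefficients follow the printed k-formulas", {
  h <- hemodynamic_params(theta0 = 40.3, r0 = 25, epsilon = 1.43,
                          rho = 0.34, te = 0.04)
  expect_equal(h$k1, 4.3 * 40.3 * 0.34 * 0.04)
  expect_equal(h$k2, 1.43 * 25 * 0.34 * 0.04)
  expect_equal(h$k3, 1 - 1.43)
})

test_that("constant steady-state input leaves the hemodynamics at rest", {
  rates <- matrix(10, 5000, 2)
  b <- bold_forward(rates, hemo0, dt = 0.01, tr_out = 1,
                    baseline = c(10, 10))
  expect_lt(max(abs(b$data)), 1e-12)
})

test_that("an activity impulse produces the canonical response shape", {
  rates <- matrix(10, 60000, 1)
  rates[5000:5100, 1] <- 10.001      # 0.1 s impulse at t = 5 s
  b <- bold_forward(rates, hemo0, dt = 0.001, tr_out = 0.5,
                    baseline = 10)
  y <- b$data[, 1]
  peak <- which.max(y)
  trough <- which.min(y)
  expect_gt(max(y), 0)
  expect_lt(min(y), 0)
  expect_lt(peak, trough)            # positive lobe precedes the undershoot
  expect_lt(abs(y[length(y)]), max(y) * 0.05)  # returns to baseline
})

test_that("hemodynamic state collapse is caught with a diagnostic", {
  rates <- matrix(10, 2000, 1)
  rates[100:2000] <- -3000
  expect_error(bold_forward(rates, hemo0, dt = 0.01, tr_out = 1,
                            baseline = 10),
               "hemodynamic state collapse")
})

test_that("matched seeds give an exactly zero null-perturbation delta-INT", {
  args <- sim_args_small()
  ref <- estimate_insilico_int(mod0, NULL, n_reps = args$n_reps,
                               duration = args$duration, seed = 5,
                               dt = args$dt, record_dt = args$record_dt,
                               burn_in = args$burn_in)
  zero <- estimate_insilico_int(mod0, ei_perturbation(4, 0, 0),
                                n_reps = args$n_reps, duration = args$duration,
                                seed = 5, dt = args$dt,
                                record_dt = args$record_dt,
                                burn_in = args$burn_in, reference = ref)
  expect_identical(unname(zero$delta), rep(0, 9))
})

test_that("a global E/I reduction shortens INT at every node", {
  # a uniform 1% reduction (wIE scaled up everywhere); the delta is averaged
  # over matched noise seeds because the lowest node sits near the fast floor
  gm <- uniform_ei_change(mod0, -1)
  acc <- 0
  for (s in 1:6) {
    ref <- estimate_insilico_int(mod0, NULL, n_reps = 2, duration = 360,
                                 seed = s * 11, dt = 5e-4, record_dt = 2e-3,
                                 burn_in = 20)
    gl <- estimate_insilico_int(gm, NULL, n_reps = 2, duration = 360,
                                seed = s * 11, dt = 5e-4, record_dt = 2e-3,
                                burn_in = 20)
    acc <- acc + (gl$int - ref$int)
  }
  expect_true(all(acc / 6 < 0))
})

test_that("higher hierarchy levels have longer in-silico INT", {
  acc <- 0
  for (s in 1:3) {
    acc <- acc + estimate_insilico_int(mod0, NULL, n_reps = 2,
                                       duration = 360, seed = 100 + s,
                                       dt = 5e-4, record_dt = 2e-3,
                                       burn_in = 20)$int
  }
  int_avg <- acc / 3
  expect_gt(int_avg["46d"], int_avg["V1"])
  expect_gt(int_avg["8l"], int_avg["V2"])
})

test_that("raising the peak E/I magnitude does not shorten INT at the peak", {
  ref <- estimate_insilico_int(mod0, NULL, n_reps = 2, duration = 360,
                               seed = 7, dt = 5e-4, record_dt = 2e-3,
                               burn_in = 20)
  ladder <- sapply(1:4, function(mag)
    estimate_insilico_int(mod0, ei_perturbation(8, mag, 0), n_reps = 2,
                          duration = 360, seed = 7, dt = 5e-4,
                          record_dt = 2e-3, burn_in = 20,
                          reference = ref)$delta["8l"])
  expect_true(all(diff(c(0, ladder)) > -0.02))
  expect_gt(ladder[4], 0.05)
})

test_that("both E/I mechanisms produce sign-consistent delta-INT profiles", {
  ref <- estimate_insilico_int(mod0, NULL, n_reps = 2, duration = 360,
                               seed = 7, dt = 5e-4, record_dt = 2e-3,
                               burn_in = 20)
  d_wie <- estimate_insilico_int(mod0, ei_perturbation(8, 2.5, 0,
                                                       "reduce_wie"),
                                 n_reps = 2, duration = 360, seed = 7,
                                 dt = 5e-4, record_dt = 2e-3, burn_in = 20,
                                 reference = ref)$delta
  d_wee <- estimate_insilico_int(mod0, ei_perturbation(8, 2.5, 0,
                                                       "increase_wee"),
                                 n_reps = 2, duration = 360, seed = 7,
                                 dt = 5e-4, record_dt = 2e-3, burn_in = 20,
                                 reference = ref)$delta
  upper <- c("V4", "MT", "8l", "46d")
  expect_true(all(d_wie[upper] > 0))
  expect_true(all(d_wee[upper] > 0))
})

test_that("exemplary-profile conversion picks the matched levels in order", {
  sim <- sim_cohort(n_patients = 40, n_controls = 0, n_parcels = 25, seed = 9)
  m1 <- fit_parcelwise_glm(sim$int, sim$cohort, "M1_primary")
  prof <- exemplary_profiles(m1, sim$hierarchies$auditory)
  m <- invivo_delta_matrix(prof, mod0$node_levels)
  expect_equal(dim(m), c(6L, 3L))
  expect_identical(rownames(m),
                   paste0("level", c(1, 2, 4, 5, 8, 9)))
  expect_equal(unname(m[, "both"]),
               unname(m[, "hallucinations_only"] + m[, "delusions_only"]),
               tolerance = 1e-10)
})
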