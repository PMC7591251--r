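#' Simulate the rate network
#'
#' Euler-Maruyama integration of the excitatory-inhibitory rate equations
#' with rectified input currents, hierarchy-scaled local and long-range
#' excitation, and seeded white-noise drive. Integration starts at the
#' model's (possibly perturbed) noiseless steady state unless `init` is
#' given.
#'
#' @param model A calibrated [rate_model()].
#' @param duration Simulated time (s), at least 10.
#' @param dt Integration step (s); must satisfy `dt <= tau_i / 10`.
#' @param seed Integer seed (consumed via `set.seed`); `NULL` leaves the RNG
#'   state untouched.
#' @param record_dt Recording interval for the returned trajectories (s).
#' @param burn_in Initial span (s) discarded before recording.
#' @param noise_sd Override of the model's noise amplitude (Hz); `0` gives a
#'   deterministic run.
#' @param init Optional list `v_e`, `v_i` of initial rates (Hz).
#' @return Object of class `network_sim`: `rates_e`, `rates_i` (time x node,
#'   Hz), `dt` (recording interval), `nodes`, `baseline` (steady-state rates).
#' @export
simulate_network <- function(model, duration, dt = 2e-4, seed = NULL,
                             record_dt = 1e-3, burn_in = 0,
                             noise_sd = NULL, init = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (is.null(model$iext_e)) stop("model is not calibrated")
  p <- model$params
  if (dt > p$tau_i / 10 + 1e-12)
    stop("'dt' must not exceed tau_i / 10 = ", p$tau_i / 10, " s")
  if (duration < 10) stop("'duration' must be at least 10 s")
  if (is.null(noise_sd)) noise_sd <- p$noise_sd
  n <- length(model$h)
  w <- node_weights(p, n)
  fp <- steady_state(model)
  if (is.null(init)) init <- fp
  if (!is.null(seed)) set.seed(seed)
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  n_steps <- as.integer(round(duration / dt))
  burn_steps <- as.integer(round(burn_in / dt))
  res <- simulate_rates_cpp(model$conn$fln, model$h,
                            p$tau_e, p$tau_i, p$beta_e, p$beta_i,
                            w$w_ee, w$w_ie, p$w_ei, p$w_ii,
                            p$mu_ee, p$mu_ie, p$eta,
                            model$iext_e, model$iext_i,
                            init$v_e, init$v_i,
                            dt, n_steps, noise_sd, record_every, burn_steps)
  colnames(res$rates_e) <- colnames(res$rates_i) <- model$conn$node_names
  structure(list(rates_e = res$rates_e, rates_i = res$rates_i,
                 dt = record_every * dt, nodes = model$conn$node_names,
                 baseline = fp),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat("<network_sim> ", nrow(x$rates_e), " samples x ", ncol(x$rates_e),
      " nodes at ", x$dt, " s\n  mean E rates (Hz): ",
      paste(signif(colMeans(x$rates_e), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' `simulate` method for rate-network models
#'
#' Thin wrapper around [simulate_network()] following the base-R `simulate`
#' generic.
#'
#' @param object A calibrated [rate_model()].
#' @param nsim Number of independent runs.
#' @param seed Integer seed; run `r` uses `seed + r - 1`.
#' @param duration,... Passed to [simulate_network()].
#' @return List of `network_sim` objects (length `nsim`).
#' @export
simulate.rate_model <- function(object, nsim = 1, seed = 1,
                                duration = 60, ...) {
  lapply(seq_len(nsim), function(r)
    simulate_network(object, duration = duration, seed = seed + r - 1, ...))
}

#' Balloon-Windkessel BOLD forward model
#'
#' Integrates the vasodilatory-signal / inflow / volume / deoxyhemoglobin
#' ODE system per node, driven by the deviation of the excitatory rate from
#' its steady-state baseline, and returns the BOLD signal decimated to the
#' output repetition time.
#'
#' @param rates A `network_sim` or a time x node matrix of excitatory rates
#'   (Hz).
#' @param hemo A [hemodynamic_params()].
#' @param dt Sampling interval of `rates` (s); taken from a `network_sim`
#'   automatically.
#' @param tr_out Output repetition time (s), default 2.
#' @param baseline Per-node baseline rate subtracted before transduction;
#'   default: the `network_sim` steady state, else column means.
#' @return A [bold_ts()] at `tr_out` resolution.
#' @export
bold_forward <- function(rates, hemo = hemodynamic_params(), dt = NULL,
                         tr_out = 2, baseline = NULL) {
  if (inherits(rates, "network_sim")) {
    if (is.null(baseline)) baseline <- rates$baseline$v_e
    if (is.null(dt)) dt <- rates$dt
    rates <- rates$rates_e
  }
  rates <- as.matrix(rates)
  if (is.null(dt)) stop("'dt' is required for a plain rate matrix")
  if (is.null(baseline)) baseline <- colMeans(rates)
  z <- sweep(rates, 2L, baseline, "-")
  decim <- as.integer(round(tr_out / dt))
  if (decim < 1L) stop("'tr_out' must be at least 'dt'")
  b <- bold_forward_cpp(z, dt, hemo$kappa, hemo$gamma_f, hemo$tau_mtt,
                        hemo$alpha, hemo$rho, hemo$v0,
                        hemo$k1, hemo$k2, hemo$k3, decim)
  colnames(b) <- colnames(rates)
  bold_ts(b, tr = tr_out)
}

# INT per column from an averaged ACF matrix (lags x units).
int_from_acf <- function(acfmat, tr) {
  apply(acfmat, 2L, function(a) {
    if (all(is.na(a))) return(NA_real_)
    i <- which(a <= 0)
    n_pos <- if (length(i)) i[1L] - 1L else length(a)
    if (n_pos < 1L) 0 else tr * sum(a[seq_len(n_pos)])
  })
}

#' In-silico INT of the simulated network
#'
#' Simulates the (optionally E/I-perturbed) model with resting-state noise,
#' transduces the excitatory rates to BOLD, downsamples to the fMRI
#' repetition time, averages the autocorrelation function across repetitions,
#' and computes the per-node INT. The same seeds drive the unaltered
#' reference model, so a zero perturbation yields a delta of exactly zero.
#'
#' @param model A calibrated, unaltered [rate_model()].
#' @param perturbations `NULL`, a single [ei_perturbation()], or a list.
#' @param n_reps Repetitions whose ACFs are averaged before INT computation.
#' @param duration Simulated seconds per repetition (excluding `burn_in`).
#' @param seed Base integer seed; repetition `r` uses `seed + r - 1`.
#' @param dt,record_dt Integration/recording steps (s).
#' @param tr_out Output TR for the BOLD signal (s), default 2.
#' @param burn_in Seconds discarded at the start of each repetition.
#' @param reference Optional `insilico_int` of the unaltered model with
#'   matched settings, to avoid recomputing it across fits.
#' @return Object of class `insilico_int`: `int` (s per node), `delta`
#'   (versus the unaltered reference), `reference`, `acf`, `nodes`.
#' @export
estimate_insilico_int <- function(model, perturbations = NULL, n_reps = 5,
                                  duration = 1800, seed = 1, dt = 2e-4,
                                  record_dt = 1e-3, tr_out = 2, burn_in = 20,
                                  reference = NULL) {
  run_int <- function(m) {
    acfs <- NULL
    for (r in seq_len(n_reps)) {
      sim <- simulate_network(m, duration = duration + burn_in, dt = dt,
                              seed = seed + r - 1, record_dt = record_dt,
                              burn_in = burn_in)
      bts <- bold_forward(sim, hemo = model$hemo, tr_out = tr_out)
      prof <- acf_profile(bts)
      acfs <- if (is.null(acfs)) prof$coefficients
              else acfs + prof$coefficients
    }
    acfs <- acfs / n_reps
    list(int = int_from_acf(acfs, tr_out), acf = acfs)
  }

  perturbed <- !is.null(perturbations) &&
    (inherits(perturbations, "ei_perturbation") || length(perturbations))
  if (is.null(reference)) {
    ref_run <- run_int(model)
    reference <- structure(
      list(int = ref_run$int, delta = ref_run$int * 0, reference = NULL,
           acf = ref_run$acf, nodes = model$conn$node_names),
      class = "insilico_int")
  }
  if (!perturbed) return(reference)

  pm <- apply_ei_perturbation(model, perturbations)
  run <- run_int(pm)
  structure(list(int = run$int, delta = run$int - reference$int,
                 reference = reference$int, acf = run$acf,
                 nodes = model$conn$node_names),
            class = "insilico_int")
}

#' @export
print.insilico_int <- function(x, ...) {
  out <- rbind(int_s = x$int, delta_s = x$delta)
  colnames(out) <- x$nodes
  print(round(out, 4))
  invisible(x)
}

# logistic reparametrization for bounded Nelder-Mead
to_bounded <- function(x, lo, hi) lo + (hi - lo) * stats::plogis(x)
from_bounded <- function(p, lo, hi) {
  z <- (p - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-6), 1 - 1e-6)
  stats::qlogis(z)
}

#' Fit E/I perturbation parameters to observed delta-INT profiles
#'
#' Grid search over the peak levels of two triangle-shaped E/I perturbations
#' (one per symptom), with an inner two-stage optimization of the four
#' magnitude parameters: a deterministic coarse scan over peak-magnitude
#' pairs locates the basin (combinations that destabilize the network score
#' infinity and are skipped), then bounded Nelder-Mead refines from the best
#' lattice point(s). The objective is the sum of squared errors
#' between the simulated delta-INT and the supplied in-vivo delta-INT over
#' 18 points (3 exemplary cases x 6 matched levels); the combined case is
#' modeled as the sum of the two perturbations' E/I changes. Every objective
#' evaluation reuses the same noise seeds (common random numbers), so the fit
#' is deterministic given `seed`.
#'
#' @param invivo_delta 6 x 3 matrix of delta-INT (s): rows = the six matched
#'   hierarchy levels in increasing order, columns = cases (first symptom
#'   only, second symptom only, both). An [exemplary_profiles()] object is
#'   accepted and converted via [invivo_delta_matrix()].
#' @param model A calibrated, unaltered [rate_model()] whose `node_levels`
#'   cover the six matched levels.
#' @param peak_grid Data frame / matrix of candidate peak-level pairs
#'   (columns: first and second symptom); default the full 8 x 8 grid.
#' @param mechanism Perturbation mechanism, see [ei_perturbation()].
#' @param n_reps,duration,dt,record_dt,tr_out,burn_in,seed Simulation
#'   settings passed to [estimate_insilico_int()].
#' @param restarts Number of lattice points (best first) refined by
#'   Nelder-Mead per grid cell.
#' @param maxit Iteration cap per restart.
#' @return Object of class `ei_fit`: `peaks` (named pair), `magnitudes`
#'   (peak/min per symptom), `sse`, `sse_surface` (per grid cell), `grid`,
#'   diagnostics.
#' @export
fit_ei_parameters <- function(invivo_delta, model,
                              peak_grid = expand.grid(peak1 = 1:8, peak2 = 1:8),
                              mechanism = c("reduce_wie", "increase_wee"),
                              n_reps = 5, duration = 1800, dt = 2e-4,
                              record_dt = 1e-3, tr_out = 2, burn_in = 20,
                              seed = 1, restarts = 3, maxit = 60) {
  mechanism <- match.arg(mechanism)
  if (inherits(invivo_delta, "exemplary_profile"))
    invivo_delta <- invivo_delta_matrix(invivo_delta, model$node_levels)
  invivo_delta <- as.matrix(invivo_delta)
  if (!all(dim(invivo_delta) == c(length(model$node_levels), 3L)))
    stop("'invivo_delta' must be ", length(model$node_levels), " levels x 3 cases")

  node_order <- names(sort(model$node_levels))
  ref <- estimate_insilico_int(model, NULL, n_reps = n_reps,
                               duration = duration, seed = seed, dt = dt,
                               record_dt = record_dt, tr_out = tr_out,
                               burn_in = burn_in)

  delta_of <- function(pert) {
    est <- estimate_insilico_int(model, pert, n_reps = n_reps,
                                 duration = duration, seed = seed, dt = dt,
                                 record_dt = record_dt, tr_out = tr_out,
                                 burn_in = burn_in, reference = ref)
    stats::setNames(est$delta, est$nodes)[node_order]
  }

  lo <- c(0, -30, 0, -30); hi <- c(40, 40, 40, 40)
  objective <- function(mags, peaks) {
    p1 <- ei_perturbation(peaks[1], mags[1], mags[2], mechanism)
    p2 <- ei_perturbation(peaks[2], mags[3], mags[4], mechanism)
    tryCatch({
      d1 <- delta_of(p1)
      d2 <- delta_of(p2)
      d12 <- delta_of(list(p1, p2))
      sum((d1 - invivo_delta[, 1])^2) + sum((d2 - invivo_delta[, 2])^2) +
        sum((d12 - invivo_delta[, 3])^2)
    }, error = function(e) Inf)
  }

  # Per grid cell: a deterministic coarse scan over peak-magnitude pairs
  # locates the basin (unstable combinations score Inf and are skipped), then
  # bounded Nelder-Mead refines all four magnitudes from the best lattice
  # point (plus optional restarts from the runners-up).
  lattice <- as.matrix(expand.grid(pm1 = c(3, 10, 25), pm2 = c(3, 10, 25)))
  surface <- rep(NA_real_, nrow(peak_grid))
  cell_fits <- vector("list", nrow(peak_grid))
  for (g in seq_len(nrow(peak_grid))) {
    peaks <- as.integer(unlist(peak_grid[g, 1:2]))
    scan <- apply(lattice, 1L, function(pm)
      objective(c(pm[1], 0, pm[2], 0), peaks))
    ord <- order(scan)
    best <- NULL
    for (r in ord[seq_len(min(restarts, sum(is.finite(scan))))] ) {
      x0 <- from_bounded(c(lattice[r, 1], 0, lattice[r, 2], 0), lo, hi)
      o <- tryCatch(
        stats::optim(x0, function(x) objective(to_bounded(x, lo, hi), peaks),
                     method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      surface[g] <- Inf
      cell_fits[[g]] <- list(peaks = peaks, magnitudes = rep(NA_real_, 4),
                             sse = Inf)
    } else {
      surface[g] <- best$value
      cell_fits[[g]] <- list(peaks = peaks,
                             magnitudes = to_bounded(best$par, lo, hi),
                             sse = best$value)
    }
  }
  if (all(!is.finite(surface))) stop("all grid cells failed simulation")
  gbest <- which.min(surface)
  bf <- cell_fits[[gbest]]
  mags <- bf$magnitudes
  structure(list(
    peaks = stats::setNames(bf$peaks, c("symptom1", "symptom2")),
    magnitudes = data.frame(symptom = c("symptom1", "symptom2"),
                            peak_mag = mags[c(1, 3)],
                            min_mag = mags[c(2, 4)]),
    sse = bf$sse, sse_surface = surface, grid = peak_grid,
    cell_fits = cell_fits, mechanism = mechanism),
    class = "ei_fit")
}

#' @export
print.ei_fit <- function(x, ...) {
  cat("<ei_fit> mechanism = ", x$mechanism, "\n  peak levels: ",
      paste(x$peaks, collapse = ", "), "; SSE = ", signif(x$sse, 4), "\n",
      sep = "")
  print(transform(x$magnitudes, peak_mag = round(peak_mag, 2),
                  min_mag = round(min_mag, 2)))
  invisible(x)
}

#' Convert an exemplary-case profile to the 6-level fitting target
#'
#' Selects the hierarchy levels matched to the model nodes and returns the
#' delta-INT of the three symptomatic exemplary cases.
#'
#' @param profile An [exemplary_profiles()] object.
#' @param node_levels Named node -> level mapping of the model (its levels
#'   select the rows).
#' @return 6 x 3 numeric matrix (levels in increasing order; cases:
#'   hallucinations only, delusions only, both).
#' @export
invivo_delta_matrix <- function(profile, node_levels) {
  lv <- sort(unique(as.integer(node_levels)))
  rows <- match(lv, profile$levels)
  if (anyNA(rows))
    stop("profile lacks levels: ", paste(lv[is.na(rows)], collapse = ", "))
  m <- profile$delta[rows, c("hallucinations_only", "delusions_only", "both"),
                     drop = FALSE]
  rownames(m) <- paste0("level", lv)
  m
}
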