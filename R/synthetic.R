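#' Ornstein-Uhlenbeck BOLD surrogate with known timescale
#'
#' Generates per-unit stationary Ornstein-Uhlenbeck series sampled at the
#' repetition time using the exact discretization `x_{t+1} = phi x_t +
#' sqrt(1 - phi^2) e_t`, `phi = exp(-tr / tau)`, so the ground-truth discrete
#' lag-k autocorrelation is exactly `phi^k` and the implied discrete-sum INT
#' is `tr * phi / (1 - phi)`. Optional white observation noise attenuates the
#' observable autocorrelation.
#'
#' @param timescale Target OU timescale(s) tau in seconds, recycled across
#'   units.
#' @param tr Sampling interval / repetition time (s).
#' @param n_timepoints Number of samples (>= 100).
#' @param n_units Number of units; defaults to `length(timescale)`.
#' @param obs_noise_sd SD of added white observation noise (signal SD is 1).
#' @param seed Integer seed.
#' @return A [bold_ts()] with attributes `timescale`, `phi` and `int_true`
#'   (the noise-free discrete-sum ground truth, seconds).
#' @export
sim_bold_ou <- function(timescale, tr, n_timepoints, n_units = length(timescale),
                        obs_noise_sd = 0, seed = 1) {
  stopifnot(all(timescale > 0), tr > 0)
  if (n_timepoints < 100) stop("need at least 100 timepoints")
  tau <- rep_len(timescale, n_units)
  phi <- exp(-tr / tau)
  set.seed(seed)
  x <- matrix(stats::rnorm(n_timepoints * n_units), n_timepoints, n_units)
  for (j in seq_len(n_units)) {
    z <- x[, j]
    out <- numeric(n_timepoints)
    out[1] <- z[1]
    a <- sqrt(1 - phi[j]^2)
    for (t in 2:n_timepoints) out[t] <- phi[j] * out[t - 1] + a * z[t]
    x[, j] <- out
  }
  if (obs_noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = obs_noise_sd), nrow(x))
  out <- bold_ts(x, tr = tr)
  attr(out, "timescale") <- tau
  attr(out, "phi") <- phi
  attr(out, "int_true") <- tr * phi / (1 - phi)
  out
}

# ---- ordinal symptom scores via a thresholded Gaussian copula -------------

# Default marginal score distribution over 0..5, matched to the coarse shape
# of the observed hallucination/delusion ratings (mean ~2.4, SD ~1.9).
default_score_probs <- function() c(0.25, 0.14, 0.13, 0.14, 0.15, 0.19)

# Bivariate standard-normal CDF by 1-D quadrature (no external dependency).
pbvnorm <- function(a, b, rho) {
  if (!is.finite(a) && a < 0) return(0)
  if (!is.finite(b) && b < 0) return(0)
  if (!is.finite(a)) return(stats::pnorm(b))
  if (!is.finite(b)) return(stats::pnorm(a))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((b - rho * x) / s),
    -Inf, a, rel.tol = 1e-10)$value
}

# Population Spearman correlation of two scores obtained by cutting a
# bivariate standard normal with latent correlation rho at the same
# cutpoints. Uses the grade transform u_k = P(S < k) + P(S = k)/2.
spearman_discretized <- function(rho, probs = default_score_probs()) {
  k <- length(probs)
  cuts <- c(-Inf, stats::qnorm(cumsum(probs))[-k], Inf)
  cdf <- matrix(0, k + 1, k + 1)
  for (i in seq_len(k + 1)) for (j in seq_len(k + 1))
    cdf[i, j] <- pbvnorm(cuts[i], cuts[j], rho)
  cell <- cdf[-1, -1] - cdf[-(k + 1), -1] - cdf[-1, -(k + 1)] +
    cdf[-(k + 1), -(k + 1)]
  u <- cumsum(probs) - probs / 2
  mu <- sum(probs * u)
  v <- sum(probs * u^2) - mu^2
  (drop(t(u) %*% cell %*% u) - mu^2) / v
}

#' Latent correlation needed to hit a target score Spearman correlation
#'
#' Inverts the discretization map: finds the latent Gaussian correlation for
#' which two 0-5 scores, obtained by thresholding a bivariate normal at the
#' default marginal cutpoints, have the requested population Spearman
#' correlation.
#'
#' @param target Target Spearman correlation of the discrete scores.
#' @param probs Marginal score distribution over 0..5.
#' @return Latent correlation in (-1, 1). Errors when the target exceeds the
#'   attainable bound (the value reached as the latent correlation tends
#'   to 1), reporting that bound.
#' @export
latent_rho_for_spearman <- function(target, probs = default_score_probs()) {
  bound <- spearman_discretized(0.9999, probs)
  if (abs(target) >= abs(bound))
    stop("target Spearman ", target, " infeasible after discretization; ",
         "attainable bound is ", signif(bound, 4))
  stats::uniroot(function(r) spearman_discretized(r, probs) - target,
                 c(-0.999, 0.999), tol = 1e-6)$root
}

score_from_latent <- function(z, probs) {
  cuts <- stats::qnorm(cumsum(probs))[-length(probs)]
  findInterval(z, cuts)
}

#' Synthetic patient-control cohort with hierarchical symptom effects
#'
#' Generates a cohort table (seven correlated 0-5 symptom scores, age,
#' gender, mean FD, site) and a subjects x parcels INT matrix carrying a base
#' hierarchical INT gradient plus injected symptom-specific gradient effects:
#' a hallucination-linked compression (negative level slope, auditory system)
#' and a delusion-linked expansion (positive level slope, auditory and
#' somatosensory systems), a global percentage diagnosis effect, covariate
#' effects, site offsets, and between-subject / within-parcel Gaussian noise.
#' Symptom scores come from a thresholded Gaussian copula whose
#' hallucination-delusion latent correlation is calibrated so the discrete
#' scores hit the target rank correlation.
#'
#' @param n_patients,n_controls Group sizes (defaults 127 and 158).
#' @param target_spearman Target hallucination-delusion Spearman correlation
#'   (default 0.62).
#' @param n_parcels Total parcels including the hierarchy parcels (default
#'   188).
#' @param base_intercept,base_slope Base INT at level 0 and per-level
#'   increment (s); filler parcels get base values drawn around the same
#'   range.
#' @param hall_slope,del_slope Injected effect, seconds per score-point per
#'   centered hierarchy level (negative default for hallucinations, positive
#'   for delusions).
#' @param diagnosis_pct Global percent INT change in patients (default -5).
#' @param subject_sd Between-subject INT offset SD (s).
#' @param noise_sd Within-parcel residual SD (s).
#' @param n_sites Number of acquisition sites (default 4).
#' @param seed Integer seed.
#' @return List: `int` (subjects x parcels), `cohort` ([cohort_table()]),
#'   `hierarchies` (the winning orderings used), `truth` (all generating
#'   parameters).
#' @export
sim_cohort <- function(n_patients = 127, n_controls = 158,
                       target_spearman = 0.62, n_parcels = 188,
                       base_intercept = 0.55, base_slope = 0.03,
                       hall_slope = -0.005, del_slope = 0.004,
                       diagnosis_pct = -5, subject_sd = 0.10,
                       noise_sd = 0.06, n_sites = 4, seed = 1) {
  set.seed(seed)
  n <- n_patients + n_controls
  diagnosis <- rep(c(1L, 0L), c(n_patients, n_controls))

  # --- symptoms: 7-dim latent Gaussian, thresholded ---
  probs <- default_score_probs()
  rho_hd <- latent_rho_cached(target_spearman, probs)
  items <- symptom_items()
  pos <- c("hallucinations", "delusions", "conceptual_disorganization")
  R <- matrix(0.25, 7, 7, dimnames = list(items, items))
  R[pos, pos] <- 0.5
  R[setdiff(items, pos), setdiff(items, pos)] <- 0.5
  R["hallucinations", "delusions"] <- R["delusions", "hallucinations"] <- rho_hd
  diag(R) <- 1
  Lc <- chol(R)
  z <- matrix(stats::rnorm(n_patients * 7), n_patients) %*% Lc
  scores <- apply(z, 2L, score_from_latent, probs = probs)
  colnames(scores) <- items
  scores_all <- matrix(0L, n, 7, dimnames = list(NULL, items))
  scores_all[diagnosis == 1L, ] <- scores

  # --- covariates ---
  age <- round(pmin(pmax(stats::rnorm(n, 32, 10), 18), 65), 1)
  gender <- stats::rbinom(n, 1, 0.8)
  mean_fd <- round(exp(stats::rnorm(n, log(0.13), 0.35)), 3)
  site <- factor(sample.int(n_sites, n, replace = TRUE),
                 labels = paste0("site", seq_len(n_sites)))

  cohort <- cohort_table(data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    diagnosis = diagnosis, scores_all, age = age, gender = gender,
    mean_fd = mean_fd, site = site))

  # --- parcels and their levels per system ---
  hier <- winning_hierarchies()
  level_of <- list()
  for (sys in names(hier)) {
    a <- hier[[sys]]$assignment
    for (p in names(a)) level_of[[p]] <- unname(a[p])
  }
  hier_parcels <- names(level_of)
  n_fill <- max(0L, n_parcels - length(hier_parcels))
  fillers <- if (n_fill > 0) sprintf("P%03d", seq_len(n_fill)) else character()
  parcels <- c(hier_parcels, fillers)

  base <- c(base_intercept + base_slope * unlist(level_of),
            base_intercept + base_slope *
              stats::runif(n_fill, 1, 9))
  names(base) <- parcels

  aud <- names(hier$auditory$assignment)
  som <- names(hier$somatosensory$assignment)
  center <- 5
  eff_hall <- stats::setNames(rep(0, length(parcels)), parcels)
  eff_hall[aud] <- hall_slope * (unlist(level_of[aud]) - center)
  eff_del <- stats::setNames(rep(0, length(parcels)), parcels)
  eff_del[aud] <- del_slope * (unlist(level_of[aud]) - center)
  eff_del[som] <- eff_del[som] + del_slope * (unlist(level_of[som]) - center)

  site_offset <- stats::setNames(
    c(0, 0.02, -0.02, 0.01)[seq_len(n_sites)], levels(site))
  age_eff <- -0.001; fd_eff <- -0.3

  int <- matrix(rep(base, each = n), n, length(parcels),
                dimnames = list(cohort$subject_id, parcels))
  int <- int * (1 + (diagnosis_pct / 100) * diagnosis)
  int <- int + outer(scores_all[, "hallucinations"], eff_hall) +
    outer(scores_all[, "delusions"], eff_del)
  int <- int + age_eff * (age - mean(age)) + fd_eff * (mean_fd - mean(mean_fd))
  int <- int + site_offset[as.character(site)]
  int <- int + stats::rnorm(n, sd = subject_sd)          # subject offset
  int <- int + matrix(stats::rnorm(n * length(parcels), sd = noise_sd), n)
  int <- pmax(int, 0.01)

  list(int = int, cohort = cohort, hierarchies = hier,
       truth = list(hall_slope = hall_slope, del_slope = del_slope,
                    diagnosis_pct = diagnosis_pct, base_slope = base_slope,
                    latent_rho = rho_hd, target_spearman = target_spearman,
                    effect_systems = list(hallucinations = "auditory",
                                          delusions = c("auditory",
                                                        "somatosensory"))))
}

# memoized latent-correlation calibration (quadrature is deterministic)
.latent_cache <- new.env(parent = emptyenv())
latent_rho_cached <- function(target, probs) {
  key <- paste(signif(target, 8), paste(signif(probs, 8), collapse = ","))
  if (is.null(.latent_cache[[key]]))
    .latent_cache[[key]] <- latent_rho_for_spearman(target, probs)
  .latent_cache[[key]]
}

#' Synthetic structural cohort with a hierarchical gradient
#'
#' T1w/T2w decreases and cortical thickness increases with hierarchical
#' level, plus per-subject random intercepts and slopes and measurement
#' noise; emulates the structural data used for ordering selection.
#'
#' @param ordering Generating [hierarchy_ordering()].
#' @param n_subjects Number of subjects.
#' @param t1w_slope,thick_slope Fixed-effect gradients per level (ratio units
#'   and mm).
#' @param subject_sd Length-2: SD of per-subject random intercept and random
#'   slope.
#' @param noise_sd Residual SD (applied to both measures).
#' @param seed Integer seed.
#' @return A [structural_cohort()].
#' @export
sim_structural_cohort <- function(ordering, n_subjects = 20,
                                  t1w_slope = -0.07, thick_slope = 0.08,
                                  subject_sd = c(0.05, 0.01),
                                  noise_sd = 0.04, seed = 1) {
  set.seed(seed)
  lv <- ordering$assignment
  parcels <- names(lv)
  np <- length(parcels)
  mk <- function(base, slope) {
    b0 <- stats::rnorm(n_subjects, 0, subject_sd[1])
    b1 <- stats::rnorm(n_subjects, 0, subject_sd[2])
    m <- outer(rep(base, n_subjects), rep(1, np)) +
      outer(b0, rep(1, np)) + outer(b1 + slope, as.numeric(lv)) +
      matrix(stats::rnorm(n_subjects * np, 0, noise_sd), n_subjects)
    dimnames(m) <- list(sprintf("sub%03d", seq_len(n_subjects)), parcels)
    m
  }
  structural_cohort(t1w_t2w = mk(1.8, t1w_slope),
                    thickness = mk(2.2, thick_slope))
}

#' Synthetic tract-tracing connectivity with known hierarchy
#'
#' Generates an FLN/SLN connectivity set consistent with a known hierarchy.
#' SLN always follows the logistic of the hierarchy difference (slope
#' `sln_slope`) with optional link noise, clipped to (0.01, 0.99). FLN
#' weights are log-normal with a mean that decays with hierarchy-value
#' distance and an additional penalty on feedback projections (source above
#' target) scaled by the same distance; rows are normalized to 1 (target x
#' source).
#'
#' The default layout emulates the dynamical structure of the tract-traced
#' macaque network used for the E/I modeling: the six matched
#' visual-stream nodes (V1, V2, V4, MT, 8l, 46d; levels 1, 2, 4, 5, 8, 9)
#' plus a three-node association "core" placed high in the hierarchy. The
#' core projects into the matched nodes with a share that grows along the
#' hierarchy (`core_mix`) but receives no projections back from them, so it
#' carries a slow near-critical rate mode (the counterpart of the strongly
#' recurrent association cluster of the real network) whose expression in
#' the matched nodes increases with hierarchical level, while E/I
#' perturbations of the matched nodes cannot destabilize it.
#'
#' @param h Named true hierarchy values in \[0, 1\]; overrides the default
#'   matched-node layout and disables the core (plain distance-decay
#'   connectivity over these nodes).
#' @param n_nodes When `h` is `NULL` and `core = FALSE`: number of equally
#'   spaced generic nodes.
#' @param core Add the three-node association core (default `TRUE` for the
#'   standard layout).
#' @param core_h Hierarchy value of the core cluster (its criticality knob;
#'   the core's internal Perron mode has unit connectivity eigenvalue, so
#'   `core_h` alone sets its stability margin).
#' @param core_mix Length-6 share of each matched node's long-range input
#'   originating from the core, in hierarchy order.
#' @param fln_decay Decay rate of mean log-FLN with |h_i - h_j|.
#' @param fb_penalty Additional log-FLN penalty per unit distance for
#'   feedback projections.
#' @param fln_sd Log-normal SD of FLN weights.
#' @param sln_slope Logistic slope applied to (h_i - h_j).
#' @param sln_noise SD of additive SLN link noise (probability scale).
#' @param seed Integer seed.
#' @return List: `conn` (a [connectivity_data()]), `h` (true values for all
#'   nodes), `node_levels` (matched nodes only, for the E/I machinery),
#'   `core_nodes`.
#' @export
sim_connectivity <- function(h = NULL, n_nodes = 6, core = is.null(h),
                             core_h = 0.77,
                             core_mix = c(0.02, 0.05, 0.08, 0.10, 0.13, 0.18),
                             fln_decay = 2, fb_penalty = 6, fln_sd = 0.15,
                             sln_slope = 4, sln_noise = 0.02, seed = 1) {
  force(core)   # default references h, which is reassigned below
  set.seed(seed)
  node_levels <- NULL
  core_nodes <- character()
  if (is.null(h)) {
    node_levels <- c(V1 = 1L, V2 = 2L, V4 = 4L, MT = 5L, `8l` = 8L,
                     `46d` = 9L)
    h <- c(V1 = 0, V2 = 0.125, V4 = 0.375, MT = 0.5, `8l` = 0.8, `46d` = 1)
    if (core) {
      core_nodes <- c("C1", "C2", "C3")
      h <- c(h, stats::setNames(core_h + c(0, 0.005, 0.01), core_nodes))
    }
    if (!core && n_nodes != 6)
      h <- stats::setNames(seq(0, 1, length.out = n_nodes),
                           paste0("node", seq_len(n_nodes)))
  } else {
    core <- FALSE
    if (is.null(names(h))) names(h) <- paste0("node", seq_along(h))
  }
  n <- length(h)
  if (n < 3) stop("need at least 3 nodes")

  dh <- outer(h, h, "-")            # h_i - h_j (target minus source)
  lw <- -fln_decay * abs(dh) - fb_penalty * pmax(-dh, 0) +
    matrix(stats::rnorm(n * n, 0, fln_sd), n)
  fln <- exp(lw)
  diag(fln) <- 0
  if (core) {
    im <- seq_len(6); ic <- 6L + seq_len(3L)
    fln[ic, im] <- 0                # core is self-contained
    fln <- fln / rowSums(fln)
    for (i in im) {                 # graded core share of long-range input
      s <- core_mix[i]
      fln[i, im] <- (1 - s) * fln[i, im] / sum(fln[i, im])
      fln[i, ic] <- s * fln[i, ic] / sum(fln[i, ic])
    }
  } else {
    fln <- fln / rowSums(fln)
  }

  sln <- stats::plogis(sln_slope * dh)
  if (sln_noise > 0)
    sln <- sln + matrix(stats::rnorm(n * n, 0, sln_noise), n)
  sln <- pmin(pmax(sln, 0.01), 0.99)
  diag(sln) <- NA
  dimnames(fln) <- dimnames(sln) <- list(names(h), names(h))
  list(conn = connectivity_data(fln, sln), h = h,
       node_levels = node_levels, core_nodes = core_nodes)
}
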