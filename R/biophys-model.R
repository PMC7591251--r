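#' Rate-model parameters
#'
#' The printed parameter set of the hierarchical excitatory-inhibitory rate
#' network: intrinsic time constants, f-I slopes, local coupling weights,
#' long-range scaling, hierarchy gain, and the resting-state noise amplitude.
#' Local weights `w_ee` and `w_ie` may be given per node (used by the E/I
#' perturbations); scalars are recycled.
#'
#' @param tau_e,tau_i Intrinsic time constants (s); defaults 20 and 10 ms.
#' @param beta_e,beta_i f-I slopes (Hz/pA).
#' @param w_ee,w_ie,w_ei,w_ii Local coupling weights (pA/Hz).
#' @param mu_ee,mu_ie Long-range coupling scalars (pA/Hz).
#' @param eta Hierarchy gain applied to local-excitatory and long-range drive.
#' @param noise_sd SD of the white-noise external drive, expressed as a
#'   rate-equivalent (Hz) through the f-I slope; default 1e-5.
#' @return Object of class `rate_model_params`.
#' @export
rate_model_params <- function(tau_e = 0.020, tau_i = 0.010,
                              beta_e = 0.066, beta_i = 0.351,
                              w_ee = 24.3, w_ie = 12.2,
                              w_ei = 19.7, w_ii = 12.5,
                              mu_ee = 33.7, mu_ie = 25.3,
                              eta = 0.68, noise_sd = 1e-5) {
  stopifnot(tau_e > 0, tau_i > 0, beta_e > 0, beta_i > 0, noise_sd >= 0)
  structure(list(tau_e = tau_e, tau_i = tau_i, beta_e = beta_e,
                 beta_i = beta_i, w_ee = w_ee, w_ie = w_ie, w_ei = w_ei,
                 w_ii = w_ii, mu_ee = mu_ee, mu_ie = mu_ie, eta = eta,
                 noise_sd = noise_sd),
            class = "rate_model_params")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Constants of the hemodynamic forward model for 3 T acquisitions. The BOLD
#' coefficients are always derived as `k1 = 4.3 * theta0 * rho * te`,
#' `k2 = epsilon * r0 * rho * te`, `k3 = 1 - epsilon`, never set directly.
#'
#' @param kappa Vasodilatory signal decay rate (1/s).
#' @param gamma_f Flow-dependent elimination rate (1/s).
#' @param tau_mtt Mean transit time of blood (s).
#' @param alpha Venous resistance (stiffness) exponent.
#' @param rho Resting oxygen extraction fraction.
#' @param v0 Resting venous blood volume fraction.
#' @param theta0 Frequency offset at the vessel surface for fully
#'   deoxygenated blood (Hz).
#' @param r0 Slope of intravascular relaxation rate against oxygen
#'   saturation (Hz).
#' @param epsilon Intra-/extra-vascular signal ratio.
#' @param te Echo time (s).
#' @return Object of class `hemodynamic_params` including derived `k1`, `k2`,
#'   `k3`.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma_f = 0.41, tau_mtt = 0.98,
                               alpha = 0.32, rho = 0.34, v0 = 0.02,
                               theta0 = 40.3, r0 = 25, epsilon = 1.43,
                               te = 0.04) {
  stopifnot(kappa > 0, gamma_f > 0, tau_mtt > 0, alpha > 0, alpha < 1,
            rho > 0, rho < 1, v0 > 0, te > 0)
  structure(list(kappa = kappa, gamma_f = gamma_f, tau_mtt = tau_mtt,
                 alpha = alpha, rho = rho, v0 = v0, theta0 = theta0,
                 r0 = r0, epsilon = epsilon, te = te,
                 k1 = 4.3 * theta0 * rho * te,
                 k2 = epsilon * r0 * rho * te,
                 k3 = 1 - epsilon),
            class = "hemodynamic_params")
}

#' Tract-tracing connectivity container (FLN and SLN)
#'
#' @param fln Nonnegative node x node matrix of fractions of labeled neurons,
#'   target x source, with each nonzero row summing to 1.
#' @param sln Node x node matrix of supragranular labeled-neuron fractions in
#'   \[0, 1\], defined wherever `fln > 0` (`NA` elsewhere is accepted).
#' @param node_names Node identifiers; defaults to `rownames(fln)`.
#' @return Object of class `connectivity_data`.
#' @export
connectivity_data <- function(fln, sln = NULL, node_names = rownames(fln)) {
  fln <- as.matrix(fln)
  if (nrow(fln) != ncol(fln)) stop("'fln' must be square")
  if (any(fln < 0)) stop("'fln' must be nonnegative")
  rs <- rowSums(fln)
  if (any(rs > 0 & abs(rs - 1) > 1e-6))
    stop("nonzero FLN rows must sum to 1 (target x source normalization)")
  if (is.null(node_names)) node_names <- paste0("node", seq_len(nrow(fln)))
  dimnames(fln) <- list(node_names, node_names)
  if (!is.null(sln)) {
    sln <- as.matrix(sln)
    if (!all(dim(sln) == dim(fln))) stop("'sln' must match 'fln' in shape")
    on_edges <- sln[fln > 0]
    if (any(!is.na(on_edges) & (on_edges < 0 | on_edges > 1)))
      stop("'sln' values must lie in [0, 1]")
    dimnames(sln) <- dimnames(fln)
  }
  structure(list(fln = fln, sln = sln, node_names = node_names),
            class = "connectivity_data")
}

#' @export
print.connectivity_data <- function(x, ...) {
  cat("<connectivity_data> ", length(x$node_names), " nodes, ",
      sum(x$fln > 0), " directed projections",
      if (!is.null(x$sln)) " (with SLN)", "\n", sep = "")
  invisible(x)
}

#' Read FLN/SLN matrices from CSV
#'
#' Square matrices with node-name headers and row names in the first column.
#'
#' @param fln_path,sln_path CSV paths; `sln_path` optional.
#' @return A [connectivity_data()].
#' @export
read_connectivity_csv <- function(fln_path, sln_path = NULL) {
  fln <- as.matrix(utils::read.csv(fln_path, row.names = 1, check.names = FALSE))
  sln <- if (!is.null(sln_path))
    as.matrix(utils::read.csv(sln_path, row.names = 1, check.names = FALSE))
  connectivity_data(fln, sln)
}

#' Estimate hierarchy values from laminar projection data
#'
#' Fits the logistic model `SLN(j -> i) ~ logistic(h_i - h_j)` by weighted
#' logistic regression on a signed node-indicator design (+1 for the target,
#' -1 for the source, one node's value fixed at zero as the gauge), with each
#' projection weighted by the logarithm of its FLN (shifted to be positive:
#' `log(FLN) - log(min FLN) + 1`, which preserves the log-FLN ordering). The
#' fitted values are min-max normalized to \[0, 1\].
#'
#' @param conn A [connectivity_data()] with SLN.
#' @return Object of class `hierarchy_values`: `h` (named, in \[0, 1\]),
#'   `h_raw` (pre-normalization, gauge node at 0), `fit`.
#' @export
build_hierarchy_from_tracing <- function(conn) {
  stopifnot(inherits(conn, "connectivity_data"))
  if (is.null(conn$sln)) stop("connectivity has no SLN data")
  n <- length(conn$node_names)
  if (n < 2) stop("need at least 2 nodes")
  edges <- which(conn$fln > 0 & is.finite(conn$sln), arr.ind = TRUE)
  if (nrow(edges) < 1) stop("no connected pair with SLN")

  # connected components of the undirected projection graph
  adj <- (conn$fln > 0) | t(conn$fln > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  if (cid > 1L)
    stop("disconnected projection graph; components: ",
         paste(vapply(seq_len(cid), function(k)
           paste(conn$node_names[comp == k], collapse = "+"), character(1)),
           collapse = " | "))

  y <- conn$sln[edges]
  w <- log(conn$fln[edges])
  w <- w - min(w) + 1
  X <- matrix(0, nrow(edges), n, dimnames = list(NULL, conn$node_names))
  X[cbind(seq_len(nrow(edges)), edges[, 1])] <- 1    # target i
  X[cbind(seq_len(nrow(edges)), edges[, 2])] <-
    X[cbind(seq_len(nrow(edges)), edges[, 2])] - 1   # source j
  X <- X[, -1, drop = FALSE]                         # gauge: first node at 0

  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w,
                   family = stats::quasibinomial("logit")))
  h_raw <- c(0, fit$coefficients)
  h_raw[!is.finite(h_raw)] <- 0
  names(h_raw) <- conn$node_names
  rng <- diff(range(h_raw))
  if (rng < 1e-8) {
    warning("all hierarchy values equal; returning flat zero vector")
    h <- stats::setNames(rep(0, n), conn$node_names)
  } else {
    h <- (h_raw - min(h_raw)) / rng
  }
  structure(list(h = h, h_raw = h_raw, fit = fit),
            class = "hierarchy_values")
}

#' @export
print.hierarchy_values <- function(x, ...) {
  cat("<hierarchy_values>\n")
  print(round(x$h, 3))
  invisible(x)
}

# expand scalar weights to per-node vectors
node_weights <- function(params, n) {
  list(w_ee = rep_len(params$w_ee, n), w_ie = rep_len(params$w_ie, n))
}

#' Assemble a hierarchical rate-network model
#'
#' Bundles parameters, connectivity, hierarchy values, node-to-level mapping
#' and hemodynamics into one simulatable object. Background currents start
#' unset; see [calibrate_background()].
#'
#' @param conn A [connectivity_data()].
#' @param h Hierarchy values in \[0, 1\]: a [build_hierarchy_from_tracing()]
#'   result or a named numeric vector over the nodes.
#' @param params A [rate_model_params()].
#' @param hemo A [hemodynamic_params()].
#' @param node_levels Named integer vector mapping nodes to hierarchical
#'   levels 1..9 (used by the E/I triangle perturbation); default is the
#'   six-node visual-hierarchy mapping V1=1, V2=2, V4=4, MT=5, 8l=8, 46d=9
#'   restricted to the model's nodes.
#' @return Object of class `rate_model`.
#' @export
rate_model <- function(conn, h, params = rate_model_params(),
                       hemo = hemodynamic_params(), node_levels = NULL) {
  if (inherits(h, "hierarchy_values")) h <- h$h
  h <- h[conn$node_names]
  if (anyNA(h)) stop("hierarchy values missing for some nodes")
  if (min(h) < -1e-9 || max(h) > 1 + 1e-9)
    stop("hierarchy values must lie in [0, 1]")
  if (is.null(node_levels)) {
    default_map <- c(V1 = 1L, V2 = 2L, V4 = 4L, MT = 5L, `8l` = 8L, `46d` = 9L)
    node_levels <- default_map[intersect(names(default_map), conn$node_names)]
  }
  structure(list(conn = conn, h = as.numeric(h), params = params,
                 hemo = hemo, node_levels = node_levels,
                 iext_e = NULL, iext_i = NULL, fixed_point = NULL),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> ", length(x$conn$node_names), " nodes (",
      paste(x$conn$node_names, collapse = ", "), ")\n",
      if (is.null(x$iext_e)) "  background currents: not calibrated\n"
      else "  background currents: calibrated\n", sep = "")
  invisible(x)
}

# Linearized-system matrices at an all-positive operating point.
model_matrices <- function(model) {
  p <- model$params
  n <- length(model$h)
  w <- node_weights(p, n)
  hs <- 1 + p$eta * model$h
  fln <- model$conn$fln
  s_e <- hs * (diag(w$w_ee, n) + p$mu_ee * fln)
  s_i <- hs * (diag(w$w_ie, n) + p$mu_ie * fln)
  list(s_e = s_e, s_i = s_i, n = n, w = w)
}

#' Jacobian and stability of the calibrated operating point
#'
#' @param model A calibrated [rate_model()].
#' @return List: `jacobian` (2n x 2n), `eigenvalues`, `stable`.
#' @export
model_stability <- function(model) {
  p <- model$params
  mm <- model_matrices(model)
  n <- mm$n
  id <- diag(n)
  j_ee <- (-id + p$beta_e * mm$s_e) / p$tau_e
  j_ei <- -(p$beta_e * p$w_ei * id) / p$tau_e
  j_ie <- (p$beta_i * mm$s_i) / p$tau_i
  j_ii <- (-id - p$beta_i * p$w_ii * id) / p$tau_i
  J <- rbind(cbind(j_ee, j_ei), cbind(j_ie, j_ii))
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev, stable = all(Re(ev) < 0))
}

#' Calibrate background currents to a target operating point
#'
#' Solves the steady-state equations with the rectifications active at the
#' target rates, including long-range inputs, for the per-node background
#' currents that make every excitatory population fire at `target_e` and
#' every inhibitory population at `target_i`. The linearized system at the
#' resulting fixed point must be stable, otherwise an error is raised.
#'
#' @param model A [rate_model()].
#' @param target_e,target_i Target excitatory/inhibitory rates (Hz);
#'   defaults 10 and 35.
#' @return The model with `iext_e`, `iext_i` and `fixed_point` filled in.
#' @export
calibrate_background <- function(model, target_e = 10, target_i = 35) {
  stopifnot(inherits(model, "rate_model"), target_e > 0, target_i > 0)
  p <- model$params
  mm <- model_matrices(model)
  ve <- rep(target_e, mm$n); vi <- rep(target_i, mm$n)
  iext_e <- ve / p$beta_e - drop(mm$s_e %*% ve) + p$w_ei * vi
  iext_i <- vi / p$beta_i - drop(mm$s_i %*% ve) + p$w_ii * vi
  model$iext_e <- iext_e
  model$iext_i <- iext_i
  model$fixed_point <- list(v_e = ve, v_i = vi)
  st <- model_stability(model)
  if (!st$stable)
    stop("unstable operating point (Jacobian eigenvalue with positive ",
         "real part: ", signif(max(Re(st$eigenvalues)), 4), ")")
  model
}

#' Steady state of a calibrated (possibly perturbed) model
#'
#' Solves the fixed-point system for the model's current parameters and
#' background inputs. The rectified input currents make the fixed point
#' piecewise linear: starting from the all-positive branch, populations whose
#' solution turns negative are clamped to zero and the reduced linear system
#' is re-solved (active-set iteration) until the branch is self-consistent.
#'
#' @param model A calibrated [rate_model()].
#' @return List `v_e`, `v_i` (Hz per node).
#' @export
steady_state <- function(model) {
  if (is.null(model$iext_e)) stop("model is not calibrated")
  p <- model$params
  mm <- model_matrices(model)
  n <- mm$n
  id <- diag(n)
  A <- rbind(cbind(id - p$beta_e * mm$s_e,  p$beta_e * p$w_ei * id),
             cbind(-p$beta_i * mm$s_i,      id + p$beta_i * p$w_ii * id))
  b <- c(p$beta_e * model$iext_e, p$beta_i * model$iext_i)
  # gain matrix translating rates into (beta * input current)
  G <- rbind(cbind(p$beta_e * mm$s_e, -p$beta_e * p$w_ei * id),
             cbind(p$beta_i * mm$s_i, -p$beta_i * p$w_ii * id))
  active <- rep(TRUE, 2 * n)
  for (it in 1:100) {
    x <- numeric(2 * n)
    x[active] <- solve(A[active, active, drop = FALSE], b[active])
    neg <- active & x < -1e-12
    # a clamped population rejoins when its rectified input turns positive
    drive <- G %*% x + b
    pos <- !active & drive > 1e-12
    if (!any(neg) && !any(pos)) break
    active <- (active & !neg) | pos
    if (it == 100) {
      # cycling active set: fall back to noiseless relaxation from the
      # clamped all-positive solution
      x0 <- solve(A, b)
      x0[x0 < 0] <- 0
      w <- node_weights(p, n)
      res <- simulate_rates_cpp(model$conn$fln, model$h,
                                p$tau_e, p$tau_i, p$beta_e, p$beta_i,
                                w$w_ee, w$w_ie, p$w_ei, p$w_ii,
                                p$mu_ee, p$mu_ie, p$eta,
                                model$iext_e, model$iext_i,
                                x0[seq_len(n)], x0[n + seq_len(n)],
                                1e-3, 60000L, 0, 1000L, 0L)
      x <- c(res$rates_e[nrow(res$rates_e), ],
             res$rates_i[nrow(res$rates_i), ])
      break
    }
  }
  x[x < 0] <- 0
  list(v_e = x[seq_len(n)], v_i = x[n + seq_len(n)])
}

#' E/I ratio perturbation (triangle profile over hierarchy levels)
#'
#' A local E/I elevation peaking at one hierarchical level and decaying
#' linearly with absolute level distance: at level L,
#' `delta(L) = min_mag + (peak_mag - min_mag) * (1 - |L - peak| / D)` where D
#' is the largest level distance from the peak among non-fixed nodes.
#'
#' @param peak_level Integer 1..8, level of the peak E/I increase.
#' @param peak_mag Percent change at the peak, in \[0, 40\].
#' @param min_mag Percent change at the furthest level, in \[-30, 40\].
#' @param mechanism `"reduce_wie"` (weaken local excitatory-to-inhibitory
#'   coupling) or `"increase_wee"` (strengthen local recurrent excitation).
#' @param fixed_nodes Nodes whose couplings never change (default `"46d"`,
#'   whose strong connectivity makes the model unstable under even small
#'   changes).
#' @return Object of class `ei_perturbation`.
#' @export
ei_perturbation <- function(peak_level, peak_mag, min_mag = 0,
                            mechanism = c("reduce_wie", "increase_wee"),
                            fixed_nodes = "46d") {
  mechanism <- match.arg(mechanism)
  peak_level <- as.integer(peak_level)
  if (peak_level < 1L || peak_level > 8L)
    stop("'peak_level' must be an integer in 1..8")
  if (peak_mag < 0 || peak_mag > 40) stop("'peak_mag' must lie in [0, 40]")
  if (min_mag < -30 || min_mag > 40) stop("'min_mag' must lie in [-30, 40]")
  structure(list(peak_level = peak_level, peak_mag = peak_mag,
                 min_mag = min_mag, mechanism = mechanism,
                 fixed_nodes = fixed_nodes),
            class = "ei_perturbation")
}

#' Per-node E/I change implied by one or more perturbations
#'
#' @param perturbations A single [ei_perturbation()] or a list; the triangle
#'   profiles of multiple perturbations are summed node-wise.
#' @param node_levels Named integer vector node -> level.
#' @return Named numeric vector of percent E/I changes (0 at fixed nodes).
#' @export
ei_delta_profile <- function(perturbations, node_levels) {
  if (inherits(perturbations, "ei_perturbation"))
    perturbations <- list(perturbations)
  delta <- stats::setNames(rep(0, length(node_levels)), names(node_levels))
  for (pb in perturbations) {
    free <- setdiff(names(node_levels), pb$fixed_nodes)
    D <- max(abs(node_levels[free] - pb$peak_level))
    if (D == 0) D <- 1
    tri <- pb$min_mag + (pb$peak_mag - pb$min_mag) *
      (1 - abs(node_levels - pb$peak_level) / D)
    tri[pb$fixed_nodes[pb$fixed_nodes %in% names(tri)]] <- 0
    delta <- delta + tri
  }
  delta
}

#' Apply E/I perturbations to a model
#'
#' Sums the triangle profiles of all perturbations and applies the resulting
#' per-node percent change through the stated mechanism:
#' `reduce_wie` rescales `w_ie` by `(1 - delta/100)`, `increase_wee` rescales
#' `w_ee` by `(1 + delta/100)`. Fixed nodes are untouched. Background currents
#' are kept at their unaltered calibration (the perturbation shifts the
#' operating point).
#'
#' @param model A calibrated [rate_model()].
#' @param perturbations A single [ei_perturbation()] or a list of them (all
#'   sharing one mechanism).
#' @return A new `rate_model` with per-node local weights.
#' @export
apply_ei_perturbation <- function(model, perturbations) {
  if (inherits(perturbations, "ei_perturbation"))
    perturbations <- list(perturbations)
  if (!length(perturbations)) return(model)
  mech <- unique(vapply(perturbations, `[[`, character(1), "mechanism"))
  if (length(mech) > 1)
    stop("all summed perturbations must share one mechanism")
  nl <- model$node_levels
  if (is.null(nl) || !length(nl)) stop("model has no node-level mapping")
  if (any(nl < 1 | nl > 9)) stop("node levels must lie in 1..9")
  delta <- ei_delta_profile(perturbations, nl)
  n <- length(model$h)
  w <- node_weights(model$params, n)
  dvec <- stats::setNames(rep(0, n), model$conn$node_names)
  dvec[names(delta)] <- delta
  if (mech == "reduce_wie") {
    if (any(abs(dvec) >= 100))
      stop("summed |E/I change| >= 100% makes w_ie nonphysical")
    model$params$w_ie <- w$w_ie * (1 - dvec / 100)
  } else {
    model$params$w_ee <- w$w_ee * (1 + dvec / 100)
  }
  model
}

#' Uniform (global) E/I scenario
#'
#' Applies a single percent E/I change to every node (including otherwise
#' fixed ones), e.g. a globally reduced E/I ratio as a diagnosis-level
#' scenario.
#'
#' @param model A calibrated [rate_model()].
#' @param delta_pct Percent E/I change (negative = reduced E/I).
#' @param mechanism As in [ei_perturbation()].
#' @return Perturbed `rate_model`.
#' @export
uniform_ei_change <- function(model, delta_pct,
                              mechanism = c("reduce_wie", "increase_wee")) {
  mechanism <- match.arg(mechanism)
  n <- length(model$h)
  w <- node_weights(model$params, n)
  if (mechanism == "reduce_wie") {
    if (abs(delta_pct) >= 100) stop("|delta_pct| must be < 100")
    model$params$w_ie <- w$w_ie * (1 - delta_pct / 100)
  } else {
    model$params$w_ee <- w$w_ee * (1 + delta_pct / 100)
  }
  model
}
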