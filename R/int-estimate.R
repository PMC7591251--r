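#' Autocorrelation profile of a BOLD time series
#'
#' Computes, per unit, the sample autocorrelation at lags `1..K` using the
#' biased estimator with the full-series variance in the denominator:
#' `ACF_k = sum_{t=k+1}^{T} (y_t - ybar)(y_{t-k} - ybar) / sum_t (y_t - ybar)^2`.
#' Censored volumes are handled in one of two modes: `"pairwise"` (default)
#' keeps a lag-k product only when both frames are retained and computes the
#' mean and denominator over retained frames only; `"concatenate"` drops
#' censored frames and re-indexes the series as if contiguous.
#'
#' @param series A [bold_ts()] object.
#' @param max_lag Maximum lag K; default `min(T_retained - 1, ceiling(100 / tr))`.
#' @param censor_mode `"pairwise"` or `"concatenate"`.
#'
#' @return An object of class `acf_profile`: list with `coefficients` (K x units
#'   matrix), `first_nonpositive_lag` (integer per unit; `K + 1` when all K
#'   coefficients are positive), `undefined` (logical per unit; `TRUE` for
#'   zero-variance series), `tr`, `unit_ids`.
#' @export
acf_profile <- function(series, max_lag = NULL,
                        censor_mode = c("pairwise", "concatenate")) {
  stopifnot(inherits(series, "bold_ts"))
  censor_mode <- match.arg(censor_mode)
  y <- series$data
  mask <- series$censor_mask
  if (sum(mask) < 8L) stop("need at least 8 retained timepoints")

  if (censor_mode == "concatenate") {
    y <- y[mask, , drop = FALSE]
    mask <- rep(TRUE, nrow(y))
  }
  tt <- nrow(y)
  if (is.null(max_lag))
    max_lag <- min(sum(mask) - 1L, as.integer(ceiling(100 / series$tr)))
  max_lag <- max(1L, min(max_lag, tt - 1L))

  m <- as.numeric(mask)
  nm <- sum(m)
  ybar <- colSums(y * m) / nm
  yc <- sweep(y, 2L, ybar, "-") * m        # zero out censored frames
  denom <- colSums(yc^2)
  undefined <- denom <= 0 | !is.finite(denom)

  co <- matrix(NA_real_, max_lag, ncol(y),
               dimnames = list(NULL, series$unit_ids))
  for (k in seq_len(max_lag)) {
    idx1 <- (k + 1L):tt
    idx0 <- 1L:(tt - k)
    num <- colSums(yc[idx1, , drop = FALSE] * yc[idx0, , drop = FALSE])
    co[k, ] <- num / denom
  }
  co[, undefined] <- NA_real_

  fnp <- apply(co, 2L, function(a) {
    if (all(is.na(a))) return(NA_integer_)
    i <- which(a <= 0)
    if (length(i)) i[1L] else max_lag + 1L
  })

  structure(
    list(coefficients = co, first_nonpositive_lag = fnp,
         undefined = undefined, tr = series$tr, unit_ids = series$unit_ids),
    class = "acf_profile"
  )
}

#' @export
print.acf_profile <- function(x, ...) {
  cat("<acf_profile> ", nrow(x$coefficients), " lags x ",
      ncol(x$coefficients), " units (TR = ", x$tr, " s)\n", sep = "")
  invisible(x)
}

#' Intrinsic neural timescale (INT) estimation
#'
#' INT is the repetition-time-scaled area under the initial positive segment of
#' the autocorrelation function: `INT = TR * sum_{k=1}^{N} ACF_k`, where `N` is
#' the lag directly preceding the first non-positive ACF coefficient. A series
#' whose lag-1 autocorrelation is already non-positive gets INT = 0 (empty
#' sum); a constant (zero-variance) series has an undefined ACF and its INT is
#' reported as `NA` and flagged, never as 0.
#'
#' @param series A [bold_ts()] object.
#' @param exp_fit If `TRUE`, additionally fit `A * exp(-k * TR / tau)` to the
#'   initial positive ACF segment by nonlinear least squares and report the
#'   decay constant `tau` (seconds) per unit; units whose positive segment is
#'   shorter than 2 lags get `NA`.
#' @param max_lag,censor_mode Passed to [acf_profile()].
#'
#' @return An object of class `int_map`: list with `values` (seconds per unit),
#'   `space_tag`, `unit_ids`, `undefined` flags, the `acf` profile, and
#'   optionally `exp_timescale`.
#' @export
#' @examples
#' y <- sim_bold_ou(timescale = 1, tr = 0.72, n_timepoints = 2000, seed = 1)
#' estimate_int(y)
estimate_int <- function(series, exp_fit = FALSE, max_lag = NULL,
                         censor_mode = c("pairwise", "concatenate")) {
  prof <- acf_profile(series, max_lag = max_lag, censor_mode = censor_mode)
  co <- prof$coefficients
  nv <- ncol(co)
  vals <- numeric(nv)
  for (j in seq_len(nv)) {
    if (prof$undefined[j]) { vals[j] <- NA_real_; next }
    n_pos <- prof$first_nonpositive_lag[j] - 1L
    vals[j] <- if (n_pos < 1L) 0 else prof$tr * sum(co[seq_len(n_pos), j])
  }

  out <- structure(
    list(values = vals, space_tag = "unit", unit_ids = prof$unit_ids,
         undefined = prof$undefined, acf = prof, tr = prof$tr),
    class = "int_map"
  )

  if (exp_fit) {
    out$exp_timescale <- vapply(seq_len(nv), function(j) {
      if (prof$undefined[j]) return(NA_real_)
      n_pos <- prof$first_nonpositive_lag[j] - 1L
      if (n_pos < 2L) return(NA_real_)
      fit_acf_exponential(co[seq_len(n_pos), j], prof$tr)
    }, numeric(1))
  }
  out
}

# Least-squares fit of A*exp(-k*TR/tau) to positive ACF coefficients;
# tau initialized from a log-linear fit restricted to clearly positive
# coefficients (the noisy near-zero tail would otherwise dominate the slope).
fit_acf_exponential <- function(a, tr) {
  k <- seq_along(a)
  lead <- which(a > 0.05)
  if (length(lead) < 2L) lead <- seq_len(min(2L, length(a)))
  sl <- stats::coef(stats::lm(log(a[lead]) ~ lead))
  names(sl) <- c("(Intercept)", "k")
  tau0 <- if (is.na(sl["k"]) || sl["k"] >= 0) tr else max(tr * -1 / sl["k"], tr / 10)
  fit <- tryCatch(
    stats::nls(a ~ A * exp(-k * tr / tau),
               start = list(A = exp(unname(sl[1])), tau = unname(tau0)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(unname(tau0))
  unname(stats::coef(fit)[["tau"]])
}

#' Construct an INT map from plain values
#'
#' @param values Numeric vector of timescales (seconds), `NA` allowed.
#' @param unit_ids Identifiers, defaults to names of `values` or an index.
#' @param space_tag Free-form label, e.g. `"voxel"` or `"parcel"`.
#' @return An `int_map` object.
#' @export
int_map <- function(values, unit_ids = NULL, space_tag = "unit") {
  nm <- names(values)
  values <- as.numeric(values)
  if (is.null(unit_ids)) unit_ids <- nm
  if (is.null(unit_ids)) unit_ids <- as.character(seq_along(values))
  names(values) <- unit_ids
  if (any(values[is.finite(values)] < 0))
    stop("INT values must be non-negative")
  structure(list(values = values, space_tag = space_tag, unit_ids = unit_ids,
                 undefined = is.na(values)),
            class = "int_map")
}

#' @export
print.int_map <- function(x, ...) {
  ok <- x$values[is.finite(x$values)]
  cat("<int_map> ", length(x$values), " ", x$space_tag, "s; median ",
      signif(stats::median(ok), 4), " s [IQR ",
      signif(stats::IQR(ok), 3), "], ", sum(!is.finite(x$values)),
      " undefined\n", sep = "")
  invisible(x)
}

#' @export
summary.int_map <- function(object, ...) {
  c(summary(object$values), n_undefined = sum(!is.finite(object$values)))
}
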