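#' BOLD time-series container
#'
#' Bundles a timepoints-by-units signal matrix with its repetition time and a
#' per-timepoint censor mask. All timescale estimation in the package operates
#' on this container.
#'
#' @param data Numeric matrix (timepoints x units) or a numeric vector for a
#'   single unit. Arbitrary signal units.
#' @param tr Repetition time in seconds (> 0).
#' @param censor_mask Logical vector, one element per timepoint; `TRUE` marks a
#'   retained volume. Defaults to all retained.
#' @param unit_ids Optional character identifiers for the units (columns).
#'
#' @return An object of class `bold_ts` with elements `data`, `tr`,
#'   `censor_mask`, `unit_ids`.
#' @export
#' @examples
#' y <- bold_ts(matrix(rnorm(200), 100, 2), tr = 0.72)
#' y
bold_ts <- function(data, tr, censor_mask = NULL, unit_ids = NULL) {
  if (is.vector(data)) data <- matrix(as.numeric(data), ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  nt <- nrow(data)
  if (is.null(censor_mask)) censor_mask <- rep(TRUE, nt)
  censor_mask <- as.logical(censor_mask)
  if (length(censor_mask) != nt)
    stop("'censor_mask' length (", length(censor_mask),
         ") must equal the number of timepoints (", nt, ")")
  if (is.null(unit_ids)) {
    unit_ids <- colnames(data)
    if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(ncol(data)))
  }
  if (length(unit_ids) != ncol(data))
    stop("'unit_ids' must have one entry per column of 'data'")
  colnames(data) <- unit_ids
  structure(
    list(data = data, tr = tr, censor_mask = censor_mask, unit_ids = unit_ids),
    class = "bold_ts"
  )
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("<bold_ts> ", nrow(x$data), " timepoints x ", ncol(x$data),
      " units, TR = ", x$tr, " s, ", sum(x$censor_mask), " retained\n", sep = "")
  invisible(x)
}

n_retained <- function(x) sum(x$censor_mask)

#' Clean a BOLD time series for timescale estimation
#'
#' Applies, in order: nuisance regression of the supplied confound columns and
#' their first (backward-difference) derivatives, zero-phase band-pass
#' filtering, and head-motion censoring of every volume whose framewise
#' displacement exceeds `fd_threshold` together with the volumes immediately
#' preceding and following it. Filtering precedes censoring because the filter
#' needs contiguous samples; the censor mask only marks volumes for exclusion
#' from downstream autocorrelation sums.
#'
#' @param series A [bold_ts()] object.
#' @param confounds Numeric matrix of nuisance regressors (timepoints x q), or
#'   `NULL` for none. First derivatives are appended automatically unless
#'   `add_derivatives = FALSE`. The standard resting-state set includes
#'   white-matter, cerebrospinal-fluid and global-brain signals plus the six
#'   motion parameters; include the global signal here (the default cohort
#'   processing keeps it) or omit its column to skip global-signal
#'   regression.
#' @param band Length-2 numeric, band-pass edges in Hz (low, high); must satisfy
#'   0 < low < high < Nyquist. `NULL` skips filtering.
#' @param fd Framewise displacement per volume (mm), or `NULL` to skip
#'   censoring.
#' @param fd_threshold Censoring threshold in mm (default 0.3).
#' @param add_derivatives Append first derivatives of the confounds?
#' @param filter_order Butterworth filter order (applied forward-backward).
#'
#' @return A `bold_ts` with cleaned data and an updated censor mask; the number
#'   of retained volumes is reported in an attribute `n_retained`.
#' @export
clean_bold <- function(series, confounds = NULL, band = c(0.01, 0.1),
                       fd = NULL, fd_threshold = 0.3,
                       add_derivatives = TRUE, filter_order = 2L) {
  stopifnot(inherits(series, "bold_ts"))
  y <- series$data
  nt <- nrow(y)
  mask <- series$censor_mask

  q <- 0L
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop("confound matrix must have one row per timepoint")
    X <- confounds
    if (add_derivatives) {
      d <- rbind(0, diff(confounds))
      X <- cbind(X, d)
    }
    X <- cbind(1, X)
    q <- qr(X)$rank
    # project out confound subspace (least squares residual)
    fit <- qr(X)
    y <- y - X %*% qr.coef(fit, y)
    y[!is.finite(y)] <- 0
  } else {
    y <- sweep(y, 2L, colMeans(y), "-")
  }

  if (!is.null(band)) {
    fs <- 1 / series$tr
    nyq <- fs / 2
    if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq)
      stop("'band' must satisfy 0 < low < high < Nyquist (", signif(nyq, 4), " Hz)")
    bf <- signal::butter(filter_order, band / nyq, type = "pass")
    y <- apply(y, 2L, function(col) signal::filtfilt(bf, col))
  }

  if (!is.null(fd)) {
    if (length(fd) != nt) stop("'fd' must have one value per timepoint")
    bad <- which(fd > fd_threshold)
    if (length(bad)) {
      drop <- unique(c(bad - 1L, bad, bad + 1L))
      drop <- drop[drop >= 1L & drop <= nt]
      mask[drop] <- FALSE
    }
  }

  kept <- sum(mask)
  if (kept < q + 8L)
    stop("insufficient degrees of freedom: ", kept,
         " retained timepoints for ", q, " confound regressors")
  out <- bold_ts(y, tr = series$tr, censor_mask = mask, unit_ids = series$unit_ids)
  attr(out, "n_retained") <- kept
  out
}
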