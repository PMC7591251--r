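#' Parcellation scheme
#'
#' Maps units (voxels or vertices) to named parcels, optionally with
#' left/right hemisphere pairing so paired parcels can be averaged into a
#' single value, as done for the 188-parcel scheme (180 cortical + 8
#' subcortical) used throughout the package.
#'
#' @param labels Integer vector (one label per unit; 0 or `NA` = background)
#'   or a character vector of parcel names per unit.
#' @param parcel_names Optional named character vector translating integer
#'   labels to parcel names.
#' @param hemisphere_pairs Optional 2-column character matrix or data.frame
#'   (`left`, `right`) of paired parcel names; each paired parcel must appear
#'   exactly once.
#' @return An object of class `parcel_scheme`.
#' @export
parcel_scheme <- function(labels, parcel_names = NULL, hemisphere_pairs = NULL) {
  if (is.numeric(labels)) {
    lab <- as.integer(labels)
    lab[lab == 0L] <- NA_integer_
    if (!is.null(parcel_names)) {
      nm <- parcel_names[as.character(lab)]
    } else {
      nm <- ifelse(is.na(lab), NA_character_, paste0("parcel", lab))
    }
  } else {
    nm <- as.character(labels)
  }
  if (!is.null(hemisphere_pairs)) {
    hp <- as.data.frame(hemisphere_pairs, stringsAsFactors = FALSE)
    names(hp) <- c("left", "right")
    all_p <- c(hp$left, hp$right)
    if (anyDuplicated(all_p))
      stop("each paired parcel must appear exactly once in 'hemisphere_pairs'")
    hemisphere_pairs <- hp
  }
  structure(list(unit_parcel = nm, hemisphere_pairs = hemisphere_pairs),
            class = "parcel_scheme")
}

#' @export
print.parcel_scheme <- function(x, ...) {
  cat("<parcel_scheme> ", length(x$unit_parcel), " units, ",
      length(unique(stats::na.omit(x$unit_parcel))), " parcels",
      if (!is.null(x$hemisphere_pairs))
        paste0(", ", nrow(x$hemisphere_pairs), " hemisphere pairs"),
      "\n", sep = "")
  invisible(x)
}

#' Aggregate a unit-level INT map to parcels
#'
#' Parcel value = unweighted arithmetic mean of its member units, missing
#' units excluded. An empty parcel (or one with only missing members) yields
#' `NA` with a warning, never 0. With `hemi_average = TRUE`, each left/right
#' pair in the scheme is averaged into one value named after the left parcel
#' stripped of any `L_`/`R_`-style prefix when present.
#'
#' @param map An [int_map()] (or any object with `values` per unit).
#' @param scheme A [parcel_scheme()]; `unit_parcel` must be as long as
#'   `map$values`.
#' @param hemi_average Average paired parcels across hemispheres?
#' @return An `int_map` in parcel space.
#' @export
parcellate_map <- function(map, scheme, hemi_average = FALSE) {
  stopifnot(inherits(scheme, "parcel_scheme"))
  v <- map$values
  if (length(v) != length(scheme$unit_parcel))
    stop("map has ", length(v), " units but scheme describes ",
         length(scheme$unit_parcel))
  grp <- scheme$unit_parcel
  keep <- !is.na(grp)
  means <- tapply(v[keep], grp[keep], mean, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  parcels <- unique(stats::na.omit(grp))
  out <- means[parcels]
  names(out) <- parcels
  if (anyNA(out))
    warning("empty or all-missing parcels: ",
            paste(parcels[is.na(out)], collapse = ", "))

  if (hemi_average) {
    hp <- scheme$hemisphere_pairs
    if (is.null(hp)) stop("scheme has no hemisphere pairs")
    paired <- (out[hp$left] + out[hp$right]) / 2
    pname <- sub("^[LR]_", "", hp$left)
    rest <- setdiff(parcels, c(hp$left, hp$right))
    out <- c(stats::setNames(as.numeric(paired), pname), out[rest])
  }
  int_map(as.numeric(out), unit_ids = names(out), space_tag = "parcel")
}

#' Test-retest reliability of stacked INT maps via ICC(2,1)
#'
#' Computes the two-way random-effects, single-measure intraclass correlation
#' (Shrout-Fleiss ICC(2,1)) per unit across the subject dimension of two
#' stacked maps (e.g. split-half INT estimates), plus the median and
#' interquartile range across units.
#'
#' @param map_a,map_b Numeric matrices, subjects x units, identically shaped
#'   and with matching unit order.
#' @return List with `icc` (per unit; `NA` and flagged where between-subject
#'   variance is zero), `median`, `iqr`, `flagged`.
#' @export
icc_reliability <- function(map_a, map_b) {
  map_a <- as.matrix(map_a); map_b <- as.matrix(map_b)
  if (!all(dim(map_a) == dim(map_b)))
    stop("maps must have identical subject x unit dimensions")
  n <- nrow(map_a)
  if (n < 2L) stop("need at least 2 subjects")
  icc <- vapply(seq_len(ncol(map_a)), function(j)
    icc21(cbind(map_a[, j], map_b[, j])), numeric(1))
  flagged <- !is.finite(icc)
  list(icc = icc, median = stats::median(icc[!flagged]),
       iqr = stats::IQR(icc[!flagged]), flagged = flagged)
}

# Shrout & Fleiss two-way random, single score ICC from ANOVA mean squares.
icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  msr <- k * sum((row_m - g)^2) / (n - 1)              # between subjects
  msc <- n * sum((col_m - g)^2) / (k - 1)              # between measurements
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= .Machine$double.eps && mse <= .Machine$double.eps) return(NA_real_)
  if (denom <= 0) return(NA_real_)
  (msr - mse) / denom
}
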