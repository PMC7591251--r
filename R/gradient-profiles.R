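#' Fitted INT profiles for exemplary symptom cases
#'
#' Uses the parcel-wise regression coefficients (patients-only symptom model)
#' to predict INT at each level of a hierarchy for four exemplary symptom
#' profiles: (hallucinations, delusions) scores of (0,0), (5,0), (0,5) and
#' (5,5), with all other symptoms and covariates fixed at the patient-sample
#' means (site dummies at their sample proportions). Delta-INT is reported for
#' cases 2-4 relative to the (0,0) case; by linearity of the model the (5,5)
#' delta equals the sum of the single-symptom deltas.
#'
#' @param m1 A [fit_parcelwise_glm()] result with design `"M1_primary"` whose
#'   parcels cover the hierarchy.
#' @param hierarchy A 9-level [hierarchy_ordering()].
#' @return Object of class `exemplary_profile`: `fitted` (levels x 4 cases,
#'   seconds), `delta` (levels x 4, case minus the no-symptom case), `levels`,
#'   `parcels`.
#' @export
exemplary_profiles <- function(m1, hierarchy) {
  stopifnot(inherits(m1, "parcel_effects"))
  if (m1$design != "M1_primary")
    stop("exemplary profiles require the patients-only symptom model")
  a <- hierarchy$assignment
  parcels <- names(sort(a))
  miss <- setdiff(parcels, colnames(m1$coefficients))
  if (length(miss))
    stop("coefficients missing for parcels: ", paste(miss, collapse = ", "))

  x0 <- colMeans(m1$X)             # patient-sample means of every predictor
  cases <- list(none = c(0, 0), hallucinations_only = c(5, 0),
                delusions_only = c(0, 5), both = c(5, 5))
  fitted <- sapply(cases, function(hd) {
    x <- x0
    x["hallucinations"] <- hd[1]
    x["delusions"] <- hd[2]
    drop(x %*% m1$coefficients[, parcels])
  })
  rownames(fitted) <- parcels
  delta <- fitted - fitted[, "none"]
  structure(list(fitted = fitted, delta = delta,
                 levels = sort(a), parcels = parcels),
            class = "exemplary_profile")
}

#' @export
print.exemplary_profile <- function(x, ...) {
  cat("<exemplary_profile> delta-INT (s) by level:\n")
  out <- cbind(level = x$levels, round(x$delta, 4))
  print(out)
  invisible(x)
}

#' Rank-binned, anatomy-agnostic hierarchy control
#'
#' Ranks voxels by a reference INT map, splits them into `n_bins` equally
#' sized bins along the ranking (bin size `floor(V / n_bins)`; any remainder
#' goes to the last bin with a warning), averages the voxel-wise symptom
#' t-statistics per bin, and fits the hierarchical-gradient model using the
#' bin index as hierarchical level (single-system variant).
#'
#' @param voxel_effects Numeric matrix voxels x symptoms of t-statistics (or a
#'   vector for one symptom); column names name the symptoms.
#' @param reference_int Numeric vector of reference INT values, one per voxel.
#' @param n_bins Number of bins (default 10).
#' @return List of class `rank_binned_profile`: `bin_means` (n_bins x
#'   symptoms), `bin_size`, `gradient` (a [fit_gradient_glm()]-style
#'   `gradient_fit` over bins; `NULL` when only one symptom and a plain slope
#'   is reported instead), `slopes` (per-symptom OLS slope of bin mean on bin
#'   index).
#' @export
rank_binned_profile <- function(voxel_effects, reference_int, n_bins = 10) {
  if (is.vector(voxel_effects))
    voxel_effects <- matrix(voxel_effects, ncol = 1L,
                            dimnames = list(NULL, "effect"))
  voxel_effects <- as.matrix(voxel_effects)
  v <- nrow(voxel_effects)
  if (length(reference_int) != v)
    stop("'reference_int' must have one value per voxel")
  if (n_bins > v) stop("more bins than voxels")
  size <- v %/% n_bins
  if (v %% n_bins != 0L)
    warning(v %% n_bins, " leftover voxels assigned to the last bin")
  ord <- order(reference_int)
  bin <- rep(n_bins, v)
  bin[seq_len(size * n_bins)] <- rep(seq_len(n_bins), each = size)
  bin_of_voxel <- integer(v)
  bin_of_voxel[ord] <- bin

  bin_means <- apply(voxel_effects, 2L, function(tv)
    tapply(tv, bin_of_voxel, mean))
  bin_means <- matrix(bin_means, nrow = n_bins,
                      dimnames = list(NULL, colnames(voxel_effects)))

  slopes <- apply(bin_means, 2L, function(m)
    stats::coef(stats::lm(m ~ seq_len(n_bins)))[2L])

  gradient <- NULL
  if (ncol(bin_means) >= 2L) {
    # Assemble a synthetic effects table so the standard gradient model can
    # run with bin index as level in a single pseudo-system.
    symptoms <- colnames(bin_means)[1:2]
    tstats <- t(bin_means[, symptoms, drop = FALSE])
    colnames(tstats) <- paste0("bin", seq_len(n_bins))
    eff <- structure(list(tstats = tstats, design = "M1_primary"),
                     class = "parcel_effects")
    h <- hierarchy_ordering(
      stats::setNames(seq_len(n_bins), colnames(tstats)), "custom")
    gradient <- fit_gradient_glm(eff, list(binned = h), symptoms = symptoms)
  }
  structure(list(bin_means = bin_means, bin_size = size, slopes = slopes,
                 gradient = gradient, n_bins = n_bins),
            class = "rank_binned_profile")
}

#' @export
print.rank_binned_profile <- function(x, ...) {
  cat("<rank_binned_profile> ", x$n_bins, " bins of ", x$bin_size,
      " voxels\n", sep = "")
  print(round(x$bin_means, 3))
  invisible(x)
}

#' Winning extended sensory hierarchies
#'
#' The 9-level dorsal-stream hierarchies selected by the structural
#' model-comparison procedure (area 46 highest in all three systems), plus
#' the ventral-auditory variant (area 12vl highest). These are the orderings
#' used by the symptom-gradient analyses.
#'
#' @param systems Which systems to return.
#' @return Named list of [hierarchy_ordering()] objects.
#' @export
winning_hierarchies <- function(systems = c("auditory", "visual",
                                            "somatosensory")) {
  all <- list(
    auditory = hierarchy_ordering(c(
      A1 = 1, LBelt = 2, MBelt = 3, PBelt = 4, RI = 5, A4 = 6, A5 = 7,
      `8a` = 8, `46` = 9), "auditory"),
    visual = hierarchy_ordering(c(
      V1 = 1, V2 = 2, V3 = 3, MT = 4, V4 = 5, V6 = 6, V7 = 7,
      `8a` = 8, `46` = 9), "visual"),
    somatosensory = hierarchy_ordering(c(
      `3b` = 1, `3a` = 2, `1` = 3, `2` = 4, `5m` = 5, `7b` = 6, `7a` = 7,
      `8a` = 8, `46` = 9), "somatosensory"),
    auditory_ventral = hierarchy_ordering(c(
      A1 = 1, LBelt = 2, MBelt = 3, PBelt = 4, RI = 5, A4 = 6, A5 = 7,
      `10` = 8, `12vl` = 9), "auditory_ventral")
  )
  all[systems]
}
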