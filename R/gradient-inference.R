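# Internal: refit M1 (patients only) with a permuted or resampled design and
# return the t-statistics for the parcels M2 needs.
m1_tstats <- function(X, Y) {
  fit <- ols_fit(X, Y)
  fit$t
}

needed_parcels <- function(hierarchies) {
  unique(unlist(lapply(hierarchies, function(h) names(h$assignment))))
}

#' Joint permutation test for hierarchical-gradient effects
#'
#' Generates surrogate datasets in which the rows of the seven-symptom block
#' are jointly permuted across patients (covariates and INT stay in place, so
#' every surrogate preserves the inter-symptom correlation matrix exactly),
#' refits the parcel-wise symptom regression and the hierarchical-gradient
#' model for each surrogate, and returns two-sided add-one permutation
#' p-values, `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)`, for the derived
#' gradient effects. All null draws are retained for set-level testing.
#'
#' @param int_matrix Subjects x parcels INT matrix aligned with `cohort`.
#' @param cohort A [cohort_table()].
#' @param hierarchies Named list of 9-level [hierarchy_ordering()] objects.
#' @param terms Effects to report p-values for (default: all derived effects).
#' @param n_perm Number of surrogates (>= 100 recommended).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param symptoms Focal symptoms passed to [fit_gradient_glm()].
#' @param permutations Optional explicit permutation matrix (n_perm x
#'   n_patients) for exhaustive enumeration on toy problems.
#' @return Object of class `gradient_perm`: `p` (named), `observed` (derived
#'   effect t values), `null` (n_perm x effects matrix), `n_perm`, `m2`.
#' @export
permutation_null_gradient <- function(int_matrix, cohort, hierarchies,
                                      terms = NULL, n_perm = 1000, seed = 1,
                                      symptoms = c("hallucinations", "delusions"),
                                      permutations = NULL) {
  int_matrix <- as.matrix(int_matrix)
  m1 <- fit_parcelwise_glm(int_matrix[, needed_parcels(hierarchies),
                                      drop = FALSE], cohort, "M1_primary")
  m2 <- fit_gradient_glm(m1, hierarchies, symptoms = symptoms)
  observed <- stats::setNames(m2$effects$t, rownames(m2$effects))

  X <- m1$X
  sym_cols <- match(symptom_items(), colnames(X))
  n_pat <- nrow(X)
  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(replicate(n_perm, sample.int(n_pat)))
  }
  n_perm <- nrow(permutations)

  null <- matrix(NA_real_, n_perm, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[, sym_cols] <- X[permutations[b, ], sym_cols]
    tstats <- m1_tstats(Xp, m1$Y)
    null[b, ] <- refit_gradient_effects(m2, tstats)
  }

  if (is.null(terms)) terms <- names(observed)
  unknown <- setdiff(terms, names(observed))
  if (length(unknown)) stop("unknown terms: ", paste(unknown, collapse = ", "))
  p <- vapply(terms, function(tm)
    (1 + sum(abs(null[, tm]) >= abs(observed[tm]) - 1e-12)) / (n_perm + 1),
    numeric(1))
  structure(list(p = p, observed = observed, null = null, n_perm = n_perm,
                 m2 = m2, m1 = m1),
            class = "gradient_perm")
}

#' @export
print.gradient_perm <- function(x, ...) {
  cat("<gradient_perm> ", x$n_perm, " surrogates\n", sep = "")
  print(data.frame(t = signif(x$observed[names(x$p)], 4),
                   p_permutation = signif(x$p, 4)))
  invisible(x)
}

#' Set-level permutation test over a family of gradient effects
#'
#' Estimates the probability of spuriously obtaining an observed *set* of
#' significant effects. Within each surrogate of a [permutation_null_gradient()]
#' run, an effect counts as significant when it exceeds the two-sided 95%
#' plug-in threshold of its own null distribution (its 2.5th/97.5th null
#' percentiles) with the expected sign; the predicate is a conjunction of
#' clauses of the form "effect present with given sign in at least k of m
#' listed effects". The set-level p-value is the add-one fraction of
#' surrogates satisfying the full predicate.
#'
#' @param perm A `gradient_perm` object.
#' @param predicate List of clauses; each clause is a list with `terms`
#'   (character, m effect names), `sign` (+1 or -1), and `k` (minimum count).
#' @param alpha Two-sided plug-in threshold level (default 0.05).
#' @return List: `p` (set-level), `observed_satisfied` (does the observed data
#'   satisfy the predicate), per-clause observed counts.
#' @export
set_level_test <- function(perm, predicate, alpha = 0.05) {
  stopifnot(inherits(perm, "gradient_perm"))
  null <- perm$null
  all_terms <- colnames(null)
  for (cl in predicate) {
    unknown <- setdiff(cl$terms, all_terms)
    if (length(unknown))
      stop("predicate references unknown terms: ",
           paste(unknown, collapse = ", "))
  }
  lo <- apply(null, 2L, stats::quantile, probs = alpha / 2)
  hi <- apply(null, 2L, stats::quantile, probs = 1 - alpha / 2)

  satisfies <- function(vals) {
    all(vapply(predicate, function(cl) {
      v <- vals[cl$terms]
      ok <- if (cl$sign > 0) v > hi[cl$terms] else v < lo[cl$terms]
      sum(ok) >= cl$k
    }, logical(1)))
  }
  n_sat <- sum(apply(null, 1L, satisfies))
  counts <- vapply(predicate, function(cl) {
    v <- perm$observed[cl$terms]
    ok <- if (cl$sign > 0) v > hi[cl$terms] else v < lo[cl$terms]
    sum(ok)
  }, numeric(1))
  list(p = (1 + n_sat) / (nrow(null) + 1),
       observed_satisfied = satisfies(perm$observed),
       observed_counts = counts)
}

#' Accelerated bias-corrected (BCa) bootstrap intervals for gradient effects
#'
#' Resamples patients with replacement, refits the parcel-wise symptom
#' regression and the hierarchical-gradient model per draw, and forms
#' two-sided 95% BCa intervals for the derived gradient effects (on the
#' t-statistic scale, matching how the effects are reported). The bias
#' correction z0 comes from the bootstrap CDF at the observed value; the
#' acceleration a from the jackknife-over-patients skewness.
#'
#' @inheritParams permutation_null_gradient
#' @param n_boot Number of bootstrap draws (>= 200).
#' @param level Confidence level (default 0.95).
#' @return Object of class `gradient_bca`: data.frame with `lower`, `upper`,
#'   `z0`, `accel` per effect, plus `observed`, `n_boot`, `flags` (draws where
#'   a site level vanished and its dummy was dropped; degenerate effects whose
#'   bootstrap distribution collapsed).
#' @export
bca_ci <- function(int_matrix, cohort, hierarchies, terms = NULL,
                   n_boot = 1000, seed = 1, level = 0.95,
                   symptoms = c("hallucinations", "delusions")) {
  if (n_boot < 200) stop("'n_boot' must be at least 200")
  int_matrix <- as.matrix(int_matrix)
  parc <- needed_parcels(hierarchies)
  m1 <- fit_parcelwise_glm(int_matrix[, parc, drop = FALSE], cohort, "M1_primary")
  m2 <- fit_gradient_glm(m1, hierarchies, symptoms = symptoms)
  observed <- stats::setNames(m2$effects$t, rownames(m2$effects))
  if (is.null(terms)) terms <- names(observed)

  X <- m1$X; Y <- m1$Y
  n_pat <- nrow(X)
  site_cols <- grep("^site", colnames(X))

  eval_draw <- function(idx) {
    Xb <- X[idx, , drop = FALSE]
    keep <- seq_len(ncol(Xb))
    dropped_site <- FALSE
    if (length(site_cols)) {
      const <- site_cols[apply(Xb[, site_cols, drop = FALSE], 2L,
                               function(v) length(unique(v)) == 1L)]
      if (length(const)) { keep <- setdiff(keep, const); dropped_site <- TRUE }
    }
    tstats <- m1_tstats(Xb[, keep, drop = FALSE], Y[idx, , drop = FALSE])
    list(t = refit_gradient_effects(m2, tstats), dropped = dropped_site)
  }

  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(observed),
                  dimnames = list(NULL, names(observed)))
  dropped <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    r <- eval_draw(sample.int(n_pat, replace = TRUE))
    draws[b, ] <- r$t
    dropped[b] <- r$dropped
  }

  jack <- matrix(NA_real_, n_pat, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (i in seq_len(n_pat)) jack[i, ] <- eval_draw(setdiff(seq_len(n_pat), i))$t

  res <- do.call(rbind, lapply(terms, function(tm) {
    ci <- bca_interval(draws[, tm], observed[tm], jack[, tm], level = level)
    data.frame(term = tm, lower = ci$lower, upper = ci$upper, z0 = ci$z0,
               accel = ci$accel, degenerate = ci$degenerate)
  }))
  rownames(res) <- res$term
  structure(list(intervals = res, observed = observed[terms],
                 draws = draws, n_boot = n_boot,
                 flags = list(site_dummy_dropped = which(dropped),
                              degenerate = res$term[res$degenerate])),
            class = "gradient_bca")
}

#' @export
print.gradient_bca <- function(x, ...) {
  cat("<gradient_bca> ", x$n_boot, " bootstrap draws\n", sep = "")
  out <- cbind(t = signif(x$observed, 4),
               x$intervals[names(x$observed), c("lower", "upper")])
  print(signif(out, 4))
  if (length(x$flags$site_dummy_dropped))
    cat(length(x$flags$site_dummy_dropped),
        " draws lost a site level (dummy dropped)\n")
  invisible(x)
}

#' Accelerated bias-corrected bootstrap interval from draws
#'
#' The BCa core used by [bca_ci()], exposed for any statistic: the bias
#' correction `z0` is the normal quantile of the bootstrap CDF at the
#' observed value (ties split), the acceleration `a` is the jackknife
#' skewness `sum(d^3) / (6 * sum(d^2)^1.5)` with `d` the deviations of the
#' jackknife values from their mean, and the interval endpoints are the
#' bootstrap quantiles at the BCa-adjusted probabilities.
#'
#' @param draws Bootstrap replicates of the statistic.
#' @param observed Observed (full-sample) statistic.
#' @param jackknife Leave-one-out statistics; `NULL` sets the acceleration
#'   to zero (plain bias-corrected interval).
#' @param level Confidence level (default 0.95).
#' @return List: `lower`, `upper`, `z0`, `accel`, `degenerate` (`TRUE` when
#'   the bootstrap distribution has collapsed to a point, in which case the
#'   interval collapses to the observed value).
#' @export
bca_interval <- function(draws, observed, jackknife = NULL, level = 0.95) {
  if (stats::sd(draws) < .Machine$double.eps^0.5)
    return(list(lower = unname(observed), upper = unname(observed),
                z0 = 0, accel = 0, degenerate = TRUE))
  z0 <- stats::qnorm(mean(draws < observed) + 0.5 * mean(draws == observed))
  accel <- 0
  if (!is.null(jackknife)) {
    d <- mean(jackknife) - jackknife
    if (sum(d^2) > 0) accel <- sum(d^3) / (6 * sum(d^2)^1.5)
  }
  alpha <- (1 - level) / 2
  zs <- stats::qnorm(c(alpha, 1 - alpha))
  probs <- stats::pnorm(z0 + (z0 + zs) / (1 - accel * (z0 + zs)))
  ci <- stats::quantile(draws, probs, names = FALSE, type = 6)
  list(lower = ci[1], upper = ci[2], z0 = z0, accel = accel,
       degenerate = FALSE)
}

#' Overall parcel-count permutation test for a diagnosis effect
#'
#' Paper-style "overall effect" test for the exploratory diagnosis analysis:
#' the statistic is the number of parcels whose diagnosis |t| exceeds the
#' two-sided Student threshold; the null permutes the diagnosis labels across
#' subjects.
#'
#' @param int_matrix Subjects x parcels INT matrix.
#' @param cohort A [cohort_table()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alpha Parcel-level two-sided threshold (default 0.05).
#' @return List: `n_significant`, `n_parcels`, `p`, `tstats` (diagnosis t per
#'   parcel), `null` (counts).
#' @export
diagnosis_overall_test <- function(int_matrix, cohort, n_perm = 1000, seed = 1,
                                   alpha = 0.05) {
  int_matrix <- as.matrix(int_matrix)
  m1 <- fit_parcelwise_glm(int_matrix, cohort, "M1_exploratory")
  tcrit <- stats::qt(1 - alpha / 2, m1$df)
  tobs <- m1$tstats["diagnosis", ]
  n_sig <- sum(abs(tobs) > tcrit)
  X <- m1$X
  dcol <- match("diagnosis", colnames(X))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    Xp <- X
    Xp[, dcol] <- X[sample.int(nrow(X)), dcol]
    sum(abs(m1_tstats(Xp, m1$Y)["diagnosis", ]) > tcrit)
  }, numeric(1))
  list(n_significant = n_sig, n_parcels = ncol(int_matrix),
       p = (1 + sum(null >= n_sig)) / (n_perm + 1),
       tstats = tobs, null = null)
}
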