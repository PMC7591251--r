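#' Hierarchical ordering of a sensory system
#'
#' A mapping from parcel names to integer hierarchical levels `1..L`
#' (`L` = 7 for sensory-cortex orderings, 9 once the two prefrontal regions
#' are appended).
#'
#' @param assignment Named integer vector, parcel -> level; levels must be a
#'   permutation of `1..L`.
#' @param system_tag One of `"auditory"`, `"visual"`, `"somatosensory"`,
#'   `"auditory_ventral"`, `"custom"`.
#' @return Object of class `hierarchy_ordering`.
#' @export
hierarchy_ordering <- function(assignment, system_tag = "custom") {
  lv <- as.integer(assignment)
  names(lv) <- names(assignment)
  L <- length(lv)
  if (is.null(names(lv)) || any(!nzchar(names(lv))))
    stop("'assignment' must be a named vector (parcel -> level)")
  if (!setequal(lv, seq_len(L)))
    stop("levels must be a permutation of 1..", L)
  structure(list(assignment = lv, system_tag = system_tag),
            class = "hierarchy_ordering")
}

#' @export
print.hierarchy_ordering <- function(x, ...) {
  o <- names(sort(x$assignment))
  cat("<hierarchy_ordering> [", x$system_tag, "] ",
      paste(o, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Constraint tables for the candidate orderings considered per system.
# Fixed positions plus swap pairs: each swap pair may occupy its two levels in
# either order, giving 2 x 2 = 4 sensory candidates per system.
hierarchy_constraints <- function(system) {
  switch(system,
    auditory = ,
    auditory_ventral = list(
      fixed = c(A1 = 1L, A4 = 6L, A5 = 7L),
      swaps = list(list(parcels = c("LBelt", "MBelt"), levels = c(2L, 3L)),
                   list(parcels = c("PBelt", "RI"),   levels = c(4L, 5L)))),
    visual = list(
      fixed = c(V1 = 1L, V2 = 2L, V3 = 3L),
      swaps = list(list(parcels = c("V4", "MT"), levels = c(4L, 5L)),
                   list(parcels = c("V6", "V7"), levels = c(6L, 7L)))),
    somatosensory = list(
      fixed = c("5m" = 5L, "7b" = 6L, "7a" = 7L),
      swaps = list(list(parcels = c("3b", "3a"), levels = c(1L, 2L)),
                   list(parcels = c("1", "2"),   levels = c(3L, 4L)))),
    stop("unknown system '", system, "'; valid tags: ",
         "auditory, visual, somatosensory, auditory_ventral")
  )
}

# Downstream prefrontal regions appended at levels 8/9. The dorsal streams use
# areas 8a and 46; the ventral auditory stream uses areas 10 and 12vl.
pfc_regions <- function(system) {
  if (identical(system, "auditory_ventral")) c("10", "12vl") else c("8a", "46")
}

#' Enumerate candidate sensory-cortex orderings for a system
#'
#' Each system has fixed anchor regions and two swap pairs whose members may
#' occupy their two levels in either order, giving exactly four candidates,
#' enumerated in a canonical deterministic order.
#'
#' @param system System tag (see [hierarchy_ordering()]).
#' @return List of four `hierarchy_ordering` objects (7 levels each).
#' @export
candidate_orderings <- function(system) {
  con <- hierarchy_constraints(system)
  out <- list()
  for (s1 in 1:2) for (s2 in 1:2) {
    a <- con$fixed
    p1 <- con$swaps[[1]]; p2 <- con$swaps[[2]]
    o1 <- if (s1 == 1) p1$parcels else rev(p1$parcels)
    o2 <- if (s2 == 1) p2$parcels else rev(p2$parcels)
    a[o1] <- p1$levels
    a[o2] <- p2$levels
    out[[length(out) + 1L]] <- hierarchy_ordering(a[order(a)], system)
  }
  out
}

#' Enumerate prefrontal extensions of a winning sensory ordering
#'
#' Appends the system's two downstream prefrontal regions at levels 8 and 9 in
#' either order, giving exactly two extended candidates.
#'
#' @param winner A 7-level `hierarchy_ordering`.
#' @param system System tag.
#' @return List of two 9-level `hierarchy_ordering` objects.
#' @export
pfc_extended_orderings <- function(winner, system = winner$system_tag) {
  pfc <- pfc_regions(system)
  lapply(1:2, function(i) {
    ext <- if (i == 1) pfc else rev(pfc)
    a <- c(winner$assignment, stats::setNames(c(8L, 9L), ext))
    hierarchy_ordering(a, system)
  })
}

#' Structural MRI cohort (myelin proxy + cortical thickness)
#'
#' @param t1w_t2w Subjects x parcels matrix of T1w/T2w ratio values.
#' @param thickness Subjects x parcels matrix of cortical thickness (mm),
#'   same shape and dimnames.
#' @return Object of class `structural_cohort`.
#' @export
structural_cohort <- function(t1w_t2w, thickness) {
  t1w_t2w <- as.matrix(t1w_t2w); thickness <- as.matrix(thickness)
  if (!all(dim(t1w_t2w) == dim(thickness)))
    stop("'t1w_t2w' and 'thickness' must have identical dimensions")
  if (is.null(colnames(t1w_t2w))) stop("parcel names (colnames) are required")
  if (is.null(rownames(t1w_t2w)))
    rownames(t1w_t2w) <- rownames(thickness) <- paste0("sub", seq_len(nrow(t1w_t2w)))
  if (any(colSums(is.finite(t1w_t2w)) == 0))
    stop("entirely-missing parcel in 't1w_t2w'")
  structure(list(t1w_t2w = t1w_t2w, thickness = thickness,
                 subject_ids = rownames(t1w_t2w),
                 parcel_ids = colnames(t1w_t2w)),
            class = "structural_cohort")
}

cohort_long <- function(cohort, parcels) {
  miss <- setdiff(parcels, cohort$parcel_ids)
  if (length(miss))
    stop("parcels absent from cohort: ", paste(miss, collapse = ", "))
  ns <- length(cohort$subject_ids)
  data.frame(
    subject = factor(rep(cohort$subject_ids, times = length(parcels))),
    parcel = rep(parcels, each = ns),
    t1w_t2w = as.vector(cohort$t1w_t2w[, parcels]),
    thickness = as.vector(cohort$thickness[, parcels])
  )
}

#' Goodness of fit of a hierarchical ordering to structural maps
#'
#' Fits a linear mixed model predicting hierarchical level from T1w/T2w and
#' cortical thickness with a per-subject random intercept and random slopes
#' for both predictors (independent/diagonal random-effects covariance), and
#' scores the ordering by the squared correlation between the observed levels
#' and the model predictions. By default predictions include the random
#' effects (conditional R^2); `r2 = "marginal"` uses fixed effects only. The
#' `engine = "fixed"` switch replaces the mixed model by ordinary least
#' squares, which is used for large permutation ensembles.
#'
#' @param ordering A [hierarchy_ordering()].
#' @param cohort A [structural_cohort()]; must contain the ordering's parcels
#'   and at least two subjects.
#' @param engine `"mixed"` (lme4) or `"fixed"` (OLS).
#' @param r2 `"conditional"` or `"marginal"`.
#' @return Object of class `ordering_fit`: `r_squared`, `ordering`,
#'   `converged`, `engine`.
#' @export
score_ordering <- function(ordering, cohort,
                           engine = c("mixed", "fixed"),
                           r2 = c("conditional", "marginal")) {
  engine <- match.arg(engine); r2 <- match.arg(r2)
  stopifnot(inherits(ordering, "hierarchy_ordering"))
  if (length(cohort$subject_ids) < 2L) stop("need at least 2 subjects")
  df <- cohort_long(cohort, names(ordering$assignment))
  df$level <- as.numeric(ordering$assignment[df$parcel])
  converged <- TRUE

  if (engine == "fixed") {
    fit <- stats::lm(level ~ t1w_t2w + thickness, data = df)
    pred <- stats::fitted(fit)
  } else {
    fit <- withCallingHandlers(
      tryCatch(
        lme4::lmer(level ~ t1w_t2w + thickness +
                     (1 + t1w_t2w + thickness || subject),
                   data = df, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
        error = function(e) NULL),
      warning = function(w) {converged <<- FALSE; invokeRestart("muffleWarning")})
    if (is.null(fit) || !converged) {
      converged <- FALSE
      fit <- suppressWarnings(
        lme4::lmer(level ~ t1w_t2w + thickness + (1 | subject),
                   data = df, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")))
    }
    pred <- stats::predict(fit,
                           re.form = if (r2 == "marginal") NA else NULL)
  }
  rsq <- suppressWarnings(stats::cor(df$level, pred)^2)
  if (!is.finite(rsq)) rsq <- 0
  structure(list(r_squared = rsq, ordering = ordering, converged = converged,
                 engine = engine),
            class = "ordering_fit")
}

#' @export
print.ordering_fit <- function(x, ...) {
  cat("<ordering_fit> R^2 = ", signif(x$r_squared, 4),
      if (!x$converged) " (fallback fit: no random slopes)", "\n", sep = "")
  print(x$ordering)
  invisible(x)
}

#' Data-driven selection of a system's hierarchical ordering
#'
#' Enumerates the four anatomically plausible sensory-cortex orderings of the
#' system, selects the one whose levels are best predicted by the structural
#' maps (maximum R^2), then enumerates the two prefrontal extensions of the
#' winner (levels 8/9) and selects again. Exact ties are broken by canonical
#' enumeration order with a warning.
#'
#' @inheritParams score_ordering
#' @param system System tag (see [hierarchy_ordering()]).
#' @return Object of class `hierarchy_selection`: `winner` (9-level
#'   `hierarchy_ordering`), `sensory_fits`, `extended_fits`.
#' @export
select_hierarchy <- function(system, cohort, engine = c("mixed", "fixed"),
                             r2 = c("conditional", "marginal")) {
  engine <- match.arg(engine); r2 <- match.arg(r2)
  cands <- candidate_orderings(system)
  fits <- lapply(cands, score_ordering, cohort = cohort, engine = engine, r2 = r2)
  r <- vapply(fits, `[[`, numeric(1), "r_squared")
  if (sum(r == max(r)) > 1L)
    warning("tied orderings at R^2 = ", signif(max(r), 6),
            "; keeping the first in canonical order")
  best <- which.max(r)
  ext <- pfc_extended_orderings(cands[[best]], system)
  efits <- lapply(ext, score_ordering, cohort = cohort, engine = engine, r2 = r2)
  er <- vapply(efits, `[[`, numeric(1), "r_squared")
  if (sum(er == max(er)) > 1L)
    warning("tied prefrontal extensions; keeping the first in canonical order")
  structure(list(winner = ext[[which.max(er)]],
                 winner_fit = efits[[which.max(er)]],
                 sensory_fits = fits, extended_fits = efits),
            class = "hierarchy_selection")
}

#' @export
print.hierarchy_selection <- function(x, ...) {
  cat("<hierarchy_selection>\n  sensory R^2: ",
      paste(signif(vapply(x$sensory_fits, `[[`, numeric(1), "r_squared"), 3),
            collapse = ", "),
      "\n  extended R^2: ",
      paste(signif(vapply(x$extended_fits, `[[`, numeric(1), "r_squared"), 3),
            collapse = ", "), "\n  winner: ", sep = "")
  print(x$winner)
  invisible(x)
}

#' Permutation null for an ordering's goodness of fit
#'
#' Re-scores the cohort under `n_perm` random assignments of the levels
#' `1..L` to the ordering's regions (full permutations over all regions) and
#' returns the one-sided add-one permutation p-value
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param cohort A [structural_cohort()].
#' @param winner_fit An [score_ordering()] result for the observed ordering.
#' @param n_perm Number of permutations (>= 100 recommended; smaller values
#'   are accepted for exhaustive toy enumerations).
#' @param seed Integer seed.
#' @param permutations Optional matrix (n_perm x L) of explicit level
#'   assignments, for exhaustive enumeration; overrides random sampling.
#' @return List: `p`, `observed`, `null` (vector of null R^2).
#' @export
ordering_permutation_null <- function(cohort, winner_fit, n_perm = 1000,
                                      seed = 1, permutations = NULL) {
  ordering <- winner_fit$ordering
  L <- length(ordering$assignment)
  parcels <- names(ordering$assignment)
  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(replicate(n_perm, sample.int(L)))
  }
  null <- apply(permutations, 1L, function(perm) {
    o <- hierarchy_ordering(stats::setNames(perm, parcels), "custom")
    score_ordering(o, cohort, engine = winner_fit$engine)$r_squared
  })
  obs <- winner_fit$r_squared
  # numerically tied null values (e.g. the reversal-symmetric assignment)
  # count as >= observed
  list(p = (1 + sum(null >= obs - 1e-12)) / (length(null) + 1),
       observed = obs, null = null)
}

#' Spearman validation of an ordering against a parcel metric
#'
#' Correlates hierarchical level with any parcel-wise metric (group-averaged
#' INT, layer-IV gene expression, ...) using Spearman's rank correlation, with
#' a parametric p-value and a two-sided permutation p-value over random level
#' assignments.
#'
#' @param ordering A [hierarchy_ordering()].
#' @param parcel_metric Named numeric vector, parcel -> metric value; must
#'   cover at least 4 of the ordering's parcels.
#' @param n_perm Number of random orderings for the permutation p.
#' @param seed Integer seed.
#' @return List: `rho`, `p_parametric`, `p_permutation`, `flagged` (`TRUE`
#'   when the metric is entirely tied and rho is undefined).
#' @export
spearman_validate <- function(ordering, parcel_metric, n_perm = 1000, seed = 1) {
  lv <- ordering$assignment
  metric <- parcel_metric[names(lv)]
  ok <- is.finite(metric)
  if (sum(ok) < 4L) stop("need metric values for at least 4 parcels")
  lv <- lv[ok]; metric <- metric[ok]
  if (length(unique(metric)) == 1L)
    return(list(rho = NA_real_, p_parametric = NA_real_,
                p_permutation = NA_real_, flagged = TRUE))
  rho <- stats::cor(lv, metric, method = "spearman")
  p_par <- suppressWarnings(
    stats::cor.test(lv, metric, method = "spearman")$p.value)
  set.seed(seed)
  null <- replicate(n_perm,
    stats::cor(sample(lv), metric, method = "spearman"))
  p_perm <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(rho = rho, p_parametric = p_par, p_permutation = p_perm, flagged = FALSE)
}
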