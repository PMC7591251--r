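#' Seven-item symptom set used throughout the package
#'
#' The seven clinical items scored 0-5 that are common to the PANSS and
#' SAPS/SANS instruments after rescaling.
#' @return Character vector of column names.
#' @export
symptom_items <- function() {
  c("hallucinations", "delusions", "conceptual_disorganization",
    "emotional_withdrawal", "social_withdrawal", "blunted_affect", "alogia")
}

#' Rescale PANSS item scores to the common 0-5 scale
#'
#' PANSS items (1-7) are decreased by one point and the top two levels
#' (moderately severe, severe) merged, yielding the 0-5 range of the
#' SAPS/SANS global ratings.
#'
#' @param x Integer vector of PANSS item scores in 1..7.
#' @return Integer vector in 0..5.
#' @export
rescale_panss <- function(x) {
  if (any(x < 1 | x > 7, na.rm = TRUE)) stop("PANSS items must lie in 1..7")
  pmin(as.integer(x) - 1L, 5L)
}

#' Cohort table of diagnoses, symptoms and covariates
#'
#' Validates a per-subject table carrying a diagnosis flag, the seven symptom
#' items (integers 0-5, `NA` allowed for controls), age (years), gender,
#' mean framewise displacement (mm) and acquisition site.
#'
#' @param df data.frame with columns `diagnosis` (0/1 or logical), the seven
#'   [symptom_items()], `age`, `gender` (two-level factor or 0/1), `mean_fd`,
#'   `site` (factor).
#' @return The validated data.frame with class `cohort_table` prepended;
#'   `site` is releveled so the largest site is the reference.
#' @export
cohort_table <- function(df) {
  need <- c("diagnosis", symptom_items(), "age", "gender", "mean_fd", "site")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  df$diagnosis <- as.integer(as.logical(df$diagnosis))
  for (s in symptom_items()) {
    v <- df[[s]]
    if (any(v < 0 | v > 5, na.rm = TRUE))
      stop("symptom scores must lie in 0..5 (", s, ")")
  }
  df$site <- as.factor(df$site)
  df$site <- stats::relevel(df$site, ref = names(which.max(table(df$site))))
  if (!is.numeric(df$gender)) df$gender <- as.integer(as.factor(df$gender)) - 1L
  class(df) <- c("cohort_table", class(df))
  df
}

# Model matrix for the parcel-wise regressions. M1_primary regresses INT on
# the seven symptoms in patients; M1_exploratory on diagnosis in the full
# sample. Both control for age, gender, mean FD and site (treatment-coded,
# largest site as reference).
build_m1_design <- function(cohort, design = c("M1_primary", "M1_exploratory")) {
  design <- match.arg(design)
  rows <- if (design == "M1_primary") which(cohort$diagnosis == 1L)
          else seq_len(nrow(cohort))
  d <- droplevels(as.data.frame(cohort[rows, , drop = FALSE]))
  if (any(table(d$site) < 2L))
    stop("every site level in the fitted design needs at least 2 subjects")
  focal <- if (design == "M1_primary") symptom_items() else "diagnosis"
  if (anyNA(d[c(focal, "age", "gender", "mean_fd")]))
    stop("missing values in predictors for ", design)
  site_mm <- if (nlevels(d$site) > 1L)
    stats::model.matrix(~site, data = d)[, -1, drop = FALSE]
  else matrix(numeric(0), nrow(d), 0)
  X <- cbind("(Intercept)" = 1,
             as.matrix(d[focal]),
             age = d$age, gender = d$gender, mean_fd = d$mean_fd,
             site_mm)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  list(X = X, rows = rows, focal = focal, design = design)
}

# OLS of a multi-column response on a fixed design; returns coefficients,
# t-statistics and the shared residual df.
ols_fit <- function(X, Y) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  qrx <- qr(X)
  coef <- qr.coef(qrx, Y)
  res <- Y - X %*% coef
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qrx)))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  list(coefficients = coef, t = coef / se, se = se, df = df,
       sigma2 = sigma2, qr = qrx)
}

#' Parcel-wise mass-univariate regression (M1)
#'
#' Fits, per parcel, an ordinary least-squares model of INT on either the
#' seven symptom scores (`"M1_primary"`, patients only) or the diagnosis flag
#' (`"M1_exploratory"`, patients and controls), always controlling for age,
#' gender, mean framewise displacement and acquisition site.
#'
#' @param int_matrix Subjects x parcels numeric matrix of INT values
#'   (seconds), rows aligned with `cohort`.
#' @param cohort A [cohort_table()].
#' @param design `"M1_primary"` or `"M1_exploratory"`.
#' @return Object of class `parcel_effects`: per-parcel `coefficients` and
#'   `tstats` (predictors x parcels), residual `df`, the design matrix used,
#'   and bookkeeping needed by the resampling machinery.
#' @export
fit_parcelwise_glm <- function(int_matrix, cohort,
                               design = c("M1_primary", "M1_exploratory")) {
  design <- match.arg(design)
  int_matrix <- as.matrix(int_matrix)
  if (nrow(int_matrix) != nrow(cohort))
    stop("'int_matrix' rows must align with the cohort table")
  bd <- build_m1_design(cohort, design)
  Y <- int_matrix[bd$rows, , drop = FALSE]
  fit <- ols_fit(bd$X, Y)
  structure(list(coefficients = fit$coefficients, tstats = fit$t,
                 se = fit$se, df = fit$df, design = design,
                 X = bd$X, Y = Y, rows = bd$rows, focal = bd$focal,
                 parcels = colnames(int_matrix)),
            class = "parcel_effects")
}

#' @export
print.parcel_effects <- function(x, ...) {
  cat("<parcel_effects> [", x$design, "] ", ncol(x$tstats), " parcels, ",
      nrow(x$X), " subjects, residual df = ", x$df, "\n", sep = "")
  invisible(x)
}

#' @export
coef.parcel_effects <- function(object, ...) object$coefficients

# --- M2: hierarchical-gradient model over M1 t-statistics ------------------

# Long table of one t-statistic per (symptom, level, system). Prefrontal
# parcels shared between systems contribute one point per system.
gradient_data <- function(effects, hierarchies, symptoms) {
  if (is.null(names(hierarchies)))
    names(hierarchies) <- vapply(hierarchies, `[[`, character(1), "system_tag")
  rows <- list()
  missing_cells <- character()
  for (sys in names(hierarchies)) {
    a <- hierarchies[[sys]]$assignment
    for (sym in symptoms) {
      for (lv in sort(unique(a))) {
        parcel <- names(a)[a == lv]
        if (!(parcel %in% colnames(effects$tstats)) ||
            !(sym %in% rownames(effects$tstats))) {
          missing_cells <- c(missing_cells,
                             sprintf("(%s, level %d, %s)", sym, lv, sys))
          next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(t = effects$tstats[sym, parcel], symptom = sym,
                     level = as.numeric(lv), system = sys, parcel = parcel)
      }
    }
  }
  if (length(missing_cells))
    stop("missing (symptom, level, system) cells: ",
         paste(missing_cells, collapse = "; "))
  do.call(rbind, rows)
}

# Named contrast vectors for the paper-style effects: per-system gradient
# slope of each symptom, and per-system symptom difference in slopes.
gradient_contrasts <- function(mm, dat, symptoms, systems) {
  grad_vec <- function(sym, sys) {
    # d E[t] / d level at (symptom = sym, system = sys): numeric derivative
    # of the model-matrix row in `level`.
    base <- data.frame(symptom = factor(sym, levels = levels(dat$symptom)),
                       level = 0, system = factor(sys, levels = levels(dat$system)))
    hi <- base; hi$level <- 1
    f <- attr(mm, "formula")
    m0 <- stats::model.matrix(f, rbind(base, hi))
    m0[2, ] - m0[1, ]
  }
  out <- list()
  for (sys in systems) {
    for (sym in symptoms)
      out[[paste0("grad_", sym, "_", sys)]] <- grad_vec(sym, sys)
    if (length(symptoms) == 2L)
      out[[paste0("interact_", sys)]] <-
        grad_vec(symptoms[2L], sys) - grad_vec(symptoms[1L], sys)
  }
  out
}

#' Hierarchical-gradient model (M2) over parcel-wise symptom effects
#'
#' Regresses the M1 t-statistics of the focal symptoms, one per
#' (symptom, hierarchical level, sensory system) cell, on symptom, level and
#' system with full interactions (ordinary least squares; level is numeric,
#' symptom and system are treatment-coded factors). With two symptoms and
#' three 9-level systems this is the 54-point, 12-coefficient design with 42
#' residual degrees of freedom; single-symptom and two-system variants are
#' obtained by passing one symptom or two hierarchies.
#'
#' Besides the raw coefficient table, the fit reports the paper-style derived
#' effects as linear contrasts: the per-system hierarchical-gradient slope of
#' each symptom (`grad_<symptom>_<system>`) and the per-system
#' symptom-by-level interaction (`interact_<system>`, slope difference of the
#' second minus the first symptom). Cohen's f^2 is computed per effect by an
#' explicit full-versus-reduced refit, `(R2_full - R2_reduced)/(1 - R2_full)`.
#'
#' @param effects A [fit_parcelwise_glm()] result (`M1_primary` for symptom
#'   gradients).
#' @param hierarchies Named list of [hierarchy_ordering()] objects, one per
#'   sensory system.
#' @param symptoms Character vector of one or two focal symptoms
#'   (default hallucinations and delusions).
#' @param reference Optional list with elements `symptom` and/or `system`
#'   giving the reference (implicit) factor levels, so that each paper
#'   contrast can be read directly off the coefficient table.
#' @return Object of class `gradient_fit` with elements `coefficients`
#'   (raw coefficient table), `effects` (derived contrast table), `omnibus`
#'   (F, df, p), `df`, `data`, and the underlying `lm` fit.
#' @export
fit_gradient_glm <- function(effects, hierarchies,
                             symptoms = c("hallucinations", "delusions"),
                             reference = NULL) {
  dat <- gradient_data(effects, hierarchies, symptoms)
  dat$symptom <- factor(dat$symptom, levels = symptoms)
  dat$system <- factor(dat$system, levels = names(hierarchies))
  if (!is.null(reference$symptom))
    dat$symptom <- stats::relevel(dat$symptom, ref = reference$symptom)
  if (!is.null(reference$system))
    dat$system <- stats::relevel(dat$system, ref = reference$system)

  f <- if (length(symptoms) > 1L) t ~ symptom * level * system
       else t ~ level * system
  if (length(unique(dat$system)) == 1L)
    f <- if (length(symptoms) > 1L) t ~ symptom * level else t ~ level
  fit <- stats::lm(f, data = dat)
  smy <- summary(fit)
  df_res <- fit$df.residual
  r2_full <- smy$r.squared

  mm <- stats::model.matrix(fit)
  attr(mm, "formula") <- stats::delete.response(stats::terms(fit))

  # raw coefficients with refit-based f^2
  ct <- smy$coefficients
  f2 <- vapply(seq_len(ncol(mm)), function(j) {
    res <- stats::lm.fit(mm[, -j, drop = FALSE], dat$t)$residuals
    r2_red <- 1 - sum(res^2) / sum((dat$t - mean(dat$t))^2)
    (r2_full - r2_red) / (1 - r2_full)
  }, numeric(1))
  coef_table <- data.frame(estimate = ct[, 1], se = ct[, 2], t = ct[, 3],
                           f2 = f2, p = ct[, 4], row.names = rownames(ct))

  # derived contrasts
  cons <- gradient_contrasts(mm, dat, levels(dat$symptom), levels(dat$system))
  beta <- stats::coef(fit)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  s2 <- sum(stats::residuals(fit)^2) / df_res
  eff <- do.call(rbind, lapply(names(cons), function(nm) {
    cvec <- cons[[nm]]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% xtx_inv %*% cvec) * s2)
    tv <- est / se
    data.frame(term = nm, estimate = est, se = se, t = tv,
               f2 = tv^2 / df_res,
               p = 2 * stats::pt(-abs(tv), df_res))
  }))
  rownames(eff) <- eff$term

  fstat <- smy$fstatistic
  omnibus <- list(F = unname(fstat[1]), df1 = unname(fstat[2]),
                  df2 = unname(fstat[3]),
                  p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                       lower.tail = FALSE)))

  structure(list(coefficients = coef_table, effects = eff, omnibus = omnibus,
                 df = df_res, data = dat, fit = fit, contrasts = cons,
                 symptoms = symptoms, systems = names(hierarchies)),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("<gradient_fit> ", nrow(x$data), " points, ",
      nrow(x$coefficients), " coefficients, residual df = ", x$df, "\n",
      "omnibus F(", x$omnibus$df1, ",", x$omnibus$df2, ") = ",
      signif(x$omnibus$F, 4), ", p = ", format.pval(x$omnibus$p, digits = 3),
      "\nDerived hierarchical-gradient effects:\n", sep = "")
  print(x$effects[, c("estimate", "t", "f2", "p")], digits = 3)
  invisible(x)
}

#' @export
summary.gradient_fit <- function(object, ...) {
  list(coefficients = object$coefficients, effects = object$effects,
       omnibus = object$omnibus)
}

#' @export
coef.gradient_fit <- function(object, ...) object$coefficients$estimate |>
  stats::setNames(rownames(object$coefficients))

# Fast M2 refit used inside permutation/bootstrap loops: same design rows,
# new t-vector; returns the derived-effect t statistics (and estimates).
refit_gradient_effects <- function(gfit, tstats) {
  dat <- gfit$data
  tvec <- tstats[cbind(as.character(dat$symptom), dat$parcel)]
  mm <- stats::model.matrix(gfit$fit)
  fit <- stats::lm.fit(mm, tvec)
  df_res <- length(tvec) - fit$rank
  s2 <- sum(fit$residuals^2) / df_res
  xtx_inv <- chol2inv(qr.R(fit$qr))
  beta <- fit$coefficients
  vapply(gfit$contrasts, function(cvec) {
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% xtx_inv %*% cvec) * s2)
    est / se
  }, numeric(1))
}
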