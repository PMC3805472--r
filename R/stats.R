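## Behavioral and intersubject statistics: bisquare robust regression
## (IRLS), per-subject slope tests, choice-rate summaries, quantile
## binning, the stacked interaction GLM for condition-specific
## intersubject correlations, the mixed-design Group x Condition ANOVA,
## and the age-adjusted group GLM.

#' Robust linear regression (IRLS, Tukey bisquare)
#'
#' Iteratively reweighted least squares with the Tukey bisquare weight
#' function (tuning constant 4.685, giving 95% efficiency at the normal)
#' and robust scale `MAD/0.6745` of the residuals, iterated until the
#' maximum coefficient change falls below `tol` or `max_iter` is
#' reached. Standard errors come from the final weighted least-squares
#' step; the studentized coefficients `t = coef/SE` are what downstream
#' one-sided tests use.
#'
#' @param x numeric predictor vector or matrix (without intercept
#'   column).
#' @param y numeric response.
#' @param intercept include an intercept (default `TRUE`).
#' @param tune bisquare tuning constant.
#' @param max_iter,tol iteration controls.
#' @return object of class `robust_fit`: `coefficients`, `se`, `t`,
#'   `sigma`, `df`, `iterations`, `converged`, `weights`, `residuals`.
#' @examples
#' f <- robust_fit(1:20, 2 * (1:20))
#' coef(f)
#' @export
robust_fit <- function(x, y, intercept = TRUE, tune = 4.685,
                       max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) {
    colnames(X) <- if (ncol(X) == 1L) "x" else paste0("x", seq_len(ncol(X)))
  }
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  ok <- complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters (n > p)")
  if (sd(y) == 0) stop("constant response")
  if (qr(X)$rank < p) stop("rank-deficient design matrix")

  b <- qr.solve(X, y)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  repeat {
    iter <- iter + 1L
    r <- y - drop(X %*% b)
    s <- mad(r) # median(|r - median(r)|) / 0.6745
    if (s < 1e-12) { converged <- TRUE; break } # (near-)exact fit
    u <- r / (tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < p) { converged <- FALSE; break }
    b_new <- lm.wfit(X, y, w)$coefficients
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  r <- y - drop(X %*% b)
  s <- max(mad(r), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  s2 <- sum(w * r^2) / max(n - p, 1L)
  covb <- tryCatch(solve(XtWX) * s2, error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(covb))
  out <- list(
    coefficients = setNames(drop(b), colnames(X)),
    se = setNames(se, colnames(X)),
    t = setNames(drop(b) / se, colnames(X)),
    sigma = s,
    df = n - p,
    iterations = iter,
    converged = converged,
    weights = w,
    residuals = r
  )
  class(out) <- "robust_fit"
  out
}

#' @export
coef.robust_fit <- function(object, ...) object$coefficients

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> bisquare IRLS, %d iteration(s)%s\n",
              x$iterations, if (x$converged) "" else " (not converged)"))
  print(data.frame(coef = x$coefficients, se = x$se, t = x$t))
  invisible(x)
}

one_sided_p <- function(t, df, side) {
  switch(side,
         two.sided = 2 * pt(abs(t), df, lower.tail = FALSE),
         greater = pt(t, df, lower.tail = FALSE),
         less = pt(t, df))
}

#' Intersubject robust-regression test
#'
#' Robust regression of `y` on `x` across subjects, with a t test on the
#' studentized slope coefficient (one- or two-sided).
#'
#' @param x,y per-subject values.
#' @param side `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `slope`, `t`, `df`, `p`, `side`, `fit`.
#' @export
robust_slope_test <- function(x, y, side = c("two.sided", "greater", "less")) {
  side <- match.arg(side)
  fit <- robust_fit(x, y)
  t <- unname(fit$t[2L])
  list(slope = unname(fit$coefficients[2L]), t = t, df = fit$df,
       p = one_sided_p(t, fit$df, side), side = side, fit = fit)
}

#' Group-level test on per-subject robust slopes
#'
#' Fits a robust regression of `yvar` on `xvar` within every subject,
#' then performs a one-sample t test on the subject-level slopes --
#' the random-effects style summary used for trial-level couplings such
#' as likeability rating versus simulation richness.
#'
#' @param data data.frame with one row per trial/observation.
#' @param subject,xvar,yvar column names in `data`.
#' @param side test sidedness (default `"greater"`: a directional
#'   positive-coupling test).
#' @return list with `slopes`, `t`, `df`, `p`, `side`.
#' @export
per_subject_slope_test <- function(data, subject = "subject", xvar = "x",
                                   yvar = "y",
                                   side = c("greater", "two.sided", "less")) {
  side <- match.arg(side)
  stopifnot(all(c(subject, xvar, yvar) %in% names(data)))
  split_data <- split(data, data[[subject]])
  if (length(split_data) < 2L) {
    stop("need at least two subjects (one-sample t test has df = n - 1)")
  }
  slopes <- vapply(split_data, function(d) {
    d <- d[complete.cases(d[, c(xvar, yvar)]), , drop = FALSE]
    if (nrow(d) < 3L) stop("subject with fewer than 3 usable trials")
    if (sd(d[[xvar]]) == 0) return(NA_real_)
    unname(coef(robust_fit(d[[xvar]], d[[yvar]]))[2L])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  tt <- t.test(slopes, mu = 0,
               alternative = switch(side, greater = "greater",
                                    less = "less", two.sided = "two.sided"))
  list(slopes = slopes, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, side = side)
}

#' Nonimpulsive choice rate
#'
#' Fraction of trials on which the delayed option was chosen, optionally
#' restricted to one condition.
#'
#' @param trials data.frame with a `choice` column (and a `condition`
#'   column if `condition` is given).
#' @param condition optional condition filter (`"ecological"` /
#'   `"control"`).
#' @return rate in \[0, 1\].
#' @export
nonimpulsive_rate <- function(trials, condition = NULL) {
  stopifnot("choice" %in% names(trials), is_choice(trials$choice))
  if (!is.null(condition)) {
    trials <- trials[trials$condition %in% condition, , drop = FALSE]
  }
  if (nrow(trials) == 0L) stop("no trials left after filtering")
  mean(trials$choice == "nonimpulsive")
}

#' Quantile-binned summary of y against x
#'
#' Equal-count (quantile) bins of `x` computed within each subject (ties
#' broken by stable order); bin means of `x` and `y` are then averaged
#' across subjects, with the intersubject SEM per bin -- the summary
#' behind binned choice-rate and rating-by-richness displays.
#'
#' @param data data.frame.
#' @param xvar,yvar,subject column names (`subject = NULL` treats the
#'   data as a single subject; SEMs are then `NA`).
#' @param n_bins number of bins (each subject needs >= `n_bins` rows).
#' @return data.frame with one row per bin: `bin`, `x_mean`, `y_mean`,
#'   `x_sem`, `y_sem`, `n_subjects`.
#' @export
bin_summary <- function(data, xvar = "x", yvar = "y", subject = NULL,
                        n_bins = 9L) {
  stopifnot(all(c(xvar, yvar) %in% names(data)), n_bins >= 1L)
  groups <- if (is.null(subject)) list(all = data) else split(data, data[[subject]])
  per_subj <- lapply(groups, function(d) {
    n <- nrow(d)
    if (n < n_bins) stop("fewer observations than bins for one subject")
    ord <- rank(d[[xvar]], ties.method = "first")
    bin <- ceiling(ord * n_bins / n)
    data.frame(
      bin = seq_len(n_bins),
      x = as.numeric(tapply(d[[xvar]], bin, mean)),
      y = as.numeric(tapply(d[[yvar]], bin, mean))
    )
  })
  stacked <- do.call(rbind, per_subj)
  agg <- function(v) tapply(v, stacked$bin, mean)
  sem <- function(v) tapply(v, stacked$bin, function(z) {
    if (length(z) > 1L) sd(z) / sqrt(length(z)) else NA_real_
  })
  data.frame(
    bin = sort(unique(stacked$bin)),
    x_mean = as.numeric(agg(stacked$x)),
    y_mean = as.numeric(agg(stacked$y)),
    x_sem = as.numeric(sem(stacked$x)),
    y_sem = as.numeric(sem(stacked$y)),
    n_subjects = as.integer(table(stacked$bin))
  )
}

#' Condition-specific intersubject correlation (interaction GLM)
#'
#' Tests whether an outcome measured once per subject and condition
#' (e.g. a per-condition activation summary) correlates more strongly
#' with an intersubject behavioral variable in the ecological than in
#' the control condition. Rows are stacked over conditions and the GLM
#' `Y = b0 + b1*X + b2*Z + b3*(X*Z) + covariates` is fitted, with `Z` a
#' condition dummy (ecological = 1); the test concerns the interaction
#' coefficient `b3`.
#'
#' @param y_ecological,y_control per-subject outcomes in each condition.
#' @param x per-subject behavioral variable (same for both conditions).
#' @param covariates optional data.frame of per-subject covariates of
#'   no interest (each gets stacked over the two conditions).
#' @param side sidedness of the interaction test (default
#'   `"greater"`: higher correlation in the ecological condition).
#' @return list with `coefficients` (full table), `b3`, `t`, `df`, `p`,
#'   `side`.
#' @export
interaction_correlation_test <- function(y_ecological, y_control, x,
                                         covariates = NULL,
                                         side = c("greater", "two.sided", "less")) {
  side <- match.arg(side)
  n <- length(x)
  if (length(y_ecological) != n || length(y_control) != n) {
    stop("y_ecological, y_control and x must have one value per subject")
  }
  if (anyNA(y_ecological) || anyNA(y_control)) {
    stop("missing condition rows: each subject needs one Y per condition")
  }
  Y <- c(y_ecological, y_control)
  Z <- rep(c(1, 0), each = n)
  X <- rep(x, 2L)
  M <- cbind("(Intercept)" = 1, X = X, Z = Z, "X:Z" = X * Z)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    C <- as.matrix(rbind(covariates, covariates))
    colnames(C) <- names(covariates)
    M <- cbind(M, C)
  }
  if (qr(M)$rank < ncol(M)) {
    stop("rank-deficient design (collinear regressors)")
  }
  fit <- lm.fit(M, Y)
  df <- length(Y) - ncol(M)
  r <- fit$residuals
  s2 <- sum(r^2) / df
  covb <- chol2inv(chol(crossprod(M))) * s2
  se <- sqrt(diag(covb))
  tvals <- fit$coefficients / se
  pvals <- 2 * pt(abs(tvals), df, lower.tail = FALSE)
  tab <- data.frame(estimate = fit$coefficients, se = se, t = tvals,
                    p = pvals, row.names = colnames(M))
  t3 <- tvals[["X:Z"]]
  list(coefficients = tab, b3 = fit$coefficients[["X:Z"]], t = t3,
       df = df, p = one_sided_p(t3, df, side), side = side)
}

#' Group x Condition interaction (mixed-design ANOVA)
#'
#' Split-plot ANOVA on per-subject nonimpulsive choice rates with
#' condition as the within-subject factor and group as the
#' between-subject factor; returns the interaction F test (the key
#' comparison for ecological-specific group impulsivity). Degrees of
#' freedom follow the standard convention: interaction
#' `(g-1)(c-1)`, error `(N-g)(c-1)`.
#'
#' @param data data.frame with columns `subject`, `group`, `condition`,
#'   `rate` (one row per subject x condition).
#' @return list with `F`, `df1`, `df2`, `p` for the interaction, plus
#'   the full ANOVA `table`.
#' @export
group_condition_interaction <- function(data) {
  stopifnot(all(c("subject", "group", "condition", "rate") %in% names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$condition <- factor(data$condition)
  if (nlevels(data$group) < 2L) stop("need at least two groups")
  n_per_group <- rowSums(table(data$group, data$subject) > 0)
  if (all(n_per_group <= 1L)) {
    stop("insufficient degrees of freedom: need more than one subject per group")
  }
  fit <- aov(rate ~ group * condition + Error(subject), data = data)
  within <- summary(fit)[["Error: Within"]][[1L]]
  row <- grep("group:condition", rownames(within))
  resid_row <- grep("Residuals", rownames(within))
  Fv <- within[row, "F value"]
  df1 <- within[row, "Df"]
  df2 <- within[resid_row, "Df"]
  if (is.na(Fv) || df2 < 1) stop("insufficient degrees of freedom for the interaction test")
  list(F = Fv, df1 = df1, df2 = df2,
       p = within[row, "Pr(>F)"], table = summary(fit))
}

#' Covariate-adjusted group test on condition differences
#'
#' OLS of the per-subject ecological-minus-control rate difference on a
#' group indicator and age, with t tests on both coefficients --
#' verifies that a group effect survives adjustment for age.
#'
#' @param delta per-subject rate difference (ecological - control).
#' @param group group labels (factor or character, 2+ levels).
#' @param age per-subject age.
#' @return list with the coefficient `table` (estimate, se, t, df, p)
#'   and `dropped` (names of constant covariates removed).
#' @export
covariate_adjusted_group_test <- function(delta, group, age) {
  group <- factor(group)
  dropped <- character()
  dat <- data.frame(delta = delta, group = group, age = age)
  if (sd(age) == 0) {
    warning("age is constant; dropping it from the model")
    dropped <- "age"
    fit <- lm(delta ~ group, data = dat)
  } else {
    fit <- lm(delta ~ group + age, data = dat)
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(estimate = sm[, 1], se = sm[, 2], t = sm[, 3],
                    df = fit$df.residual, p = sm[, 4],
                    row.names = rownames(sm))
  list(table = tab, dropped = dropped, fit = fit)
}
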