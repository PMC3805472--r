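## The computational model: hyperbolic discounting V = R/(1 + kD) of a
## reward R delayed by D days, a softmax choice rule with temperature
## beta, and deterministic maximum-likelihood fitting of (k, beta).

#' Map monetary amounts onto the likeability-rating scale
#'
#' Affine, order-preserving map of euro amounts onto the \[-10, 10\]
#' rating interval used by the episodic task, so both tasks feed the
#' discounting model values in the same units: the minimum amount maps to
#' -10 and the maximum to +10.
#'
#' @param amounts numeric euro amounts (at least two distinct values);
#'   by default all amounts of a session (immediate and delayed pooled)
#'   define the range.
#' @param range optional numeric length-2 override of the mapped range,
#'   e.g. `c(0.5, 72)` for the theoretical grid limits of the task.
#' @return numeric values in \[-10, 10\].
#' @examples
#' transform_monetary(c(0.5, 36.25, 72))
#' @export
transform_monetary <- function(amounts, range = NULL) {
  stopifnot(is.numeric(amounts))
  r <- if (is.null(range)) base::range(amounts) else sort(range)
  if (diff(r) <= 0) stop("degenerate amount range: all amounts are equal")
  -10 + 20 * (amounts - r[1]) / (r[2] - r[1])
}

#' Hyperbolic discounted value
#'
#' `V = R / (1 + k * D)` with `R` the undiscounted value (likeability
#' rating or transformed payoff), `D` the delay in days and `k` the
#' discount rate per day. Negative values shrink toward zero with delay.
#'
#' @param R numeric reward value(s).
#' @param D non-negative delay(s) in days.
#' @param k non-negative discount rate (per day).
#' @return numeric discounted value(s).
#' @examples
#' discounted_value(8, 365, 1 / 365) # 4
#' @export
discounted_value <- function(R, D, k) {
  if (any(k < 0)) stop("k must be non-negative")
  if (any(D < 0)) stop("D must be non-negative")
  R / (1 + k * D)
}

#' Softmax probability of the impulsive choice
#'
#' `Pimp = exp(Vi/beta) / (exp(Vi/beta) + exp(Vd/beta))`, computed in the
#' overflow-safe logistic form `1 / (1 + exp((Vd - Vi)/beta))`.
#'
#' @param Vi value of the immediate option.
#' @param Vd discounted value of the delayed option.
#' @param beta softmax temperature (> 0); larger beta, noisier choices.
#' @param log.p return log-probability instead.
#' @return probability (or log-probability) of choosing the immediate
#'   option, strictly inside (0, 1) for finite inputs.
#' @examples
#' choice_probability(10, 0, 10) # 1 / (1 + exp(-1))
#' @export
choice_probability <- function(Vi, Vd, beta, log.p = FALSE) {
  if (any(beta <= 0)) stop("beta must be strictly positive")
  plogis((Vi - Vd) / beta, log.p = log.p)
}

## Internal: pull the (Vi, R_d, D, choice) columns out of a trial table
## and fail early on malformed input.
check_valued_trials <- function(trials, need_choice = TRUE) {
  stopifnot(is.data.frame(trials))
  need <- c("Vi", "R_d", "D")
  if (need_choice) need <- c(need, "choice")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("empty trial list")
  if (need_choice && !is_choice(trials$choice)) {
    stop("choice must be 'impulsive' or 'nonimpulsive'")
  }
  invisible(trials)
}

#' Negative log-likelihood of observed choices
#'
#' `-sum(log P(observed choice))` under the hyperbolic + softmax model.
#' Finite for any `beta > 0` (log-probabilities are computed directly,
#' never via an intermediate probability that could underflow).
#'
#' @param params list or named vector with elements `k` and `beta`.
#' @param trials data.frame of valued trials with columns `Vi`
#'   (immediate value), `R_d` (undiscounted delayed value), `D` (delay in
#'   days) and `choice` (`"impulsive"` / `"nonimpulsive"`).
#' @return scalar negative log-likelihood.
#' @examples
#' tr <- data.frame(Vi = 10, R_d = 0, D = 365, choice = "impulsive")
#' negative_log_likelihood(list(k = 0.01, beta = 10), tr)
#' @export
negative_log_likelihood <- function(params, trials) {
  check_valued_trials(trials)
  k <- params[["k"]]; beta <- params[["beta"]]
  if (k < 0) stop("k must be non-negative")
  if (beta <= 0) stop("beta must be strictly positive")
  Vd <- trials$R_d / (1 + k * trials$D)
  x <- (trials$Vi - Vd) / beta
  imp <- trials$choice == "impulsive"
  lp <- numeric(nrow(trials))
  lp[imp] <- plogis(x[imp], log.p = TRUE)
  lp[!imp] <- plogis(-x[!imp], log.p = TRUE)
  -sum(lp)
}

## Search bounds (log10 k and natural-log beta) shared by the grid and
## the boundary-flag logic.
FIT_BOUNDS <- list(log10k = c(-5, 0), logbeta = c(-2, 3))

#' Fit the discounting model by maximum likelihood
#'
#' Deterministic two-stage search: a coarse grid over
#' `log10(k) in [-5, 0]` and `log(beta) in [-2, 3]` (25 x 25 points by
#' default), then Nelder--Mead refinement from the grid optimum.
#' Parameters are fitted in log space, which enforces positivity without
#' constraints. `mode = "group"` pools the trials of several subjects
#' (pass a list of trial tables) into a single likelihood, yielding one
#' common parameter set.
#'
#' @param trials a valued-trial data.frame (see
#'   [negative_log_likelihood()]), or for group fits a list of them.
#' @param mode `"subject"` (default) or `"group"`.
#' @param grid_n number of grid points per dimension.
#' @return an object of class `fit_result`: list with `k`, `beta`,
#'   `logLik`, `n_trials`, `prediction_score`, `boundary`, `mode`,
#'   `convergence`.
#' @examples
#' tr <- data.frame(Vi = c(2, -1, 5), R_d = c(8, 6, 9),
#'                  D = c(30, 365, 3650),
#'                  choice = c("nonimpulsive", "nonimpulsive", "impulsive"))
#' fit_parameters(tr)
#' @export
fit_parameters <- function(trials, mode = c("subject", "group"), grid_n = 25L) {
  mode <- match.arg(mode)
  if (mode == "group" && is.data.frame(trials) == FALSE && is.list(trials)) {
    trials <- do.call(rbind, lapply(trials, function(x)
      x[, c("Vi", "R_d", "D", "choice")]))
  }
  check_valued_trials(trials)
  imp <- trials$choice == "impulsive"
  degenerate <- length(unique(imp)) < 2L

  nll_par <- function(p) {
    negative_log_likelihood(list(k = 10^p[1], beta = exp(p[2])), trials)
  }
  g1 <- seq(FIT_BOUNDS$log10k[1], FIT_BOUNDS$log10k[2], length.out = grid_n)
  g2 <- seq(FIT_BOUNDS$logbeta[1], FIT_BOUNDS$logbeta[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(log10k = g1, logbeta = g2))
  vals <- apply(grid, 1L, nll_par)
  best <- which.min(vals)
  start <- grid[best, ]
  opt <- optim(start, nll_par, method = "Nelder-Mead",
               control = list(maxit = 500L, reltol = 1e-10))
  slack <- 0.25
  at_edge <- opt$par[1] <= FIT_BOUNDS$log10k[1] + slack ||
    opt$par[1] >= FIT_BOUNDS$log10k[2] - slack ||
    opt$par[2] <= FIT_BOUNDS$logbeta[1] + slack ||
    opt$par[2] >= FIT_BOUNDS$logbeta[2] - slack
  params <- list(k = unname(10^opt$par[1]), beta = unname(exp(opt$par[2])))
  out <- list(
    k = params$k,
    beta = params$beta,
    logLik = -opt$value,
    n_trials = nrow(trials),
    prediction_score = prediction_score(params, trials),
    boundary = degenerate || at_edge,
    degenerate = degenerate,
    mode = mode,
    convergence = opt$convergence
  )
  class(out) <- "fit_result"
  out
}

#' Model prediction score
#'
#' Percentage of trials in which the option with the strictly higher
#' discounted value estimate was actually chosen. Trials where the two
#' estimates tie are excluded from the denominator.
#'
#' @param fit a `fit_result`, or any list with `k` and `beta`.
#' @param trials valued-trial data.frame with observed choices.
#' @return percentage in \[0, 100\] (`NA` if every trial is tied).
#' @export
prediction_score <- function(fit, trials) {
  check_valued_trials(trials)
  k <- fit[["k"]]
  Vd <- trials$R_d / (1 + k * trials$D)
  imp <- trials$choice == "impulsive"
  tied <- trials$Vi == Vd
  if (all(tied)) {
    warning("all trials have tied value estimates; prediction score undefined")
    return(NA_real_)
  }
  correct <- (imp & trials$Vi > Vd) | (!imp & Vd > trials$Vi)
  100 * sum(correct[!tied]) / sum(!tied)
}

#' Per-trial value differences under fitted parameters
#'
#' Returns, for each trial, the signed difference between the immediate
#' and (discounted) delayed value estimates and between the chosen and
#' unchosen option values -- the quantities used for binned choice-rate
#' summaries and for fit-quality comparisons between conditions.
#'
#' @param trials valued-trial data.frame.
#' @param params list with `k` (and optionally `beta`, unused here).
#' @return data.frame with columns `Vi`, `Vd`, `vi_minus_vd`,
#'   `chosen_minus_unchosen`.
#' @export
value_difference <- function(trials, params) {
  check_valued_trials(trials)
  Vd <- trials$R_d / (1 + params[["k"]] * trials$D)
  imp <- trials$choice == "impulsive"
  chosen <- ifelse(imp, trials$Vi, Vd)
  unchosen <- ifelse(imp, Vd, trials$Vi)
  data.frame(
    trial_index = trials$trial_index %||% seq_len(nrow(trials)),
    Vi = trials$Vi,
    Vd = Vd,
    vi_minus_vd = trials$Vi - Vd,
    chosen_minus_unchosen = chosen - unchosen
  )
}

#' Build the model's valued-trial table from a schedule
#'
#' Joins a trial schedule with a subject's likeability ratings (episodic
#' task) or transforms the session's euro amounts onto the rating scale
#' (monetary task), yielding the `Vi` / `R_d` / `D` columns the
#' likelihood works on. Immediate options carry delay 0 and are never
#' discounted.
#'
#' @param schedule a `trial_schedule`.
#' @param ratings for episodic schedules, a data.frame with columns
#'   `item`, `mode`, `rating` (one row per item x presentation mode), as
#'   produced by [simulate_ratings_and_richness()].
#' @param choices optional data.frame with columns `trial_index`,
#'   `choice` to merge in.
#' @param money_range optional range override passed to
#'   [transform_monetary()].
#' @return data.frame with columns `trial_index`, `condition`,
#'   `subtype`, `Vi`, `R_d`, `D` (+ `choice` if supplied).
#' @export
valued_trials <- function(schedule, ratings = NULL, choices = NULL,
                          money_range = NULL) {
  s <- as.data.frame(schedule)
  if (identical(s$task[1], "monetary")) {
    all_amounts <- c(s$imm_amount, s$del_amount)
    r <- if (is.null(money_range)) range(all_amounts) else money_range
    Vi <- transform_monetary(s$imm_amount, range = r)
    Rd <- transform_monetary(s$del_amount, range = r)
  } else {
    if (is.null(ratings)) stop("episodic schedules require a ratings table")
    key <- paste(ratings$item, ratings$mode, sep = "\r")
    val <- setNames(ratings$rating, key)
    ki <- paste(s$imm_item, s$imm_mode, sep = "\r")
    kd <- paste(s$del_item, s$del_mode, sep = "\r")
    miss <- c(s$imm_item[!(ki %in% key)], s$del_item[!(kd %in% key)])
    if (length(miss)) {
      stop("missing rating for scheduled item(s): ",
           paste(unique(miss), collapse = "; "))
    }
    Vi <- unname(val[ki])
    Rd <- unname(val[kd])
  }
  out <- data.frame(
    trial_index = s$trial_index,
    condition = s$condition,
    subtype = s$subtype,
    Vi = Vi,
    R_d = Rd,
    D = s$delay_days
  )
  if (!is.null(choices)) {
    out <- merge(out, choices[, c("trial_index", "choice")],
                 by = "trial_index", sort = TRUE)
  }
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> k = %.5g /day, beta = %.4g (%s fit, n = %d)\n",
              x$k, x$beta, x$mode, x$n_trials))
  cat(sprintf("  logLik = %.3f, prediction score = %.1f%%%s\n",
              x$logLik, x$prediction_score,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
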