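## End-to-end experiment runners: design -> simulate -> fit -> analyze
## -> mediate, from a single config and master seed, with deterministic
## outputs and a checksum manifest.

#' Configuration for a healthy-cohort experiment
#'
#' One healthy group performing two episodic sessions and one monetary
#' session (the main-study layout), with the neural coupling switched on
#' so that anatomy and activation relate to ecological choice behavior.
#'
#' @param n number of subjects.
#' @param seed master seed.
#' @param coupling Sim-valuation deficit per unit of neural score (see
#'   [cohort_config()]).
#' @param ... further overrides passed to [group_spec()].
#' @return a `cohort_config`.
#' @export
healthy_config <- function(n = 20L, seed = 1L, coupling = 1.5, ...) {
  cohort_config(
    groups = list(healthy = group_spec("healthy", n, ...)),
    variant = "exp2",
    neural = list(coupling = coupling),
    seed = seed
  )
}

#' Configuration for a patient-cohort experiment
#'
#' AD-like and elderly-control groups performing the short food-only
#' task variant with delays 1 day / 1 month / 5 years.
#'
#' @param n_per_group named integer vector of group sizes; names must be
#'   phenotypes (`"AD"`, `"CTL"`, `"bvFTD"`).
#' @param variant schedule variant (default `"expB"`).
#' @param seed master seed.
#' @return a `cohort_config`.
#' @export
patient_config <- function(n_per_group = c(AD = 15L, CTL = 15L),
                           variant = "expB", seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be a named vector of group sizes")
  }
  groups <- lapply(seq_along(n_per_group), function(i) {
    group_spec(names(n_per_group)[i], n_per_group[i])
  })
  names(groups) <- names(n_per_group)
  cohort_config(groups = groups, variant = variant,
                episodic_sessions = 1L, monetary_sessions = 0L,
                seed = seed)
}

fit_subject_tasks <- function(cohort) {
  rows <- lapply(cohort$subjects, function(su) {
    out <- list()
    fe <- fit_parameters(su$episodic_trials)
    out$episodic <- data.frame(
      subject = su$id, group = su$group, task = "episodic",
      k = fe$k, beta = fe$beta, logLik = fe$logLik,
      n_trials = fe$n_trials, prediction_score = fe$prediction_score,
      boundary = fe$boundary, stringsAsFactors = FALSE)
    if (!is.null(su$monetary_trials)) {
      fm <- fit_parameters(su$monetary_trials)
      out$monetary <- data.frame(
        subject = su$id, group = su$group, task = "monetary",
        k = fm$k, beta = fm$beta, logLik = fm$logLik,
        n_trials = fm$n_trials, prediction_score = fm$prediction_score,
        boundary = fm$boundary, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Per-condition prediction score and mean chosen-minus-unchosen value
## difference, under each subject's own episodic fit.
condition_fit_quality <- function(cohort, fits) {
  epi <- fits[fits$task == "episodic", ]
  rows <- lapply(cohort$subjects, function(su) {
    k <- epi$k[epi$subject == su$id]
    params <- list(k = k, beta = epi$beta[epi$subject == su$id])
    tr <- su$episodic_trials
    vd <- value_difference(tr, params)
    out <- lapply(c("ecological", "control"), function(cond) {
      sel <- tr$condition == cond
      data.frame(
        subject = su$id, condition = cond,
        prediction_score = prediction_score(params, tr[sel, ]),
        mean_chosen_minus_unchosen = mean(vd$chosen_minus_unchosen[sel]),
        nonimpulsive_rate = nonimpulsive_rate(tr, cond),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  slim <- config
  slim$catalog <- NULL # reproduced by default_item_catalog()
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = 10, force = TRUE)
  unname(tools::md5sum(tmp))
}

build_manifest <- function(config, stage_seeds, out_dir, files) {
  rel <- files
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  list(
    package = "delaychoice",
    version = as.character(utils::packageVersion("delaychoice")),
    config_hash = config_hash(config),
    master_seed = config$seed,
    stage_seeds = stage_seeds,
    files = data.frame(file = rel, md5 = sums, stringsAsFactors = FALSE)
  )
}

write_bundle <- function(bundle, config, stage_seeds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put_csv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
    files <<- c(files, name)
  }
  put_json <- function(x, name) {
    write_json_file(x, file.path(out_dir, name))
    files <<- c(files, name)
  }
  put_csv(bundle$summary, "cohort_summary.csv")
  if (!is.null(bundle$trials)) put_csv(bundle$trials, "trials.csv")
  if (!is.null(bundle$fits)) put_csv(bundle$fits, "fits.csv")
  if (!is.null(bundle$condition_quality)) {
    put_csv(bundle$condition_quality, "condition_quality.csv")
  }
  if (!is.null(bundle$bins_richness)) put_csv(bundle$bins_richness, "bins_richness.csv")
  if (!is.null(bundle$bins_choice)) put_csv(bundle$bins_choice, "bins_choice.csv")
  put_json(bundle$results, "results.json")
  if (!is.null(bundle$mediation)) {
    med <- bundle$mediation
    put_json(list(paths = cbind(path = rownames(med$paths), med$paths),
                  total = med$total, full_mediation = med$full_mediation,
                  n = med$n, n_boot = med$n_boot, seed = med$seed, ci = med$ci),
             "mediation.json")
  }
  manifest <- build_manifest(config, stage_seeds, out_dir, files)
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

## Combined valued-trial table (episodic + monetary) with subject ids.
stack_trials <- function(cohort) {
  rows <- lapply(cohort$subjects, function(su) {
    e <- cbind(subject = su$id, task = "episodic", su$episodic_trials)
    if (!is.null(su$monetary_trials)) {
      m <- cbind(subject = su$id, task = "monetary", su$monetary_trials)
      rbind(e, m)
    } else {
      e
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the healthy-cohort experiment end to end
#'
#' Simulates the cohort, fits the discounting model per subject and
#' pooled over subjects, computes the behavioral statistics (richness
#' slope test, per-condition fit quality, binned summaries, intersubject
#' correlations of choice rate and discount rate between tasks), the
#' condition-specific intersubject interaction GLM on the activation
#' summaries, and the GM / BOLD / CHOICE mediation analysis.
#'
#' @param config a `cohort_config` (default [healthy_config()]).
#' @param out_dir optional output directory; when given, all tables and
#'   results are written (CSV/JSON) along with a checksum manifest.
#' @param n_boot bootsamples for the mediation analysis.
#' @return a list (class `delaychoice_run`) with elements `cohort`,
#'   `summary`, `fits`, `group_fit`, `condition_quality`,
#'   `richness_slope`, `bins_richness`, `bins_choice`,
#'   `intertask_choice`, `intertask_k`, `interaction_glm`, `mediation`,
#'   `results`, and `manifest` (if written).
#' @export
run_healthy_experiment <- function(config = healthy_config(),
                                   out_dir = NULL, n_boot = 10000L) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  if (sum(vapply(config$groups, `[[`, 0L, "n")) < 2L) {
    stop("config must provide at least two subjects")
  }
  if (config$monetary_sessions < 1L || config$variant %in% c("expA", "expB")) {
    stop("healthy experiment requires a monetary session (exp1/exp2 variant)")
  }
  stage_seeds <- list(
    cohort = config$seed,
    mediation = substream_seed(config$seed, "mediation")
  )
  cohort <- simulate_cohort(config)
  sm <- cohort$summary
  fits <- fit_subject_tasks(cohort)
  group_fit <- fit_parameters(lapply(cohort$subjects, `[[`, "episodic_trials"),
                              mode = "group")
  cq <- condition_fit_quality(cohort, fits)

  ## trial-level coupling of likeability and simulation richness
  rat <- do.call(rbind, lapply(cohort$subjects, function(su) {
    d <- su$ratings[su$ratings$mode == "Sim", c("richness", "rating")]
    cbind(subject = su$id, d)
  }))
  richness_slope <- per_subject_slope_test(rat, subject = "subject",
                                           xvar = "richness", yvar = "rating",
                                           side = "greater")
  bins_richness <- bin_summary(rat, xvar = "richness", yvar = "rating",
                               subject = "subject", n_bins = 8L)

  ## choice rate as a function of the value difference (subject fits)
  epi_fits <- fits[fits$task == "episodic", ]
  vd_data <- do.call(rbind, lapply(cohort$subjects, function(su) {
    k <- epi_fits$k[epi_fits$subject == su$id]
    vd <- value_difference(su$episodic_trials, list(k = k))
    data.frame(subject = su$id,
               vd_minus_vi = -vd$vi_minus_vd,
               nonimpulsive = as.numeric(su$episodic_trials$choice == "nonimpulsive"))
  }))
  bins_choice <- bin_summary(vd_data, xvar = "vd_minus_vi",
                             yvar = "nonimpulsive", subject = "subject",
                             n_bins = 9L)

  ## intersubject consistency between tasks
  mon_fits <- fits[fits$task == "monetary", ]
  intertask_choice <- robust_slope_test(sm$mon_rate, sm$epi_rate,
                                        side = "greater")
  intertask_k <- robust_slope_test(log10(mon_fits$k), log10(epi_fits$k),
                                   side = "greater")

  ## condition-specific intersubject correlation of activation with
  ## behavior (ecological vs control)
  interaction_glm <- interaction_correlation_test(
    y_ecological = sm$BOLD_eco, y_control = sm$BOLD_ctl,
    x = sm$eco_rate, covariates = data.frame(age = sm$age),
    side = "greater")

  medi <- mediate(GM = sm$GM, BOLD = sm$BOLD, CHOICE = 1 - sm$eco_rate,
                  n_boot = n_boot, seed = stage_seeds$mediation)

  agg <- function(v) c(mean = mean(v), sem = sd(v) / sqrt(length(v)))
  results <- list(
    n_subjects = nrow(sm),
    impulsive_rate_monetary_pct = agg(100 * (1 - sm$mon_rate)),
    impulsive_rate_episodic_pct = agg(100 * (1 - sm$epi_rate)),
    prediction_score_control_pct =
      agg(cq$prediction_score[cq$condition == "control"]),
    prediction_score_ecological_pct =
      agg(cq$prediction_score[cq$condition == "ecological"]),
    chosen_minus_unchosen_control =
      agg(cq$mean_chosen_minus_unchosen[cq$condition == "control"]),
    chosen_minus_unchosen_ecological =
      agg(cq$mean_chosen_minus_unchosen[cq$condition == "ecological"]),
    richness_slope = richness_slope[c("t", "df", "p", "side")],
    intertask_choice = intertask_choice[c("slope", "t", "df", "p", "side")],
    intertask_k = intertask_k[c("slope", "t", "df", "p", "side")],
    interaction_glm = interaction_glm[c("b3", "t", "df", "p", "side")],
    group_fit = list(k = group_fit$k, beta = group_fit$beta,
                     logLik = group_fit$logLik,
                     prediction_score = group_fit$prediction_score),
    mediation = list(
      indirect = medi$paths["indirect (b1*b2)", "estimate"],
      indirect_p = medi$paths["indirect (b1*b2)", "p"],
      direct = medi$paths["direct (GM->CHOICE|BOLD)", "estimate"],
      direct_p = medi$paths["direct (GM->CHOICE|BOLD)", "p"],
      full_mediation = medi$full_mediation)
  )
  bundle <- list(
    cohort = cohort, summary = sm, trials = stack_trials(cohort),
    fits = fits, group_fit = group_fit, condition_quality = cq,
    richness_slope = richness_slope, bins_richness = bins_richness,
    bins_choice = bins_choice, intertask_choice = intertask_choice,
    intertask_k = intertask_k, interaction_glm = interaction_glm,
    mediation = medi, results = results, stage_seeds = stage_seeds
  )
  if (!is.null(out_dir)) {
    bundle$manifest <- write_bundle(bundle, config, stage_seeds, out_dir)
  }
  class(bundle) <- "delaychoice_run"
  bundle
}

#' Run the patient-cohort experiment end to end
#'
#' Simulates a multi-group cohort on the short task variant, computes
#' per-group nonimpulsive rates by condition, within-group
#' ecological-minus-control tests, two-sample group comparisons per
#' condition, the Group x Condition mixed ANOVA and the age-adjusted
#' group GLM on the condition difference.
#'
#' @param config a `cohort_config` with at least two groups (default
#'   [patient_config()]).
#' @param out_dir optional output directory (CSV/JSON + manifest).
#' @return a list (class `delaychoice_run`).
#' @export
run_patient_experiment <- function(config = patient_config(),
                                   out_dir = NULL) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  if (length(config$groups) < 2L) {
    stop("patient experiment requires at least two groups")
  }
  cohort <- simulate_cohort(config)
  sm <- cohort$summary
  long <- rbind(
    data.frame(subject = sm$subject, group = sm$group,
               condition = "ecological", rate = sm$eco_rate),
    data.frame(subject = sm$subject, group = sm$group,
               condition = "control", rate = sm$ctl_rate)
  )
  group_means <- do.call(rbind, lapply(split(long, long[c("group", "condition")]),
    function(d) data.frame(group = d$group[1], condition = d$condition[1],
                           rate_mean = mean(d$rate),
                           rate_sem = sd(d$rate) / sqrt(nrow(d)))))
  rownames(group_means) <- NULL

  delta <- sm$eco_rate - sm$ctl_rate
  within_tests <- lapply(split(seq_len(nrow(sm)), sm$group), function(ix) {
    tt <- t.test(delta[ix], mu = 0)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         mean_delta = mean(delta[ix]))
  })
  groups <- unique(sm$group)
  between_tests <- list()
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    for (pr in pairs) {
      for (cond in c("ecological", "control")) {
        v <- if (cond == "ecological") sm$eco_rate else sm$ctl_rate
        tt <- t.test(v[sm$group == pr[1]], v[sm$group == pr[2]],
                     var.equal = TRUE)
        between_tests[[paste(pr[1], "vs", pr[2], cond)]] <-
          list(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
      }
    }
  }
  interaction <- group_condition_interaction(long)
  age_glm <- covariate_adjusted_group_test(delta, sm$group, sm$age)

  results <- list(
    n_per_group = as.list(table(sm$group)),
    group_means = group_means,
    within_group_eco_minus_ctl = within_tests,
    between_group_tests = between_tests,
    group_condition_interaction = interaction[c("F", "df1", "df2", "p")],
    age_adjusted_glm = cbind(term = rownames(age_glm$table), age_glm$table)
  )
  stage_seeds <- list(cohort = config$seed)
  bundle <- list(
    cohort = cohort, summary = sm, trials = stack_trials(cohort),
    rates_long = long, group_means = group_means,
    within_tests = within_tests, between_tests = between_tests,
    interaction = interaction, age_glm = age_glm,
    results = results, stage_seeds = stage_seeds
  )
  if (!is.null(out_dir)) {
    bundle$manifest <- write_bundle(bundle, config, stage_seeds, out_dir)
  }
  class(bundle) <- "delaychoice_run"
  bundle
}
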