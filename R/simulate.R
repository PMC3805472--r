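## Synthetic agents and cohorts. Agents value items on the -10..10
## likeability scale, with values coupled to the richness (0..20 detail
## count) of their mental simulation of the item; choices follow the
## hyperbolic + softmax model with the agent's true (k, beta). Patient
## phenotypes are operationalised as a Sim-specific valuation deficit
## (AD-like) or an elevated discount rate (bvFTD-like). Per-subject
## scalar neural measures (grey-matter density GM, activation contrast
## BOLD) are generated with GM -> BOLD -> behavior directionality.

#' Ground-truth generative parameters of one synthetic agent
#'
#' @param k discount rate per day (> 0).
#' @param beta softmax temperature (> 0), in rating units.
#' @param baseline_mean mean item likeability (rating units).
#' @param baseline_sd item-to-item likeability noise SD (rating units).
#' @param richness_mean,richness_sd mean and SD of simulation richness
#'   (0--20 detail counts).
#' @param b richness-to-rating slope (rating units per detail).
#' @param tier_slope price-tier-to-rating slope (rating units per tier
#'   step); makes higher-tier -- hence delayed -- items more desirable.
#' @param delta_sim Sim-valuation deficit (rating units subtracted from
#'   the value of any simulated option; >= 0).
#' @param group group label.
#' @param age age in years.
#' @return a list of class `agent_params`.
#' @export
agent_params <- function(k = 0.01, beta = 2, baseline_mean = 2,
                         baseline_sd = 2, richness_mean = 10,
                         richness_sd = 4, b = 0.4, tier_slope = 0.7,
                         delta_sim = 0, group = "healthy", age = 25) {
  stopifnot(k > 0, beta > 0, delta_sim >= 0,
            richness_mean >= 0, richness_mean <= 20,
            richness_sd >= 0, baseline_sd >= 0)
  out <- list(k = k, beta = beta, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, richness_mean = richness_mean,
              richness_sd = richness_sd, b = b, tier_slope = tier_slope,
              delta_sim = delta_sim, group = group, age = age)
  class(out) <- "agent_params"
  out
}

#' Simulate likeability ratings and simulation richness for one agent
#'
#' For each catalog item, richness is a truncated-normal draw on
#' \[0, 20\], rounded to an integer. The latent item value is
#' `baseline + tier_slope * (tier - mean tier) + b * (richness -
#' richness_mean) + noise`; the reported rating is that value rounded
#' and clipped to the \[-10, 10\] scale. Simulated (text-only)
#' presentations are additionally reduced by the agent's `delta_sim`
#' before clipping, so the table carries one rating per item x
#' presentation mode. Richness reports are attached to Sim rows (the
#' scale only applies to options that must be imagined).
#'
#' @param agent an [agent_params()] object.
#' @param catalog item catalog.
#' @param seed integer seed.
#' @param richness optional integer vector (one per catalog item)
#'   overriding the richness draw, for controlled experiments.
#' @return data.frame with columns `item`, `domain`, `tier`, `mode`,
#'   `rating`, `richness`, plus `latent` -- the agent's continuous
#'   internal valuation of the item, of which the integer ratings are
#'   the measured counterpart (used by [simulate_choices()]).
#' @export
simulate_ratings_and_richness <- function(agent, catalog = default_item_catalog(),
                                          seed = 1L, richness = NULL) {
  validate_catalog(catalog)
  n <- nrow(catalog)
  with_seed(seed, {
    if (is.null(richness)) {
      richness <- round(rtruncnorm(n, agent$richness_mean,
                                   agent$richness_sd, 0, 20))
    }
    stopifnot(length(richness) == n, all(richness >= 0 & richness <= 20))
    latent <- agent$baseline_mean +
      agent$tier_slope * (catalog$tier - mean(catalog$tier)) +
      agent$b * (richness - agent$richness_mean) +
      rnorm(n, 0, agent$baseline_sd)
    rating_obs <- clip(round(latent), -10, 10)
    rating_sim <- clip(round(latent - agent$delta_sim), -10, 10)
    ## `latent` is the agent's internal (continuous, unclipped) item
    ## valuation; the choice generator works from it, the reported
    ## integer ratings are its measured counterpart
    data.frame(
      item = rep(catalog$item, 2L),
      domain = rep(catalog$domain, 2L),
      tier = rep(catalog$tier, 2L),
      mode = rep(c("Obs", "Sim"), each = n),
      rating = c(rating_obs, rating_sim),
      richness = c(rep(NA_integer_, n), as.integer(richness)),
      latent = rep(latent, 2L),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate an agent's choices on a schedule
#'
#' Values each option from the agent's latent item valuations (episodic;
#' the `latent` column of the ratings table, falling back to the
#' reported ratings when absent) or the transformed euro amounts
#' (monetary), discounts the delayed option hyperbolically, subtracts
#' the agent's Sim-valuation deficit from the decision value of any
#' simulated option, and draws each choice as a Bernoulli with the
#' softmax probability under the agent's true `(k, beta)`. Applying the
#' deficit after discounting makes control trials (Obs/Obs, Sim/Sim)
#' value-neutral by construction: in Sim/Sim trials the deficit cancels
#' from the value difference, so only ecological trials are penalised.
#'
#' @param agent an [agent_params()] object.
#' @param schedule a `trial_schedule`.
#' @param ratings ratings table (required for episodic schedules).
#' @param seed integer seed.
#' @return data.frame with columns `trial_index`, `p_impulsive`,
#'   `choice`.
#' @export
simulate_choices <- function(agent, schedule, ratings = NULL, seed = 1L) {
  s <- as.data.frame(schedule)
  if (identical(s$task[1], "episodic") && !is.null(ratings) &&
      "latent" %in% names(ratings)) {
    ## value options from the latent valuations (mode-independent)
    lat <- ratings[ratings$mode == "Obs", ]
    vt <- valued_trials(schedule,
                        ratings = data.frame(item = rep(lat$item, 2L),
                                             mode = rep(c("Obs", "Sim"),
                                                        each = nrow(lat)),
                                             rating = rep(lat$latent, 2L)))
  } else {
    vt <- valued_trials(schedule, ratings = ratings)
  }
  modes <- t(vapply(vt$subtype, subtype_modes, character(2)))
  Vd0 <- discounted_value(vt$R_d, vt$D, agent$k)
  ## Sim-presented options lose delta_sim at decision time (monetary
  ## included: the deficit concerns the presentation mode, not the
  ## reward type; it is 0 for healthy agents anyway)
  Vi <- vt$Vi - agent$delta_sim * (modes[, "imm"] == "Sim")
  Vd <- Vd0 - agent$delta_sim * (modes[, "del"] == "Sim")
  p <- choice_probability(Vi, Vd, agent$beta)
  with_seed(seed, {
    imp <- runif(length(p)) < p
    data.frame(
      trial_index = vt$trial_index,
      p_impulsive = p,
      choice = ifelse(imp, "impulsive", "nonimpulsive"),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate per-subject scalar neural measures
#'
#' Generates grey-matter density and activation-contrast scalars linked
#' by the mediation path structure `BOLD = beta1 * GM + noise` and
#' `CHOICE = beta0 * GM + beta2 * BOLD + noise`. If a per-subject
#' behavioral summary `choice` is supplied it is carried through
#' unchanged (the cohort simulator builds the GM -> BOLD -> behavior
#' link at generation time instead); otherwise a synthetic CHOICE
#' variable is drawn from the stated path equations.
#'
#' @param choice optional numeric vector of behavioral summaries (one
#'   per subject, e.g. ecological nonimpulsive choice rate).
#' @param n number of subjects (defaults to `length(choice)`).
#' @param beta0 direct GM -> CHOICE path.
#' @param beta1 GM -> BOLD path.
#' @param beta2 BOLD -> CHOICE path.
#' @param gm_sd SD of GM draws (arbitrary units).
#' @param bold_noise_sd,choice_noise_sd path noise SDs (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `GM`, `BOLD`, `CHOICE`.
#' @export
simulate_neural <- function(choice = NULL, n = length(choice), beta0 = 0,
                            beta1 = 1, beta2 = 0.5, gm_sd = 1,
                            bold_noise_sd = 0.5, choice_noise_sd = 0.5,
                            seed = 1L) {
  if (bold_noise_sd < 0 || choice_noise_sd < 0 || gm_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  if (n < 1L) stop("need at least one subject")
  with_seed(seed, {
    GM <- rnorm(n, 0, gm_sd)
    BOLD <- beta1 * GM + rnorm(n, 0, bold_noise_sd)
    CHOICE <- if (is.null(choice)) {
      beta0 * GM + beta2 * BOLD + rnorm(n, 0, choice_noise_sd)
    } else {
      stopifnot(length(choice) == n)
      choice
    }
    data.frame(GM = GM, BOLD = BOLD, CHOICE = CHOICE)
  })
}

group_phenotypes <- function() {
  base <- list(
    n = 15L,
    k_meanlog = log(0.01), k_sdlog = 0.9,
    beta_meanlog = log(2), beta_sdlog = 0.3,
    baseline_mean = 2, baseline_between_sd = 1.5, baseline_sd = 2,
    richness_mean = 10, richness_between_sd = 2, richness_sd = 4,
    b_mean = 0.4, b_sd = 0.1, tier_slope = 0.7,
    delta_sim_mean = 0, delta_sim_sd = 0,
    age_mean = 24, age_sd = 2
  )
  list(
    healthy = modifyList(base, list(delta_sim_mean = 1.5, delta_sim_sd = 0.5)),
    CTL = modifyList(base, list(age_mean = 68, age_sd = 6)),
    AD = modifyList(base, list(delta_sim_mean = 6, delta_sim_sd = 1,
                               age_mean = 72, age_sd = 6)),
    bvFTD = modifyList(base, list(k_meanlog = log(0.1),
                                  age_mean = 67, age_sd = 7))
  )
}

#' Specify one group of a synthetic cohort
#'
#' Starts from the phenotype's default generative distributions and
#' applies any override. Phenotypes: `"healthy"` (young adults),
#' `"CTL"` (elderly controls; same behavior, older), `"AD"` (AD-like:
#' Sim-specific valuation deficit `delta_sim` > 0, ecological-specific
#' impulsivity), `"bvFTD"` (bvFTD-like: tenfold discount rate,
#' condition-general impulsivity).
#'
#' @param phenotype one of `"healthy"`, `"CTL"`, `"AD"`, `"bvFTD"`.
#' @param n group size (>= 1).
#' @param ... named overrides of the phenotype defaults (e.g.
#'   `delta_sim_mean = 0`).
#' @return a list of class `group_spec`.
#' @export
group_spec <- function(phenotype = c("healthy", "CTL", "AD", "bvFTD"),
                       n = 15L, ...) {
  phenotype <- match.arg(phenotype)
  spec <- modifyList(group_phenotypes()[[phenotype]],
                     c(list(n = as.integer(n)), list(...)))
  if (spec$n < 1L) stop("group size must be >= 1")
  spec$phenotype <- phenotype
  class(spec) <- "group_spec"
  spec
}

#' Configure a synthetic cohort
#'
#' @param groups named list of [group_spec()] objects; names are the
#'   group labels.
#' @param variant experiment variant passed to the schedule generators.
#' @param episodic_sessions,monetary_sessions sessions per subject
#'   (monetary sessions are only generated for `exp1`/`exp2` variants).
#' @param neural list of neural-generation parameters: path
#'   coefficients `beta0`, `beta1`, `beta2`, `gm_sd`, `bold_noise_sd`,
#'   `ctl_noise_sd` (noise-only control-condition activation), and
#'   `coupling` (rating units of extra Sim-valuation deficit per unit of
#'   the neural score `beta0*GM + beta2*BOLD_eco`; builds the
#'   GM -> BOLD -> behavior directionality into the forward simulation).
#' @param catalog item catalog.
#' @param seed master seed; all stages draw named substreams from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(groups = list(healthy = group_spec("healthy", 20L)),
                          variant = "exp2",
                          episodic_sessions = 2L, monetary_sessions = 1L,
                          neural = list(), catalog = default_item_catalog(),
                          seed = 1L) {
  if (!length(groups)) stop("config must name at least one group")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list")
  }
  for (g in groups) {
    if (!inherits(g, "group_spec")) stop("each group must be a group_spec")
  }
  neural <- modifyList(list(beta0 = 0, beta1 = 1, beta2 = 0.5, gm_sd = 1,
                            bold_noise_sd = 0.5, ctl_noise_sd = 0.5,
                            coupling = 0), neural)
  if (neural$bold_noise_sd < 0 || neural$ctl_noise_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  out <- list(groups = groups, variant = variant,
              episodic_sessions = as.integer(episodic_sessions),
              monetary_sessions = as.integer(monetary_sessions),
              neural = neural, catalog = catalog, seed = as.integer(seed))
  class(out) <- "cohort_config"
  out
}

## Draw one agent's true parameters from its group's distributions.
draw_agent <- function(spec, group, neural_score, coupling) {
  delta <- max(0, spec$delta_sim_mean + rnorm(1, 0, spec$delta_sim_sd) -
                 coupling * neural_score)
  agent_params(
    k = rlnorm(1, spec$k_meanlog, spec$k_sdlog),
    beta = rlnorm(1, spec$beta_meanlog, spec$beta_sdlog),
    baseline_mean = rnorm(1, spec$baseline_mean, spec$baseline_between_sd),
    baseline_sd = spec$baseline_sd,
    richness_mean = clip(rnorm(1, spec$richness_mean, spec$richness_between_sd), 0, 20),
    richness_sd = spec$richness_sd,
    b = rnorm(1, spec$b_mean, spec$b_sd),
    tier_slope = spec$tier_slope,
    delta_sim = delta,
    group = group,
    age = rnorm(1, spec$age_mean, spec$age_sd)
  )
}

#' Simulate a full cohort
#'
#' For every subject: draws true agent parameters from the group's
#' distributions, generates per-subject schedules (episodic sessions,
#' plus a monetary session for healthy-experiment variants), simulates
#' ratings/richness and trial-by-trial choices, and generates the
#' scalar neural record. When `neural$coupling > 0`, subjects with a
#' lower neural score (`beta0*GM + beta2*BOLD_eco`) receive a larger
#' Sim-valuation deficit, so behavior is consistent with the
#' GM -> BOLD -> CHOICE path by construction.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: list with `subjects` (list of
#'   per-subject records), `config`, and `summary` (see
#'   [cohort_summary()]).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  nr <- config$neural
  episodic_only <- config$variant %in% c("expA", "expB")
  subjects <- list()
  sid <- 0L
  for (gname in names(config$groups)) {
    spec <- config$groups[[gname]]
    for (i in seq_len(spec$n)) {
      sid <- sid + 1L
      sseed <- substream_seed(config$seed, paste0("subject:", gname, ":", i))
      neural <- with_seed(substream_seed(sseed, "neural"), {
        GM <- rnorm(1, 0, nr$gm_sd)
        BOLD_eco <- nr$beta1 * GM + rnorm(1, 0, nr$bold_noise_sd)
        BOLD_ctl <- rnorm(1, 0, nr$ctl_noise_sd)
        list(GM = GM, BOLD_eco = BOLD_eco, BOLD_ctl = BOLD_ctl,
             BOLD = BOLD_eco - BOLD_ctl)
      })
      score <- nr$beta0 * neural$GM + nr$beta2 * neural$BOLD_eco
      agent <- with_seed(substream_seed(sseed, "params"),
                         draw_agent(spec, gname, score, nr$coupling))
      ratings <- simulate_ratings_and_richness(
        agent, config$catalog, seed = substream_seed(sseed, "ratings"))
      episodic <- lapply(seq_len(config$episodic_sessions), function(s) {
        sch <- generate_episodic_schedule(
          config$variant, config$catalog,
          seed = substream_seed(sseed, paste0("schedule:episodic:", s)),
          session = s)
        ch <- simulate_choices(agent, sch, ratings,
                               seed = substream_seed(sseed, paste0("choices:episodic:", s)))
        list(schedule = sch, choices = ch,
             trials = valued_trials(sch, ratings, choices = ch))
      })
      monetary <- if (!episodic_only && config$monetary_sessions > 0L) {
        lapply(seq_len(config$monetary_sessions), function(s) {
          sch <- generate_monetary_schedule(
            config$variant,
            seed = substream_seed(sseed, paste0("schedule:monetary:", s)),
            session = s)
          ch <- simulate_choices(agent, sch,
                                 seed = substream_seed(sseed, paste0("choices:monetary:", s)))
          list(schedule = sch, choices = ch,
               trials = valued_trials(sch, choices = ch))
        })
      } else {
        list()
      }
      epi_trials <- do.call(rbind, lapply(episodic, `[[`, "trials"))
      mon_trials <- if (length(monetary)) {
        do.call(rbind, lapply(monetary, `[[`, "trials"))
      } else {
        NULL
      }
      subjects[[sid]] <- list(
        id = sid, group = gname, agent = agent, neural = neural,
        ratings = ratings, episodic = episodic, monetary = monetary,
        episodic_trials = epi_trials, monetary_trials = mon_trials
      )
    }
  }
  out <- list(subjects = subjects, config = config)
  class(out) <- "cohort"
  out$summary <- cohort_summary(out)
  out
}

#' Per-subject summary table of a cohort
#'
#' One row per subject: group, age, true parameters, neural scalars and
#' nonimpulsive choice rates overall and by condition (episodic task).
#'
#' @param cohort a `cohort`.
#' @return a data.frame.
#' @export
cohort_summary <- function(cohort) {
  rows <- lapply(cohort$subjects, function(su) {
    tr <- su$episodic_trials
    data.frame(
      subject = su$id,
      group = su$group,
      age = su$agent$age,
      k_true = su$agent$k,
      beta_true = su$agent$beta,
      delta_sim = su$agent$delta_sim,
      GM = su$neural$GM,
      BOLD = su$neural$BOLD,
      BOLD_eco = su$neural$BOLD_eco,
      BOLD_ctl = su$neural$BOLD_ctl,
      eco_rate = nonimpulsive_rate(tr, condition = "ecological"),
      ctl_rate = nonimpulsive_rate(tr, condition = "control"),
      epi_rate = nonimpulsive_rate(tr),
      mon_rate = if (is.null(su$monetary_trials)) NA_real_ else
        nonimpulsive_rate(su$monetary_trials),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<cohort> %d subjects (%s), variant %s, seed %d\n",
              length(x$subjects),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
              x$config$variant, x$config$seed))
  invisible(x)
}
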