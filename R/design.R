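## Task-schedule generation: the factorial intertemporal-choice designs.
##
## An episodic session crosses domain (food/culture/sport) x condition
## (ecological vs control) x delay, with 72 trials split 36 Obs/Sim,
## 18 Obs/Obs and 18 Sim/Sim, so that Obs and Sim options are equally
## frequent in ecological and control conditions. The monetary session
## uses the same subtype/delay crossing with euro payoffs instead of
## items. Delays are carried in days throughout.

DELAY_SETS <- list(
  exp1 = c(month = 30L, year = 365L, decade = 3650L),
  exp2 = c(month = 30L, year = 365L, decade = 3650L),
  expA = c(month = 30L, year = 365L, decade = 3650L),
  expB = c(day = 1L, month = 30L, five_years = 1825L)
)

SUBTYPES <- c("Obs/Sim", "Obs/Obs", "Sim/Sim")

subtype_condition <- function(subtype) {
  ifelse(subtype == "Obs/Sim", "ecological", "control")
}

subtype_modes <- function(subtype) {
  ## ecological trials: immediate observed, delayed simulated
  switch(subtype,
         "Obs/Sim" = c(imm = "Obs", del = "Sim"),
         "Obs/Obs" = c(imm = "Obs", del = "Obs"),
         "Sim/Sim" = c(imm = "Sim", del = "Sim"),
         stop("unknown subtype: ", subtype))
}

#' Convert a named delay to days
#'
#' The model discounts with delay expressed in days; the conversion used
#' throughout is 1 day = 1, 1 month = 30, 1 year = 365, 5 years = 1825,
#' 10 years = 3650.
#'
#' @param label character vector among "day", "month", "year",
#'   "five_years", "decade".
#' @return integer vector of days.
#' @export
delay_days <- function(label) {
  map <- c(day = 1L, month = 30L, year = 365L,
           five_years = 1825L, decade = 3650L)
  unknown <- setdiff(label, names(map))
  if (length(unknown)) stop("unknown delay label(s): ",
                            paste(unknown, collapse = ", "))
  unname(map[label])
}

## Replicate the subtype x (domain x) delay cells of one session.
episodic_cells <- function(variant) {
  delays <- DELAY_SETS[[variant]]
  if (variant == "expB") {
    domains <- "food"
    reps <- c("Obs/Sim" = 6L, "Obs/Obs" = 3L, "Sim/Sim" = 3L)
  } else {
    domains <- c("food", "culture", "sport")
    reps <- c("Obs/Sim" = 4L, "Obs/Obs" = 2L, "Sim/Sim" = 2L)
  }
  cells <- expand.grid(subtype = SUBTYPES, domain = domains,
                       delay_days = unname(delays),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells[rep(seq_len(nrow(cells)), reps[cells$subtype]), , drop = FALSE]
}

## Exact 50/50 counterbalancing of a two-level factor over n trials.
counterbalance <- function(n, levels) {
  stopifnot(n %% 2L == 0L)
  sample(rep(levels, each = n %/% 2L))
}

new_schedule <- function(df, task, variant, session, seed) {
  df$trial_index <- seq_len(nrow(df))
  df$task <- task
  df$variant <- variant
  df$session <- session
  cols <- c("trial_index", "task", "variant", "session", "subtype",
            "condition", "domain", "delay_days", "imm_mode", "del_mode",
            "imm_item", "del_item", "imm_amount", "del_amount",
            "order_flag", "imm_side")
  df <- df[, cols]
  rownames(df) <- NULL
  attr(df, "seed") <- seed
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' Generate an episodic intertemporal-choice session
#'
#' Builds one fully crossed session of the episodic task: each trial
#' opposes an immediate item (delay 0) to a delayed, higher-tier item of
#' the same domain. Variants `"exp1"`/`"exp2"` (and `"expA"`, the
#' choice-only patient version with identical factor structure) produce
#' 72 trials -- 36 Obs/Sim (ecological), 18 Obs/Obs and 18 Sim/Sim
#' (control) -- crossing domain, condition and delay (1 month / 1 year /
#' 10 years) with equal cell frequency. Variant `"expB"` restricts the
#' design to the food domain with delays 1 day / 1 month / 5 years
#' (36 trials: 18 ecological, 9 + 9 control).
#'
#' Item pairs are drawn without replacement from a shuffled per-domain
#' pool; the pool is reshuffled and refilled whenever fewer than two
#' items remain, so a 10-item domain list can serve a whole session.
#' Presentation order and the screen side of the immediate option are
#' counterbalanced exactly 50/50 and the trial order is randomized.
#'
#' @param variant one of `"exp1"`, `"exp2"`, `"expA"`, `"expB"`.
#' @param catalog item catalog (see [default_item_catalog()]).
#' @param seed integer seed; the schedule is a deterministic function of
#'   `(variant, catalog, seed, session)`.
#' @param session session index stored with the schedule.
#' @return a `trial_schedule` data.frame, one row per trial.
#' @examples
#' s <- generate_episodic_schedule("exp2", seed = 1)
#' table(s$subtype)
#' @export
generate_episodic_schedule <- function(variant = c("exp2", "exp1", "expA", "expB"),
                                       catalog = default_item_catalog(),
                                       seed = 1L, session = 1L) {
  variant <- match.arg(variant)
  validate_catalog(catalog)
  cells <- episodic_cells(variant)
  needed <- unique(cells$domain)
  for (d in needed) {
    if (sum(catalog$domain == d) < 2L) {
      stop("catalog too small: fewer than 2 items in domain '", d, "'")
    }
  }
  with_seed(seed, {
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    n <- nrow(cells)
    pools <- lapply(setNames(needed, needed), function(d) {
      sample(which(catalog$domain == d))
    })
    imm_item <- del_item <- character(n)
    for (i in seq_len(n)) {
      d <- cells$domain[i]
      if (length(pools[[d]]) < 2L) {
        pools[[d]] <- sample(which(catalog$domain == d))
      }
      pick <- pools[[d]][1:2]
      pools[[d]] <- pools[[d]][-(1:2)]
      ## delayed option is the more desirable (higher price tier) item
      if (catalog$tier[pick[1]] > catalog$tier[pick[2]]) pick <- rev(pick)
      imm_item[i] <- catalog$item[pick[1]]
      del_item[i] <- catalog$item[pick[2]]
    }
    modes <- t(vapply(cells$subtype, subtype_modes, character(2)))
    df <- data.frame(
      subtype = cells$subtype,
      condition = subtype_condition(cells$subtype),
      domain = cells$domain,
      delay_days = cells$delay_days,
      imm_mode = modes[, "imm"],
      del_mode = modes[, "del"],
      imm_item = imm_item,
      del_item = del_item,
      imm_amount = NA_real_,
      del_amount = NA_real_,
      order_flag = counterbalance(n, c("imm_first", "del_first")),
      imm_side = counterbalance(n, c("left", "right")),
      stringsAsFactors = FALSE
    )
    new_schedule(df, task = "episodic", variant = variant,
                 session = session, seed = seed)
  })
}

#' Generate a monetary intertemporal-choice session
#'
#' One 72-trial session of the monetary task. Immediate payoffs are a
#' without-replacement draw from the 0.5, 1, ..., 36 euro grid (72 values,
#' each used exactly once); the delayed payoff adds an extra amount drawn
#' without replacement from 1, 2, ..., 36 euros -- the 36-element extras
#' vector is refilled once, so each extra occurs exactly twice across the
#' session. Subtype and delay are fully crossed as in the episodic task.
#'
#' @inheritParams generate_episodic_schedule
#' @param variant `"exp1"` or `"exp2"` (the monetary task was only run in
#'   the healthy-subject experiments).
#' @return a `trial_schedule` data.frame.
#' @examples
#' m <- generate_monetary_schedule("exp2", seed = 3)
#' range(m$imm_amount)
#' @export
generate_monetary_schedule <- function(variant = c("exp2", "exp1"),
                                       seed = 1L, session = 1L) {
  variant <- match.arg(variant)
  delays <- DELAY_SETS[[variant]]
  reps <- c("Obs/Sim" = 12L, "Obs/Obs" = 6L, "Sim/Sim" = 6L)
  cells <- expand.grid(subtype = SUBTYPES, delay_days = unname(delays),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[rep(seq_len(nrow(cells)), reps[cells$subtype]), , drop = FALSE]
  with_seed(seed, {
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    n <- nrow(cells) # 72
    imm <- sample(seq(0.5, 36, by = 0.5)) # 72 values, no replacement
    extra <- c(sample(1:36), sample(1:36)) # refilled once at block scale
    modes <- t(vapply(cells$subtype, subtype_modes, character(2)))
    df <- data.frame(
      subtype = cells$subtype,
      condition = subtype_condition(cells$subtype),
      domain = "monetary",
      delay_days = cells$delay_days,
      imm_mode = modes[, "imm"],
      del_mode = modes[, "del"],
      imm_item = NA_character_,
      del_item = NA_character_,
      imm_amount = imm,
      del_amount = imm + extra,
      order_flag = counterbalance(n, c("imm_first", "del_first")),
      imm_side = counterbalance(n, c("left", "right")),
      stringsAsFactors = FALSE
    )
    new_schedule(df, task = "monetary", variant = variant,
                 session = session, seed = seed)
  })
}

#' Validate a trial schedule against its design invariants
#'
#' Checks every design invariant the generators promise (trial count,
#' subtype split, condition/mode consistency, delay and domain balance,
#' payoff grids, counterbalancing) and reports each as pass/fail with the
#' offending trial indices. Always returns a report, never throws.
#'
#' @param schedule a `trial_schedule` (or equivalent data.frame).
#' @return a data.frame with columns `check`, `pass`, `detail`, of class
#'   `schedule_validation`.
#' @examples
#' all(validate_schedule(generate_episodic_schedule("exp2", seed = 1))$pass)
#' @export
validate_schedule <- function(schedule) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  s <- as.data.frame(schedule)
  task <- s$task[1]
  variant <- s$variant[1]
  n_expected <- if (identical(variant, "expB")) 36L else 72L
  add("trial_count", nrow(s) == n_expected,
      sprintf("expected %d, found %d", n_expected, nrow(s)))

  tab <- table(factor(s$subtype, levels = SUBTYPES))
  exp_tab <- round(n_expected * c(1, 0.5, 0.5) / 2)
  add("subtype_split", all(tab == exp_tab),
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "))

  bad_cond <- which(s$condition != subtype_condition(s$subtype))
  add("condition_consistency", length(bad_cond) == 0L,
      if (length(bad_cond)) paste("trials", paste(bad_cond, collapse = ",")) else "")

  exp_modes <- t(vapply(s$subtype, subtype_modes, character(2)))
  bad_mode <- which(s$imm_mode != exp_modes[, "imm"] |
                    s$del_mode != exp_modes[, "del"])
  add("mode_consistency", length(bad_mode) == 0L,
      if (length(bad_mode)) paste("trials", paste(bad_mode, collapse = ",")) else "")

  delays <- DELAY_SETS[[variant]] %||% integer()
  add("delay_set", all(s$delay_days %in% delays) && all(s$delay_days > 0),
      paste(sort(unique(s$delay_days)), collapse = ","))
  bal <- tapply(seq_len(nrow(s)), list(s$subtype, s$delay_days), length)
  add("delay_balance_within_subtype",
      all(apply(bal, 1, function(x) length(unique(x)) == 1L)), "")

  ## equal Obs and Sim option totals in ecological vs control conditions
  opt_modes <- data.frame(cond = rep(s$condition, 2L),
                          mode = c(s$imm_mode, s$del_mode))
  mm <- table(opt_modes$cond, opt_modes$mode)
  add("obs_sim_balance_across_conditions",
      nrow(mm) == 2L && all(mm["ecological", ] == mm["control", ]),
      paste(capture_table(mm), collapse = "; "))

  add("counterbalance_order",
      sum(s$order_flag == "imm_first") == nrow(s) %/% 2L, "")
  add("counterbalance_side",
      sum(s$imm_side == "left") == nrow(s) %/% 2L, "")

  if (identical(task, "episodic")) {
    dom_bal <- table(s$domain)
    add("domain_balance", length(unique(dom_bal)) == 1L,
        paste(names(dom_bal), dom_bal, sep = "=", collapse = ", "))
    bad_pair <- which(s$imm_item == s$del_item)
    add("distinct_items_within_trial", length(bad_pair) == 0L,
        if (length(bad_pair)) paste("trials", paste(bad_pair, collapse = ",")) else "")
  }
  if (identical(task, "monetary")) {
    grid <- seq(0.5, 36, by = 0.5)
    add("immediate_on_grid", all(s$imm_amount %in% grid), "")
    add("immediate_distinct", !any(duplicated(s$imm_amount)), "")
    extras <- s$del_amount - s$imm_amount
    add("extra_in_1_36", all(extras >= 1 & extras <= 36), "")
    add("extras_twice_each",
        all(table(factor(extras, levels = 1:36)) == 2L), "")
  }
  out <- do.call(rbind, checks)
  class(out) <- c("schedule_validation", "data.frame")
  out
}

capture_table <- function(tab) {
  paste(rep(rownames(tab), each = ncol(tab)),
        rep(colnames(tab), nrow(tab)),
        as.integer(t(tab)), sep = ":")
}

#' Write / read a schedule as CSV
#'
#' UTF-8, comma separated, header row, dot decimal; two writes of the
#' same schedule are byte-identical.
#'
#' @param schedule a `trial_schedule`.
#' @param path file path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` returns a `trial_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE,
            quote = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s task, variant %s, session %s: %d trials\n",
              x$task[1], x$variant[1], x$session[1], nrow(x)))
  tab <- table(x$subtype)
  cat("  subtypes:", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  print(head(as.data.frame(x), 4L))
  invisible(x)
}
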