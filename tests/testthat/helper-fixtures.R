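# Shared fixtures: all synthetic, generated in code at test time.

# A tiny catalog with two items per domain (the legal minimum).
tiny_catalog <- function() {
  data.frame(
    domain = rep(c("food", "culture", "sport"), each = 2L),
    item = paste0("item", 1:6),
    tier = rep(c(1L, 2L), times = 3L),
    stringsAsFactors = FALSE
  )
}

# Valued trials with choices generated by an agent with true (k, beta)
# over `sessions` episodic sessions (72 trials each).
make_recovery_trials <- function(k, beta, seed, sessions = 10L) {
  agent <- agent_params(k = k, beta = beta, delta_sim = 0)
  ratings <- simulate_ratings_and_richness(agent, seed = substream_seed(seed, "ratings"))
  do.call(rbind, lapply(seq_len(sessions), function(s) {
    sch <- generate_episodic_schedule("exp2",
                                      seed = substream_seed(seed, paste0("sch", s)),
                                      session = s)
    ch <- simulate_choices(agent, sch, ratings,
                           seed = substream_seed(seed, paste0("ch", s)))
    valued_trials(sch, ratings, choices = ch)
  }))
}

# Hand-specifiable valued-trial table.
vt <- function(Vi, R_d, D, choice) {
  data.frame(Vi = Vi, R_d = R_d, D = D, choice = choice,
             stringsAsFactors = FALSE)
}
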