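# Small shared fixtures, built in code at test time.

# A tiny response table with two hand-built participants for the exclusion
# and fitting tests: one well-behaved, one constant responder.
tiny_responses <- function() {
  x <- rep(c(1, 2, 3), each = 4)
  tibble::tibble(
    participant_id = rep(c("ok", "flat"), each = 12 + 2),
    kind = rep(c(rep("testing", 12), rep("probe", 2)), 2),
    task = "judgment",
    x_value = rep(c(x, NA, NA), 2),
    response = c(c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1, 1), NA, NA,
                 rep(1L, 12), NA, NA),
    probe_correct = rep(c(rep(NA, 12), TRUE, TRUE), 2)
  )
}

tiny_participants <- function() {
  tibble::tibble(
    participant_id = c("ok", "flat"),
    msi = c(80, 90),
    completed = TRUE, questionnaire = TRUE, headphone_pass = TRUE
  )
}

# Low-rate synthesis settings that keep audio tests fast.
fast_synth <- list(rate = 8000, duration = 4, extract = 2, env_rate = 1000)
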