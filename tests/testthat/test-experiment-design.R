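test_that("condition grids carry the published design arithmetic", {
  g1 <- condition_grid(1)
  expect_equal(nrow(g1), 10)
  expect_equal(attr(g1, "draws") * nrow(g1), 150)
  expect_equal(attr(g1, "pool_size"), 100)
  expect_equal(range(g1$m_hz), c(0.6, 6))
  expect_true(all(g1$sigma == 0.35))

  g2 <- condition_grid(2)
  expect_equal(nrow(g2), 15)
  expect_setequal(unique(g2$m_hz), c(1, 2.5, 4))
  expect_equal(attr(g2, "draws") * nrow(g2), 150)
  expect_equal(attr(g2, "pool_size"), 50)

  g3 <- condition_grid(3)
  expect_equal(nrow(g3) * attr(g3, "draws"), 75)

  g4 <- condition_grid(4)
  expect_true(all(g4$m_hz == 2))
  expect_equal(nrow(g4) * attr(g4, "draws"), 75)

  expect_error(condition_grid(5), "1, 2, 3 or 4")
  expect_error(condition_grid(1, draws = 7), "unique stimuli")
})

test_that("judgment-experiment schedules present each stimulus once per half", {
  s <- build_schedule(condition_grid(1), seed = 21)
  testing <- dplyr::filter(s, kind == "testing")
  expect_equal(nrow(testing), 300)
  counts <- table(testing$stimulus_id, testing$half)
  expect_true(all(counts == 1))
  expect_equal(sum(s$kind == "probe"), 12)
  expect_equal(sum(s$kind == "practice"), 4)
  # breaks every 10 testing trials
  expect_equal(sum(s$break_after), 30)
  # practice levels are inside but not equal to the tested levels
  pr <- dplyr::filter(s, kind == "practice")
  expect_true(all(pr$m_hz > 0.6 & pr$m_hz < 6))
  expect_false(any(pr$m_hz %in% testing$m_hz))
})

test_that("detection-experiment schedules reuse the same stimuli across 4 blocks", {
  s <- build_schedule(condition_grid(3), seed = 22)
  testing <- dplyr::filter(s, kind == "testing")
  expect_equal(nrow(testing), 300)
  expect_equal(sum(testing$task == "music"), 150)
  expect_equal(sum(testing$task == "speech"), 150)
  # every stimulus appears exactly once per block
  expect_true(all(table(testing$stimulus_id, testing$block) == 1))
  # identical condition multiset across blocks
  per_block <- split(testing$condition, testing$block)
  expect_true(all(vapply(per_block[-1], function(b) {
    identical(sort(b), sort(per_block[[1]]))
  }, logical(1))))
  # each half holds one block of each task
  expect_equal(unname(as.matrix(table(testing$task, testing$half))),
               matrix(75L, 2, 2))
  # two practice phases: one before the first block of each task
  expect_equal(sum(s$kind == "practice"), 8)
})

test_that("schedule counts are seed-invariant while orderings are not", {
  a <- build_schedule(condition_grid(1), seed = 1)
  b <- build_schedule(condition_grid(1), seed = 2)
  expect_identical(table(a$kind), table(b$kind))
  expect_false(identical(a$stimulus_id, b$stimulus_id))
  # determinism for a fixed seed
  expect_identical(tibble::as_tibble(a),
                   tibble::as_tibble(build_schedule(condition_grid(1), seed = 1)))
})

test_that("probes are roughly evenly spaced over the session", {
  for (seed in 1:10) {
    s <- build_schedule(condition_grid(1), seed = seed)
    pos <- cumsum(s$kind == "testing")[s$kind == "probe"]
    gaps <- diff(pos)
    expect_lte(max(gaps), 2 * mean(gaps))
  }
})

test_that("probe trials fit 1-4 non-overlapping tones into a 2-s window", {
  n_tones <- integer(0)
  for (seed in 1:1000) {
    p <- make_probe_trial(seed)
    n_tones <- c(n_tones, p$n_tones)
    expect_true(all(p$onsets >= 0 & p$onsets <= 2 - p$tone_dur))
    if (p$n_tones > 1) expect_true(all(diff(p$onsets) >= p$tone_dur))
  }
  expect_setequal(unique(n_tones), 1:4)
  expect_identical(make_probe_trial(77), make_probe_trial(77))
})
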