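test_that("MAD threshold matches hand computation", {
  # median 340, raw MAD 20, scaled 29.652 -> 340 + 2.5 * 29.652
  expect_equal(mad_upper_threshold(c(300, 320, 340, 360, 2000)), 414.13)
  expect_equal(mad_upper_threshold(c(300, 320, 340, 360, 2000), constant = 1),
               340 + 2.5 * 20)
  expect_equal(mad_upper_threshold(c(7, 7, 7)), 7)         # zero MAD
  expect_equal(mad_upper_threshold(c(1, 2, 9), multiplier = 0), 2)
  expect_error(mad_upper_threshold(500), "at least 2")
})

test_that("both exclusion rules partition a subject's trials", {
  tr <- data.frame(subject_id = "a", task = "flange",
                   rt_ms = c(300, 320, 340, 360, 2000, 150))
  res <- filter_trials(tr)
  expect_setequal(res$retained$rt_ms, c(300, 320, 340, 360))
  expect_equal(res$excluded$exclusion_reason[res$excluded$rt_ms == 2000],
               "slow")
  expect_equal(res$excluded$exclusion_reason[res$excluded$rt_ms == 150],
               "fast")
  rp <- res$reports[[1]]
  expect_equal(rp$n_collected, 6)
  expect_equal(rp$n_excluded_fast + rp$n_excluded_slow + rp$n_retained,
               rp$n_collected)
  # threshold computed on the full batch, before the floor rule
  expect_equal(rp$threshold_ms, mad_upper_threshold(tr$rt_ms))
})

test_that("degenerate inputs are handled explicitly", {
  empty <- data.frame(subject_id = character(0), task = character(0),
                      rt_ms = numeric(0))
  res <- filter_trials(empty)
  expect_equal(nrow(res$retained), 0)
  expect_equal(res$report$n_collected, 0)

  inrange <- data.frame(subject_id = "a", task = "flange",
                        rt_ms = c(300, 310, 320, 330))
  expect_equal(nrow(filter_trials(inrange)$retained), 4)  # no-op case

  single <- data.frame(subject_id = "b", task = "flange", rt_ms = 400)
  res1 <- filter_trials(single)
  expect_true(res1$reports[[1]]$unfilterable)
  expect_equal(nrow(res1$retained), 1)  # kept, not silently dropped
})

test_that("retained trials always sit inside their subject's window", {
  # re-applying the recorded thresholds to the retained set removes nothing
  set.seed(42)
  tr <- data.frame(subject_id = rep(c("a", "b"), each = 60),
                   task = "flange",
                   rt_ms = c(rnorm(60, 500, 60), rexp(60, 1 / 400) + 100))
  res <- filter_trials(tr)
  for (rp in res$reports) {
    kept <- res$retained$rt_ms[res$retained$subject_id == rp$subject_id]
    expect_true(all(kept >= 200 & kept <= rp$threshold_ms))
  }
})

test_that("a larger multiplier never shrinks the retained set", {
  set.seed(7)
  tr <- data.frame(subject_id = rep("a", 80), task = "flange",
                   rt_ms = rlnorm(80, log(450), 0.5),
                   row_id = 1:80)
  kept25 <- filter_trials(tr, multiplier = 2.5)$retained$row_id
  kept35 <- filter_trials(tr, multiplier = 3.5)$retained$row_id
  expect_true(all(kept25 %in% kept35))
})

test_that("filter accounting always sums, on random tables", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:60, 1)
    tr <- data.frame(subject_id = sample(letters[1:3], n, TRUE),
                     task = sample(c("flange", "symmetry"), n, TRUE),
                     rt_ms = rlnorm(n, log(400), 0.8))
    res <- filter_trials(tr)
    expect_equal(nrow(res$retained) + nrow(res$excluded), n)
    for (rp in res$reports)
      expect_equal(rp$n_excluded_fast + rp$n_excluded_slow + rp$n_retained,
                   rp$n_collected)
    expect_equal(res$report$n_collected, n)
  }
})

test_that("injected anticipatory trials are exactly the fast exclusions", {
  plan <- schedule_dotprobe(stimulus_pairs(72, "flange"), 6, 24, seed = 1)
  p <- dotprobe_gen_params(intercept_ms = 600, resid_scale_ms = 30,
                           p_anticipatory = 0.08, p_slow = 0)
  tr <- simulate_dotprobe(plan, p, seed = 2)
  res <- filter_trials(tr)
  expect_equal(res$report$n_excluded_fast, sum(tr$is_anticipatory))
})

test_that("repetition round merges into the final dataset", {
  plan <- schedule_dotprobe(stimulus_pairs(72, "flange"), 6, 24, seed = 3)
  p <- dotprobe_gen_params()
  tr <- simulate_dotprobe(plan, p, subject_id = "kawan", seed = 4)
  primary <- filter_trials(tr)
  rep_tr <- simulate_dotprobe(repetition_plan(primary$excluded, "R1"), p,
                              subject_id = "kawan", seed = 5)
  repetition <- filter_trials(rep_tr)
  merged <- merge_repetitions(primary, repetition)
  expect_equal(nrow(merged$trials),
               nrow(primary$retained) + nrow(repetition$retained))
  expect_equal(merged$report$n_retained, nrow(merged$trials))
  expect_equal(merged$report$n_collected,
               primary$report$n_collected + repetition$report$n_collected)
  expect_true(any(merged$trials$is_repetition))

  # empty repetition set: final dataset is just the primary retained trials
  empty_rep <- filter_trials(tr[0, ])
  merged0 <- merge_repetitions(primary, empty_rep)
  expect_equal(nrow(merged0$trials), nrow(primary$retained))
})

test_that("unmatched repetition trials are warned about but kept", {
  plan <- schedule_dotprobe(stimulus_pairs(4, "flange"), 1, 8, seed = 6)
  p <- dotprobe_gen_params(p_anticipatory = 0, p_slow = 0)
  tr <- simulate_dotprobe(plan, p, seed = 7)
  primary <- filter_trials(tr)          # nothing excluded
  stray <- simulate_dotprobe(repetition_plan(tr[1, ], "R1"), p, seed = 8)
  repetition <- filter_trials(stray)
  expect_warning(merged <- merge_repetitions(primary, repetition),
                 "no matching excluded")
  expect_equal(nrow(merged$trials),
               nrow(primary$retained) + nrow(repetition$retained))
})

test_that("published-style accounting combines across rounds", {
  primary <- filter_report(n_collected = 423, n_excluded = 96)
  repetition <- filter_report(n_collected = 105, n_excluded = 28)
  combined <- combine_filter_reports(primary, repetition)
  expect_equal(combined$n_retained, 404)
  expect_equal(exclusion_rate(primary), 22.69, tolerance = 0.001)
})
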