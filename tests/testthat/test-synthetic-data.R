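test_that("dot-probe schedules probe every pair twice with opposite congruence", {
  cases <- list(list(pairs = 72, sessions = 6, tps = 24, trials = 144),
                list(pairs = 80, sessions = 8, tps = 20, trials = 160),
                list(pairs = 1, sessions = 1, tps = 2, trials = 2))
  for (cs in cases) {
    plan <- schedule_dotprobe(stimulus_pairs(cs$pairs, "flange"),
                              cs$sessions, cs$tps, seed = 11)
    expect_equal(nrow(plan), cs$trials)
    expect_true(all(table(plan$pair_id) == 2))
    cong_per_pair <- tapply(plan$congruence, plan$pair_id,
                            function(x) sort(unique(x)))
    expect_true(all(vapply(cong_per_pair, identical, logical(1),
                           c("congruent", "incongruent"))))
    expect_true(all(table(plan$session_id) == cs$tps))
  }
})

test_that("schedule rejects a session grid that does not match the pairs", {
  expect_error(schedule_dotprobe(stimulus_pairs(72, "flange"), 6, 23, seed = 1),
               "twice the number of pairs")
})

test_that("probe sides are balanced within each session up to rounding", {
  plan <- schedule_dotprobe(stimulus_pairs(80, "symmetry"), 8, 20, seed = 3)
  for (s in unique(plan$session_id)) {
    sides <- table(plan$probe_side[plan$session_id == s])
    expect_lte(abs(sides[["left"]] - sides[["right"]]), 1)
  }
})

test_that("simulation is byte-identical under the same seed", {
  plan <- schedule_dotprobe(stimulus_pairs(10, "flange"), 2, 10, seed = 4)
  p <- dotprobe_gen_params()
  expect_identical(simulate_dotprobe(plan, p, seed = 9),
                   simulate_dotprobe(plan, p, seed = 9))
  plan2 <- schedule_preference(c("a", "b"), seed = 5)
  cp <- choice_gen_params()
  expect_identical(simulate_choices(plan2, cp, seed = 9),
                   simulate_choices(plan2, cp, seed = 9))
})

test_that("sum coding doubles the congruence gap on the condition scale", {
  # large balanced schedule so the empirical contrast is precise
  plan <- schedule_dotprobe(stimulus_pairs(5000, "flange"), 2, 5000, seed = 6)
  p0 <- dotprobe_gen_params(b_congruent_ms = 0, session_sd_ms = 0,
                            p_anticipatory = 0, p_slow = 0)
  tr0 <- simulate_dotprobe(plan, p0, seed = 7)
  gap0 <- mean(tr0$rt_ms[tr0$congruence == "congruent"]) -
    mean(tr0$rt_ms[tr0$congruence == "incongruent"])
  expect_lt(abs(gap0), 3)  # ~3 MC standard errors of the null gap

  p10 <- dotprobe_gen_params(b_congruent_ms = -10, session_sd_ms = 0,
                             p_anticipatory = 0, p_slow = 0)
  tr10 <- simulate_dotprobe(plan, p10, seed = 7)
  gap10 <- mean(tr10$rt_ms[tr10$congruence == "congruent"]) -
    mean(tr10$rt_ms[tr10$congruence == "incongruent"])
  expect_lt(abs(gap10 - (-20)), 3)
})

test_that("anticipatory contamination hits the expected share of trials", {
  plan <- schedule_dotprobe(stimulus_pairs(500, "flange"), 2, 500, seed = 8)
  p <- dotprobe_gen_params(intercept_ms = 600, resid_scale_ms = 30,
                           p_anticipatory = 0.1, p_slow = 0)
  tr <- simulate_dotprobe(plan, p, seed = 9)
  n_fast <- sum(tr$rt_ms < 200)
  expect_true(abs(n_fast - 100) < 40)          # ~4 binomial SDs around 100
  expect_true(all(tr$rt_ms[tr$is_anticipatory] < 200))
  expect_identical(n_fast, sum(tr$is_anticipatory))  # clean RTs never dip
})

test_that("clean RTs match the Student-t location at n = 1e4", {
  plan <- schedule_dotprobe(stimulus_pairs(5000, "flange"), 2, 5000, seed = 10)
  p <- dotprobe_gen_params(b_congruent_ms = 0, b_left_ms = 0,
                           session_sd_ms = 0, p_anticipatory = 0, p_slow = 0)
  tr <- simulate_dotprobe(plan, p, seed = 11)
  # SE of the sample median of a t(8) location-scale family at this n is
  # ~0.52 ms (1 / (2 f(0) sqrt(n))); allow 3 SE
  expect_lt(abs(median(tr$rt_ms) - p$intercept_ms), 1.6)
})

test_that("preference plan has the full blocked design", {
  plan <- schedule_preference(sprintf("s%d", 1:6), seed = 12)
  expect_equal(nrow(plan), 864)
  expect_equal(sum(plan$phase == "choice"), 576)
  expect_equal(unname(table(plan$order[!duplicated(plan$subject_id)])),
               c(3L, 3L), ignore_attr = TRUE)
  expect_true(all(abs(plan$flanged_dot_height) <= 0.35))
  for (s in unique(plan$subject_id)) {
    d <- plan[plan$subject_id == s, ]
    # 8 forced trials (4 per colour) precede 16 choice trials per session
    for (sess in unique(d$session_id)) {
      ds <- d[d$session_id == sess, ]
      ds <- ds[order(ds$trial_index), ]
      expect_identical(ds$phase, rep(c("forced", "choice"), c(8L, 16L)))
      expect_equal(sum(ds$forced_colour == "red", na.rm = TRUE), 4)
    }
    # blocks contiguous: 3 sessions of one colour coding then 3 of the other
    blocks <- d$block[!duplicated(paste(d$session_id))]
    expect_equal(rle(blocks)$lengths, c(3L, 3L))
  }
})

test_that("dot heights are centred by the circular placement geometry", {
  plan <- schedule_preference(sprintf("s%d", 1:40), seed = 13)
  h <- plan$flanged_dot_height
  # E[0.35 cos(U)] = 0, SD = 0.35/sqrt(2); allow 3 SE of the mean
  expect_lt(abs(mean(h)), 3 * 0.35 / sqrt(2) / sqrt(length(h)))
})

test_that("null generator yields chance-level choices across seeds", {
  plan <- schedule_preference(sprintf("s%d", 1:105), seed = 14)  # 10080 choices
  p <- choice_gen_params(subject_sd = 0, session_sd = 0, colour_slope_sd = 0)
  ok <- vapply(1:20, function(seed) {
    tr <- simulate_choices(plan, p, seed = 1000 + seed)
    prop <- mean(tr$choice[tr$phase == "choice"])
    prop >= 0.48 && prop <= 0.52
  }, logical(1))
  expect_gte(sum(ok), 19)  # >= 95% of seeds
})

test_that("height effect drives choices at the covariate extremes", {
  plan <- schedule_preference(sprintf("s%d", 1:30), seed = 15)
  p <- choice_gen_params(b_height = log(17.01) / 0.7,
                         subject_sd = 0, session_sd = 0, colour_slope_sd = 0)
  tr <- simulate_choices(plan, p, seed = 16)
  ch <- tr[tr$phase == "choice", ]
  hi <- mean(ch$choice[ch$flanged_dot_height > 0.3])
  lo <- mean(ch$choice[ch$flanged_dot_height < -0.3])
  expect_gt(hi, 0.7)
  expect_lt(lo, 0.3)
})

test_that("forced trials deterministically follow the colour mapping", {
  plan <- schedule_preference(c("a", "b"), seed = 17)
  tr <- simulate_choices(plan, choice_gen_params(), seed = 18)
  forced <- tr[tr$phase == "forced", ]
  expect_identical(forced$choice,
                   as.integer(forced$forced_colour == forced$flanged_colour))
})
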