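#' Build a stimulus-pair table
#'
#' Each row is one pair of male-face stimulus versions shown together in the
#' dot-probe task. For the flange task the two versions differ in cheek-pad
#' (flange) width and the absolute width difference is carried as a covariate
#' for the sensitivity analysis; the symmetry task has no width covariate.
#'
#' @param n Number of pairs (72 for the flange task, 80 for symmetry).
#' @param task `"flange"` or `"symmetry"`.
#' @param width_diff Optional numeric vector of absolute width differences in
#'   pixels (flange task only); defaults to evenly spaced values in [2, 60].
#' @return data.frame with columns `pair_id`, `task`, `width_diff`.
#' @export
stimulus_pairs <- function(n, task = c("flange", "symmetry"),
                           width_diff = NULL) {
  task <- match.arg(task)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (task == "symmetry") {
    if (!is.null(width_diff))
      stop("width_diff applies to the flange task only")
    wd <- rep(NA_real_, n)
  } else {
    wd <- if (is.null(width_diff)) seq(2, 60, length.out = n) else width_diff
    if (length(wd) != n || any(wd < 0))
      stop("width_diff must be nonnegative, one value per pair")
  }
  data.frame(pair_id = sprintf("%s_pair%02d", task, seq_len(n)),
             task = task, width_diff = wd, stringsAsFactors = FALSE)
}

#' Generator truth for dot-probe reaction times
#'
#' Parameters of the generative model mirrored by the analysis model:
#' RT (ms) = `intercept_ms` + `b_congruent_ms` * c + `b_left_ms` * l
#' + session effect + Student-t noise, with c, l sum-coded +/-1
#' (congruent = +1, left = +1). A negative `b_congruent_ms` makes congruent
#' trials faster; on the condition scale the congruent-incongruent gap is
#' twice the coefficient. Contamination mimics what the filtering stage must
#' remove: anticipatory responses (RT replaced by Uniform(50, 199) ms) and
#' slow outliers (RT shifted by `slow_shift_ms`).
#'
#' @param intercept_ms Baseline RT in ms.
#' @param b_congruent_ms Sum-coded congruence effect (ms).
#' @param b_left_ms Sum-coded probe-side effect (ms).
#' @param session_sd_ms SD of session-level intercept deviations (ms).
#' @param resid_scale_ms Scale of the Student-t residual (ms).
#' @param resid_df Residual degrees of freedom (> 2 so the variance exists).
#' @param p_anticipatory,p_slow Contamination probabilities (sum <= 1).
#' @param slow_shift_ms Shift added to slow-outlier trials (ms).
#' @return List of class `dotprobe_gen_params`.
#' @export
dotprobe_gen_params <- function(intercept_ms = 500, b_congruent_ms = 0,
                                b_left_ms = 0, session_sd_ms = 10,
                                resid_scale_ms = 40, resid_df = 8,
                                p_anticipatory = 0.05, p_slow = 0.05,
                                slow_shift_ms = 600) {
  stopifnot(resid_scale_ms > 0, resid_df > 2, session_sd_ms >= 0,
            slow_shift_ms > 0,
            p_anticipatory >= 0, p_anticipatory <= 1,
            p_slow >= 0, p_slow <= 1)
  if (p_anticipatory + p_slow > 1)
    stop("p_anticipatory + p_slow must not exceed 1")
  structure(as.list(environment()), class = "dotprobe_gen_params")
}

#' Generator truth for preference choices
#'
#' Parameters of the Bernoulli generative model mirrored by the preference
#' analysis model, on the logit scale with sum coding (green = +1,
#' red_first = +1): P(choice = flanged) =
#' logistic(intercept + b_green g + b_order o + b_height height
#' + subject effect + session-in-subject effect + subject colour slope * g).
#'
#' @param logit_intercept Intercept (logit).
#' @param b_green Sum-coded colour effect (logit).
#' @param b_order Sum-coded order effect (logit).
#' @param b_height Effect per unit of dot height; the observable height range
#'   spans 0.7 units (-0.35 to 0.35).
#' @param subject_sd,session_sd,colour_slope_sd Random-effect SDs (>= 0).
#' @return List of class `choice_gen_params`.
#' @export
choice_gen_params <- function(logit_intercept = 0, b_green = 0, b_order = 0,
                              b_height = 0, subject_sd = 0.3,
                              session_sd = 0.2, colour_slope_sd = 0.2) {
  stopifnot(subject_sd >= 0, session_sd >= 0, colour_slope_sd >= 0)
  structure(as.list(environment()), class = "choice_gen_params")
}

#' Schedule dot-probe trials over sessions
#'
#' Every stimulus pair is probed exactly twice across the whole schedule:
#' once congruently (probe behind the large-flange / symmetrised version)
#' and once incongruently. The session grid must therefore hold exactly
#' `2 * nrow(pairs)` trials. Trial order is randomised by `seed` and probe
#' sides are balanced within each session up to rounding.
#'
#' @param pairs data.frame from [stimulus_pairs()].
#' @param n_sessions Number of sessions.
#' @param trials_per_session Trials per session.
#' @param seed Integer seed.
#' @return data.frame (plan) with columns `session_id`, `trial_index`,
#'   `pair_id`, `task`, `width_diff`, `congruence`, `probe_side`.
#' @examples
#' plan <- schedule_dotprobe(stimulus_pairs(72, "flange"), 6, 24, seed = 1)
#' nrow(plan)                     # 144
#' table(table(plan$pair_id))     # every pair exactly twice
#' @export
schedule_dotprobe <- function(pairs, n_sessions, trials_per_session, seed) {
  n_sessions <- as.integer(n_sessions)
  trials_per_session <- as.integer(trials_per_session)
  n_trials <- n_sessions * trials_per_session
  if (n_trials != 2L * nrow(pairs))
    stop(sprintf(paste0("session grid (%d sessions x %d trials = %d) must ",
                        "equal twice the number of pairs (2 x %d = %d)"),
                 n_sessions, trials_per_session, n_trials,
                 nrow(pairs), 2L * nrow(pairs)))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  plan <- data.frame(
    pair_id = rep(pairs$pair_id, 2L),
    task = pairs$task[1L],
    width_diff = rep(pairs$width_diff, 2L),
    congruence = rep(c("congruent", "incongruent"), each = nrow(pairs)),
    stringsAsFactors = FALSE)
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
  plan$session_id <- rep(sprintf("S%d", seq_len(n_sessions)),
                         each = trials_per_session)
  plan$trial_index <- rep(seq_len(trials_per_session), n_sessions)
  # balanced probe sides within session, order shuffled
  plan$probe_side <- unlist(lapply(seq_len(n_sessions), function(s) {
    k <- trials_per_session
    sides <- rep(c("left", "right"), length.out = k)
    sample(sides)
  }), use.names = FALSE)
  rownames(plan) <- NULL
  plan[, c("session_id", "trial_index", "pair_id", "task", "width_diff",
           "congruence", "probe_side")]
}

#' Simulate dot-probe reaction times for a planned schedule
#'
#' Draws one RT per planned trial from the location-scale Student-t model in
#' [dotprobe_gen_params()], then contaminates trials: with probability
#' `p_anticipatory` the RT is replaced by a Uniform(50, 199) ms anticipatory
#' response, else with probability `p_slow` it is shifted upward by
#' `slow_shift_ms`. A simulated RT below 50 ms is clipped to 50 ms and
#' flagged in `clipped`. The same (plan, params, seed) always reproduces the
#' identical table.
#'
#' @param plan Schedule from [schedule_dotprobe()].
#' @param params A [dotprobe_gen_params()] object.
#' @param subject_id Subject label attached to all trials.
#' @param seed Integer seed.
#' @return data.frame of trials with the plan columns plus `subject_id`,
#'   `rt_ms`, `is_repetition` (FALSE) and the generator-truth flags
#'   `is_anticipatory`, `is_slow`, `clipped`.
#' @export
simulate_dotprobe <- function(plan, params, subject_id = "subj1", seed = 1) {
  stopifnot(inherits(params, "dotprobe_gen_params"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- nrow(plan)
  sessions <- unique(plan$session_id)
  sess_eff <- stats::rnorm(length(sessions), 0, params$session_sd_ms)
  names(sess_eff) <- sessions
  cc <- ifelse(plan$congruence == "congruent", 1, -1)
  ll <- ifelse(plan$probe_side == "left", 1, -1)
  rt <- params$intercept_ms + params$b_congruent_ms * cc +
    params$b_left_ms * ll + sess_eff[plan$session_id] +
    params$resid_scale_ms * stats::rt(n, df = params$resid_df)
  u <- stats::runif(n)
  is_ant <- u < params$p_anticipatory
  is_slow <- !is_ant & u < params$p_anticipatory + params$p_slow
  rt[is_ant] <- stats::runif(sum(is_ant), 50, 199)
  rt[is_slow] <- rt[is_slow] + params$slow_shift_ms
  clipped <- rt < 50
  rt[clipped] <- 50
  out <- plan
  out$subject_id <- subject_id
  out$rt_ms <- as.numeric(rt)
  out$is_repetition <- FALSE
  out$is_anticipatory <- is_ant
  out$is_slow <- is_slow
  out$clipped <- clipped
  rownames(out) <- NULL
  out[, c("subject_id", "session_id", "trial_index", "task", "congruence",
          "probe_side", "rt_ms", "pair_id", "width_diff", "is_repetition",
          "is_anticipatory", "is_slow", "clipped")]
}

#' Build a repetition-session plan for excluded trials
#'
#' After filtering, excluded dot-probe trials are re-run in subject-specific
#' repetition sessions. This rebuilds a plan (same pair, congruence and probe
#' side) for those trials under a fresh session label so they can be
#' re-simulated and re-filtered.
#'
#' @param excluded data.frame of excluded trials (from [filter_trials()]).
#' @param session_id Label for the repetition session.
#' @return Plan data.frame accepted by [simulate_dotprobe()].
#' @export
repetition_plan <- function(excluded, session_id = "R1") {
  if (nrow(excluded) == 0L)
    return(excluded[, c("session_id", "trial_index", "pair_id", "task",
                        "width_diff", "congruence", "probe_side")])
  plan <- excluded[, c("pair_id", "task", "width_diff", "congruence",
                       "probe_side")]
  plan$session_id <- session_id
  plan$trial_index <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  plan[, c("session_id", "trial_index", "pair_id", "task", "width_diff",
           "congruence", "probe_side")]
}

#' Schedule the two-alternative preference experiment
#'
#' Each subject receives 6 sessions in two contiguous blocks of 3: in one
#' block the flanged-male stimuli are announced by red dots, in the other by
#' green dots. Subjects alternate order group (red block first vs green
#' block first), so 6 subjects split 3/3. A session holds 8 forced trials
#' (4 per colour, teaching the colour-to-category mapping) followed by 16
#' choice trials. The vertical position of the dot that represents the
#' flanged stimulus follows the circular opposite-placement geometry:
#' height = 0.35 * cos(phi), phi ~ Uniform(0, 2*pi), so heights lie in
#' [-0.35, 0.35] with mean zero (negative = higher on screen).
#'
#' @param subjects Character vector of subject identifiers.
#' @param seed Integer seed.
#' @return data.frame of plan entries: `subject_id`, `session_id`, `block`,
#'   `order`, `phase`, `trial_index`, `flanged_colour`, `forced_colour`
#'   (NA on choice trials), `flanged_dot_height`.
#' @examples
#' plan <- schedule_preference(sprintf("subj%d", 1:6), seed = 1)
#' nrow(plan)                          # 864
#' sum(plan$phase == "choice")         # 576
#' @export
schedule_preference <- function(subjects, seed) {
  stopifnot(length(subjects) >= 1L)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  res <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    order_grp <- if (i %% 2L == 1L) "red_first" else "green_first"
    blocks <- if (order_grp == "red_first")
      c("red_flanged", "red_flanged", "red_flanged",
        "green_flanged", "green_flanged", "green_flanged")
    else
      c("green_flanged", "green_flanged", "green_flanged",
        "red_flanged", "red_flanged", "red_flanged")
    # session labels randomised within each block
    labels <- c(sample(sprintf("S%d", 1:3)), sample(sprintf("S%d", 4:6)))
    sess <- vector("list", 6L)
    for (s in 1:6) {
      flanged_colour <- if (blocks[s] == "red_flanged") "red" else "green"
      forced_colour <- c(sample(rep(c("red", "green"), 2L)),
                         sample(rep(c("red", "green"), 2L)))
      phase <- rep(c("forced", "choice"), c(8L, 16L))
      height <- 0.35 * cos(stats::runif(24L, 0, 2 * pi))
      sess[[s]] <- data.frame(
        subject_id = subjects[i], session_id = labels[s],
        block = blocks[s], order = order_grp, phase = phase,
        trial_index = 1:24,
        flanged_colour = flanged_colour,
        forced_colour = c(forced_colour, rep(NA_character_, 16L)),
        flanged_dot_height = height, stringsAsFactors = FALSE)
    }
    res[[i]] <- do.call(rbind, sess)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate preference choices for a planned schedule
#'
#' Choice-phase trials are Bernoulli draws from the logit model in
#' [choice_gen_params()] with subject, session-in-subject and subject-level
#' colour-slope random effects. Forced trials are deterministic: the subject
#' must take the offered colour, so `choice` records whether that colour was
#' the flanged-associated one.
#'
#' @param plan Plan from [schedule_preference()].
#' @param params A [choice_gen_params()] object.
#' @param seed Integer seed.
#' @return data.frame of trials: plan columns plus `choice` (1 = flanged
#'   stimulus selected).
#' @export
simulate_choices <- function(plan, params, seed = 1) {
  stopifnot(inherits(params, "choice_gen_params"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  subjects <- unique(plan$subject_id)
  a_subj <- stats::rnorm(length(subjects), 0, params$subject_sd)
  slope <- stats::rnorm(length(subjects), 0, params$colour_slope_sd)
  names(a_subj) <- names(slope) <- subjects
  sess_key <- paste(plan$subject_id, plan$session_id)
  sess_levels <- unique(sess_key)
  a_sess <- stats::rnorm(length(sess_levels), 0, params$session_sd)
  names(a_sess) <- sess_levels
  g <- ifelse(plan$flanged_colour == "green", 1, -1)
  o <- ifelse(plan$order == "red_first", 1, -1)
  eta <- params$logit_intercept + params$b_green * g + params$b_order * o +
    params$b_height * plan$flanged_dot_height +
    a_subj[plan$subject_id] + a_sess[sess_key] + slope[plan$subject_id] * g
  p <- stats::plogis(eta)
  choice <- stats::rbinom(nrow(plan), 1L, p)
  forced <- plan$phase == "forced"
  choice[forced] <- as.integer(plan$forced_colour[forced] ==
                                 plan$flanged_colour[forced])
  out <- plan
  out$choice <- choice
  rownames(out) <- NULL
  out
}
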