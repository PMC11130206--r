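## JAGS code for the Bernoulli logistic mixed model over all subjects.
## Random effects: subject intercept and subject colour slope, bivariate
## normal with uniform(-1, 1) correlation (the 2x2 LKJ(1) marginal), plus a
## session-in-subject intercept. Fixed-effect priors Normal(0, 0.5) on the
## logit scale; half Student-t(3, 2.5) on all SDs.
.preference_model_code <- function(include_height) {
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    logit(p[i]) <- b_intercept + b_green*g[i] + b_order*o[i]",
    if (include_height) " + b_height*h[i]" else "",
    " + a_subj[subj[i]] + b_slope[subj[i]]*g[i] + a_sess[sess[i]]\n",
    "    y[i] ~ dbern(p[i])\n",
    "  }\n",
    "  for (j in 1:S) {\n",
    "    z1[j] ~ dnorm(0, 1)\n",
    "    z2[j] ~ dnorm(0, 1)\n",
    "    a_subj[j] <- sd_subject * z1[j]\n",
    "    b_slope[j] <- sd_slope * (rho*z1[j] + sqrt(1 - rho*rho)*z2[j])\n",
    "  }\n",
    "  for (k in 1:K) { a_sess[k] ~ dnorm(0, tau_sess) }\n",
    "  b_intercept ~ dnorm(0, 4)\n",   # Normal(0, SD 0.5), logit scale
    "  b_green ~ dnorm(0, 4)\n",
    "  b_order ~ dnorm(0, 4)\n",
    if (include_height) "  b_height ~ dnorm(0, 4)\n" else "",
    "  sd_subject ~ dt(0, 0.16, 3) T(0,)\n",  # half-t(3, scale 2.5)
    "  sd_slope ~ dt(0, 0.16, 3) T(0,)\n",
    "  sd_session ~ dt(0, 0.16, 3) T(0,)\n",
    "  tau_sess <- pow(sd_session, -2)\n",
    "  rho ~ dunif(-1, 1)\n",
    "}\n")
}

## odds-ratio summary from logit-scale draws: median/MAD/HDI on the
## exponentiated draws, but pd from the sign of the coefficient (an OR is
## always positive, so its own pd would be vacuously 1).
.or_summary <- function(b_draws) {
  s <- summarize_effect(exp(b_draws))
  s$pd <- prob_direction(b_draws)
  s
}

#' Fit the pooled Bernoulli preference model
#'
#' One Bayesian logistic mixed model over all subjects' choice-phase trials:
#' binary choice (1 = flanged stimulus selected) regressed on Colour Flanged
#' (sum-coded, green = +1) and Order (sum-coded, red_first = +1), optionally
#' the zero-centred vertical dot-height covariate, with random intercepts by
#' subject and by session within subject and a by-subject Colour Flanged
#' slope correlated with the subject intercept. Priors are Normal(0, 0.5)
#' on the logit scale for intercept and coefficients and half Student-t(3)
#' for all SDs. Forced-phase trials are not choices and are dropped from the
#' likelihood. All odds-ratio summaries exponentiate the draws first and
#' summarise after.
#'
#' @param trials data.frame of preference trials (see [simulate_choices()]);
#'   only `phase == "choice"` rows enter the model.
#' @param include_height Add the `flanged_dot_height` covariate.
#' @param settings A [sampler_settings()] object.
#' @return Object of class `preference_fit`: odds-ratio effect summaries
#'   (`intercept_or`, `colour_or`, `order_or`, optionally `height_or`),
#'   per-subject intercept odds ratios (`subject_or`, combining the fixed
#'   intercept with the subject deviation draws), the [posterior_draws()],
#'   diagnostics and a `converged` flag.
#' @export
fit_preference <- function(trials, include_height = FALSE,
                           settings = sampler_settings()) {
  d <- trials[trials$phase == "choice", , drop = FALSE]
  subjects <- unique(d$subject_id)
  if (length(subjects) < 2L)
    stop("the pooled preference model needs choice trials from >= 2 subjects")
  if (!all(d$choice %in% c(0L, 1L)))
    stop("choice must be binary (1 = flanged)")
  degenerate <- vapply(subjects, function(s) {
    ch <- d$choice[d$subject_id == s]
    length(unique(ch)) == 1L
  }, logical(1))
  if (any(degenerate))
    message("subject(s) with all-identical choices (priors regularize): ",
            paste(subjects[degenerate], collapse = ", "))
  sess_key <- paste(d$subject_id, d$session_id)
  sess_levels <- unique(sess_key)
  data <- list(y = as.integer(d$choice),
               g = ifelse(d$flanged_colour == "green", 1, -1),
               o = ifelse(d$order == "red_first", 1, -1),
               subj = match(d$subject_id, subjects),
               sess = match(sess_key, sess_levels),
               N = nrow(d), S = length(subjects), K = length(sess_levels))
  if (include_height) data$h <- d$flanged_dot_height
  monitor <- c("b_intercept", "b_green", "b_order",
               if (include_height) "b_height",
               "a_subj", "sd_subject", "sd_slope", "sd_session", "rho")
  draws <- sample_posterior(.preference_model_code(include_height),
                            data, monitor, settings)
  diag <- mcmc_diagnostics(draws)
  max_rhat <- .max_rhat(diag)
  converged <- is.na(max_rhat) || max_rhat <= 1.05
  if (!converged)
    message(sprintf("non-convergence flagged: max split-R-hat %.3f", max_rhat))
  m <- draws$draws
  subject_or <- lapply(seq_along(subjects), function(j)
    .or_summary(m[, "b_intercept"] + m[, sprintf("a_subj[%d]", j)]))
  names(subject_or) <- subjects
  res <- list(subjects = subjects,
              n_trials = nrow(d),
              intercept_or = .or_summary(m[, "b_intercept"]),
              colour_or = .or_summary(m[, "b_green"]),
              order_or = .or_summary(m[, "b_order"]),
              subject_or = subject_or,
              draws = draws, diagnostics = diag, converged = converged,
              include_height = include_height)
  if (include_height)
    res$height_or <- .or_summary(m[, "b_height"])
  structure(res, class = "preference_fit")
}

#' @export
print.preference_fit <- function(x, ...) {
  cat(sprintf("preference fit: %d subjects, %d choice trials\n",
              length(x$subjects), x$n_trials))
  cat("  OR intercept: "); print(x$intercept_or)
  cat("  OR green:     "); print(x$colour_or)
  cat("  OR red-first: "); print(x$order_or)
  if (!is.null(x$height_or)) {
    cat("  OR height:    "); print(x$height_or)
  }
  if (!x$converged) cat("  WARNING: non-convergence flagged\n")
  invisible(x)
}

#' Per-subject probability of choosing the flanged stimulus
#'
#' Logistic transform, per draw, of each subject's level (fixed intercept
#' plus subject deviation), summarised with the standard effect-size
#' indices; 0.5 is chance level.
#'
#' @param fit A [fit_preference()] result.
#' @param subjects Subjects to report (default all in the fit); an unknown
#'   subject is an error.
#' @return Named list of [summarize_effect()] objects on the probability
#'   scale.
#' @export
per_subject_probability <- function(fit, subjects = NULL) {
  stopifnot(inherits(fit, "preference_fit"))
  if (is.null(subjects)) subjects <- fit$subjects
  unknown <- setdiff(subjects, fit$subjects)
  if (length(unknown) > 0)
    stop("unknown subject(s): ", paste(unknown, collapse = ", "))
  m <- fit$draws$draws
  out <- lapply(subjects, function(s) {
    j <- match(s, fit$subjects)
    eta <- m[, "b_intercept"] + m[, sprintf("a_subj[%d]", j)]
    sm <- summarize_effect(stats::plogis(eta))
    sm$pd <- prob_direction(eta)  # direction relative to chance (0.5)
    sm
  })
  names(out) <- subjects
  out
}

#' Tabulate a preference fit
#'
#' @param fit A [fit_preference()] result.
#' @return data.frame with one row per fixed term on the odds-ratio scale
#'   (term, or_median, or_mad, hdi_low, hdi_high, pd).
#' @export
preference_results_table <- function(fit) {
  terms <- list(intercept = fit$intercept_or, colour_green = fit$colour_or,
                order_red_first = fit$order_or)
  if (!is.null(fit$height_or)) terms$height <- fit$height_or
  out <- do.call(rbind, lapply(names(terms), function(nm) {
    s <- terms[[nm]]
    data.frame(term = nm, or_median = s$median, or_mad = s$mad,
               hdi_low = s$hdi_low, hdi_high = s$hdi_high, pd = s$pd,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
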