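#' Count switches in a binary choice series
#'
#' The switch statistic T: number of adjacent unequal pairs. A session with
#' low T shows temporal clustering (runs of the same choice); high T shows
#' temporal dispersion (alternation).
#'
#' @param series Binary vector (0/1 or logical), length >= 1.
#' @return Integer switch count in 0..(length - 1).
#' @examples
#' count_switches(c(1, 1, 0, 0, 1))  # 2
#' @export
count_switches <- function(series) {
  x <- .check_binary(series)
  n <- length(x)
  if (n < 1L) stop("series must have length >= 1")
  if (n == 1L) return(0L)
  sum(x[-1L] != x[-n])
}

.check_binary <- function(series) {
  if (is.logical(series)) series <- as.integer(series)
  if (!is.numeric(series) || anyNA(series) || !all(series %in% c(0, 1)))
    stop("series must contain only 0/1 values")
  as.integer(series)
}

#' Conjugate Beta posterior for the choice probability
#'
#' Updates a Beta(prior_a, prior_b) prior on theta, the probability of
#' choosing the flanged category, with the session's choices. The default
#' Beta(10, 10) encodes a fairly strong expectation of 50/50 selection.
#'
#' @param series Binary choice series (possibly empty).
#' @param prior_a,prior_b Beta prior parameters (> 0).
#' @return Named vector `c(a, b)` of posterior parameters.
#' @examples
#' posterior_theta(c(rep(1, 10), rep(0, 6)))  # Beta(20, 16)
#' @export
posterior_theta <- function(series, prior_a = 10, prior_b = 10) {
  stopifnot(prior_a > 0, prior_b > 0)
  x <- if (length(series) == 0L) integer(0) else .check_binary(series)
  c(a = prior_a + sum(x == 1L), b = prior_b + sum(x == 0L))
}

#' Monte-Carlo null distribution of the switch count
#'
#' Simulates `n_sims` independent binary series of length `n`: each draws
#' theta* from Beta(a, b) and then n independent Bernoulli(theta*) trials,
#' i.e. the posterior predictive under independence. Returns the switch
#' count of every replicate. The expected value has the closed form
#' (n - 1) * 2ab / ((a + b)(a + b + 1)), used as a cross-check in the test
#' suite.
#'
#' @param a,b Beta parameters (> 0).
#' @param n Series length (>= 2).
#' @param n_sims Number of simulated series.
#' @param seed Integer seed.
#' @return Integer vector of `n_sims` switch counts.
#' @export
simulate_null_T <- function(a, b, n, n_sims = 10000, seed = 1) {
  stopifnot(a > 0, b > 0, n >= 2, n_sims >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  theta <- stats::rbeta(n_sims, a, b)
  mat <- matrix(stats::rbinom(n_sims * n, 1L, rep(theta, each = n)),
                nrow = n)
  as.integer(colSums(mat[-1L, , drop = FALSE] != mat[-n, , drop = FALSE]))
}

#' Exact null distribution of the switch count (enumeration oracle)
#'
#' Exact Beta-Binomial posterior-predictive pmf of T by enumerating all 2^n
#' binary sequences: a sequence with k ones has probability
#' B(a + k, b + n - k) / B(a, b). Intended as a verification oracle for the
#' Monte-Carlo null at small n; refuses n > 12.
#'
#' @param a,b Beta parameters (> 0).
#' @param n Series length (2..12).
#' @return data.frame with columns `t` (0..n-1) and `prob` (sums to 1).
#' @export
exact_null_T <- function(a, b, n) {
  stopifnot(a > 0, b > 0, n >= 2)
  if (n > 12) stop("exact enumeration limited to n <= 12")
  seqs <- 0:(2^n - 1)
  bits <- matrix(0L, nrow = length(seqs), ncol = n)
  for (j in seq_len(n)) bits[, j] <- bitwAnd(seqs %/% 2L^(j - 1L), 1L)
  k <- rowSums(bits)
  tt <- rowSums(bits[, -1L, drop = FALSE] != bits[, -n, drop = FALSE])
  w <- exp(lbeta(a + k, b + n - k) - lbeta(a, b))
  prob <- vapply(0:(n - 1L), function(t0) sum(w[tt == t0]), numeric(1))
  data.frame(t = 0:(n - 1L), prob = prob)
}

## 95% HDI over a discrete empirical distribution: greedy accumulation of
## the highest-probability values until >= mass is covered; ties broken
## toward values nearer the mode (keeps the reported interval short). The
## reported interval is the [min, max] of the selected support.
.discrete_hdi <- function(t_samples, mass = 0.95) {
  tab <- table(t_samples)
  vals <- as.integer(names(tab))
  p <- as.numeric(tab) / length(t_samples)
  mode_v <- vals[which.max(p)]
  ord <- order(-p, abs(vals - mode_v))
  cum <- cumsum(p[ord])
  keep <- ord[seq_len(which(cum >= mass)[1L])]
  c(low = min(vals[keep]), high = max(vals[keep]))
}

#' Beta-Binomial switch test for independence of a binary series
#'
#' Posterior-predictive check of temporal structure in one session's binary
#' choices: (1) count the observed switches T_obs; (2) update a
#' Beta(prior_a, prior_b) prior on the choice probability with the session's
#' choices; (3) simulate `n_sims` independent series of the same length from
#' the posterior predictive and count their switches; (4) compare T_obs with
#' the 95% highest-density interval of the null switch distribution and
#' report the tail shares P(T_null >= T_obs) and P(T_null <= T_obs) (both
#' including equality, so they overlap). T_obs below the interval means
#' temporal clustering, above means temporal dispersion, inside means the
#' series is consistent with independent choices.
#'
#' @param series Binary choice series (1 = flanged), length >= 2.
#' @param prior_a,prior_b Beta prior parameters (default Beta(10, 10)).
#' @param n_sims Simulated null series (default 10000).
#' @param seed Integer seed for the Monte-Carlo null.
#' @return Object of class `switch_test`: `n`, `t_obs`, `posterior_a`,
#'   `posterior_b`, `n_sims`, `t_null` (the simulated counts), `hdi95`,
#'   `p_ge`, `p_le`, `verdict` (`"clustering"`, `"dispersion"` or
#'   `"consistent"`).
#' @examples
#' res <- switch_test(rep(c(1, 0), 8), seed = 1)  # alternating: dispersion
#' res$verdict
#' @export
switch_test <- function(series, prior_a = 10, prior_b = 10,
                        n_sims = 10000, seed = 1) {
  x <- .check_binary(series)
  n <- length(x)
  if (n < 2L) stop("series must have length >= 2")
  t_obs <- count_switches(x)
  post <- posterior_theta(x, prior_a, prior_b)
  t_null <- simulate_null_T(post["a"], post["b"], n, n_sims, seed)
  h <- .discrete_hdi(t_null, 0.95)
  verdict <- if (t_obs < h["low"]) "clustering"
  else if (t_obs > h["high"]) "dispersion"
  else "consistent"
  structure(list(n = n, t_obs = t_obs,
                 posterior_a = unname(post["a"]),
                 posterior_b = unname(post["b"]),
                 n_sims = n_sims, t_null = t_null,
                 hdi95 = unname(h),
                 p_ge = mean(t_null >= t_obs),
                 p_le = mean(t_null <= t_obs),
                 verdict = verdict),
            class = "switch_test")
}

#' @export
print.switch_test <- function(x, ...) {
  cat(sprintf("switch test: n = %d, T_obs = %d, null Beta(%g, %g)\n",
              x$n, x$t_obs, x$posterior_a, x$posterior_b))
  cat(sprintf("  95%% HDI of null T: [%d, %d]; P(T >= T_obs) = %.3f, P(T <= T_obs) = %.3f\n",
              x$hdi95[1L], x$hdi95[2L], x$p_ge, x$p_le))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Run the switch test on every session of a choice table
#'
#' Applies [switch_test()] independently to each subject x session series of
#' choice-phase trials, in trial order, as the temporal-clustering analysis
#' does. Sessions shorter than 2 choices are skipped.
#'
#' @param trials Preference trial table (see [simulate_choices()]).
#' @param prior_a,prior_b,n_sims See [switch_test()].
#' @param seed Base seed; each session uses a deterministic offset.
#' @return data.frame with one row per session: subject, session, n, t_obs,
#'   hdi bounds, tail shares and verdict.
#' @export
switch_test_sessions <- function(trials, prior_a = 10, prior_b = 10,
                                 n_sims = 10000, seed = 1) {
  d <- trials[trials$phase == "choice", , drop = FALSE]
  key <- paste(d$subject_id, d$session_id, sep = "\r")
  out <- list()
  i <- 0L
  for (k in unique(key)) {
    s <- d[key == k, , drop = FALSE]
    s <- s[order(s$trial_index), , drop = FALSE]
    if (nrow(s) < 2L) next
    i <- i + 1L
    r <- switch_test(s$choice, prior_a, prior_b, n_sims,
                     seed = (as.integer(seed) + i) %% .Machine$integer.max)
    out[[i]] <- data.frame(subject_id = s$subject_id[1L],
                           session_id = s$session_id[1L],
                           n = r$n, t_obs = r$t_obs,
                           hdi_low = r$hdi95[1L], hdi_high = r$hdi95[2L],
                           p_ge = r$p_ge, p_le = r$p_le,
                           verdict = r$verdict, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
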