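#' Sampler settings for MCMC model fits
#'
#' Bundles the chain configuration shared by all model-fitting functions.
#' `n_iterations` is the total number of iterations per chain, of which the
#' first `n_warmup` are used for adaptation/burn-in and discarded, so the
#' number of retained posterior draws is
#' `n_chains * (n_iterations - n_warmup)`. The defaults (4 chains, 6000
#' iterations, 1000 warmup) give 20000 retained draws.
#'
#' @param n_chains Number of independent chains (>= 1; >= 2 needed for
#'   split-R-hat diagnostics).
#' @param n_iterations Total iterations per chain, including warmup.
#' @param n_warmup Warmup iterations per chain, discarded before summarising.
#' @param seed Integer seed; each chain uses a deterministic offset of it, so
#'   identical settings give bit-identical draws.
#' @return An object of class `sampler_settings`.
#' @examples
#' sampler_settings(seed = 1)
#' sampler_settings(n_chains = 2, n_iterations = 1500, n_warmup = 500, seed = 42)
#' @export
sampler_settings <- function(n_chains = 4L, n_iterations = 6000L,
                             n_warmup = 1000L, seed = 1L) {
  n_chains <- as.integer(n_chains)
  n_iterations <- as.integer(n_iterations)
  n_warmup <- as.integer(n_warmup)
  seed <- as.integer(seed)
  stopifnot(n_chains >= 1L, n_iterations > 0L, n_warmup >= 0L)
  if (n_warmup >= n_iterations)
    stop("n_warmup must be smaller than n_iterations")
  if (is.na(seed)) stop("seed must be a finite integer")
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 n_warmup = n_warmup, seed = seed),
            class = "sampler_settings")
}

#' Container for labelled posterior draws
#'
#' A matrix of post-warmup MCMC draws (rows) by parameter (columns), together
#' with the chain index of every draw. All chains must contribute the same
#' number of draws and no draw may be missing.
#'
#' @param draws Numeric matrix with named columns (one per parameter).
#' @param chain Integer vector of chain indices, one per row of `draws`.
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, chain) {
  draws <- as.matrix(draws)
  if (is.null(colnames(draws))) stop("draws must have named columns")
  chain <- as.integer(chain)
  if (length(chain) != nrow(draws))
    stop("chain index must have one entry per draw")
  if (anyNA(draws)) stop("posterior draws contain missing values")
  sizes <- table(chain)
  if (length(unique(as.integer(sizes))) != 1L)
    stop("all chains must have the same number of draws")
  structure(list(draws = draws, chain = chain,
                 parameters = colnames(draws)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws x %d parameters (%d chains)\n",
              nrow(x$draws), ncol(x$draws), length(unique(x$chain))))
  cat("parameters:", paste(x$parameters, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.posterior_draws <- function(x, ...) x$draws

## internal: coda mcmc.list -> posterior_draws
.from_mcmc_list <- function(samples) {
  mats <- lapply(samples, function(ch) as.matrix(ch))
  draws <- do.call(rbind, mats)
  chain <- rep(seq_along(mats), vapply(mats, nrow, integer(1)))
  posterior_draws(draws, chain)
}

## internal: posterior_draws -> coda mcmc.list (for ESS etc.)
.to_mcmc_list <- function(draws) {
  idx <- split(seq_along(draws$chain), draws$chain)
  coda::as.mcmc.list(lapply(idx, function(i)
    coda::mcmc(draws$draws[i, , drop = FALSE])))
}

#' Draw from a posterior defined by JAGS model code
#'
#' Thin, seeded wrapper around [rjags::jags.model()] /
#' [rjags::coda.samples()]. Warmup is split between the JAGS adaptation
#' phase and a burn-in update; every chain is given its own RNG seed derived
#' from `settings$seed`, so a rerun with the same settings and backend
#' version reproduces the draws exactly.
#'
#' @param model A model specification: either a string of JAGS model code or
#'   a list with elements `code` (string) and optionally `inits` (a function
#'   of chain index returning an inits list merged with the RNG settings).
#' @param data Named list of data passed to JAGS. Referenced columns must all
#'   be present; a non-finite likelihood at initialisation is reported with
#'   the JAGS error rather than silently.
#' @param monitor Character vector of parameters to record.
#' @param settings A [sampler_settings()] object.
#' @return A [posterior_draws()] object.
#' @examples
#' \donttest{
#' code <- "model { for (i in 1:N) { y[i] ~ dbern(p) } p ~ dbeta(1, 1) }"
#' d <- sample_posterior(code, list(y = rep(0:1, 10), N = 20), "p",
#'                       sampler_settings(n_chains = 2, n_iterations = 1000,
#'                                        n_warmup = 500, seed = 7))
#' mean(as.matrix(d))  # ~ 0.5
#' }
#' @export
sample_posterior <- function(model, data, monitor, settings) {
  stopifnot(inherits(settings, "sampler_settings"))
  if (is.character(model)) model <- list(code = model)
  code <- model$code
  init_fun <- model$inits
  seed <- settings$seed %% .Machine$integer.max
  inits <- lapply(seq_len(settings$n_chains), function(k) {
    base <- if (is.null(init_fun)) list() else init_fun(k)
    c(base, list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = (seed + k - 1L) %% .Machine$integer.max))
  })
  n_adapt <- max(100L, settings$n_warmup %/% 2L)
  n_burn <- max(0L, settings$n_warmup - n_adapt)
  jm <- tryCatch(
    rjags::jags.model(textConnection(code), data = data, inits = inits,
                      n.chains = settings$n_chains, n.adapt = n_adapt,
                      quiet = TRUE),
    error = function(e) stop("model initialisation failed: ",
                             conditionMessage(e), call. = FALSE))
  if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(
    jm, variable.names = monitor,
    n.iter = settings$n_iterations - settings$n_warmup,
    progress.bar = "none")
  .from_mcmc_list(samples)
}

#' Highest-density interval of a posterior sample
#'
#' Shortest interval containing at least `mass` of the draws, computed by the
#' shortest-sorted-window algorithm: among all windows of
#' `ceiling(mass * n)` consecutive order statistics the narrowest is
#' returned. For a multimodal posterior this still yields one contiguous
#' interval.
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass the interval must contain (in (0, 1);
#'   0.89 is the reporting default throughout this package).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' set.seed(1)
#' hdi(runif(1e4), 0.89)      # length close to 0.89
#' hdi(rnorm(1e4), 0.89)      # roughly (-1.6, 1.6)
#' @export
hdi <- function(samples, mass = 0.89) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("mass must be a single probability strictly between 0 and 1")
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 1L) stop("no finite samples")
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1L], high = x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)
  c(low = x[i], high = x[i + m - 1L])
}

#' Probability of direction
#'
#' The posterior probability that a parameter is strictly positive or
#' strictly negative, whichever is larger; ranges from 0.5 (sign completely
#' uncertain) to 1. Draws exactly at zero are counted toward neither side
#' and the shares are renormalised over the non-zero draws.
#'
#' @param samples Numeric vector of posterior draws (>= 1).
#' @return A probability in [0.5, 1] (0.5 if every draw is exactly zero).
#' @examples
#' prob_direction(c(-1, 2, 3, 4))  # 0.75
#' prob_direction(c(-1, 1, -2, 2)) # 0.5
#' @export
prob_direction <- function(samples) {
  x <- samples[is.finite(samples)]
  if (length(x) < 1L) stop("need at least one sample")
  nz <- x[x != 0]
  if (length(nz) == 0L) return(0.5)
  max(mean(nz > 0), mean(nz < 0))
}

#' Summarise a posterior sample with the package's effect-size indices
#'
#' Produces the reporting quartet used for every effect: posterior median,
#' scaled median absolute deviation of the draws (consistency constant
#' 1.4826, as in [stats::mad()]), the 89% highest-density interval and the
#' probability of direction. Odds-ratio summaries should be computed by
#' exponentiating the draws first and then calling this function (the median
#' commutes with monotone transforms, but the MAD and HDI do not).
#'
#' @param samples Numeric vector of posterior draws (>= 50 recommended for a
#'   stable HDI).
#' @param mass HDI mass, default 0.89.
#' @return An object of class `effect_summary`: list with `median`, `mad`,
#'   `hdi_low`, `hdi_high`, `mass`, `pd`.
#' @export
summarize_effect <- function(samples, mass = 0.89) {
  h <- hdi(samples, mass)
  structure(list(median = stats::median(samples),
                 mad = stats::mad(samples),
                 hdi_low = unname(h["low"]),
                 hdi_high = unname(h["high"]),
                 mass = mass,
                 pd = prob_direction(samples)),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f [%.*f], %d%% CrI [%.*f; %.*f], pd = %.2f\n",
              digits, x$median, digits, x$mad, round(100 * x$mass),
              digits, x$hdi_low, digits, x$hdi_high, x$pd))
  invisible(x)
}

#' @export
as.data.frame.effect_summary <- function(x, ...) {
  data.frame(median = x$median, mad = x$mad, hdi_low = x$hdi_low,
             hdi_high = x$hdi_high, mass = x$mass, pd = x$pd)
}

#' Posterior draws of a linear contrast
#'
#' Per-draw weighted sum of named parameters, e.g. the congruent-minus-
#' incongruent condition difference under sum (+/-1) coding is twice the
#' congruence coefficient: `contrast_draws(d, c(b_congruence = 2))`.
#'
#' @param draws A [posterior_draws()] object.
#' @param weights Named numeric vector mapping parameter names to weights.
#' @return Numeric vector, one value per retained draw.
#' @export
contrast_draws <- function(draws, weights) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a named vector")
  missing <- setdiff(names(weights), draws$parameters)
  if (length(missing) > 0)
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  as.numeric(draws$draws[, names(weights), drop = FALSE] %*% weights)
}

## split-R-hat for a single parameter: each chain halved, then the classic
## Gelman-Rubin potential scale reduction over the 2m half-chains.
.split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n2 <- length(v) %/% 2L
    if (n2 < 2L) return(NA_real_)
    halves <- c(halves, list(v[seq_len(n2)], v[seq_len(n2) + n2]))
  }
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for posterior draws
#'
#' Split-R-hat (each chain halved before computing the potential scale
#' reduction factor), effective sample size, and the maximum lag-1
#' autocorrelation across chains, per parameter. The JAGS backend uses
#' Gibbs/slice updates, which have no divergence diagnostic, so
#' `n_divergences` is always 0 and carries a note.
#'
#' @param draws A [posterior_draws()] object.
#' @return Object of class `mcmc_diagnostics`: list with a per-parameter
#'   data.frame (`rhat`, `ess`, `lag1_autocorr`), `n_divergences`, and
#'   `rhat_available` (FALSE when only one chain was run).
#' @export
mcmc_diagnostics <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  chains <- unique(draws$chain)
  multi <- length(chains) >= 2L
  ml <- .to_mcmc_list(draws)
  ess <- tryCatch(coda::effectiveSize(ml), error = function(e) NULL)
  per <- data.frame(parameter = draws$parameters,
                    rhat = NA_real_, ess = NA_real_,
                    lag1_autocorr = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(draws$parameters)) {
    x <- draws$draws[, j]
    if (multi) per$rhat[j] <- .split_rhat(x, draws$chain)
    acs <- vapply(chains, function(ch) {
      v <- x[draws$chain == ch]
      if (stats::sd(v) == 0) return(1)  # constant chain: flag as maximal
      stats::acf(v, lag.max = 1, plot = FALSE)$acf[2L]
    }, numeric(1))
    per$lag1_autocorr[j] <- max(acs)
    if (!is.null(ess)) per$ess[j] <- unname(ess[draws$parameters[j]])
  }
  structure(list(parameters = per, n_divergences = 0L,
                 divergence_note = "backend (JAGS) reports no divergences",
                 rhat_available = multi),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  if (!x$rhat_available)
    cat("single chain: R-hat unavailable\n")
  print(x$parameters, row.names = FALSE)
  cat(sprintf("divergent transitions: %d (%s)\n",
              x$n_divergences, x$divergence_note))
  invisible(x)
}

## internal: largest finite rhat, NA-safe
.max_rhat <- function(diag) {
  r <- diag$parameters$rhat
  if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
}
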