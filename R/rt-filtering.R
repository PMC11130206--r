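#' Per-subject upper reaction-time threshold from the MAD
#'
#' Slow-response cutoff: median + `multiplier` x MAD of the submitted
#' reaction times. By default the MAD is scaled by the normal-consistency
#' constant 1.4826 (the [stats::mad()] default, following the convention of
#' robust-outlier detection with median +/- 2.5 MAD); pass `constant = 1`
#' for the raw median absolute deviation.
#'
#' @param rts Numeric vector of reaction times in ms (>= 2 finite values).
#' @param multiplier MAD multiplier, default 2.5.
#' @param constant MAD consistency constant, default 1.4826.
#' @return Threshold in ms.
#' @examples
#' mad_upper_threshold(c(300, 320, 340, 360, 2000))  # 414.13
#' @export
mad_upper_threshold <- function(rts, multiplier = 2.5, constant = 1.4826) {
  x <- rts[is.finite(rts)]
  if (length(x) < 2L)
    stop("need at least 2 finite reaction times to form a threshold")
  stats::median(x) + multiplier * stats::mad(x, constant = constant)
}

#' Per-subject trial accounting of an RT filtering pass
#'
#' Records how many trials a subject contributed and how many were removed
#' by each exclusion rule. The counts always satisfy
#' `n_collected = n_excluded_fast + n_excluded_slow + n_retained`; when only
#' the total exclusion count is known (e.g. published accounting), the
#' fast/slow split may be NA.
#'
#' @param n_collected Trials submitted to the filter.
#' @param n_excluded Total excluded trials.
#' @param n_excluded_fast,n_excluded_slow Optional split of the exclusions.
#' @param threshold_ms Upper threshold applied (NA when unknown/unfilterable).
#' @param subject_id,task Optional labels.
#' @param unfilterable TRUE when the subject had too few trials for a
#'   threshold.
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(n_collected, n_excluded,
                          n_excluded_fast = NA_integer_,
                          n_excluded_slow = NA_integer_,
                          threshold_ms = NA_real_,
                          subject_id = NA_character_, task = NA_character_,
                          unfilterable = FALSE) {
  n_collected <- as.integer(n_collected)
  n_excluded <- as.integer(n_excluded)
  stopifnot(n_collected >= 0L, n_excluded >= 0L, n_excluded <= n_collected)
  if (!is.na(n_excluded_fast) && !is.na(n_excluded_slow) &&
      n_excluded_fast + n_excluded_slow != n_excluded)
    stop("fast + slow exclusions must sum to n_excluded")
  structure(list(subject_id = subject_id, task = task,
                 n_collected = n_collected,
                 n_excluded = n_excluded,
                 n_excluded_fast = as.integer(n_excluded_fast),
                 n_excluded_slow = as.integer(n_excluded_slow),
                 n_retained = n_collected - n_excluded,
                 threshold_ms = threshold_ms,
                 unfilterable = isTRUE(unfilterable)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s%s]: %d collected, %d excluded (%.2f%%), %d retained\n",
              ifelse(is.na(x$subject_id), "all", x$subject_id),
              ifelse(is.na(x$task), "", paste0("/", x$task)),
              x$n_collected, x$n_excluded, exclusion_rate(x), x$n_retained))
  invisible(x)
}

#' Percentage of submitted trials excluded by the filter
#'
#' @param report A [filter_report()].
#' @return Exclusion percentage on the 0-100 scale.
#' @export
exclusion_rate <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  if (report$n_collected == 0L) return(0)
  100 * report$n_excluded / report$n_collected
}

#' Combine filtering reports across rounds or subjects
#'
#' Sums the trial accounting of several [filter_report()] objects, e.g. a
#' primary round and its repetition round: collected, excluded and retained
#' counts all add.
#'
#' @param ... `filter_report` objects (or a single list of them).
#' @return A combined `filter_report`.
#' @examples
#' primary <- filter_report(n_collected = 423, n_excluded = 96)
#' repetition <- filter_report(n_collected = 105, n_excluded = 28)
#' combine_filter_reports(primary, repetition)$n_retained  # 404
#' @export
combine_filter_reports <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "filter_report"))
    reports <- reports[[1L]]
  stopifnot(all(vapply(reports, inherits, logical(1), "filter_report")))
  sum_or_na <- function(v) if (anyNA(v)) NA_integer_ else sum(v)
  subj <- unique(vapply(reports, `[[`, character(1), "subject_id"))
  task <- unique(vapply(reports, `[[`, character(1), "task"))
  filter_report(
    n_collected = sum(vapply(reports, `[[`, integer(1), "n_collected")),
    n_excluded = sum(vapply(reports, `[[`, integer(1), "n_excluded")),
    n_excluded_fast = sum_or_na(vapply(reports, `[[`, integer(1),
                                       "n_excluded_fast")),
    n_excluded_slow = sum_or_na(vapply(reports, `[[`, integer(1),
                                       "n_excluded_slow")),
    subject_id = if (length(subj) == 1L) subj else NA_character_,
    task = if (length(task) == 1L) task else NA_character_,
    unfilterable = any(vapply(reports, `[[`, logical(1), "unfilterable")))
}

#' Filter dot-probe trials by the two RT exclusion rules
#'
#' Excludes (1) anticipatory responses faster than `floor_ms` and (2) slow
#' outliers above a per-subject (and per-task) threshold of
#' median + `multiplier` x MAD, computed on all trials that subject
#' submitted in the batch. With `fast_first = TRUE` the threshold is instead
#' computed after removing the fast trials. The partition into retained and
#' excluded trials is exhaustive and disjoint. A subject contributing fewer
#' than 2 trials cannot support a MAD threshold: their trials are kept
#' subject only to the floor rule and the report is flagged `unfilterable`.
#'
#' @param trials data.frame of dot-probe trials with at least `subject_id`,
#'   `task`, `rt_ms`.
#' @param floor_ms Anticipatory cutoff in ms (default 200).
#' @param multiplier MAD multiplier (default 2.5).
#' @param constant MAD consistency constant (default 1.4826; 1 = raw MAD).
#' @param fast_first Exclude sub-floor trials before computing the threshold.
#' @return Object of class `filter_result`: list with `retained` and
#'   `excluded` data.frames (the latter with an `exclusion_reason` column),
#'   `reports` (one [filter_report()] per subject x task) and `report`
#'   (their combination).
#' @examples
#' tr <- data.frame(subject_id = "a", task = "flange",
#'                  rt_ms = c(300, 320, 340, 360, 2000, 150))
#' res <- filter_trials(tr)
#' res$retained$rt_ms          # 300 320 340 360
#' res$excluded$exclusion_reason
#' @export
filter_trials <- function(trials, floor_ms = 200, multiplier = 2.5,
                          constant = 1.4826, fast_first = FALSE) {
  empty_reason <- function(d) {
    d$exclusion_reason <- character(0)
    d
  }
  if (nrow(trials) == 0L) {
    return(structure(list(retained = trials,
                          excluded = empty_reason(trials),
                          reports = list(),
                          report = filter_report(0L, 0L, 0L, 0L)),
                     class = "filter_result"))
  }
  if (!all(c("subject_id", "rt_ms") %in% names(trials)))
    stop("trials must have subject_id and rt_ms columns")
  task_col <- if ("task" %in% names(trials)) trials$task else "all"
  key <- paste(trials$subject_id, task_col, sep = "\r")
  retained <- list(); excluded <- list(); reports <- list()
  for (k in unique(key)) {
    d <- trials[key == k, , drop = FALSE]
    rts <- d$rt_ms
    unfilterable <- FALSE
    fast <- rts < floor_ms
    if (nrow(d) < 2L) {
      unfilterable <- TRUE
      threshold <- NA_real_
      slow <- rep(FALSE, nrow(d))
    } else {
      base <- if (fast_first) rts[!fast] else rts
      if (length(base) < 2L) {
        unfilterable <- TRUE
        threshold <- NA_real_
        slow <- rep(FALSE, nrow(d))
      } else {
        threshold <- mad_upper_threshold(base, multiplier, constant)
        slow <- rts > threshold
      }
    }
    slow <- slow & !fast  # fast rule takes precedence in the accounting
    keep <- !fast & !slow
    exc <- d[!keep, , drop = FALSE]
    exc$exclusion_reason <- ifelse(fast[!keep], "fast", "slow")
    retained[[k]] <- d[keep, , drop = FALSE]
    excluded[[k]] <- exc
    reports[[k]] <- filter_report(
      n_collected = nrow(d), n_excluded = sum(!keep),
      n_excluded_fast = sum(fast), n_excluded_slow = sum(slow),
      threshold_ms = threshold,
      subject_id = d$subject_id[1L],
      task = if ("task" %in% names(d)) d$task[1L] else NA_character_,
      unfilterable = unfilterable)
  }
  ret <- do.call(rbind, retained)
  exc <- do.call(rbind, excluded)
  rownames(ret) <- rownames(exc) <- NULL
  structure(list(retained = ret, excluded = exc,
                 reports = unname(reports),
                 report = combine_filter_reports(unname(reports))),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Merge a primary filtering round with its repetition round
#'
#' Trials excluded in the primary round are re-run in subject-specific
#' repetition sessions and filtered by the same criteria; the final dataset
#' is the union of trials retained in either round. Trials excluded in both
#' rounds are lost. A repetition trial that does not correspond to an
#' excluded primary trial (matched on subject, pair and congruence) raises a
#' warning but still enters by its own filter verdict. The combined report
#' sums the accounting of both rounds.
#'
#' @param primary,repetition `filter_result` objects from [filter_trials()].
#' @return List of class `merged_filter_result` with `trials` (final table),
#'   `report` (combined [filter_report()]) and both round reports.
#' @export
merge_repetitions <- function(primary, repetition) {
  stopifnot(inherits(primary, "filter_result"),
            inherits(repetition, "filter_result"))
  match_key <- function(d) paste(d$subject_id, d$pair_id, d$congruence)
  rep_all <- rbind(repetition$retained,
                   repetition$excluded[, names(repetition$retained),
                                       drop = FALSE])
  if (nrow(rep_all) > 0L && nrow(primary$excluded) > 0L) {
    unmatched <- !(match_key(rep_all) %in% match_key(primary$excluded))
    if (any(unmatched))
      warning(sum(unmatched), " repetition trial(s) have no matching ",
              "excluded primary trial; included per their own verdict")
  } else if (nrow(rep_all) > 0L && nrow(primary$excluded) == 0L) {
    warning(nrow(rep_all), " repetition trial(s) have no matching ",
            "excluded primary trial; included per their own verdict")
  }
  final <- rbind(primary$retained, repetition$retained)
  if (!is.null(final) && "is_repetition" %in% names(final) &&
      nrow(repetition$retained) > 0L) {
    final$is_repetition[seq_len(nrow(repetition$retained)) +
                          nrow(primary$retained)] <- TRUE
  }
  rownames(final) <- NULL
  structure(list(trials = final,
                 report = combine_filter_reports(primary$report,
                                                 repetition$report),
                 primary_report = primary$report,
                 repetition_report = repetition$report),
            class = "merged_filter_result")
}

#' @export
print.merged_filter_result <- function(x, ...) {
  cat("merged filtering rounds\n  primary:    ")
  cat(sprintf("%d collected, %d excluded (%.2f%%)\n",
              x$primary_report$n_collected, x$primary_report$n_excluded,
              exclusion_rate(x$primary_report)))
  cat("  repetition: ")
  cat(sprintf("%d collected, %d excluded (%.2f%%)\n",
              x$repetition_report$n_collected, x$repetition_report$n_excluded,
              exclusion_rate(x$repetition_report)))
  cat(sprintf("  final dataset: %d trials\n", x$report$n_retained))
  invisible(x)
}
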