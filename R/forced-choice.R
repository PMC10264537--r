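#' Participant and trial exclusion rules for the 2AFC experiment
#'
#' Thresholds for the pre-registered exclusion machinery:
#' \itemize{
#'   \item participants failing strictly more than `attention_fail_frac` of
#'     their attention-check trials are excluded;
#'   \item participants who responded before the end of the second audio file
#'     on `premature_frac` or more of their trials are excluded;
#'   \item participants whose no-replay trials exceed `rt_multiplier` times
#'     the median no-replay reaction time on `premature_frac` or more of
#'     those trials are excluded;
#'   \item optionally (off by default) participants with any run of
#'     `run_length` or more identical responses are excluded — disabled by
#'     default because an attentive random responder triggers it surprisingly
#'     often (see [run_exclusion_probability()]).
#' }
#'
#' @param attention_fail_frac Strict threshold on the attention-check error
#'   fraction (default 0.25).
#' @param premature_frac Inclusive threshold on premature/slow trial
#'   fractions (default 0.10).
#' @param rt_multiplier Slow-trial cut as a multiple of the median no-replay
#'   RT (default 3).
#' @param run_rule_enabled Enable the identical-response run rule.
#' @param run_length Minimum run length for the run rule (default 10).
#' @param rt_median_scope Compute the no-replay RT median per
#'   `"participant"` (default) or globally.
#' @return List of class `"exclusion_rules"`.
#' @export
exclusion_rules <- function(attention_fail_frac = 0.25,
                            premature_frac = 0.10,
                            rt_multiplier = 3,
                            run_rule_enabled = FALSE,
                            run_length = 10,
                            rt_median_scope = c("participant", "global")) {
  stopifnot(attention_fail_frac > 0, premature_frac > 0, rt_multiplier > 0,
            run_length >= 1)
  structure(list(attention_fail_frac = attention_fail_frac,
                 premature_frac = premature_frac,
                 rt_multiplier = rt_multiplier,
                 run_rule_enabled = isTRUE(run_rule_enabled),
                 run_length = run_length,
                 rt_median_scope = match.arg(rt_median_scope)),
            class = "exclusion_rules")
}

trial_columns <- function() {
  c("participant", "native_language", "item", "trial_index",
    "response_choice", "selected_affricate", "trial_type", "correct",
    "rt", "replays", "responded_before_audio_end")
}

validate_trials <- function(trials) {
  missing <- setdiff(trial_columns(), names(trials))
  if (length(missing) > 0L) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- !trials$trial_type %in% c("experimental", "filler", "attention_check")
  if (any(bad)) stop("invalid trial_type at row(s) ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(trials$replays > 3, na.rm = TRUE)) {
    stop("replays must be at most 3")
  }
  invisible(trials)
}

#' Read a 2AFC trial table
#'
#' CSV with one row per trial and the columns `participant`,
#' `native_language`, `item`, `trial_index`, `response_choice`
#' (first/second), `selected_affricate` (logical; empty for fillers and
#' attention checks), `trial_type` (experimental/filler/attention_check),
#' `correct` (logical; attention checks only), `rt` (ms), `replays` (0–3),
#' `responded_before_audio_end` (logical).
#'
#' @param path CSV path.
#' @return Validated trial data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("selected_affricate", "correct", "responded_before_audio_end")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  validate_trials(df)
  df
}

slow_trial_flags <- function(trials, rules) {
  no_replay <- trials$replays == 0
  flags <- rep(FALSE, nrow(trials))
  if (!any(no_replay)) return(flags)
  if (rules$rt_median_scope == "global") {
    med <- stats::median(trials$rt[no_replay])
    flags[no_replay] <- trials$rt[no_replay] > rules$rt_multiplier * med
  } else {
    for (p in unique(trials$participant)) {
      sel <- no_replay & trials$participant == p
      if (!any(sel)) next
      med <- stats::median(trials$rt[sel])
      flags[sel] <- trials$rt[sel] > rules$rt_multiplier * med
    }
  }
  flags
}

longest_run <- function(x) {
  if (length(x) == 0L) return(0L)
  max(rle(as.character(x))$lengths)
}

#' Apply participant-level exclusions
#'
#' Evaluates the four participant rules of [exclusion_rules()] and removes
#' every participant that matches any enabled rule. All matching reasons are
#' recorded (a participant can match several). Participants with no
#' attention-check trials cannot be judged by the attention rule; this is
#' logged as a message.
#'
#' @param trials Validated trial data frame.
#' @param rules An [exclusion_rules()] object.
#' @return List with `trials` (rows of kept participants) and `report`, a
#'   per-participant data frame with logical columns `attention`,
#'   `premature`, `slow`, `runs`, `excluded` and a comma-separated `reasons`
#'   string.
#' @export
apply_participant_exclusions <- function(trials, rules = exclusion_rules()) {
  validate_trials(trials)
  participants <- unique(trials$participant)
  slow <- slow_trial_flags(trials, rules)

  rows <- lapply(participants, function(p) {
    tr <- trials[trials$participant == p, , drop = FALSE]
    sl <- slow[trials$participant == p]
    checks <- tr[tr$trial_type == "attention_check", , drop = FALSE]
    if (nrow(checks) == 0L) {
      message("participant ", p,
              " has no attention-check trials; attention rule not applied")
      attention <- FALSE
    } else {
      attention <- mean(!checks$correct) > rules$attention_fail_frac
    }
    premature <- mean(tr$responded_before_audio_end) >= rules$premature_frac
    no_replay <- tr$replays == 0
    slow_flag <- if (any(no_replay)) {
      mean(sl[no_replay]) >= rules$premature_frac
    } else FALSE
    runs <- if (rules$run_rule_enabled) {
      ord <- order(tr$trial_index)
      longest_run(tr$response_choice[ord]) >= rules$run_length
    } else FALSE
    data.frame(participant = p, attention = attention, premature = premature,
               slow = slow_flag, runs = runs,
               excluded = attention || premature || slow_flag || runs,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  reason_cols <- c("attention", "premature", "slow", "runs")
  report$reasons <- apply(report[reason_cols], 1, function(r) {
    paste(reason_cols[as.logical(r)], collapse = ",")
  })
  kept <- report$participant[!report$excluded]
  list(trials = trials[trials$participant %in% kept, , drop = FALSE],
       report = report)
}

#' Apply trial-level exclusions
#'
#' Drops (a) trials where the participant responded before the second audio
#' file finished and (b) no-replay trials whose RT exceeds `rt_multiplier`
#' times the median RT of no-replay trials (the median being computed over
#' no-replay trials only, after the premature trials are removed). Intended
#' to run after [apply_participant_exclusions()].
#'
#' @inheritParams apply_participant_exclusions
#' @return The kept trials.
#' @export
apply_trial_exclusions <- function(trials, rules = exclusion_rules()) {
  validate_trials(trials)
  trials <- trials[!trials$responded_before_audio_end, , drop = FALSE]
  slow <- slow_trial_flags(trials, rules)
  trials[!slow, , drop = FALSE]
}

#' Chance probability of a long identical-response run
#'
#' Exact probability that an iid binary response sequence of length
#' `n_trials` contains at least one run of `min_run` or more identical
#' responses, computed by dynamic programming over (current response,
#' current run length) states. For a fair responder (`p = 0.5`) over 88
#' trials this is the false-exclusion rate of the run-of-10 rule for a fully
#' attentive random guesser: about 7.58%.
#'
#' @param n_trials Sequence length.
#' @param min_run Minimum run length counted as a violation.
#' @param p Per-trial probability of choosing the first response option
#'   (each trial iid); default 0.5.
#' @return Probability in `[0, 1]`, exact to double precision.
#' @examples
#' run_exclusion_probability(10, 10)        # 2 * 0.5^10
#' run_exclusion_probability(88, 10)        # ~0.0758
#' @export
run_exclusion_probability <- function(n_trials, min_run, p = 0.5) {
  stopifnot(n_trials >= 0, min_run >= 1, p > 0, p < 1)
  if (min_run > n_trials) return(0)
  if (min_run == 1L) return(1)
  k <- min_run - 1L  # states: run lengths 1..k without a violation yet
  a <- numeric(k)    # current response = "first"
  b <- numeric(k)    # current response = "second"
  a[1] <- p
  b[1] <- 1 - p
  if (n_trials >= 2) {
    for (t in 2:n_trials) {
      new_a <- c(sum(b) * p, if (k > 1) a[1:(k - 1)] * p)
      new_b <- c(sum(a) * (1 - p), if (k > 1) b[1:(k - 1)] * (1 - p))
      a <- new_a
      b <- new_b
    }
  }
  1 - sum(a) - sum(b)
}

#' Fit the intercept-only swear-word selection model
#'
#' Fits a logistic mixed model of affricate selection on the experimental
#' trials, `selected_affricate ~ 1 + (1 | participant) + (1 | item)`, with
#' crossed random intercepts for participants and items (lme4, Laplace
#' approximation). Selection of the affricate variant is coded 1 and of the
#' approximant variant 0, so a positive intercept means the approximant
#' words are avoided when guessing which word is the swear word.
#'
#' Complete separation (all responses identical) is reported with a
#' `boundary` flag and an infinite log-odds estimate instead of an error.
#'
#' @param trials Trial data frame; only rows with
#'   `trial_type == "experimental"` are used.
#' @return List of class `"glmm_fit"`: `beta`, `se`, `z`, `p`,
#'   `var_participant`, `var_item`, `n_trials`, `n_participants`, `n_items`,
#'   `method`, `boundary`.
#' @export
fit_selection_model <- function(trials) {
  validate_trials(trials)
  exp_tr <- trials[trials$trial_type == "experimental", , drop = FALSE]
  if (nrow(exp_tr) == 0L) stop("no experimental trials")
  y <- as.integer(exp_tr$selected_affricate)
  if (anyNA(y)) stop("selected_affricate must be defined on experimental trials")
  base <- list(n_trials = nrow(exp_tr),
               n_participants = length(unique(exp_tr$participant)),
               n_items = length(unique(exp_tr$item)))
  if (all(y == y[1])) {
    return(structure(c(list(
      beta = if (y[1] == 1) Inf else -Inf, se = NA_real_, z = NA_real_,
      p = NA_real_, var_participant = NA_real_, var_item = NA_real_),
      base, list(method = "complete_separation", boundary = TRUE)),
      class = "glmm_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(y ~ 1 + (1 | participant) + (1 | item),
                data = transform(exp_tr, y = y), family = stats::binomial())
  ))
  cf <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 1) v else NA_real_
  }
  structure(c(list(
    beta = unname(cf[1, "Estimate"]), se = unname(cf[1, "Std. Error"]),
    z = unname(cf[1, "z value"]), p = unname(cf[1, "Pr(>|z|)"]),
    var_participant = getvar("participant"), var_item = getvar("item")),
    base, list(method = "glmer_laplace",
               boundary = isTRUE(lme4::isSingular(fit)))),
    class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Logistic mixed model of affricate selection (", x$method, ")\n",
      sep = "")
  cat(sprintf("  beta = %.3f, SE = %.3f, z = %.2f, p = %.3g\n",
              x$beta, x$se, x$z, x$p))
  cat(sprintf("  var(participant) = %.3f, var(item) = %.3f\n",
              x$var_participant, x$var_item))
  cat(sprintf("  %d trials, %d participants, %d items\n",
              x$n_trials, x$n_participants, x$n_items))
  if (isTRUE(x$boundary)) cat("  note: boundary/singular fit\n")
  invisible(x)
}

#' Selection percentage implied by a log-odds intercept
#'
#' Inverse-logit of the fitted intercept, expressed as a percentage:
#' `100 / (1 + exp(-beta))`. An intercept of 0.52 corresponds to selecting
#' the affricate variant on 63% of trials.
#'
#' @param beta Log-odds intercept.
#' @param digits Rounding (default 0, nearest integer percent); use `NULL`
#'   for no rounding.
#' @return Percentage in (0, 100).
#' @examples
#' implied_proportion(0)     # 50
#' implied_proportion(0.52)  # 63
#' @export
implied_proportion <- function(beta, digits = 0) {
  stopifnot(is.finite(beta))
  pct <- 100 * stats::plogis(beta)
  if (is.null(digits)) pct else round(pct, digits)
}
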