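#' Default phoneme-class frequencies for synthetic lexicons
#'
#' A plausible cross-linguistic segment mixture: roughly 45% vowels, with
#' the consonant mass spread over the six groups (plosives most frequent,
#' affricates rarest). Purely a convenience default; any probability vector
#' over [phoneme_classes()] may be supplied.
#'
#' @return Named numeric probability vector over the eight classes.
#' @export
default_class_frequencies <- function() {
  c(plosive = 0.17, affricate = 0.03, approximant = 0.10,
    sibilant_fricative = 0.07, nonsibilant_fricative = 0.07,
    nasal = 0.09, vowel = 0.45, other = 0.02)
}

# symbols available per class, for word generation
class_symbol_sets <- function(table = asjp_classification()) {
  split(names(table), factor(unname(table), levels = phoneme_classes()))
}

#' Specification of a synthetic lexicon pair
#'
#' Defines per-language target ("swear") and control (Swadesh-style)
#' lexicons with known phoneme-class frequencies. The target set's
#' frequency for `depleted_group` is multiplied by `depletion` and the
#' vector renormalized, so `depletion = 1` is the null (no difference in
#' expectation) and `depletion = 0` removes the group from the target set
#' entirely.
#'
#' Defaults mirror the pilot's design: five languages, a 100-word control
#' list and a 20-word target set per language, and words of 2–8 segments
#' drawn iid from the class-frequency vector.
#'
#' @param languages Character vector of language identifiers.
#' @param n_control_words,n_target_words Words per language.
#' @param class_frequencies Probability vector over [phoneme_classes()].
#' @param depletion Factor in `[0, 1]` applied to `depleted_group` in the
#'   target set.
#' @param depleted_group Consonant group depleted in the target set
#'   (default approximant).
#' @param length_range Inclusive word-length bounds in segments.
#' @param length_geom_p Success probability of the truncated geometric word
#'   length distribution.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return List of class `"lexicon_spec"`.
#' @export
lexicon_spec <- function(languages = paste0("lang", 1:5),
                         n_control_words = 100, n_target_words = 20,
                         class_frequencies = default_class_frequencies(),
                         depletion = 1, depleted_group = "approximant",
                         length_range = c(2L, 8L), length_geom_p = 0.4,
                         seed = 1L) {
  stopifnot(length(languages) >= 1, n_control_words >= 1, n_target_words >= 1,
            depletion >= 0, depletion <= 1,
            depleted_group %in% consonant_groups(),
            length_range[1] >= 1, length_range[2] >= length_range[1],
            length_geom_p > 0, length_geom_p < 1)
  f <- class_frequencies[phoneme_classes()]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-8 || any(f < 0)) {
    stop("class_frequencies must be a probability vector over phoneme_classes()")
  }
  structure(list(languages = languages, n_control_words = n_control_words,
                 n_target_words = n_target_words, class_frequencies = f,
                 depletion = depletion, depleted_group = depleted_group,
                 length_range = as.integer(length_range),
                 length_geom_p = length_geom_p, seed = as.integer(seed)),
            class = "lexicon_spec")
}

depleted_frequencies <- function(spec) {
  f <- spec$class_frequencies
  f[spec$depleted_group] <- f[spec$depleted_group] * spec$depletion
  f / sum(f)
}

# random word lengths: truncated geometric on [min, max]
sample_lengths <- function(n, range, p) {
  support <- range[1]:range[2]
  probs <- (1 - p)^(support - range[1]) * p
  sample(support, n, replace = TRUE, prob = probs / sum(probs))
}

sample_words <- function(n, freqs, range, p, symbols) {
  lens <- sample_lengths(n, range, p)
  cls <- sample(names(freqs), sum(lens), replace = TRUE, prob = freqs)
  syms <- vapply(cls, function(k) {
    pool <- symbols[[k]]
    pool[sample.int(length(pool), 1L)]
  }, character(1), USE.NAMES = FALSE)
  vapply(split(syms, rep(seq_len(n), times = lens)),
         paste, character(1), collapse = "")
}

#' Generate a synthetic control/target lexicon pair
#'
#' Draws, for each language in the spec, a control lexicon and a target
#' lexicon whose segments are iid from the spec's class-frequency vector
#' (the target using the depletion-modified vector). Deterministic given
#' the spec: each language has its own stream derived from the spec seed.
#'
#' @param spec A [lexicon_spec()].
#' @param table Classification table (symbols are drawn from its classes).
#' @return Wordlist data frame (columns `language`, `kind`, `orthography`,
#'   `asjp`) with attributes `spec` and `true_frequencies` (list with
#'   `control` and `target` probability vectors).
#' @export
generate_lexicon_pair <- function(spec, table = asjp_classification()) {
  stopifnot(inherits(spec, "lexicon_spec"))
  symbols <- class_symbol_sets(table)
  if (any(vapply(symbols[names(spec$class_frequencies)[
    spec$class_frequencies > 0]], length, integer(1)) == 0L)) {
    stop("classification table has no symbols for a class with positive frequency")
  }
  f_control <- spec$class_frequencies
  f_target <- depleted_frequencies(spec)
  out <- lapply(spec$languages, function(lang) {
    withr::with_seed(language_seed(spec$seed, lang), {
      control <- sample_words(spec$n_control_words, f_control,
                              spec$length_range, spec$length_geom_p, symbols)
      target <- sample_words(spec$n_target_words, f_target,
                             spec$length_range, spec$length_geom_p, symbols)
      data.frame(
        language = lang,
        kind = rep(c("control", "target"),
                   c(spec$n_control_words, spec$n_target_words)),
        orthography = c(control, target),
        asjp = c(control, target),
        stringsAsFactors = FALSE
      )
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "spec") <- spec
  attr(res, "true_frequencies") <- list(control = f_control,
                                        target = f_target)
  res
}

#' Specification of a synthetic 2AFC trial table
#'
#' Emulates the forced-choice experiment's design: each participant
#' completes one trial per experimental item, plus filler and
#' attention-check trials, in a shuffled order. Experimental responses are
#' drawn from an intercept-only logistic model with crossed participant and
#' item random intercepts: `logit P(select affricate) = beta + u_p + u_i`.
#'
#' Contamination is planted deterministically so ground truth is exactly
#' recoverable: `round(attention_error_rate * n_participants)` participants
#' are inattentive (they miss half of their attention checks, which the
#' stricter-than-25% rule always catches) and
#' `round(premature_rate * n_participants)` respond prematurely on 20% of
#' their trials. Attentive participants answer every check correctly and
#' respond prematurely on a small per-trial base rate.
#'
#' Defaults follow the experiment's scale: 215 participants drawn from six
#' native-language groups, 40 experimental items, 40 fillers and 8
#' attention checks (88 trials per participant), a true log-odds intercept
#' of 0.52, and random-intercept standard deviations of 0.5.
#'
#' @param n_participants,n_items,n_fillers,n_attention_checks Design sizes.
#' @param true_beta True log-odds intercept for affricate selection.
#' @param sd_participant,sd_item Random-intercept standard deviations.
#' @param premature_rate Fraction of participants planted as premature
#'   responders.
#' @param attention_error_rate Fraction of participants planted as
#'   inattentive.
#' @param base_premature_trial_rate Per-trial premature probability for
#'   attentive participants (default 0.003).
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (ms).
#' @param native_languages Languages cycled over participants.
#' @param seed Integer seed.
#' @return List of class `"trial_spec"`.
#' @export
trial_spec <- function(n_participants = 215, n_items = 40, n_fillers = 40,
                       n_attention_checks = 8, true_beta = 0.52,
                       sd_participant = 0.5, sd_item = 0.5,
                       premature_rate = 0.025, attention_error_rate = 0.075,
                       base_premature_trial_rate = 0.003,
                       rt_meanlog = log(1500), rt_sdlog = 0.4,
                       native_languages = c("arabic", "chinese", "finnish",
                                            "french", "german", "spanish"),
                       seed = 1L) {
  stopifnot(n_participants >= 1, n_items >= 1,
            n_fillers >= 0, n_attention_checks >= 0,
            sd_participant >= 0, sd_item >= 0,
            premature_rate >= 0, premature_rate <= 1,
            attention_error_rate >= 0, attention_error_rate <= 1,
            base_premature_trial_rate >= 0, base_premature_trial_rate <= 1)
  structure(as.list(environment()), class = "trial_spec")
}

#' Generate a synthetic 2AFC trial table
#'
#' @param spec A [trial_spec()].
#' @return Trial data frame with the columns of [read_trials()] plus a
#'   hidden ground-truth column `.truth` (`"attentive"`,
#'   `"attention_failer"` or `"premature"`). Deterministic given the spec.
#' @export
generate_trials <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  withr::with_seed(spec$seed, {
    n_p <- spec$n_participants
    participants <- sprintf("P%03d", seq_len(n_p))
    u_p <- stats::rnorm(n_p, 0, spec$sd_participant)
    items <- sprintf("I%02d", seq_len(spec$n_items))
    u_i <- stats::rnorm(spec$n_items, 0, spec$sd_item)
    affricate_first <- seq_len(spec$n_items) %% 2L == 1L

    n_fail <- round(spec$attention_error_rate * n_p)
    n_prem <- round(spec$premature_rate * n_p)
    if (n_fail + n_prem > n_p) stop("contamination rates exceed cohort size")
    planted <- sample(participants, n_fail + n_prem)
    truth <- stats::setNames(rep("attentive", n_p), participants)
    truth[planted[seq_len(n_fail)]] <- "attention_failer"
    if (n_prem > 0) truth[planted[n_fail + seq_len(n_prem)]] <- "premature"

    n_trials <- spec$n_items + spec$n_fillers + spec$n_attention_checks
    rows <- lapply(seq_len(n_p), function(i) {
      p <- participants[i]
      type <- c(rep("experimental", spec$n_items),
                rep("filler", spec$n_fillers),
                rep("attention_check", spec$n_attention_checks))
      item <- c(items, sprintf("F%02d", seq_len(spec$n_fillers)),
                sprintf("A%02d", seq_len(spec$n_attention_checks)))
      ord <- sample.int(n_trials)
      type <- type[ord]; item <- item[ord]

      sel <- rep(NA, n_trials)
      is_exp <- type == "experimental"
      item_idx <- match(item[is_exp], items)
      sel[is_exp] <- stats::runif(sum(is_exp)) <
        stats::plogis(spec$true_beta + u_p[i] + u_i[item_idx])

      correct <- rep(NA, n_trials)
      is_chk <- type == "attention_check"
      if (any(is_chk)) {
        if (truth[p] == "attention_failer") {
          wrong <- sample(which(is_chk), ceiling(sum(is_chk) / 2))
          correct[is_chk] <- TRUE
          correct[wrong] <- FALSE
        } else {
          correct[is_chk] <- TRUE
        }
      }

      choice <- ifelse(stats::runif(n_trials) < 0.5, "first", "second")
      aff_first <- affricate_first[match(item, items)]
      choice[is_exp] <- ifelse(sel[is_exp] == aff_first[is_exp],
                               "first", "second")

      premature <- if (truth[p] == "premature") {
        flag <- rep(FALSE, n_trials)
        flag[sample.int(n_trials, ceiling(0.2 * n_trials))] <- TRUE
        flag
      } else {
        stats::runif(n_trials) < spec$base_premature_trial_rate
      }

      data.frame(
        participant = p,
        native_language = spec$native_languages[
          (i - 1L) %% length(spec$native_languages) + 1L],
        item = item, trial_index = seq_len(n_trials),
        response_choice = choice, selected_affricate = as.logical(sel),
        trial_type = type, correct = as.logical(correct),
        rt = round(stats::rlnorm(n_trials, spec$rt_meanlog, spec$rt_sdlog)),
        replays = sample(0:3, n_trials, replace = TRUE,
                         prob = c(0.80, 0.10, 0.07, 0.03)),
        responded_before_audio_end = premature,
        .truth = unname(truth[p]),
        stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    attr(res, "spec") <- spec
    res
  })
}

#' Specification of synthetic minced-oath pairs
#'
#' @param n_pairs Number of original/minced pairs (default 67).
#' @param insertion_prob Probability that the minced variant's single
#'   substitution inserts an approximant (default 0.6); otherwise a
#'   non-approximant consonant is substituted.
#' @param class_frequencies Segment mixture for the original words.
#' @param length_range,length_geom_p Word length distribution, as in
#'   [lexicon_spec()].
#' @param seed Integer seed.
#' @return List of class `"oath_spec"`.
#' @export
oath_spec <- function(n_pairs = 67, insertion_prob = 0.6,
                      class_frequencies = default_class_frequencies(),
                      length_range = c(2L, 8L), length_geom_p = 0.4,
                      seed = 1L) {
  stopifnot(n_pairs >= 1, insertion_prob >= 0, insertion_prob <= 1)
  f <- class_frequencies[phoneme_classes()]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-8) {
    stop("class_frequencies must be a probability vector over phoneme_classes()")
  }
  structure(list(n_pairs = n_pairs, insertion_prob = insertion_prob,
                 class_frequencies = f,
                 length_range = as.integer(length_range),
                 length_geom_p = length_geom_p, seed = as.integer(seed)),
            class = "oath_spec")
}

#' Generate synthetic minced-oath pairs
#'
#' Originals are random words; each minced variant differs by exactly one
#' segment substitution, which with probability `insertion_prob` is an
#' approximant and otherwise a non-approximant consonant.
#'
#' @param spec An [oath_spec()].
#' @param table Classification table.
#' @return Data frame with columns `original_orth`, `original_asjp`,
#'   `minced_orth`, `minced_asjp`, `source` (= "synthetic").
#' @export
generate_oath_pairs <- function(spec, table = asjp_classification()) {
  stopifnot(inherits(spec, "oath_spec"))
  symbols <- class_symbol_sets(table)
  approx_syms <- symbols[["approximant"]]
  nonapprox_syms <- unlist(symbols[setdiff(consonant_groups(), "approximant")])
  withr::with_seed(spec$seed, {
    originals <- sample_words(spec$n_pairs, spec$class_frequencies,
                              spec$length_range, spec$length_geom_p, symbols)
    minced <- vapply(originals, function(w) {
      chars <- strsplit(w, "", fixed = TRUE)[[1]]
      pos <- sample.int(length(chars), 1L)
      sub <- if (stats::runif(1) < spec$insertion_prob) {
        approx_syms[sample.int(length(approx_syms), 1L)]
      } else {
        nonapprox_syms[sample.int(length(nonapprox_syms), 1L)]
      }
      chars[pos] <- sub
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    res <- data.frame(original_orth = originals, original_asjp = originals,
                      minced_orth = minced, minced_asjp = minced,
                      source = "synthetic", stringsAsFactors = FALSE)
    attr(res, "spec") <- spec
    res
  })
}
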