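test_that("attention-check rule uses a strict 25% threshold", {
  # 8 checks, 3 wrong = 37.5% > 25%: excluded
  tr <- make_trials(rep("P1", 8), trial_type = "attention_check",
                    correct = c(rep(FALSE, 3), rep(TRUE, 5)))
  res <- apply_participant_exclusions(tr)
  expect_true(res$report$excluded)
  expect_match(res$report$reasons, "attention")

  # exactly 25% wrong (2 of 8) is NOT more than 25%: kept
  tr2 <- make_trials(rep("P1", 8), trial_type = "attention_check",
                     correct = c(rep(FALSE, 2), rep(TRUE, 6)))
  expect_false(apply_participant_exclusions(tr2)$report$excluded)

  # no attention checks at all: rule inapplicable, logged
  tr3 <- make_trials(rep("P1", 4))
  tr3$selected_affricate <- TRUE
  expect_message(res3 <- apply_participant_exclusions(tr3),
                 "no attention-check")
  expect_false(res3$report$excluded)
})

test_that("premature-response rule uses an inclusive 10% threshold", {
  # exactly 10% premature trials: excluded (>= rule)
  tr <- make_trials(rep("P1", 20), premature = c(rep(TRUE, 2), rep(FALSE, 18)),
                    correct = NA)
  tr$trial_type <- "experimental"
  tr$selected_affricate <- TRUE
  res <- apply_participant_exclusions(tr)
  expect_true(res$report$excluded)
  expect_match(res$report$reasons, "premature")

  # just below 10%: kept
  tr2 <- make_trials(rep("P1", 21), premature = c(rep(TRUE, 2), rep(FALSE, 19)))
  expect_false(apply_participant_exclusions(tr2)$report$excluded)
})

test_that("a participant can match several exclusion reasons at once", {
  tr <- rbind(
    make_trials(rep("P1", 8), trial_type = "attention_check",
                correct = rep(FALSE, 8)),
    make_trials(rep("P1", 12), premature = TRUE)
  )
  tr$trial_index <- seq_len(nrow(tr))
  res <- apply_participant_exclusions(tr)
  expect_true(res$report$attention)
  expect_true(res$report$premature)
  expect_equal(res$report$reasons, "attention,premature")
})

test_that("trial exclusions drop premature and slow no-replay trials only", {
  rt <- c(rep(1000, 8), 10000, 9000)
  replays <- c(rep(0, 9), 2)
  tr <- make_trials(rep("P1", 10), rt = rt, replays = replays,
                    premature = c(TRUE, rep(FALSE, 9)))
  kept <- apply_trial_exclusions(tr)
  # premature trial 1 dropped; no-replay trial 9 (rt 10000 > 3 * 1000)
  # dropped; replayed trial 10 kept despite its huge rt
  expect_equal(nrow(kept), 8)
  expect_false(any(kept$responded_before_audio_end))
  expect_true(10000 %in% tr$rt && !(10000 %in% kept$rt))
  expect_true(9000 %in% kept$rt)

  # median is recomputed by brute force over no-replay trials only
  no_replay <- tr$replays == 0 & !tr$responded_before_audio_end
  med <- median(tr$rt[no_replay])
  manual_drop <- tr$responded_before_audio_end |
    (tr$replays == 0 & tr$rt > 3 * med)
  expect_equal(kept$rt, tr$rt[!manual_drop])
})

test_that("exclusions are idempotent", {
  tr <- generate_trials(trial_spec(n_participants = 30, n_items = 10,
                                   n_fillers = 6, n_attention_checks = 4,
                                   seed = 41))
  res1 <- apply_participant_exclusions(tr)
  res2 <- apply_participant_exclusions(res1$trials)
  expect_equal(res2$trials, res1$trials)
  kept1 <- apply_trial_exclusions(res1$trials)
  expect_equal(apply_trial_exclusions(kept1), kept1)
})

test_that("the run rule fires only when enabled", {
  tr <- make_trials(rep("P1", 30),
                    response_choice = c(rep("first", 12), rep("second", 18)))
  tr$selected_affricate <- TRUE
  off <- apply_participant_exclusions(tr, exclusion_rules())
  expect_false(off$report$excluded)
  on <- apply_participant_exclusions(
    tr, exclusion_rules(run_rule_enabled = TRUE))
  expect_true(on$report$excluded)
  expect_match(on$report$reasons, "runs")
  # a run of 9 does not trigger the run-of-10 rule
  tr9 <- make_trials(rep("P1", 30),
                     response_choice = c(rep("first", 9),
                                         rep(c("second", "first"), length.out = 21)))
  on9 <- apply_participant_exclusions(
    tr9, exclusion_rules(run_rule_enabled = TRUE))
  expect_false(on9$report$excluded)
})

test_that("run probability DP matches closed forms and is monotone", {
  expect_equal(run_exclusion_probability(10, 10), 2 * 0.5^10)
  expect_equal(run_exclusion_probability(9, 10), 0)
  expect_equal(run_exclusion_probability(5, 1), 1)
  # n = k + 1: runs starting at position 1 or 2, minus the double count
  expect_equal(run_exclusion_probability(11, 10),
               2 * (2 * 0.5^10) - 2 * 0.5^11 - 2 * 0.5^11 + 2 * 0.5^11,
               tolerance = 1e-12)
  # asymmetric p: run of n in n trials has probability p^n + (1-p)^n
  expect_equal(run_exclusion_probability(4, 4, 0.3), 0.3^4 + 0.7^4,
               tolerance = 1e-12)
  probs_n <- vapply(10:60, run_exclusion_probability, numeric(1),
                    min_run = 10)
  expect_true(all(diff(probs_n) >= 0))
  probs_k <- vapply(2:12, function(k) run_exclusion_probability(40, k),
                    numeric(1))
  expect_true(all(diff(probs_k) <= 0))
})

test_that("run probability DP agrees with Monte Carlo", {
  withr::with_seed(101, {
    mc <- oracle_run_prob_mc(20, 5, 0.5, n_seq = 4e4)
    expect_lt(abs(run_exclusion_probability(20, 5) - mc$p), 3 * mc$se)
    mc2 <- oracle_run_prob_mc(30, 4, 0.3, n_seq = 4e4)
    expect_lt(abs(run_exclusion_probability(30, 4, 0.3) - mc2$p),
              3 * mc2$se)
  })
})

test_that("the selection model flags separation and recovers a null", {
  tr <- make_trials(rep(c("P1", "P2"), each = 5),
                    selected_affricate = TRUE, item = sprintf("I%d", 1:5))
  fit <- fit_selection_model(tr)
  expect_true(fit$boundary)
  expect_equal(fit$beta, Inf)

  tr0 <- generate_trials(trial_spec(n_participants = 60, n_items = 20,
                                    n_fillers = 0, n_attention_checks = 0,
                                    true_beta = 0, sd_participant = 0,
                                    sd_item = 0, premature_rate = 0,
                                    attention_error_rate = 0, seed = 51))
  fit0 <- fit_selection_model(tr0)
  expect_lt(abs(fit0$beta), 3 * fit0$se)
})

test_that("glmer agrees with an independent GLMM implementation", {
  skip_if_not_installed("glmmTMB")
  tr <- generate_trials(trial_spec(n_participants = 40, n_items = 12,
                                   n_fillers = 0, n_attention_checks = 0,
                                   true_beta = 0.6, premature_rate = 0,
                                   attention_error_rate = 0, seed = 61))
  fit <- fit_selection_model(tr)
  exp_tr <- tr[tr$trial_type == "experimental", ]
  exp_tr$y <- as.integer(exp_tr$selected_affricate)
  alt <- glmmTMB::glmmTMB(y ~ 1 + (1 | participant) + (1 | item),
                          data = exp_tr, family = stats::binomial())
  expect_equal(fit$beta, unname(glmmTMB::fixef(alt)$cond), tolerance = 0.005)
})

test_that("implied proportion is the inverse logit in percent", {
  expect_equal(implied_proportion(0), 50)
  expect_equal(implied_proportion(0.52), 63)
  expect_gt(implied_proportion(20, digits = NULL), 99.999)
  # round trip with the logit on (0, 100)
  for (pct in c(5, 37.5, 50, 63, 99)) {
    beta <- stats::qlogis(pct / 100)
    expect_equal(implied_proportion(beta, digits = NULL), pct,
                 tolerance = 1e-9)
  }
})
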