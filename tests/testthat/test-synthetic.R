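test_that("generators are pure functions of their specs", {
  s <- lexicon_spec(seed = 14)
  expect_identical(generate_lexicon_pair(s), generate_lexicon_pair(s))
  ts <- trial_spec(n_participants = 12, n_items = 6, n_fillers = 4,
                   n_attention_checks = 2, seed = 14)
  expect_identical(generate_trials(ts), generate_trials(ts))
  os <- oath_spec(n_pairs = 10, seed = 14)
  expect_identical(generate_oath_pairs(os), generate_oath_pairs(os))
})

test_that("full depletion removes the group from the target set only", {
  lex <- generate_lexicon_pair(lexicon_spec(depletion = 0, seed = 15))
  tgt <- lex[lex$kind == "target", ]
  ctl <- lex[lex$kind == "control", ]
  expect_equal(group_counts(tgt)$counts[["approximant"]], 0)
  expect_gt(group_counts(ctl)$counts[["approximant"]], 0)

  # depletion = 1 leaves the target and control expectations equal
  f <- attr(generate_lexicon_pair(lexicon_spec(seed = 15)),
            "true_frequencies")
  expect_equal(f$control, f$target)
})

test_that("generated class frequencies converge to the spec frequencies", {
  spec <- lexicon_spec(languages = "biglang", n_control_words = 25000,
                       n_target_words = 1, seed = 16)
  lex <- generate_lexicon_pair(spec)
  g <- group_counts(lex[lex$kind == "control", ])
  expect_gt(g$total_phonemes, 1e5 * 0.8)
  obs <- g$counts / g$total_phonemes
  for (k in phoneme_classes()) {
    expect_lt(abs(obs[[k]] - spec$class_frequencies[[k]]), 0.01)
  }
})

test_that("word lengths respect the configured bounds", {
  lex <- generate_lexicon_pair(lexicon_spec(languages = "l1",
                                            length_range = c(3L, 5L),
                                            seed = 17))
  lens <- nchar(lex$asjp)
  expect_true(all(lens >= 3 & lens <= 5))
})

test_that("planted contaminants are recovered exactly by the exclusions", {
  ts <- trial_spec(n_participants = 240, n_items = 10, n_fillers = 4,
                   n_attention_checks = 8, attention_error_rate = 0.075,
                   premature_rate = 0.025, seed = 18)
  tr <- generate_trials(ts)
  truth <- unique(tr[c("participant", ".truth")])
  expect_equal(sum(truth$.truth == "attention_failer"), 18)
  expect_equal(sum(truth$.truth == "premature"), 6)

  res <- apply_participant_exclusions(tr[setdiff(names(tr), ".truth")])
  expect_setequal(res$report$participant[res$report$attention],
                  truth$participant[truth$.truth == "attention_failer"])
  expect_setequal(res$report$participant[res$report$premature],
                  truth$participant[truth$.truth == "premature"])
})

test_that("a null trial generator yields a near-50% affricate choice rate", {
  tr <- generate_trials(trial_spec(n_participants = 100, n_items = 30,
                                   n_fillers = 0, n_attention_checks = 0,
                                   true_beta = 0, sd_participant = 0,
                                   sd_item = 0, premature_rate = 0,
                                   attention_error_rate = 0, seed = 19))
  frac <- mean(tr$selected_affricate[tr$trial_type == "experimental"])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 3000))
})

test_that("trial tables carry the full schema the readers expect", {
  tr <- generate_trials(trial_spec(n_participants = 5, n_items = 4,
                                   n_fillers = 2, n_attention_checks = 2,
                                   seed = 20))
  expect_true(all(c("participant", "native_language", "item", "trial_index",
                    "response_choice", "selected_affricate", "trial_type",
                    "correct", "rt", "replays",
                    "responded_before_audio_end") %in% names(tr)))
  expect_equal(nrow(tr), 5 * 8)
  expect_true(all(is.na(tr$selected_affricate[tr$trial_type != "experimental"])))
  expect_true(all(!is.na(tr$selected_affricate[tr$trial_type == "experimental"])))
  expect_true(all(!is.na(tr$correct[tr$trial_type == "attention_check"])))
  expect_true(all(tr$replays %in% 0:3))
})

test_that("oath substitutions move approximant counts in the right direction", {
  never <- generate_oath_pairs(oath_spec(n_pairs = 60, insertion_prob = 0,
                                         seed = 21))
  d_never <- count_approximants(never$minced_asjp) -
    count_approximants(never$original_asjp)
  expect_true(all(d_never <= 0))

  always <- generate_oath_pairs(oath_spec(n_pairs = 60, insertion_prob = 1,
                                          seed = 22))
  d_always <- count_approximants(always$minced_asjp) -
    count_approximants(always$original_asjp)
  expect_true(all(d_always >= 0))
  expect_gt(mean(d_always == 1), 0.5)  # most substitutions hit non-approximants

  # exactly one segment differs per pair
  one_sub <- mapply(function(o, m) {
    sum(strsplit(o, "")[[1]] != strsplit(m, "")[[1]])
  }, always$original_asjp, always$minced_asjp)
  expect_true(all(one_sub <= 1))
})

test_that("a planted depletion produces power above the null rate", {
  reject <- function(depletion, seeds) {
    vapply(seeds, function(s) {
      lex <- generate_lexicon_pair(lexicon_spec(depletion = depletion,
                                                seed = s))
      rec <- simulate_differences(lex[lex$kind == "target", ],
                                  lex[lex$kind == "control", ],
                                  n_sims = 200, seed = s)
      fit <- test_group_representation(rec, "approximant")
      fit$beta < 0 && !is.na(fit$p) && fit$p < 0.05
    }, logical(1))
  }
  power <- mean(reject(0.2, 1:20))
  expect_gt(power, 0.5)
})
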