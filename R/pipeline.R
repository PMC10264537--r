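#' Pipeline run configuration
#'
#' Bundles inputs, module settings and the master seed for the command-level
#' wrappers. Every artifact the commands emit embeds the resolved
#' configuration and seed so runs are reproducible.
#'
#' @param wordlist Path to a wordlist TSV (see [read_wordlist()]).
#' @param trials Path to a trials CSV (see [read_trials()]).
#' @param pairs Path to an oath-pairs CSV (see [read_oath_pairs()]).
#' @param out_dir Output directory, created if needed.
#' @param seed Master integer seed for all randomness.
#' @param n_sims Simulations per language for the resampling null.
#' @param replacement,denominator Passed to [simulate_differences()].
#' @param rules An [exclusion_rules()] object.
#' @param policy An [alpha_policy()] object.
#' @param w_convention Passed to [wilcoxon_signed_rank_pratt()].
#' @param verbose Print progress messages.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(wordlist = NULL, trials = NULL, pairs = NULL,
                       out_dir = ".", seed = 1L, n_sims = 1000,
                       replacement = TRUE, denominator = "all",
                       rules = exclusion_rules(), policy = alpha_policy(),
                       w_convention = "min", verbose = TRUE) {
  structure(list(wordlist = wordlist, trials = trials, pairs = pairs,
                 out_dir = out_dir, seed = as.integer(seed), n_sims = n_sims,
                 replacement = replacement, denominator = denominator,
                 rules = rules, policy = policy,
                 w_convention = w_convention, verbose = isTRUE(verbose)),
            class = "run_config")
}

config_meta <- function(config) {
  list(seed = config$seed, n_sims = config$n_sims,
       replacement = config$replacement, denominator = config$denominator,
       rules = unclass(config$rules), policy = unclass(config$policy),
       w_convention = config$w_convention)
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  config$out_dir
}

say <- function(config, ...) if (config$verbose) message(...)

#' Run the full resampling-null analysis
#'
#' Reads the wordlist, simulates the per-language null differences for all
#' six consonant groups, fits the per-group mixed models, applies the alpha
#' policy and writes `differences.csv` (+ JSON sidecar) and
#' `group_tests.json` to the output directory.
#'
#' @param config A [run_config()] with `wordlist` set.
#' @return Invisibly, a list with `records` and `fits`.
#' @export
cmd_simulate_null <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$wordlist))
  forms <- read_wordlist(config$wordlist)
  target <- forms[forms$kind == "target", , drop = FALSE]
  control <- forms[forms$kind == "control", , drop = FALSE]
  say(config, "simulating ", config$n_sims, " null samples per language")
  records <- simulate_differences(
    target, control, n_sims = config$n_sims, seed = config$seed,
    replacement = config$replacement, denominator = config$denominator)
  fits <- test_all_groups(records, config$policy)
  out <- ensure_out_dir(config)
  write_differences(records, file.path(out, "differences.csv"))
  jsonlite::write_json(
    list(config = config_meta(config),
         groups = lapply(fits, unclass)),
    file.path(out, "group_tests.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(config, "wrote ", file.path(out, "group_tests.json"))
  invisible(list(records = records, fits = fits))
}

#' Run the 2AFC exclusion and modelling pipeline
#'
#' Applies participant then trial exclusions, fits the logistic mixed model
#' of affricate selection on the surviving experimental trials, and writes
#' `exclusions.json` and `selection_fit.json`.
#'
#' @param config A [run_config()] with `trials` set.
#' @return Invisibly, a list with `report`, `fit` and the kept `trials`.
#' @export
cmd_analyze_2afc <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$trials))
  trials <- read_trials(config$trials)
  part <- apply_participant_exclusions(trials, config$rules)
  kept <- apply_trial_exclusions(part$trials, config$rules)
  fit <- fit_selection_model(kept)
  raw_prop <- mean(kept$selected_affricate[kept$trial_type == "experimental"])
  out <- ensure_out_dir(config)
  jsonlite::write_json(
    list(config = config_meta(config), participants = part$report),
    file.path(out, "exclusions.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  jsonlite::write_json(
    list(config = config_meta(config), fit = unclass(fit),
         implied_percent = implied_proportion(fit$beta),
         raw_percent = 100 * raw_prop),
    file.path(out, "selection_fit.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(config, "wrote ", file.path(out, "selection_fit.json"))
  invisible(list(report = part$report, fit = fit, trials = kept))
}

#' Run the minced-oath analysis
#'
#' Counts approximants in each pair, runs the Wilcoxon-Pratt signed-rank
#' test and writes `oath_results.json`.
#'
#' @param config A [run_config()] with `pairs` set.
#' @return Invisibly, the [analyze_pairs()] result.
#' @export
cmd_analyze_oaths <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$pairs))
  pairs <- read_oath_pairs(config$pairs)
  res <- analyze_pairs(pairs, convention = config$w_convention)
  out <- ensure_out_dir(config)
  jsonlite::write_json(
    list(config = config_meta(config),
         total_minced = res$total_minced,
         total_original = res$total_original,
         n_pairs = res$n_pairs, test = unclass(res$test)),
    file.path(out, "oath_results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(config, "wrote ", file.path(out, "oath_results.json"))
  invisible(res)
}

#' Generate a full synthetic dataset
#'
#' Writes a synthetic wordlist TSV, trial CSV and oath-pairs CSV (all with
#' the schemas the analysis commands read) plus a ground-truth JSON sidecar
#' to the output directory. All three generators are seeded from the
#' config's master seed.
#'
#' @param config A [run_config()]; its `seed` seeds all three generators.
#' @param lex_spec,tri_spec,oa_spec Optional generator specs; defaults are
#'   used when `NULL`, reseeded from the config.
#' @return Invisibly, a list of the written paths.
#' @export
cmd_generate <- function(config, lex_spec = NULL, tri_spec = NULL,
                         oa_spec = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(lex_spec)) lex_spec <- lexicon_spec(seed = config$seed)
  if (is.null(tri_spec)) tri_spec <- trial_spec(seed = config$seed + 1L)
  if (is.null(oa_spec)) oa_spec <- oath_spec(seed = config$seed + 2L)
  out <- ensure_out_dir(config)
  lex <- generate_lexicon_pair(lex_spec)
  trials <- generate_trials(tri_spec)
  pairs <- generate_oath_pairs(oa_spec)

  paths <- list(wordlist = file.path(out, "synthetic_wordlist.tsv"),
                trials = file.path(out, "synthetic_trials.csv"),
                pairs = file.path(out, "synthetic_pairs.csv"),
                truth = file.path(out, "ground_truth.json"))
  write_wordlist(lex, paths$wordlist)
  truth_tbl <- unique(trials[c("participant", ".truth")])
  utils::write.csv(trials[setdiff(names(trials), ".truth")],
                   paths$trials, row.names = FALSE)
  utils::write.csv(pairs, paths$pairs, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         lexicon = list(spec = unclass(lex_spec)[
           setdiff(names(unclass(lex_spec)), "class_frequencies")],
           class_frequencies = as.list(lex_spec$class_frequencies),
           true_frequencies = lapply(attr(lex, "true_frequencies"), as.list)),
         trials = list(spec = unclass(tri_spec),
                       participant_truth = truth_tbl),
         oaths = list(spec = unclass(oa_spec)[
           setdiff(names(unclass(oa_spec)), "class_frequencies")])),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  say(config, "wrote synthetic data to ", out)
  invisible(paths)
}

#' Print the run-length false-exclusion probability
#'
#' Thin wrapper over [run_exclusion_probability()] used by the command-line
#' interface.
#'
#' @param n_trials,min_run,p See [run_exclusion_probability()].
#' @param digits Decimal places printed (default 4).
#' @return The probability, invisibly.
#' @export
cmd_run_prob <- function(n_trials, min_run, p = 0.5, digits = 4) {
  prob <- run_exclusion_probability(n_trials, min_run, p)
  cat(formatC(round(prob, digits), format = "fg", digits = digits), "\n")
  invisible(prob)
}
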