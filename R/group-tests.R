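#' Alpha policy for the per-group tests
#'
#' One consonant group (plosives, by default, following the prior literature
#' on profanity) is tested at the planned alpha; the other five groups are
#' exploratory and judged at the Bonferroni-corrected level 0.05 / 5 = 0.01.
#' The corrected level is kept fixed rather than recomputed.
#'
#' @param planned_group Group tested at the planned level.
#' @param alpha_planned Planned-comparison alpha (default 0.05).
#' @param alpha_corrected Bonferroni level for the remaining groups
#'   (default 0.01).
#' @return List of class `"alpha_policy"`.
#' @export
alpha_policy <- function(planned_group = "plosive", alpha_planned = 0.05,
                         alpha_corrected = 0.01) {
  stopifnot(planned_group %in% phoneme_classes(),
            alpha_planned > 0, alpha_corrected > 0,
            alpha_corrected <= alpha_planned)
  structure(list(planned_group = planned_group,
                 alpha_planned = alpha_planned,
                 alpha_corrected = alpha_corrected),
            class = "alpha_policy")
}

#' Test a consonant group's representation across languages
#'
#' Fits an intercept-only mixed model `d ~ 1 + (1 | language)` to the
#' simulated per-100-phoneme differences of one consonant group, pooling
#' languages through a random intercept (REML, Satterthwaite degrees of
#' freedom). The intercept estimate is the cross-linguistic
#' over-representation (positive) or under-representation (negative) of the
#' group in the target lexicon.
#'
#' With a single language the model degrades gracefully to a one-sample
#' t-test on that language's `d` values. Degenerate input where every `d` is
#' identical returns that value with `se = 0` and a `degenerate` flag rather
#' than an error.
#'
#' @param records Difference records from [simulate_differences()].
#' @param group One of [consonant_groups()].
#' @return List of class `"repr_fit"` with elements `group`, `beta`, `se`,
#'   `t`, `df`, `p`, `n_obs`, `n_languages`, `method`, `degenerate`.
#' @export
test_group_representation <- function(records, group) {
  stopifnot(group %in% consonant_groups())
  rec <- records[records$group == group, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for group ", sQuote(group))
  d <- rec$d
  n_lang <- length(unique(rec$language))
  base <- list(group = group, n_obs = length(d), n_languages = n_lang,
               degenerate = FALSE)

  as_fit <- function(beta, se, t, df, p, method, degenerate = FALSE) {
    structure(list(group = base$group, beta = beta, se = se, t = t, df = df,
                   p = p, n_obs = base$n_obs,
                   n_languages = base$n_languages, method = method,
                   degenerate = degenerate),
              class = "repr_fit")
  }

  if (isTRUE(all(d == d[1]))) {
    t_val <- if (d[1] == 0) 0 else sign(d[1]) * Inf
    return(as_fit(d[1], 0, t_val, NA_real_, NA_real_,
                  "degenerate_constant", degenerate = TRUE))
  }

  if (n_lang == 1L) {
    tt <- stats::t.test(d, mu = 0)
    return(as_fit(unname(tt$estimate), unname(tt$stderr),
                  unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  "one_sample_t"))
  }

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(d ~ 1 + (1 | language), data = rec, REML = TRUE)
  ))
  cf <- stats::coef(summary(fit))
  as_fit(unname(cf[1, "Estimate"]), unname(cf[1, "Std. Error"]),
         unname(cf[1, "t value"]), unname(cf[1, "df"]),
         unname(cf[1, "Pr(>|t|)"]), "lmm_reml_satterthwaite")
}

#' @export
print.repr_fit <- function(x, ...) {
  cat("Consonant-group representation test (", x$method, ")\n", sep = "")
  cat(sprintf("  group = %s: beta = %.3f, SE = %.3f, t = %.2f, p = %.4g\n",
              x$group, x$beta, x$se, x$t, x$p))
  cat(sprintf("  %d observations over %d language(s)\n",
              x$n_obs, x$n_languages))
  invisible(x)
}

#' Apply the planned/corrected alpha policy to a fit
#'
#' @param fit A `"repr_fit"` from [test_group_representation()].
#' @param policy An [alpha_policy()].
#' @return One of `"significant_planned"`, `"significant_corrected"`,
#'   `"not_significant"`.
#' @examples
#' f <- structure(list(group = "plosive", p = 0.04), class = "repr_fit")
#' decide_representation(f, alpha_policy())  # "significant_planned"
#' @export
decide_representation <- function(fit, policy = alpha_policy()) {
  stopifnot(inherits(policy, "alpha_policy"), !is.null(fit$p))
  if (is.na(fit$p)) return("not_significant")
  if (identical(fit$group, policy$planned_group)) {
    if (fit$p < policy$alpha_planned) "significant_planned"
    else "not_significant"
  } else {
    if (fit$p < policy$alpha_corrected) "significant_corrected"
    else "not_significant"
  }
}

#' Per-language empirical two-sided p-values
#'
#' Distribution-free companion to the mixed model: for each language, the
#' empirical two-sided tail probability of the simulated differences around
#' zero, `p = 2 * min(frac(d <= 0), frac(d >= 0))`, floored at `2/n_sims`
#' (the value when every simulation falls on one side) and capped at 1.
#'
#' @param records Difference records from [simulate_differences()].
#' @param group One of [consonant_groups()].
#' @return Data frame with columns `language`, `p`, `n_sims`.
#' @export
empirical_quantile_p <- function(records, group) {
  stopifnot(group %in% consonant_groups())
  rec <- records[records$group == group, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for group ", sQuote(group))
  langs <- sort(unique(rec$language))
  res <- lapply(langs, function(lang) {
    d <- rec$d[rec$language == lang]
    n <- length(d)
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    data.frame(language = lang, p = min(max(p, 2 / n), 1), n_sims = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the representation tests for all six consonant groups
#'
#' Convenience wrapper: fits [test_group_representation()] per group and
#' applies the alpha policy.
#'
#' @param records Difference records from [simulate_differences()].
#' @param policy An [alpha_policy()].
#' @return Named list of `"repr_fit"` objects, one per consonant group, each
#'   with an added `decision` element.
#' @export
test_all_groups <- function(records, policy = alpha_policy()) {
  fits <- lapply(consonant_groups(), function(g) {
    fit <- test_group_representation(records, g)
    fit$decision <- decide_representation(fit, policy)
    fit
  })
  stats::setNames(fits, consonant_groups())
}
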