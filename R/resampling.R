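#' Pool the phoneme tokens of a control lexicon
#'
#' Collects all segment tokens across all forms of the control list into a
#' single multiset (character vector with multiplicity preserved). This is
#' the population the resampling null draws from.
#'
#' @param control Data frame of control forms (columns as in
#'   [read_wordlist()]) or a character vector of ASJP transcriptions.
#' @param modifier_mode Passed to [tokenize_asjp()].
#' @return Character vector of phoneme tokens.
#' @export
build_phoneme_pool <- function(control, modifier_mode = "strip") {
  if (is.data.frame(control)) control <- control$asjp
  if (length(control) == 0L) stop("control lexicon is empty")
  pool <- unlist(lapply(control, tokenize_asjp, modifier_mode = modifier_mode))
  if (length(pool) == 0L) stop("control lexicon contains no phonemes")
  pool
}

# Deterministic 32-bit stream seed for a language under a master seed.
language_seed <- function(seed, language) {
  h <- 0
  for (code in utf8ToInt(language)) h <- (h * 31 + code) %% 2147483647
  as.integer((seed %% 2147483647 + h) %% 2147483647)
}

#' Monte-Carlo null differences of consonant-group frequencies
#'
#' For each language shared by the target (swear-word) and control (Swadesh)
#' lexicons, draws `n_sims` random samples of phonemes from the pooled
#' control list — each sample as large as the total number of phonemes in
#' that language's target set — and records, for each of the six consonant
#' groups, the difference between the group's count in the target set and in
#' the sample, divided by the target's total phoneme count and scaled (by
#' default per 100 phonemes):
#' `d = scale * (n_target(g) - n_sample(g)) / N`.
#'
#' Negative `d` therefore means the group is rarer in the swear words than
#' in control samples (under-representation). Each language gets its own
#' deterministic random stream derived from `seed`, so results are
#' reproducible and independent of language order.
#'
#' @param target,control Wordlist data frames ([read_wordlist()]); `kind`
#'   columns are not consulted, the two arguments define the roles.
#' @param n_sims Number of simulations per language (default 1000).
#' @param seed Master integer seed.
#' @param replacement Sample phonemes with replacement (default) or without
#'   (requires the pool to be at least as large as the target count).
#' @param scale Factor applied to the proportion; default 100 reports
#'   differences per 100 phonemes.
#' @param table Classification table.
#' @param denominator Count `"all"` phonemes (vowels included, default) or
#'   `"consonants"` only in the target total N and sample size.
#' @param return_counts If `TRUE`, attach the full per-simulation sampled
#'   class counts (all eight classes) as attribute `"sample_counts"`, a list
#'   of matrices keyed by language.
#' @return Data frame with columns `language`, `group`, `sim_id`, `d`, with
#'   attributes `seed` and `settings`.
#' @export
simulate_differences <- function(target, control, n_sims = 1000, seed = 1L,
                                 replacement = TRUE, scale = 100,
                                 table = asjp_classification(),
                                 denominator = c("all", "consonants"),
                                 return_counts = FALSE) {
  denominator <- match.arg(denominator)
  stopifnot(n_sims >= 1)
  langs <- sort(intersect(unique(target$language), unique(control$language)))
  if (length(langs) == 0L) stop("no language present in both lexicons")
  groups <- consonant_groups()
  out <- vector("list", length(langs))
  count_mats <- if (return_counts) vector("list", length(langs)) else NULL

  for (i in seq_along(langs)) {
    lang <- langs[i]
    tgt_tokens <- build_phoneme_pool(target[target$language == lang, ])
    pool <- build_phoneme_pool(control[control$language == lang, ])
    tgt_cls <- classify_phonemes(tgt_tokens, table)
    pool_cls <- classify_phonemes(pool, table)
    if (denominator == "consonants") {
      keep_t <- tgt_cls %in% groups
      tgt_cls <- tgt_cls[keep_t]
      keep_p <- pool_cls %in% groups
      pool_cls <- pool_cls[keep_p]
    }
    n_target <- length(tgt_cls)
    if (n_target < 1L) stop("target lexicon for ", lang, " has no phonemes")
    if (!replacement && n_target > length(pool_cls)) {
      stop("without-replacement sampling needs a control pool at least as ",
           "large as the target phoneme count (", lang, ": ",
           length(pool_cls), " < ", n_target, ")")
    }
    tgt_counts <- table(factor(tgt_cls, levels = phoneme_classes()))
    pool_f <- factor(pool_cls, levels = phoneme_classes())

    samp <- withr::with_seed(language_seed(seed, lang), {
      if (replacement) {
        idx <- sample.int(length(pool_f), n_target * n_sims, replace = TRUE)
        matrix(as.integer(pool_f)[idx], nrow = n_sims, byrow = TRUE)
      } else {
        t(vapply(seq_len(n_sims), function(s) {
          as.integer(pool_f)[sample.int(length(pool_f), n_target)]
        }, integer(n_target)))
      }
    })
    # per-sim class counts: rows sims, cols the eight classes
    counts <- vapply(seq_along(phoneme_classes()), function(k) {
      rowSums(samp == k)
    }, numeric(n_sims))
    colnames(counts) <- phoneme_classes()
    if (return_counts) count_mats[[i]] <- counts

    d <- scale * (matrix(rep(as.numeric(tgt_counts[groups]), each = n_sims),
                         nrow = n_sims) - counts[, groups, drop = FALSE]) /
      n_target
    out[[i]] <- data.frame(
      language = lang,
      group = rep(groups, each = n_sims),
      sim_id = rep(seq_len(n_sims), times = length(groups)),
      d = as.vector(d),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  attr(res, "settings") <- list(n_sims = n_sims, replacement = replacement,
                                scale = scale, denominator = denominator)
  if (return_counts) {
    names(count_mats) <- langs
    attr(res, "sample_counts") <- count_mats
  }
  res
}

#' Write simulated differences and their settings
#'
#' Saves the long-format difference records as CSV plus a JSON sidecar with
#' the simulation settings and seed.
#'
#' @param records Output of [simulate_differences()].
#' @param path CSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_differences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(seed = attr(records, "seed"), settings = attr(records, "settings")),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
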