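#' Count approximants in a transcription
#'
#' Number of segments classified as approximants (`l`, `L`, `w`, `y`, `r`)
#' in an ASJP transcription. Rhoticity is a property of the transcription,
#' not of this count: a non-rhotic (British-style) rendering of "darn" is
#' `dan` and scores zero approximants.
#'
#' @param asjp Character vector of ASJP transcriptions.
#' @param table Classification table.
#' @return Integer vector of approximant counts.
#' @examples
#' count_approximants("frigiN")  # 1 (frigging)
#' count_approximants("fakiN")   # 0 (fucking)
#' @export
count_approximants <- function(asjp, table = asjp_classification()) {
  vapply(asjp, function(x) {
    toks <- tokenize_asjp(x)
    sum(classify_phonemes(toks, table) == "approximant")
  }, integer(1), USE.NAMES = FALSE)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Signed-rank test for paired count differences. Under the Pratt method,
#' absolute differences are ranked with the zeros included (midranks for
#' ties) and the ranks belonging to zero differences are then discarded from
#' the statistic. `W` is, under the default convention, the smaller of the
#' positive and negative rank sums.
#'
#' The p-value is exact — full enumeration of all sign assignments of the
#' nonzero ranks — when the number of nonzero differences is at most
#' `exact_limit`, and otherwise uses a normal approximation with the
#' zero- and tie-adjusted variance of the positive rank sum.
#'
#' @param diffs Integer/numeric vector of paired differences (here, minced
#'   minus original approximant counts).
#' @param convention Which statistic to report as `w`: `"min"` (default) of
#'   the two rank sums, or the `"positive"` / `"negative"` sum.
#' @param zero_method `"pratt"` (default: rank zeros, then drop their
#'   ranks) or `"wilcox"` (drop zero differences before ranking).
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @param exact_limit Largest number of nonzero differences for which
#'   `"auto"` enumerates exactly (default 15).
#' @return List of class `"wilcoxon_pratt"`: `w`, `w_pos`, `w_neg`, `p`,
#'   `n_pairs`, `n_nonzero`, `method`, `zero_method`, `convention`,
#'   `degenerate`.
#' @examples
#' wilcoxon_signed_rank_pratt(c(2, 1, 1, 0, -1))
#' @export
wilcoxon_signed_rank_pratt <- function(diffs,
                                       convention = c("min", "positive",
                                                      "negative"),
                                       zero_method = c("pratt", "wilcox"),
                                       method = c("auto", "exact", "normal"),
                                       exact_limit = 15) {
  convention <- match.arg(convention)
  zero_method <- match.arg(zero_method)
  method <- match.arg(method)
  stopifnot(length(diffs) >= 1, !anyNA(diffs))
  n_pairs <- length(diffs)

  if (zero_method == "wilcox") diffs <- diffs[diffs != 0]
  nonzero <- diffs != 0
  n_nonzero <- sum(nonzero)

  if (n_nonzero == 0L) {
    return(structure(list(w = 0, w_pos = 0, w_neg = 0, p = 1,
                          n_pairs = n_pairs, n_nonzero = 0L,
                          method = "degenerate", zero_method = zero_method,
                          convention = convention, degenerate = TRUE),
                     class = "wilcoxon_pratt"))
  }

  # Pratt: rank |d| including zeros, then keep only nonzero ranks.
  r_all <- rank(abs(diffs))
  r <- r_all[nonzero]
  s <- sign(diffs)[nonzero]
  w_pos <- sum(r[s > 0])
  w_neg <- sum(r[s < 0])
  w <- switch(convention, min = min(w_pos, w_neg), positive = w_pos,
              negative = w_neg)

  use_exact <- method == "exact" ||
    (method == "auto" && n_nonzero <= exact_limit)
  if (use_exact && n_nonzero > 25L) {
    stop("exact enumeration limited to 25 nonzero differences")
  }

  if (use_exact) {
    # distribution of the positive rank sum over all 2^m sign assignments
    wdist <- 0
    for (rk in r) wdist <- c(wdist, wdist + rk)
    p <- min(1, 2 * min(mean(wdist <= w_pos), mean(wdist >= w_pos)))
    method_used <- "exact"
  } else {
    n <- length(diffs)
    z0 <- n - n_nonzero
    mu <- (n * (n + 1) - z0 * (z0 + 1)) / 4
    sigma2 <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24
    ties <- table(r)  # midrank groups among nonzero ranks
    sigma2 <- sigma2 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w_pos - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method_used <- "normal_approx"
  }

  structure(list(w = w, w_pos = w_pos, w_neg = w_neg, p = min(p, 1),
                 n_pairs = n_pairs, n_nonzero = n_nonzero,
                 method = method_used, zero_method = zero_method,
                 convention = convention, degenerate = FALSE),
            class = "wilcoxon_pratt")
}

#' @export
print.wilcoxon_pratt <- function(x, ...) {
  cat("Wilcoxon signed-rank test (zeros: ", x$zero_method, ", p: ",
      x$method, ")\n", sep = "")
  cat(sprintf("  W = %g (%s convention; W+ = %g, W- = %g), p = %.4g\n",
              x$w, x$convention, x$w_pos, x$w_neg, x$p))
  cat(sprintf("  %d pairs, %d nonzero differences\n",
              x$n_pairs, x$n_nonzero))
  if (isTRUE(x$degenerate)) cat("  note: all differences zero\n")
  invisible(x)
}

#' Read a minced-oath pairs table
#'
#' CSV with columns `original_orth`, `original_asjp`, `minced_orth`,
#' `minced_asjp` and optionally `source` (e.g. OED or wiki).
#'
#' @param path CSV path.
#' @return Data frame of pairs.
#' @export
read_oath_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("original_orth", "original_asjp", "minced_orth", "minced_asjp")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("pairs table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Paired analysis of approximants in swear words and their minced oaths
#'
#' Counts approximants in each original swear word and its minced variant
#' (originals are counted once per pair, so a source word with several
#' minced variants contributes with multiplicity, matching the paired
#' design), totals them, and runs the Wilcoxon signed-rank test with Pratt
#' zero handling on the per-pair differences (minced minus original).
#'
#' @param pairs Data frame from [read_oath_pairs()] or
#'   [generate_oath_pairs()].
#' @param table Classification table.
#' @param ... Passed to [wilcoxon_signed_rank_pratt()].
#' @return List of class `"oath_analysis"`: `total_minced`,
#'   `total_original`, `n_pairs`, `test` (a `"wilcoxon_pratt"`), and `pairs`
#'   (input with `approx_original`, `approx_minced`, `diff` columns).
#' @export
analyze_pairs <- function(pairs, table = asjp_classification(), ...) {
  stopifnot(nrow(pairs) >= 1,
            all(c("original_asjp", "minced_asjp") %in% names(pairs)))
  pairs$approx_original <- count_approximants(pairs$original_asjp, table)
  pairs$approx_minced <- count_approximants(pairs$minced_asjp, table)
  pairs$diff <- pairs$approx_minced - pairs$approx_original
  structure(list(total_minced = sum(pairs$approx_minced),
                 total_original = sum(pairs$approx_original),
                 n_pairs = nrow(pairs),
                 test = wilcoxon_signed_rank_pratt(pairs$diff, ...),
                 pairs = pairs),
            class = "oath_analysis")
}

#' @export
print.oath_analysis <- function(x, ...) {
  cat(sprintf("Approximants in %d minced-oath pairs: %d (minced) vs %d (original)\n",
              x$n_pairs, x$total_minced, x$total_original))
  print(x$test)
  invisible(x)
}
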