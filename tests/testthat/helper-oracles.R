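# Independent oracles and fixture builders shared across test files.

# Brute-force Wilcoxon signed-rank with Pratt zero handling: enumerates all
# 2^m sign assignments of the nonzero ranks via expand.grid (deliberately a
# different code path from the package's iterative doubling).
oracle_wilcoxon_pratt <- function(diffs, convention = "min") {
  r_all <- rank(abs(diffs))
  keep <- diffs != 0
  r <- r_all[keep]
  s <- sign(diffs)[keep]
  w_pos <- sum(r[s > 0])
  w_neg <- sum(r[s < 0])
  w <- switch(convention, min = min(w_pos, w_neg), positive = w_pos,
              negative = w_neg)
  m <- length(r)
  if (m == 0) return(list(w = 0, p = 1))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  wdist <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(wdist <= w_pos), mean(wdist >= w_pos)))
  list(w = w, w_pos = w_pos, w_neg = w_neg, p = p)
}

# Monte-Carlo estimate of P(run >= min_run in n iid binary trials), chunked
# so memory stays flat. Returns the estimate and its standard error.
oracle_run_prob_mc <- function(n_trials, min_run, p = 0.5, n_seq = 1e5,
                               chunk = 5e4) {
  hits <- 0
  done <- 0
  width <- min_run - 1L
  while (done < n_seq) {
    m <- min(chunk, n_seq - done)
    x <- matrix(stats::runif(m * n_trials) < p, nrow = m)
    same <- x[, -1, drop = FALSE] == x[, -n_trials, drop = FALSE]
    if (width == 0L) {
      hits <- hits + m
    } else if (ncol(same) >= width) {
      run9 <- matrix(0L, nrow = m, ncol = ncol(same) - width + 1L)
      for (j in seq_len(width)) {
        run9 <- run9 + same[, j:(j + ncol(run9) - 1L), drop = FALSE]
      }
      hits <- hits + sum(apply(run9 == width, 1, any))
    }
    done <- done + m
  }
  est <- hits / n_seq
  list(p = est, se = sqrt(est * (1 - est) / n_seq))
}

# Minimal hand-built trial table: one row per entry of the argument lists.
make_trials <- function(participant, trial_type = "experimental",
                        correct = NA, rt = 1500, replays = 0,
                        premature = FALSE, selected_affricate = NA,
                        response_choice = "first", item = NULL) {
  n <- max(length(participant), length(trial_type), length(correct),
           length(rt), length(replays), length(premature),
           length(selected_affricate), length(response_choice))
  df <- data.frame(
    participant = rep_len(participant, n),
    native_language = "testlang",
    item = if (is.null(item)) sprintf("I%02d", seq_len(n)) else
      rep_len(item, n),
    trial_index = stats::ave(rep(1, n), rep_len(participant, n),
                             FUN = seq_along),
    response_choice = rep_len(response_choice, n),
    selected_affricate = rep_len(selected_affricate, n),
    trial_type = rep_len(trial_type, n),
    correct = rep_len(correct, n),
    rt = rep_len(rt, n),
    replays = rep_len(replays, n),
    responded_before_audio_end = rep_len(premature, n),
    stringsAsFactors = FALSE
  )
  df
}
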