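# Scalp-level statistics: N2P2 peak-to-peak amplitude, habituation
# index, Welch t from summaries, permutation two-sample test, and the
# windowed-sinc FIR filter-order heuristic.

#' N2P2 peak-to-peak amplitude
#'
#' The peak-to-peak amplitude of a laser-evoked potential at one
#' channel: the maximum within the P2 window minus the minimum within
#' the N2 window. The N2 window must precede the P2 window; windows may
#' overlap. Ties are broken by the earliest sample.
#'
#' @param waveform numeric vector (µV) on a uniform epoch grid.
#' @param times sample times (s), same length as `waveform`.
#' @param n2_window length-2 numeric, N2 search window (s).
#' @param p2_window length-2 numeric, P2 search window (s).
#' @return peak-to-peak amplitude (µV).
#' @export
n2p2_amplitude <- function(waveform, times,
                           n2_window = c(0.130, 0.300),
                           p2_window = c(0.280, 0.500)) {
  stopifnot(length(waveform) == length(times),
            n2_window[1] < n2_window[2], p2_window[1] < p2_window[2],
            n2_window[1] <= p2_window[1])
  in_n2 <- times >= n2_window[1] & times <= n2_window[2]
  in_p2 <- times >= p2_window[1] & times <= p2_window[2]
  if (!any(in_n2) || !any(in_p2)) stop("empty N2 or P2 window")
  max(waveform[in_p2]) - min(waveform[in_n2])
}

#' Habituation index
#'
#' Percentage change in N2P2 amplitude from the first to the third
#' block: `(first - third) / first * 100`. Amplitude reductions
#' (habituation) give positive values; facilitations give negative
#' values.
#'
#' @param amp_block1 first-block N2P2 amplitude (µV), nonzero.
#' @param amp_block3 third-block N2P2 amplitude (µV).
#' @return habituation index (%).
#' @export
habituation_index <- function(amp_block1, amp_block3) {
  if (any(amp_block1 == 0)) stop("zero first-block amplitude")
  (amp_block1 - amp_block3) / amp_block1 * 100
}

#' Group summary statistics
#'
#' @param mean,sd,n group mean, standard deviation (>= 0) and size (>= 2).
#' @return object of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

#' Welch two-sample t statistic from group summaries
#'
#' Unequal-variance t statistic computed from means, SDs and sizes:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`. The first group is the
#' numerator's first term, so `welch_t(a, b) = -welch_t(b, a)`.
#'
#' @param g1,g2 `summary_stats` (or lists with mean/sd/n).
#' @param df also return the Welch-Satterthwaite degrees of freedom?
#' @return the t statistic, or (if `df = TRUE`) a list with `t` and `df`.
#' @export
welch_t <- function(g1, g2, df = FALSE) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  if (!df) return(t)
  nu <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  list(t = t, df = nu)
}

.welch_t_raw <- function(x, y) {
  welch_t(summary_stats(mean(x), stats::sd(x), length(x)),
          summary_stats(mean(y), stats::sd(y), length(y)))
}

#' Permutation two-sample t test
#'
#' Nonparametric two-sample test: the observed statistic is the Welch t
#' on the raw samples; the null distribution is built by randomly
#' reassigning group labels `n_perm` times. The p value uses the add-one
#' estimator `(1 + #extreme) / (1 + n_perm)`, so the smallest achievable
#' p is `1 / (1 + n_perm)`.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param n_perm number of permutations (>= 100; ignored when
#'   `exact = TRUE`).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (refers to
#'   the statistic for `x` vs `y`).
#' @param seed integer seed (mandatory for the sampled test;
#'   permutations are reproducible).
#' @param exact enumerate all group assignments instead of sampling
#'   (feasible for small samples; the p value is then the exact
#'   permutation p, with the observed assignment included).
#' @return object of class `perm_test`: list with `t`, `p`,
#'   `alternative`, `n_perm`, `seed`.
#' @export
permutation_t_test <- function(x, y, n_perm = 5000,
                               alternative = c("two.sided", "less",
                                               "greater"),
                               seed = NULL, exact = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate samples: zero variance in both groups")
  t_obs <- .welch_t_raw(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  if (exact) {
    n_total <- choose(length(pooled), nx)
    if (n_total > 1e5) stop("too many assignments for an exact test")
    idx_all <- utils::combn(length(pooled), nx)
    t_perm <- apply(idx_all, 2, function(idx)
      .welch_t_raw(pooled[idx], pooled[-idx]))
    denom <- n_total
    add <- 0
  } else {
    stopifnot(n_perm >= 100, !is.null(seed))
    t_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nx)
      .welch_t_raw(pooled[idx], pooled[-idx])
    }, numeric(1)))
    denom <- n_perm + 1
    add <- 1
  }
  extreme <- switch(alternative,
    two.sided = abs(t_perm) >= abs(t_obs) - 1e-12,
    less = t_perm <= t_obs + 1e-12,
    greater = t_perm >= t_obs - 1e-12)
  p <- (add + sum(extreme)) / denom
  structure(list(t = t_obs, p = p, alternative = alternative,
                 n_perm = if (exact) ncol(idx_all) else n_perm,
                 seed = seed, exact = exact),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation Welch t test: t = %.3f, p = %.4g (%s, %d permutations)\n",
              x$t, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' FIR filter order by the windowed-sinc default heuristic
#'
#' The default order heuristic for a Hamming-windowed sinc band-pass
#' filter: each band edge gets a transition bandwidth
#' `min(max(0.25 * edge, 2 Hz), edge)`; the order is
#' `3.3 / (narrowest transition bandwidth / sampling rate)`, rounded up
#' to the next even integer.
#'
#' @param sampling_rate sampling rate (Hz).
#' @param low_edge,high_edge band-pass edges (Hz);
#'   `0 < low_edge < high_edge < sampling_rate / 2`.
#' @return even integer filter order.
#' @export
fir_order_hamming <- function(sampling_rate, low_edge, high_edge) {
  stopifnot(low_edge > 0, high_edge > low_edge,
            high_edge < sampling_rate / 2)
  tb <- function(edge) min(max(0.25 * edge, 2), edge)
  tbw <- min(tb(low_edge), tb(high_edge))
  order <- 3.3 / (tbw / sampling_rate)
  as.integer(2 * ceiling(order / 2))
}

#' Per-subject habituation table and group comparison
#'
#' Computes each subject's N2P2 amplitudes (block 1 and block 3) at one
#' channel, the habituation index, and the between-group permutation
#' Welch t test on the indices.
#'
#' @param records list of `evoked_record`s covering both blocks for
#'   every subject (conditions `"block1"` and `"block3"`).
#' @param channel channel label to score (default: the channel with the
#'   largest mean block-1 variance across subjects, a proxy for the
#'   vertex electrode of a real montage).
#' @param n2_window,p2_window peak search windows (s), see
#'   [n2p2_amplitude()].
#' @param n_perm,seed permutation-test settings, see
#'   [permutation_t_test()].
#' @param alternative sidedness of the group test.
#' @return object of class `habituation_result`: list with `table` (one
#'   row per subject: subject, group, amp1, amp3, hi), `channel`,
#'   `group_stats`, and `test` (a `perm_test` comparing migraine vs
#'   control habituation indices).
#' @export
habituation_test <- function(records, channel = NULL,
                             n2_window = c(0.130, 0.300),
                             p2_window = c(0.280, 0.500),
                             n_perm = 5000,
                             alternative = "two.sided", seed = 1L) {
  cond <- vapply(records, function(r) r$condition, character(1))
  subj <- vapply(records, function(r) r$subject, character(1))
  b1 <- records[cond == "block1"]
  b3 <- records[cond == "block3"]
  names(b1) <- subj[cond == "block1"]
  names(b3) <- subj[cond == "block3"]
  common <- intersect(names(b1), names(b3))
  if (length(common) < 4L) stop("need block1 and block3 for >= 4 subjects")
  if (is.null(channel)) {
    v <- Reduce(`+`, lapply(b1[common],
                            function(r) apply(r$data, 1, stats::var)))
    channel <- names(which.max(v))
  }
  rows <- lapply(common, function(s) {
    r1 <- b1[[s]]; r3 <- b3[[s]]
    a1 <- n2p2_amplitude(r1$data[channel, ], evoked_times(r1),
                         n2_window, p2_window)
    a3 <- n2p2_amplitude(r3$data[channel, ], evoked_times(r3),
                         n2_window, p2_window)
    data.frame(subject = s, group = r1$group, amp1 = a1, amp3 = a3,
               hi = habituation_index(a1, a3))
  })
  tab <- do.call(rbind, rows)
  hi_m <- tab$hi[tab$group == "migraine"]
  hi_c <- tab$hi[tab$group == "control"]
  test <- permutation_t_test(hi_m, hi_c, n_perm = n_perm,
                             alternative = alternative, seed = seed)
  gs <- lapply(split(tab$hi, tab$group), function(z)
    summary_stats(mean(z), stats::sd(z), length(z)))
  structure(list(table = tab, channel = channel, group_stats = gs,
                 test = test),
            class = "habituation_result")
}

#' @export
print.habituation_result <- function(x, ...) {
  cat("Habituation at channel", x$channel, "\n")
  for (g in names(x$group_stats)) {
    s <- x$group_stats[[g]]
    cat(sprintf("  %-9s HI: M = %.2f, SD = %.2f, n = %d\n",
                g, s$mean, s$sd, s$n))
  }
  print(x$test)
  invisible(x)
}
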