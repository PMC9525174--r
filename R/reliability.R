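# Stimulus-locked firing screen: split-half PSTH reliability, a shuffled-ISI
# permutation null, and FDR correction across units.

# fast row-wise Pearson correlation of two matrices (rows are vectors);
# rows where either vector has zero variance get 0, so silent halves score 0
# rather than NA.
.row_cor0 <- function(A, B) {
  n <- ncol(A)
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A * A) * rowSums(B * B))
  r <- ifelse(den > 0, num / den, 0)
  pmax(pmin(r, 1), -1)
}

# random disjoint half-splits of `ntr` trials as 0/1 selection matrices
# (ntr x n_iter); odd counts drop one random trial per iteration. Consumes
# RNG.
.make_splits <- function(ntr, n_iter) {
  half <- ntr %/% 2L
  if (half < 1L) stop("need at least 2 trials")
  perms <- replicate(n_iter, sample.int(ntr))
  sel_a <- matrix(0, ntr, n_iter)
  sel_b <- matrix(0, ntr, n_iter)
  sel_a[cbind(as.vector(perms[seq_len(half), , drop = FALSE]),
              rep(seq_len(n_iter), each = half))] <- 1
  sel_b[cbind(as.vector(perms[half + seq_len(half), , drop = FALSE]),
              rep(seq_len(n_iter), each = half))] <- 1
  list(sel_a = sel_a, sel_b = sel_b, half = half)
}

# split-half score from a per-trial count matrix M (n_trials x n_bins);
# draws fresh splits unless a precomputed set is supplied.
.split_half_score <- function(M, n_iter, splits = NULL) {
  if (is.null(splits)) splits <- .make_splits(nrow(M), n_iter)
  A <- crossprod(splits$sel_a, M) / splits$half
  B <- crossprod(splits$sel_b, M) / splits$half
  mean(.row_cor0(A, B))
}

# bin event-relative spike times (vectors) into a trial x bin count matrix
.bin_counts <- function(tt, tr, n_trials, bin_s, span) {
  n_bins <- as.integer(round((span[2] - span[1]) / bin_s))
  keep <- tt >= span[1] & tt < span[1] + n_bins * bin_s
  bin <- pmin(floor((tt[keep] - span[1]) / bin_s), n_bins - 1L)
  counts <- tabulate(tr[keep] * n_bins + bin + 1L,
                     nbins = n_trials * n_bins)
  matrix(counts, nrow = n_trials, ncol = n_bins, byrow = TRUE)
}

#' Split-half PSTH reliability score
#'
#' For each iteration, trials are split at random into two disjoint halves, a
#' PSTH is built from each half over the analysis span, and the Pearson
#' correlation (the zero-lag cross-correlation coefficient) of the two PSTH
#' vectors is taken. The score is the mean coefficient over `n_iter`
#' iterations. An iteration in which either half-PSTH has zero variance
#' contributes a coefficient of 0.
#'
#' @param dataset a [spike_dataset()].
#' @param unit_id unit to score.
#' @param schedule optional [stimulus_schedule()] (defaults to the dataset's).
#' @param n_iter number of random splits (default 1000).
#' @param bin_s PSTH bin width, s (default 0.010).
#' @param seed optional integer seed for the trial splits.
#' @return mean split-half correlation in `[-1, 1]`.
#' @export
split_half_reliability <- function(dataset, unit_id,
                                   schedule = dataset$schedule,
                                   n_iter = 1000, bin_s = 0.010,
                                   seed = NULL) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  M <- .trial_bin_matrix(dataset, unit_id, bin_s,
                         c(schedule$analysis_start, schedule$analysis_end))
  .split_half_score(M, n_iter)
}

#' Shuffle the interspike intervals of one spike train
#'
#' Permutes the interspike intervals uniformly at random, preserving the
#' first spike time, the spike count, and (because a permutation preserves
#' the ISI sum) the last spike time. Trains with fewer than two spikes are
#' returned unchanged.
#'
#' @param spike_times sorted numeric vector of spike times for one trial.
#' @return shuffled, sorted spike times.
#' @export
isi_shuffle <- function(spike_times) {
  n <- length(spike_times)
  if (n < 2) return(spike_times)
  isi <- diff(spike_times)
  spike_times[1] + c(0, cumsum(sample(isi)))
}

# shuffle every trial of a unit independently; works on pre-split per-trial
# time lists so the surrogate loop avoids data.frame rebuilds
.shuffle_trial_list <- function(by_trial) lapply(by_trial, isi_shuffle)

#' Permutation p-value for a reliability score
#'
#' Builds a null distribution of mean reliability scores from surrogate
#' datasets in which every trial's interspike intervals are shuffled
#' independently, recomputing the split-half score for each surrogate with
#' the same `n_iter` and one common set of random trial splits (scores are
#' compared conditional on the splits, which halves the cost without
#' changing the null). The one-sided p-value uses the add-one permutation
#' formula
#' `(1 + #{null >= observed}) / (n_null + 1)`.
#'
#' @inheritParams split_half_reliability
#' @param n_null number of surrogate datasets (default 1000).
#' @param observed optionally, a precomputed observed score (otherwise it is
#'   computed here first).
#' @return list with `score` (observed) and `p_raw`.
#' @export
reliability_null_p <- function(dataset, unit_id, schedule = dataset$schedule,
                               n_iter = 1000, n_null = 1000, bin_s = 0.010,
                               seed = NULL, observed = NULL) {
  stopifnot(n_null >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  span <- c(schedule$analysis_start, schedule$analysis_end)
  if (is.null(observed)) {
    M <- .trial_bin_matrix(dataset, unit_id, bin_s, span)
    observed <- .split_half_score(M, n_iter)
  }
  sp <- .unit_spikes(dataset, unit_id)
  tr_f <- factor(sp$trial_index, levels = 0:(schedule$n_trials - 1L))
  by_trial <- split(sp$spike_time_s, tr_f)
  tr_vec <- rep.int(0:(schedule$n_trials - 1L), lengths(by_trial))
  splits <- .make_splits(schedule$n_trials, n_iter)
  null_scores <- vapply(seq_len(n_null), function(b) {
    tt <- unlist(.shuffle_trial_list(by_trial), use.names = FALSE)
    Mb <- .bin_counts(tt, tr_vec, schedule$n_trials, bin_s, span)
    .split_half_score(Mb, n_iter, splits)
  }, numeric(1))
  list(score = observed,
       p_raw = (1 + sum(null_scores >= observed)) / (n_null + 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); adjusted values are clipped at 1 and monotone in the
#' rank of the raw p-values.
#'
#' @param p_values numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Screen all units for stimulus-locked firing
#'
#' Computes the split-half reliability score for every unit, the shuffled-ISI
#' permutation p-value, BH-adjusts the p-values across units, and applies the
#' combined screen: `score >= min_score` and adjusted `p < alpha`.
#'
#' With `compute_p = "auto"` (default), the permutation p is computed only
#' for units whose score already meets `min_score`: a unit below the score
#' cutoff fails the screen regardless of its p-value, so the verdict is
#' unchanged and such units report `p_raw = NA`. Use `"always"` to compute p
#' for every unit.
#'
#' @inheritParams reliability_null_p
#' @param min_score reliability cutoff (default 0.3).
#' @param alpha FDR-adjusted significance level (default 0.01).
#' @param compute_p `"auto"` or `"always"`.
#' @return data.frame (`unit_id`, `score`, `p_raw`, `p_adj`, `passes`).
#' @export
reliability_screen <- function(dataset, schedule = dataset$schedule,
                               n_iter = 1000, n_null = 1000, bin_s = 0.010,
                               min_score = 0.3, alpha = 0.01, seed = NULL,
                               compute_p = c("auto", "always")) {
  compute_p <- match.arg(compute_p)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- unit_ids(dataset)
  span <- c(schedule$analysis_start, schedule$analysis_end)
  score <- vapply(ids, function(u)
    .split_half_score(.trial_bin_matrix(dataset, u, bin_s, span), n_iter),
    numeric(1))
  p_raw <- rep(NA_real_, length(ids))
  need_p <- if (compute_p == "always") rep(TRUE, length(ids))
            else score >= min_score
  for (i in which(need_p)) {
    p_raw[i] <- reliability_null_p(dataset, ids[i], schedule,
                                   n_iter = n_iter, n_null = n_null,
                                   bin_s = bin_s,
                                   observed = score[i])$p_raw
  }
  p_adj <- rep(NA_real_, length(ids))
  p_adj[need_p] <- bh_adjust(p_raw[need_p])
  passes <- score >= min_score & !is.na(p_adj) & p_adj < alpha
  data.frame(unit_id = ids, score = score, p_raw = p_raw, p_adj = p_adj,
             passes = passes, stringsAsFactors = FALSE, row.names = NULL)
}
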