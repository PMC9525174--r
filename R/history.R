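# Facilitation-depression index (FDI) and the cluster-level
# change-in-normalized-firing statistic.

#' Facilitation-depression index
#'
#' For response magnitudes `m` over the four stimulus repetitions, the FDI
#' for repetition `n` is `(m[n] - m[1]) / max(m)`. Facilitation gives
#' positive values, depression negative; when all magnitudes are
#' non-negative the index lies in `[-1, 1]`. Negative magnitudes are allowed
#' inside the formula, but `max(m) <= 0` makes the index undefined and is an
#' error (such units are excluded upstream).
#'
#' @param magnitudes numeric vector of length >= `n` (one magnitude per
#'   repetition, repetition 1 first).
#' @param n repetition index (2..length(magnitudes); default 4, the headline
#'   value).
#' @return the FDI.
#' @export
#' @examples
#' fdi(c(10, 8, 6, 5))      # -0.5, depression
#' fdi(c(5, 6, 7, 10))      # +0.5, facilitation
fdi <- function(magnitudes, n = 4) {
  stopifnot(n >= 2, n <= length(magnitudes))
  m <- max(magnitudes)
  if (m <= 0) stop("undefined FDI: maximum response magnitude <= 0")
  (magnitudes[n] - magnitudes[1]) / m
}

#' FDIs for one unit under every subtraction method
#'
#' Computes onset and offset FDIs for repetitions 2..4 under the
#' `minus_prior`, `minus_baseline`, `auc` and `prior_zero` methods. The
#' `prior_zero` method uses the same magnitudes as `minus_baseline` but is
#' only meaningful for units whose four prior-window rates all returned to
#' within one baseline SD of the baseline mean; the `eligible` flag records
#' this gate (it is TRUE for the other methods).
#'
#' Windows whose magnitudes have `max <= 0` yield `NA` FDIs (undefined;
#' flagged by `defined = FALSE`).
#'
#' @param measures data.frame from [detect_all_windows()] for the unit
#'   (full windows).
#' @param baseline list from [baseline_stats()].
#' @return data.frame (`kind`, `method`, `n`, `fdi`, `eligible`, `defined`).
#' @export
fdi_all_methods <- function(measures, baseline) {
  full <- measures[measures$part == "full", , drop = FALSE]
  methods <- c(minus_prior = "mag_minus_prior",
               minus_baseline = "mag_minus_baseline",
               auc = "mag_auc",
               prior_zero = "mag_minus_baseline")
  out <- list()
  for (kind in c("onset", "offset")) {
    rows <- full[full$kind == kind, , drop = FALSE]
    rows <- rows[order(rows$index), , drop = FALSE]
    prior_ok <- all(abs(rows$prior_fr - baseline$baseline_mean) <=
                      baseline$baseline_sd)
    for (meth in names(methods)) {
      m <- rows[[methods[[meth]]]]
      defined <- max(m) > 0
      eligible <- if (meth == "prior_zero") prior_ok else TRUE
      for (n in 2:4) {
        out[[length(out) + 1]] <- data.frame(
          kind = kind, method = meth, n = n,
          fdi = if (defined) fdi(m, n) else NA_real_,
          eligible = eligible, defined = defined,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Change in normalized firing rate between first and fourth response
#'
#' Takes the extremal (largest in absolute value, sign kept) normalized PSTH
#' value in the fourth window of the given kind minus that in the first
#' window. Unlike the FDI, this captures the dynamics of sound-suppressed
#' firing (where the extremum is a trough).
#'
#' @param x a [psth()] with normalized view attached.
#' @param windows data.frame from [make_windows()].
#' @param kind `"onset"` or `"offset"`.
#' @return change in normalized rate (window 4 minus window 1).
#' @export
delta_norm_fr <- function(x, windows, kind = c("onset", "offset")) {
  kind <- match.arg(kind)
  stopifnot(!is.null(x$normalized))
  extremal <- function(win) {
    v <- x$normalized[.bins_in(x, win$start, win$end)]
    v[which.max(abs(v))]
  }
  full <- windows[windows$part == "full" & windows$kind == kind, ,
                  drop = FALSE]
  w1 <- full[full$index == 1, , drop = FALSE]
  w4 <- full[full$index == max(full$index), , drop = FALSE]
  extremal(w4) - extremal(w1)
}
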