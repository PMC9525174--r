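# Cross-unit procedures: firing-rate distribution matching, transient-offset
# template matching, and hierarchical clustering of normalized PSTHs.

#' Match firing-rate distributions across groups of cells
#'
#' Bins each group's firing rates into `n_bins` equal-width bins spanning the
#' pooled range, converts the bin counts to probabilities, forms the overlap
#' distribution (the per-bin minimum probability across groups), and randomly
#' subsamples each group so that its post-selection histogram follows the
#' overlap distribution. Selection counts per group and bin are
#' `overlap * group size`, allocated with floor plus largest-remainder and
#' never exceeding the cells available in the bin.
#'
#' @param fr_by_group named list of numeric vectors (one firing rate per
#'   cell, one vector per group; at least two groups).
#' @param n_bins number of bins (default 6).
#' @param seed optional seed for the random subsampling.
#' @return named list (per group) of integer index vectors: positions of the
#'   selected cells within that group's input vector. If the groups' ranges
#'   are disjoint the selection is empty, with a warning.
#' @export
distribution_match <- function(fr_by_group, n_bins = 6L, seed = NULL) {
  stopifnot(is.list(fr_by_group), length(fr_by_group) >= 2,
            all(lengths(fr_by_group) > 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  pooled <- range(unlist(fr_by_group))
  edges <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  bin_of <- function(x) pmin(findInterval(x, edges), n_bins)
  probs <- lapply(fr_by_group, function(x)
    tabulate(bin_of(x), nbins = n_bins) / length(x))
  overlap <- do.call(pmin, probs)
  if (all(overlap == 0))
    warning("groups have disjoint firing-rate distributions; nothing selected")
  out <- lapply(fr_by_group, function(x) {
    n <- length(x)
    bins <- bin_of(x)
    avail <- tabulate(bins, nbins = n_bins)
    target <- overlap * n
    counts <- floor(target + 1e-9)
    extra <- round(sum(target)) - sum(counts)
    if (extra > 0) {
      rem <- target - counts
      rem[counts >= avail] <- -Inf
      ord <- order(rem, decreasing = TRUE)
      take <- ord[seq_len(min(extra, sum(is.finite(rem) & rem > 0)))]
      counts[take] <- counts[take] + 1L
    }
    counts <- pmin(counts, avail)
    sel <- integer(0)
    for (b in which(counts > 0)) {
      in_bin <- which(bins == b)
      sel <- c(sel, if (length(in_bin) == 1 && counts[b] == 1) in_bin
               else sample(in_bin, counts[b]))
    }
    sort(sel)
  })
  names(out) <- names(fr_by_group)
  out
}

#' Build the transient-offset response template
#'
#' Averages the normalized first-offset responses of all units whose first
#' offset response is transient: the maximum occurs within the first 50 ms
#' of the window and the mean z-score over the last 50 ms is below 1.
#'
#' @param norm_segments matrix (units x bins) of normalized PSTH segments
#'   over the first offset window (150 ms, 10 ms bins).
#' @param z_segments matrix of the same segments in z-score units.
#' @param bin_s bin width, s (default 0.010).
#' @param early_s transience window for the peak, s (default 0.050).
#' @return list with `template` (numeric vector) and `qualifying` (logical,
#'   per unit). Errors if no unit qualifies.
#' @export
build_offset_template <- function(norm_segments, z_segments, bin_s = 0.010,
                                  early_s = 0.050) {
  stopifnot(is.matrix(norm_segments),
            all(dim(norm_segments) == dim(z_segments)))
  n_bins <- ncol(norm_segments)
  early <- seq_len(round(early_s / bin_s))
  late <- (n_bins - round(early_s / bin_s) + 1L):n_bins
  peak_early <- apply(norm_segments, 1, which.max) %in% early
  late_quiet <- rowMeans(z_segments[, late, drop = FALSE]) < 1
  qualifying <- peak_early & late_quiet
  if (!any(qualifying)) stop("no transient offset responses to average")
  list(template = colMeans(norm_segments[qualifying, , drop = FALSE]),
       qualifying = qualifying)
}

#' Match a response segment against a template
#'
#' Squared Pearson correlation between the segment and the template;
#' selected iff `r^2 >= r2_min`. Because r^2 is sign-blind, anti-correlated
#' segments are additionally rejected unless `require_positive = FALSE`.
#' Zero-variance segments are not selected (`r2` is `NA`).
#'
#' @param segment,template equal-length numeric vectors.
#' @param r2_min selection cutoff (default 0.75).
#' @param require_positive also require `cor > 0` (default TRUE).
#' @return list with `r2`, `r`, `selected`.
#' @export
match_to_template <- function(segment, template, r2_min = 0.75,
                              require_positive = TRUE) {
  stopifnot(length(segment) == length(template))
  r <- if (stats::sd(segment) == 0 || stats::sd(template) == 0) NA_real_
       else stats::cor(segment, template)
  r2 <- r^2
  selected <- !is.na(r2) && r2 >= r2_min &&
    (!require_positive || r > 0)
  list(r2 = r2, r = r, selected = selected)
}

#' Hierarchical clustering of normalized PSTHs
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` between
#' units' normalized PSTHs (the span from the first burst onset to one gap
#' past the last burst), cutting the linkage tree into `k` clusters and
#' dropping clusters smaller than `min_size` (their units are unassigned,
#' label `NA`).
#'
#' @param norm_psths matrix (units x bins) of normalized PSTHs; rownames are
#'   unit ids.
#' @param k number of clusters (default 4).
#' @param min_size minimum retained cluster size (default 10).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return list with `labels` (integer per unit, `NA` for dropped clusters),
#'   `sizes` (per original cluster), `retained` (logical per cluster),
#'   `hclust` (the tree).
#' @export
cluster_psths <- function(norm_psths, k = 4L, min_size = 10L,
                          linkage = "average") {
  stopifnot(is.matrix(norm_psths), k >= 2)
  if (nrow(norm_psths) < k) stop("fewer units than clusters requested")
  cc <- suppressWarnings(stats::cor(t(norm_psths)))
  cc[is.na(cc)] <- 0  # zero-variance PSTHs: treated as uncorrelated
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = k)
  sizes <- tabulate(labels, nbins = k)
  retained <- sizes >= min_size
  labels[!retained[labels]] <- NA_integer_
  names(labels) <- rownames(norm_psths)
  list(labels = labels, sizes = sizes, retained = retained, hclust = tree)
}
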