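#!/usr/bin/env Rscript
# Population-level procedures on the screened demo units: hierarchical
# clustering of normalized PSTHs (correlation distance), the change in
# normalized firing from first to fourth response per cluster, firing-rate
# distribution matching across cell classes, and transient-offset template
# matching. Writes results/demo/clusters.tsv and matched_selection.tsv.

source(file.path("analysis", "config.R"))

gen <- demo_dataset()
ds <- gen$dataset
gt <- gen$ground_truth
scr <- utils::read.table(file.path(results_dir, "reliability.tsv"),
                         header = TRUE, sep = "\t")
keep <- scr$unit_id[scr$passes]

win <- make_windows(demo_schedule)
psths <- lapply(keep, function(u)
  zscore_and_normalize(build_psth(ds, u), baseline_stats(ds, u),
                       sd_floor = 1 / demo_schedule$n_trials))
names(psths) <- keep
span_of <- function(p) {
  lo <- p$bin_edges[-length(p$bin_edges)]
  which(lo >= -1e-9 & lo < demo_schedule$analysis_end - 1e-9)
}
M <- do.call(rbind, lapply(psths, function(p) p$normalized[span_of(p)]))
rownames(M) <- keep

cl <- cluster_psths(M, k = 4, min_size = 10)
cat("cluster sizes:", cl$sizes, "(clusters under 10 units are dropped)\n")
cat("cluster composition by archetype:\n")
print(table(archetype = gt$archetype[match(keep, gt$unit_id)],
            cluster = cl$labels))

# response dynamics per cluster: change in normalized FR, first -> fourth
delta_on <- vapply(keep, function(u)
  delta_norm_fr(psths[[u]], win, "onset"), numeric(1))
cat("median onset change in normalized FR by cluster:\n")
print(round(tapply(delta_on, cl$labels, stats::median), 3))

# distribution matching of maximal firing rates across planted cell classes
max_fr <- vapply(keep, function(u) max(psths[[u]]$rate), numeric(1))
cls <- gt$cell_class[match(keep, gt$unit_id)]
sel <- distribution_match(split(max_fr, cls), n_bins = 6,
                          seed = demo_seed + 4L)
cat(sprintf("distribution matching kept %d / %d NS and %d / %d BS units\n",
            length(sel$NS), sum(cls == "NS"),
            length(sel$BS), sum(cls == "BS")))

# transient-offset template over the first offset window
w1 <- win[win$kind == "offset" & win$index == 1, ]
seg_idx <- function(p) {
  lo <- p$bin_edges[-length(p$bin_edges)]
  which(lo >= w1$start - 1e-9 & lo < w1$end - 1e-9)
}
offs <- keep[vapply(keep, function(u) {
  det <- detect_all_windows(psths[[u]], win)
  any(det$detected[det$kind == "offset"])
}, logical(1))]
norm_seg <- do.call(rbind, lapply(offs, function(u)
  psths[[u]]$normalized[seg_idx(psths[[u]])]))
z_seg <- do.call(rbind, lapply(offs, function(u)
  psths[[u]]$zscored[seg_idx(psths[[u]])]))
tm <- build_offset_template(norm_seg, z_seg)
matched <- vapply(seq_along(offs), function(i)
  match_to_template(norm_seg[i, ], tm$template)$selected, logical(1))
cat(sprintf("offset template built from %d transient responses; %d / %d offset units match at r^2 >= 0.75\n",
            sum(tm$qualifying), sum(matched), length(offs)))

utils::write.table(
  data.frame(unit_id = keep, cluster = unname(cl$labels),
             delta_norm_fr_onset = unname(delta_on)),
  file.path(results_dir, "clusters.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(unit_id = offs, template_match = matched),
  file.path(results_dir, "matched_selection.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(results_dir, "clusters.tsv"),
    "and matched_selection.tsv\n")
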