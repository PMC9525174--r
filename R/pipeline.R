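# End-to-end orchestration: synthetic generation (or file input), the
# reliability screen, response detection, FDIs, cell typing, clustering, and
# the standard nonparametric group comparisons.

#' Default pipeline configuration
#'
#' A nested list mirroring the stage settings. Override entries by passing a
#' partial list to [run_pipeline()]; unspecified entries keep these values.
#'
#' @param n_units_per_archetype used by the built-in demo generation block.
#' @return nested configuration list.
#' @export
default_config <- function(n_units_per_archetype = 50L) {
  list(
    seed = 1L,
    schedule = list(n_bursts = 4L, burst_dur = 0.150, gap_dur = 0.150,
                    n_trials = 120L, baseline_dur = 4.0, iti = 4.5,
                    analysis_start = -0.200),
    generate = list(mix = stats::setNames(
      rep(n_units_per_archetype, 6), names(default_archetypes()))),
    reliability = list(n_iter = 1000, n_null = 1000, min_score = 0.3,
                       alpha = 0.01, compute_p = "auto"),
    thresholds = list(abs = 0.025, z = 3, prior_mult = 3),
    history = list(headline_n = 4, headline_method = "minus_prior"),
    cluster = list(k = 4L, min_size = 10L, linkage = "average"),
    tagging = list(min_spikes = 10, alpha = 0.01, max_latency_ms = 5,
                   min_waveform_corr = 0.95),
    typing = list(ns_bs_boundary_us = 600)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Stages, in order: dataset (generate from the config's archetype mix, or
#' use a supplied dataset), reliability screen, window detection and
#' responsiveness classification, FDIs per method, cell typing, hierarchical
#' clustering of normalized PSTHs, and nonparametric group comparisons
#' (onset vs offset FDI rank-sum; FDI across cell classes by Kruskal-Wallis).
#' Only units passing the reliability screen enter the later stages; unit
#' counts are conserved at every screen (excluded + retained = input).
#'
#' @param config partial configuration list (see [default_config()]), or a
#'   path to a YAML file holding one.
#' @param dataset optional [spike_dataset()]; if NULL, one is generated from
#'   `config$generate$mix` with `config$seed`.
#' @return a `pipeline_report`: list with `config`, `ground_truth` (if
#'   generated), `reliability`, `windows`, `responses`, `responsiveness`,
#'   `fdi`, `profiles`, `clusters`, `group_tests`, `counts`, `log`.
#' @export
run_pipeline <- function(config = list(), dataset = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  sch <- do.call(stimulus_schedule, cfg$schedule)
  ground_truth <- NULL
  if (is.null(dataset)) {
    if (is.null(cfg$generate$mix)) stop("stage dataset: no input dataset and no generation block")
    mix <- unlist(cfg$generate$mix)
    gen <- generate_dataset(mix, sch, seed = cfg$seed)
    dataset <- gen$dataset
    ground_truth <- gen$ground_truth
    say("generated %d units from %d archetypes (seed %d)",
        nrow(dataset$units), length(mix), cfg$seed)
  }
  ids <- unit_ids(dataset)
  n_in <- length(ids)

  rel <- reliability_screen(
    dataset, sch, n_iter = cfg$reliability$n_iter,
    n_null = cfg$reliability$n_null, min_score = cfg$reliability$min_score,
    alpha = cfg$reliability$alpha, seed = cfg$seed + 1L,
    compute_p = cfg$reliability$compute_p)
  keep <- rel$unit_id[rel$passes]
  say("reliability screen: %d / %d units stimulus-locked", length(keep), n_in)
  stopifnot(length(keep) + sum(!rel$passes) == n_in)

  thr <- do.call(detection_thresholds, cfg$thresholds)
  windows <- make_windows(sch, early_late = TRUE)
  responses <- list(); fdis <- list(); resp_class <- character(0)
  norm_mat <- NULL
  clu_bins <- NULL
  for (u in keep) {
    p <- build_psth(dataset, u, sch)
    bs <- baseline_stats(dataset, u, sch)
    p <- zscore_and_normalize(p, bs, sd_floor = 1 / sch$n_trials)
    det <- detect_all_windows(p, windows, thr)
    det$unit_id <- u
    responses[[u]] <- det
    resp_class[u] <- classify_responsiveness(det)
    f <- fdi_all_methods(det, list(baseline_mean = p$baseline_mean,
                                   baseline_sd = p$baseline_sd))
    f$unit_id <- u
    fdis[[u]] <- f
    if (is.null(clu_bins))
      clu_bins <- .bins_in(p, 0, sch$analysis_end)
    norm_mat <- rbind(norm_mat, p$normalized[clu_bins])
  }
  responses <- if (length(responses)) do.call(rbind, responses) else
    data.frame()
  fdi_tab <- if (length(fdis)) do.call(rbind, fdis) else data.frame()
  rownames(responses) <- rownames(fdi_tab) <- NULL
  responsiveness <- data.frame(unit_id = keep,
                               responsiveness = unname(resp_class[keep]),
                               stringsAsFactors = FALSE)
  say("responsiveness: %s",
      paste(sprintf("%s=%d", names(table(resp_class)),
                    as.vector(table(resp_class))), collapse = ", "))

  profiles <- unit_profiles(
    dataset, criteria = do.call(tagging_criteria, cfg$tagging),
    boundary_us = cfg$typing$ns_bs_boundary_us)

  clusters <- NULL
  if (!is.null(norm_mat) && nrow(norm_mat) >= cfg$cluster$k) {
    rownames(norm_mat) <- keep
    clusters <- cluster_psths(norm_mat, k = cfg$cluster$k,
                              min_size = cfg$cluster$min_size,
                              linkage = cfg$cluster$linkage)
    say("clustering: sizes %s (retained: %s)",
        paste(clusters$sizes, collapse = "/"),
        paste(which(clusters$retained), collapse = ","))
  }

  hl_n <- cfg$history$headline_n
  hl_m <- cfg$history$headline_method
  group_tests <- list()
  if (nrow(fdi_tab) > 0) {
    head_tab <- fdi_tab[fdi_tab$n == hl_n & fdi_tab$method == hl_m &
                          fdi_tab$defined, , drop = FALSE]
    # a unit contributes its onset (offset) FDI only if onset- (offset-)
    # responsive
    cls <- resp_class[head_tab$unit_id]
    keep_row <- (head_tab$kind == "onset" & cls %in% c("onset_only", "both")) |
      (head_tab$kind == "offset" & cls %in% c("offset_only", "both"))
    head_tab <- head_tab[keep_row, , drop = FALSE]
    on_f <- head_tab$fdi[head_tab$kind == "onset"]
    off_f <- head_tab$fdi[head_tab$kind == "offset"]
    if (length(on_f) >= 2 && length(off_f) >= 2) {
      wt <- stats::wilcox.test(on_f, off_f, exact = FALSE)
      group_tests$onset_vs_offset <- list(
        median_onset = stats::median(on_f),
        median_offset = stats::median(off_f),
        n_onset = length(on_f), n_offset = length(off_f),
        p = wt$p.value)
      say("onset FDI median %.3f (n=%d) vs offset %.3f (n=%d), rank-sum p=%.3g",
          stats::median(on_f), length(on_f), stats::median(off_f),
          length(off_f), wt$p.value)
    }
    cls_of <- stats::setNames(profiles$cell_class, profiles$unit_id)
    by_class <- split(head_tab$fdi[head_tab$kind == "onset"],
                      cls_of[head_tab$unit_id[head_tab$kind == "onset"]])
    by_class <- by_class[lengths(by_class) >= 2]
    if (length(by_class) >= 2) {
      kw <- stats::kruskal.test(by_class)
      group_tests$onset_fdi_by_class <- list(
        medians = vapply(by_class, stats::median, numeric(1)),
        p = kw$p.value)
    }
  }

  counts <- list(input = n_in, screened_out = n_in - length(keep),
                 retained = length(keep))
  structure(list(config = cfg, ground_truth = ground_truth,
                 reliability = rel, windows = windows,
                 responses = responses, responsiveness = responsiveness,
                 fdi = fdi_tab, profiles = profiles, clusters = clusters,
                 group_tests = group_tests, counts = counts, log = log),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Write a pipeline report's tables and manifest to a directory
#'
#' Writes the per-unit tables as tab-delimited text and a JSON run manifest
#' (config echo, stage log, unit counts).
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(tab, name) {
    if (!is.null(tab) && is.data.frame(tab) && nrow(tab) > 0)
      utils::write.table(tab, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$reliability, "reliability")
  wt(report$responses, "responses")
  wt(report$responsiveness, "responsiveness")
  wt(report$fdi, "fdi")
  wt(report$profiles, "unit_profiles")
  wt(report$ground_truth, "ground_truth")
  if (!is.null(report$clusters))
    wt(data.frame(unit_id = names(report$clusters$labels),
                  cluster = unname(report$clusters$labels),
                  stringsAsFactors = FALSE), "clusters")
  manifest <- list(config = report$config, counts = report$counts,
                   log = report$log, group_tests = report$group_tests)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
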