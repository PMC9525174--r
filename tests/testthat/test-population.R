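sch <- stimulus_schedule()

test_that("distribution matching reproduces the worked overlap example", {
  # group x: 10 of 100 cells (10%) in a low bin; group y: 5 there (5%);
  # overlap 5% -> exactly 5 of x's 10 cells retained from that bin
  set.seed(2)
  gx <- c(rep(1.5, 10), stats::runif(90, 10, 50))
  gy <- c(rep(1.5, 5), stats::runif(95, 10, 50))
  sel <- distribution_match(list(x = gx, y = gy), n_bins = 6, seed = 7)
  expect_equal(sum(sel$x <= 10), 5)
  expect_equal(sum(sel$y <= 5), 5)
})

test_that("identical groups are fully retained; disjoint groups select nothing", {
  set.seed(3)
  g <- stats::runif(60, 0, 40)
  sel <- distribution_match(list(a = g, b = g), seed = 1)
  expect_equal(sel$a, 1:60)
  expect_equal(sel$b, 1:60)
  expect_warning(
    sel2 <- distribution_match(list(a = stats::runif(20, 0, 1),
                                    b = stats::runif(20, 10, 11)), seed = 1),
    "disjoint")
  expect_equal(lengths(sel2), c(a = 0L, b = 0L))
})

test_that("matching never selects more cells than a bin holds and equalizes FRs", {
  set.seed(5)
  for (i in 1:20) {
    a <- stats::rgamma(80, 2, 0.2)
    b <- stats::rgamma(120, 2, 0.2)
    sel <- distribution_match(list(a = a, b = b), seed = i)
    expect_true(all(sel$a %in% seq_along(a)))
    expect_true(all(sel$b %in% seq_along(b)))
    expect_equal(anyDuplicated(sel$a), 0)
    expect_equal(anyDuplicated(sel$b), 0)
  }
  # same planted distribution: post-match samples indistinguishable (KS)
  ok <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    a <- stats::rgamma(150, 2, 0.2); b <- stats::rgamma(150, 2, 0.2)
    sel <- distribution_match(list(a = a, b = b), seed = s)
    suppressWarnings(stats::ks.test(a[sel$a], b[sel$b])$p.value) > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the offset template averages transient responses only", {
  tr <- c(0.2, 1, 0.6, 0.3, 0.15, rep(0.05, 10))   # transient shape
  su <- c(0.2, 0.6, 0.9, 1, rep(1, 11))            # sustained shape
  norm <- rbind(tr, tr, su)
  z <- norm * 8   # sustained tail z = 8 >= 1 -> excluded
  tm <- build_offset_template(norm, z)
  expect_equal(unname(tm$qualifying), c(TRUE, TRUE, FALSE))
  expect_equal(unname(tm$template), tr)
  expect_error(build_offset_template(rbind(su), rbind(su * 8)),
               "no transient")
  # generator offset-only population: template peaks within the first 50 ms
  gen <- generate_dataset(c(offset_only = 15), sch, seed = 31)
  w1 <- make_windows(sch); w1 <- w1[w1$kind == "offset" & w1$index == 1, ]
  segs <- lapply(unit_ids(gen$dataset), function(u) {
    p <- unit_psth(gen$dataset, u)
    lo <- p$bin_edges[-length(p$bin_edges)]
    idx <- which(lo >= w1$start - 1e-9 & lo < w1$end - 1e-9)
    list(norm = p$normalized[idx], z = p$zscored[idx])
  })
  tm2 <- build_offset_template(do.call(rbind, lapply(segs, `[[`, "norm")),
                               do.call(rbind, lapply(segs, `[[`, "z")))
  expect_lte(which.max(tm2$template), 5)
})

test_that("template matching is sign-guarded, affine-invariant and null-calibrated", {
  tpl <- c(0.2, 1, 0.6, 0.3, 0.15, rep(0.05, 10))
  self <- match_to_template(tpl, tpl)
  expect_equal(self$r2, 1)
  expect_true(self$selected)
  neg <- match_to_template(-tpl, tpl)
  expect_equal(neg$r2, 1)          # r^2 is sign-blind...
  expect_false(neg$selected)       # ...but the positive-correlation guard holds
  expect_true(match_to_template(-tpl, tpl, require_positive = FALSE)$selected)
  aff <- match_to_template(3 * tpl + 2, tpl)
  expect_equal(aff$r2, 1)
  # symmetric in its arguments
  set.seed(6)
  a <- stats::runif(15); b <- stats::runif(15)
  expect_equal(match_to_template(a, b)$r2, match_to_template(b, a)$r2)
  # zero-variance segment: undefined, never selected
  flat <- match_to_template(rep(1, 15), tpl)
  expect_true(is.na(flat$r2))
  expect_false(flat$selected)
  # white-noise segments rarely pass r2 >= 0.75
  set.seed(7)
  hits <- vapply(1:100, function(i)
    match_to_template(stats::rnorm(15), tpl)$selected, logical(1))
  expect_lt(mean(hits), 0.05)
})

test_that("PSTH clustering separates planted shapes and drops small clusters", {
  gen <- generate_dataset(c(transient_depressing = 30,
                            sustained_facilitating = 30,
                            offset_only = 30, suppressed = 5),
                          sch, seed = 41)
  M <- norm_psth_matrix(gen$dataset)
  cl <- cluster_psths(M, k = 4, min_size = 10)
  # the 5-unit suppressed cluster is dropped, its units unassigned
  supp <- gen$ground_truth$unit_id[gen$ground_truth$archetype == "suppressed"]
  expect_true(all(is.na(cl$labels[supp])))
  expect_equal(sum(cl$retained), 3)
  # remaining archetypes map one-to-one onto retained clusters
  others <- gen$ground_truth$archetype != "suppressed"
  tab <- table(gen$ground_truth$archetype[others],
               cl$labels[gen$ground_truth$unit_id[others]])
  expect_true(all(apply(tab > 0, 1, sum) == 1))
  # duplicate PSTHs always share a cluster
  M2 <- rbind(M[1:20, ], M[1, , drop = FALSE])
  rownames(M2) <- sprintf("r%02d", 1:21)
  cl2 <- cluster_psths(M2, k = 2, min_size = 1)
  expect_equal(unname(cl2$labels[21]), unname(cl2$labels[1]))
  expect_error(cluster_psths(M[1:3, ], k = 4), "fewer units")
})
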