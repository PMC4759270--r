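test_that("accumulate sums planes and conserves totals", {
  one <- array(3L, c(1, 4, 5))
  expect_equal(accumulate(one), matrix(3L, 4, 5))
  ones <- array(1L, c(50, 4, 4))
  expect_equal(accumulate(ones), matrix(50L, 4, 4))
  set.seed(1)
  x <- array(rpois(3 * 6 * 6, 7), c(3, 6, 6))
  expect_equal(sum(accumulate(x)), sum(x))
})

test_that("mask thresholds are strict-below: the boundary pixel is kept", {
  cn <- matrix(c(999, 1000, 1001, 0), 2, 2)
  m <- build_mask(cn_total = cn, analysis = "N")
  expect_equal(m$valid, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  s32 <- matrix(c(59, 60, 61, 0), 2, 2)
  ms <- build_mask(s32_total = s32, analysis = "S")
  expect_equal(ms$valid, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_error(build_mask(s32_total = s32, analysis = "N"),
               class = "sq_missing_input")
  expect_warning(build_mask(cn_total = matrix(0, 2, 2), analysis = "N"),
                 class = "sq_empty_mask")
})

test_that("ratio maps evaluate valid pixels and demote zero-total ones", {
  minor <- matrix(1, 3, 3); major <- matrix(999, 3, 3)
  m <- build_mask(cn_total = minor + major, analysis = "N")
  rm <- ratio_map(minor, major, m)
  expect_true(all(rm$fraction == 0.001))
  # all pixels masked
  m0 <- suppressWarnings(build_mask(cn_total = matrix(0, 3, 3),
                                    analysis = "N"))
  rm0 <- ratio_map(minor, major, m0)
  expect_true(all(is.na(rm0$fraction)))
  # S analysis can pass a pixel whose own pair total is zero -> demoted
  s32 <- matrix(100, 2, 2)
  ms <- build_mask(s32_total = s32, analysis = "S")
  minor_s <- matrix(0, 2, 2); major_s <- matrix(c(0, 10, 10, 10), 2, 2)
  rms <- ratio_map(minor_s, major_s, ms)
  expect_equal(rms$n_demoted, 1)
  expect_equal(sum(is.na(rms$fraction)), 1)
  expect_error(ratio_map(minor, matrix(1, 2, 2), m),
               class = "sq_dimension_error")
})

test_that("pixelwise and pooled agree exactly for forced arithmetic", {
  labels <- matrix(0L, 2, 3)
  labels[1, ] <- 1L
  minor <- matrix(0L, 2, 3); major <- matrix(0L, 2, 3)
  minor[1, ] <- c(1L, 2L, 3L); major[1, ] <- c(99L, 98L, 97L)
  ses <- manual_session(minor, major, "N")
  rmap <- manual_roi_map(labels, "cytosome")
  pw <- quantify_rois(ses, rmap, element = "N", method = "pixelwise",
                      cn_min = 0)
  pl <- quantify_rois(ses, rmap, element = "N", method = "pooled",
                      cn_min = 0)
  expect_equal(pw$f_mean, 0.02)
  expect_equal(pl$f_mean, 6 / 300)
  expect_equal(pl$total_minor, 6L)
  expect_equal(pl$f_se, counting_se(6, 294))
})

test_that("uniform-count ROIs give identical pixelwise and pooled estimates", {
  labels <- matrix(1L, 4, 4)
  ses <- manual_session(matrix(5L, 4, 4), matrix(995L, 4, 4), "N")
  rmap <- manual_roi_map(labels, "mitochondrion")
  pw <- quantify_rois(ses, rmap, element = "N", method = "pixelwise")
  pl <- quantify_rois(ses, rmap, element = "N", method = "pooled")
  expect_identical(pw$f_mean, pl$f_mean)
})

test_that("fully masked ROIs are reported, never dropped", {
  labels <- matrix(c(1L, 2L), 2, 2)
  minor <- matrix(c(10L, 0L), 2, 2); major <- matrix(c(1990L, 10L), 2, 2)
  ses <- manual_session(minor, major, "N")
  rmap <- manual_roi_map(labels, c("mitochondrion", "resin"))
  st <- quantify_rois(ses, rmap, element = "N")
  expect_equal(nrow(st), 2)
  expect_equal(st$n_valid[st$class == "resin"], 0)
  expect_true(is.na(st$f_mean[st$class == "resin"]))
  expect_false(is.na(st$f_mean[st$class == "mitochondrion"]))
})

test_that("raising thresholds never increases any ROI's valid-pixel count", {
  ph <- small_session(seed = 31, planes = 50)
  prev <- Inf
  for (thr in c(0, 500, 1000, 1500, 2500)) {
    st <- quantify_rois(ph$session, ph$rois, element = "N", cn_min = thr)
    expect_true(all(st$n_valid <= prev))
    prev <- st$n_valid
  }
})

test_that("pixelwise and pooled converge at high per-pixel counts", {
  ph <- small_session(seed = 32, planes = 50)  # cell classes >= 1000/px
  pw <- quantify_rois(ph$session, ph$rois, element = "N",
                      method = "pixelwise")
  pl <- quantify_rois(ph$session, ph$rois, element = "N", method = "pooled")
  keep <- !is.na(pw$f_mean) & pw$n_valid > 10 &
    (pl$total_minor + pl$total_major) / pl$n_valid >= 1000
  expect_true(all(abs(pw$f_mean[keep] - pl$f_mean[keep]) < pl$f_se[keep]))
})

test_that("quantification is invariant to plane order and label renumbering", {
  ph <- small_session(seed = 33, planes = 10)
  base <- quantify_rois(ph$session, ph$rois, element = "N", cn_min = 100)
  # shuffle planes
  shuffled <- ph$session
  perm <- sample(10)
  for (sp in names(shuffled$stacks)) {
    shuffled$stacks[[sp]] <- shuffled$stacks[[sp]][perm, , , drop = FALSE]
  }
  st2 <- quantify_rois(shuffled, ph$rois, element = "N", cn_min = 100)
  expect_equal(st2$f_mean, base$f_mean)
  expect_equal(st2$total_minor, base$total_minor)
  # renumber labels
  ren <- ph$rois
  old <- ren$table$label
  new <- rev(seq_along(old)) + 1000L
  ren$labels <- matrix(ifelse(ren$labels == 0L, 0L,
                              new[match(ren$labels, old)]),
                       nrow(ren$labels))
  ren$table$label <- new
  st3 <- quantify_rois(ph$session, ren, element = "N", cn_min = 100)
  m <- match(base$roi_id, st3$roi_id)
  expect_equal(st3$f_mean[m], base$f_mean)
})

test_that("dimension mismatches between labels and stacks are typed errors", {
  ph <- small_session(seed = 34, planes = 2)
  bad <- ph$rois
  bad$labels <- bad$labels[1:32, 1:32]
  expect_error(quantify_rois(ph$session, bad, element = "N"),
               class = "sq_dimension_error")
})

test_that("summaries aggregate ROI atom percent by class and condition", {
  st <- data.frame(
    specimen = "s", condition = "dysoxic", class = "mitochondrion",
    roi_id = sprintf("r%d", 1:3), n_valid = 10L,
    f_mean = c(0.010, 0.020, 0.030), f_sd = 0.001, f_se = 0.001,
    total_minor = 1L, total_major = 99L, label = 1:3, element = "N",
    method = "pixelwise", stringsAsFactors = FALSE)
  s <- summarize_rois(st)
  expect_equal(s$n, 3)
  expect_equal(s$mean_atom_pct, 2.0)
  expect_equal(s$sd_atom_pct, 1.0)
  one <- summarize_rois(st[1, ])
  expect_equal(one$n, 1)
  expect_true(is.na(one$sd_atom_pct))
  expect_equal(nrow(summarize_rois(st[0, ])), 0)
})

test_that("count-dependence QC flags constructed dependence, passes nulls", {
  st <- data.frame(f_mean = (1:10) / 100, total_minor = 1:10,
                   total_major = (1:10) * 100)
  qc <- qc_count_dependence(st)
  expect_equal(qc$rho, 1)
  expect_error(qc_count_dependence(st[1:2, ]),
               class = "sq_insufficient_data")
  # null: 50 ROIs whose fraction is independent of their total counts
  set.seed(99)
  ok <- 0
  for (rep in 1:100) {
    tot <- rpois(50, 5000) + 1000
    minor <- rbinom(50, tot, 0.005)
    null_st <- data.frame(f_mean = minor / tot, total_minor = minor,
                          total_major = tot - minor)
    ok <- ok + (abs(qc_count_dependence(null_st)$rho) < 0.4)
  }
  expect_gte(ok, 95)
})
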