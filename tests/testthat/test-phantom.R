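test_that("default class truths carry the condition-wise atom fractions", {
  anox <- default_class_truth("anoxic")
  dys <- default_class_truth("dysoxic")
  expect_setequal(anox$class, organelle_classes())
  expect_equal(anox$f15[anox$class == "mitochondrion"], 0.0050)
  expect_equal(dys$f15[dys$class == "electron_dense_body"], 0.0164)
  expect_error(default_class_truth("oxic"), class = "sq_invalid_argument")
  for (tr in list(anox, dys)) {
    expect_true(all(tr$f15 < 1 & tr$f15 >= 0))
    expect_true(all(tr$f34 < 1 & tr$f34 >= 0))
    expect_true(all(is.finite(tr$lambda_cn) & tr$lambda_cn >= 0))
    expect_true(all(is.finite(tr$lambda_s) & tr$lambda_s >= 0))
  }
})

test_that("label maps are deterministic given (config, seed)", {
  a <- build_label_map(small_config(seed = 7))
  b <- build_label_map(small_config(seed = 7))
  expect_identical(a$labels, b$labels)
  expect_identical(a$table, b$table)
  c <- build_label_map(small_config(seed = 8))
  expect_false(identical(a$labels, c$labels))
})

test_that("electron dense body diameters honour the 200-500 nm range", {
  cfg <- phantom_config(condition = "dysoxic", seed = 3)
  truth <- build_label_map(cfg)
  px <- cfg$pixel_size
  edb <- truth$table$label[truth$table$class == "electron_dense_body" &
                            truth$table$is_roi]
  expect_true(length(edb) > 0)
  for (lbl in edb) {
    area <- sum(truth$labels == lbl)
    d_nm <- 2 * sqrt(area / pi) * px  # area-equivalent diameter
    expect_gte(d_nm, 200 - px)
    expect_lte(d_nm, 500 + px)
  }
})

test_that("possible endobionts are elongated rods", {
  cfg <- phantom_config(condition = "dysoxic", seed = 5)
  truth <- build_label_map(cfg)
  px <- cfg$pixel_size
  rods <- truth$table$label[truth$table$class == "possible_endobiont"]
  for (lbl in rods) {
    idx <- which(truth$labels == lbl, arr.ind = TRUE)
    extent_nm <- max(dist(idx)) * px
    expect_gte(extent_nm, 600 - 2 * px)
    expect_lte(extent_nm, 1500 + 2 * px)
  }
})

test_that("with no organelles or patches only the background regions remain", {
  cfg <- small_config(seed = 1)
  cfg$organelle_counts[] <- 0
  cfg$background_patches[] <- 0
  truth <- build_label_map(cfg)
  expect_setequal(unique(truth$table$class),
                  c("resin", "organic_lining", "cytosome"))
  expect_true(all(truth$labels > 0))  # dense map
})

test_that("organic lining is a closed ring separating cytosome from resin", {
  truth <- build_label_map(small_config(seed = 2))
  cls_of <- function(lbl) truth$table$class[match(lbl, truth$table$label)]
  cmap <- matrix(cls_of(truth$labels), nrow(truth$labels))
  inside <- cmap != "resin" & cmap != "organic_lining"
  resin <- cmap == "resin"
  nr <- nrow(cmap); nc <- ncol(cmap)
  # no interior pixel may be 4-adjacent to resin
  touching <- FALSE
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sr <- seq_len(nr) + d[1]; sc <- seq_len(nc) + d[2]
    ok_r <- sr >= 1 & sr <= nr; ok_c <- sc >= 1 & sc <= nc
    shifted <- matrix(FALSE, nr, nc)
    shifted[ok_r, ok_c] <- resin[sr[ok_r], sc[ok_c]]
    touching <- touching || any(inside & shifted)
  }
  expect_false(touching)
})

test_that("anoxic mode clusters dense bodies and endobionts peripherally", {
  cfg <- phantom_config(condition = "anoxic", seed = 4)
  truth <- build_label_map(cfg)
  cls_of <- truth$table$class[match(truth$labels, truth$table$label)]
  cmap <- matrix(cls_of, nrow(truth$labels))
  cell <- cmap != "resin"
  # distance of every EDB pixel to the nearest non-cell (resin) pixel
  cy <- (nrow(cmap) + 1) / 2; cx <- (ncol(cmap) + 1) / 2
  idx <- which(matrix(cmap %in% c("electron_dense_body",
                                  "possible_endobiont"), nrow(cmap)),
               arr.ind = TRUE)
  # elliptical radius relative to the cell boundary: must sit in the outer
  # band (within band_nm + max organelle size of the lining)
  a <- 0.45 * ncol(cmap); b <- 0.42 * nrow(cmap)
  rho <- sqrt(((idx[, 1] - cy) / b)^2 + ((idx[, 2] - cx) / a)^2)
  band_frac <- (cfg$band_nm + 500 + 1500) / (min(a * cfg$pixel_size,
                                                 b * cfg$pixel_size))
  expect_true(all(rho > 1 - band_frac))
})

test_that("simulated counts follow the configured emission model", {
  truth <- build_label_map(small_config(seed = 9, jitter = FALSE))
  # zero emission: all-zero stacks
  t0 <- truth
  t0$table$lambda_cn <- 0
  s0 <- simulate_session(t0, acquisition_spec(planes = 5, raster = 64),
                         seed = 1)
  expect_true(all(s0$stacks$CN14 == 0) && all(s0$stacks$CN15 == 0))
  # zero minor fraction: minor stack identically zero
  t1 <- truth
  t1$table$f15 <- 0
  s1 <- simulate_session(t1, acquisition_spec(planes = 5, raster = 64),
                         seed = 1)
  expect_true(all(s1$stacks$CN15 == 0))
  expect_gt(sum(s1$stacks$CN14), 0)
})

test_that("accumulated totals match the Poisson law for a uniform class", {
  # single-class field: every pixel cytosome with lambda 40, 50 planes
  truth <- build_label_map(small_config(seed = 10, jitter = FALSE))
  tu <- truth
  tu$table$lambda_cn <- 40
  ses <- simulate_session(tu, acquisition_spec(planes = 50, raster = 64),
                          seed = 2)
  total <- accumulate(ses$stacks$CN14) + accumulate(ses$stacks$CN15)
  n_px <- length(total)
  expect_lt(abs(mean(total) - 2000), 3 * sqrt(2000 / n_px))
})

test_that("sessions are deterministic given seed", {
  truth <- build_label_map(small_config(seed = 11))
  s1 <- simulate_session(truth, acquisition_spec(planes = 3, raster = 64),
                         seed = 5)
  s2 <- simulate_session(truth, acquisition_spec(planes = 3, raster = 64),
                         seed = 5)
  expect_identical(s1$stacks, s2$stacks)
  s3 <- simulate_session(truth, acquisition_spec(planes = 3, raster = 64),
                         seed = 6)
  expect_false(identical(s1$stacks, s3$stacks))
})

test_that("an incompatible raster raises a dimension error", {
  truth <- build_label_map(small_config(seed = 1))
  expect_error(
    simulate_session(truth, acquisition_spec(planes = 2, raster = 48)),
    class = "sq_dimension_error")
  # stride-2 decimation works
  s <- simulate_session(truth, acquisition_spec(planes = 2, raster = 32),
                        seed = 1)
  expect_equal(dim(s$stacks$CN14), c(2, 32, 32))
})

test_that("overfilled placement fails with a typed error naming the class", {
  cfg <- small_config(seed = 1)
  cfg$organelle_counts["vacuole"] <- 500
  expect_error(build_label_map(cfg), "vacuole",
               class = "sq_placement_error")
})

test_that("pooled ROI estimates recover instance truth within counting error", {
  # moderate-count phantom, many seeds: >= 99% of pooled estimates within
  # 3 binomial standard errors of the instance-level truth
  hits <- 0L; total <- 0L
  for (seed in 1:30) {
    cond <- if (seed %% 2 == 0) "anoxic" else "dysoxic"
    ph <- small_session(cond, seed = seed, planes = 50)
    st <- quantify_rois(ph$session, ph$rois, element = "N",
                        method = "pooled")
    st <- st[!is.na(st$f_mean), ]
    truth_f <- ph$truth$table$f15[match(st$label, ph$truth$table$label)]
    ok <- abs(st$f_mean - truth_f) <= 3 * st$f_se
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.99)
})
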