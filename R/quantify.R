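# Image quantification: amalgamate planes, mask low-count pixels, map
# per-pixel atom fractions, and reduce ROIs to atom-fraction estimates
# with counting errors.

#' Amalgamate an ion-count stack over planes
#'
#' @param stack A `planes x rows x cols` integer count array (one species
#'   of a `measurement_session`).
#' @return Integer `rows x cols` matrix of accumulated counts.
#' @export
accumulate <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  out <- colSums(stack, dims = 1)
  storage.mode(out) <- "integer"
  out
}

#' Build the low-count validity mask
#'
#' Pixels whose accumulated reference counts fall below the threshold are
#' removed to reduce ratio noise: for nitrogen analysis a pixel is valid
#' iff accumulated 12C14N- + 12C15N- counts are at least `cn_min`
#' (default 1000); for sulfur analysis iff accumulated 32S- counts are at
#' least `s_min` (default 60). "Below the threshold is removed" is strict:
#' a pixel exactly at the threshold is kept.
#'
#' @param cn_total Accumulated CN-pair total count image (required for
#'   `analysis = "N"`).
#' @param s32_total Accumulated 32S- count image (required for
#'   `analysis = "S"`).
#' @param cn_min,s_min Count thresholds (>= 0).
#' @param analysis `"N"` or `"S"`.
#' @return Object of class `pixel_mask`: logical `valid` matrix plus the
#'   thresholds and analysis used. A mask with zero valid pixels is
#'   returned with a warning, not an error.
#' @export
build_mask <- function(cn_total = NULL, s32_total = NULL,
                       cn_min = 1000, s_min = 60,
                       analysis = c("N", "S")) {
  analysis <- match.arg(analysis)
  if (cn_min < 0 || s_min < 0) {
    sq_error("sq_invalid_argument", "thresholds must be >= 0")
  }
  img <- if (analysis == "N") cn_total else s32_total
  if (is.null(img)) {
    sq_error("sq_missing_input",
             sprintf("%s analysis requires the %s count image", analysis,
                     if (analysis == "N") "accumulated CN" else "accumulated 32S"))
  }
  thr <- if (analysis == "N") cn_min else s_min
  valid <- img >= thr
  if (!any(valid)) {
    sq_warn("sq_empty_mask", "mask has zero valid pixels")
  }
  structure(list(valid = valid, cn_min = cn_min, s_min = s_min,
                 analysis = analysis),
            class = "pixel_mask")
}

#' Per-pixel atom-fraction map
#'
#' Computes `minor/(minor+major)` at every valid pixel. A pixel that is
#' valid under the mask but has zero total counts for this species pair
#' (possible for sulfur, where the mask thresholds 32S- only) is demoted
#' to invalid and counted.
#'
#' @param minor,major Accumulated count images of the minor and major
#'   isotopologue.
#' @param mask A [build_mask()] result of matching dimensions.
#' @return Object of class `ratio_map`: `fraction` matrix (NA where
#'   invalid), the effective `mask`, and `n_demoted`.
#' @export
ratio_map <- function(minor, major, mask) {
  stopifnot(inherits(mask, "pixel_mask"))
  if (!all(dim(minor) == dim(major)) || !all(dim(minor) == dim(mask$valid))) {
    sq_error("sq_dimension_error", "image and mask dimensions differ")
  }
  valid <- mask$valid
  tot <- minor + major
  demote <- valid & tot == 0
  valid <- valid & tot > 0
  frac <- matrix(NA_real_, nrow(minor), ncol(minor))
  frac[valid] <- minor[valid] / tot[valid]
  out_mask <- mask
  out_mask$valid <- valid
  structure(list(fraction = frac, mask = out_mask,
                 n_demoted = sum(demote), element = mask$analysis),
            class = "ratio_map")
}

.element_species <- function(element) {
  if (element == "N") c(minor = "CN15", major = "CN14")
  else c(minor = "S34", major = "S32")
}

#' Quantify ROIs from a measurement session
#'
#' Accumulates the relevant species stacks, applies the low-count mask,
#' and reduces every nonzero ROI label to an atom-fraction estimate.
#' With `method = "pixelwise"` the estimate is the mean of per-pixel
#' fractions over valid pixels (and `f_sd` their standard deviation);
#' with `method = "pooled"` it is the fraction of the ROI-summed counts
#' (count-weighted, less ratio bias at low counts). In both cases `f_se`
#' is the binomial counting error of the pooled totals. ROIs with no
#' valid pixel are reported with `n_valid = 0` and NA estimates, never
#' dropped.
#'
#' @param session A `measurement_session` containing the species pair for
#'   `element`.
#' @param labels An `roi_label_map` whose dimensions match the session
#'   raster.
#' @param element `"N"` (15N from the CN pair) or `"S"` (34S).
#' @param method `"pixelwise"` (default) or `"pooled"`.
#' @param cn_min,s_min Mask thresholds, see [build_mask()].
#' @return Data frame of class `roi_stats`; one row per ROI with columns
#'   specimen, condition, class, roi_id, n_valid, f_mean, f_sd, f_se,
#'   total_minor, total_major, plus label, element and method.
#' @export
quantify_rois <- function(session, labels, element = c("N", "S"),
                          method = c("pixelwise", "pooled"),
                          cn_min = 1000, s_min = 60) {
  element <- match.arg(element)
  method <- match.arg(method)
  stopifnot(inherits(session, "measurement_session"),
            inherits(labels, "roi_label_map"))
  sp <- .element_species(element)
  for (s in sp) {
    if (is.null(session$stacks[[s]])) {
      sq_error("sq_missing_input",
               sprintf("session lacks species %s required for %s analysis",
                       s, element))
    }
  }
  minor <- accumulate(session$stacks[[sp["minor"]]])
  major <- accumulate(session$stacks[[sp["major"]]])
  if (!all(dim(minor) == dim(labels$labels))) {
    sq_error("sq_dimension_error",
             sprintf("label map %s does not match session raster %s",
                     paste(dim(labels$labels), collapse = "x"),
                     paste(dim(minor), collapse = "x")))
  }
  mask <- if (element == "N") {
    build_mask(cn_total = minor + major, cn_min = cn_min, s_min = s_min,
               analysis = "N")
  } else {
    build_mask(s32_total = major, cn_min = cn_min, s_min = s_min,
               analysis = "S")
  }
  rmap <- ratio_map(minor, major, mask)
  valid <- rmap$mask$valid

  tab <- labels$table
  lab_img <- labels$labels
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    sel <- lab_img == tab$label[i]
    vsel <- sel & valid
    n_valid <- sum(vsel)
    tmin <- sum(minor[vsel]); tmaj <- sum(major[vsel])
    if (n_valid == 0) {
      f_mean <- f_sd <- f_se <- NA_real_
    } else {
      f_mean <- if (method == "pixelwise") mean(rmap$fraction[vsel])
                else tmin / (tmin + tmaj)
      f_sd <- if (n_valid > 1) stats::sd(rmap$fraction[vsel]) else NA_real_
      f_se <- counting_se(tmin, tmaj)
    }
    data.frame(
      specimen = session$specimen_id,
      condition = tab$condition[i] %||% session$condition,
      class = tab$class[i],
      roi_id = tab$roi_id[i],
      n_valid = n_valid,
      f_mean = f_mean, f_sd = f_sd, f_se = f_se,
      total_minor = tmin, total_major = tmaj,
      label = tab$label[i],
      element = element, method = method,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("roi_stats", "data.frame")
  out
}

#' Summarise ROI statistics by class and condition
#'
#' @param stats An `roi_stats` data frame (rows with `n_valid = 0` are
#'   excluded from the summary). Rows from several sessions may be
#'   concatenated with `rbind` first.
#' @return Data frame with one row per (class, condition): `n` (number of
#'   ROIs), `mean_atom_pct` and `sd_atom_pct` of the ROI-level atom
#'   percent (SD is NA for a single ROI). An empty input yields an empty
#'   table.
#' @export
summarize_rois <- function(stats) {
  stats <- stats[!is.na(stats$f_mean), , drop = FALSE]
  if (nrow(stats) == 0) {
    return(data.frame(class = character(), condition = character(),
                      element = character(), n = integer(),
                      mean_atom_pct = numeric(), sd_atom_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(stats$class, stats$condition, stats$element, drop = TRUE)
  parts <- split(stats, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(
      class = g$class[1], condition = g$condition[1], element = g$element[1],
      n = nrow(g),
      mean_atom_pct = mean(g$f_mean) * 100,
      sd_atom_pct = if (nrow(g) > 1) stats::sd(g$f_mean) * 100 else NA_real_,
      stringsAsFactors = FALSE)
  }))
  ord <- order(match(out$class, organelle_classes()), out$condition)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' QC: independence of atom fraction from total counts
#'
#' During quantification it should hold that a region's isotopic
#' composition is unrelated to how many ions it produced; a strong
#' correlation flags detector artefacts or mask leakage. Reports the
#' Spearman rank correlation between per-ROI total counts
#' (minor + major) and the atom-fraction estimate.
#'
#' @param stats An `roi_stats` data frame with at least 3 estimated ROIs.
#' @return List with `rho` and `p` (from [stats::cor.test()], Spearman).
#' @export
qc_count_dependence <- function(stats) {
  stats <- stats[!is.na(stats$f_mean), , drop = FALSE]
  if (nrow(stats) < 3) {
    sq_error("sq_insufficient_data",
             "need at least 3 estimated ROIs for the count-dependence QC")
  }
  ct <- suppressWarnings(
    stats::cor.test(stats$total_minor + stats$total_major, stats$f_mean,
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
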