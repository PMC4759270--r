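# Synthetic phantom: a single-chamber foraminiferal cell section with
# labelled organelles, known per-instance isotope truths, and Poisson
# ion-count acquisitions. Everything downstream is testable against the
# ground truth this module records.

#' Organelle and ultrastructure classes
#'
#' The fixed vocabulary of quantified features: nine intracellular classes
#' plus the organic lining of the test and the embedding resin.
#'
#' @return Character vector of the 11 canonical class names, in the
#'   enumeration (and phantom placement) order.
#' @export
organelle_classes <- function() {
  c("vacuole", "food_vacuole", "mitochondrion", "peroxisome", "plastid",
    "lipid_droplet", "possible_endobiont", "electron_dense_body",
    "cytosome", "organic_lining", "resin")
}

# Classes drawn as discrete placed organelles (vs. background regions).
.placed_classes <- function() {
  setdiff(organelle_classes(), c("cytosome", "organic_lining", "resin"))
}

#' Default per-class ground truth for the phantom
#'
#' True minor-isotope atom fractions (`f15`, `f34`) are the condition-wise
#' mean 15N and 34S atom percent of each feature class divided by 100, with
#' the corresponding between-ROI standard deviations (`sd15`, `sd34`, also
#' on the fraction scale) used for optional per-ROI jitter. Plastids are
#' not tabulated in the source summaries; mitochondrion-like defaults are
#' used for them.
#'
#' Emission rates `lambda_cn` and `lambda_s` (mean total CN- and S- counts
#' per pixel per plane) are package defaults chosen so that 50-plane
#' accumulated CN totals straddle the 1000-count mask threshold — resin,
#' vacuoles and lipid droplets fall mostly (not entirely) below it, the
#' cellular classes well above — and S totals straddle the 60-count 32S
#' threshold under the reduced 25-plane sulfur acquisition.
#'
#' @param condition `"dysoxic"` or `"anoxic"`.
#' @return Data frame with columns `class`, `f15`, `sd15`, `f34`, `sd34`,
#'   `lambda_cn`, `lambda_s`; one row per class in enumeration order.
#' @examples
#' default_class_truth("anoxic")
#' @export
default_class_truth <- function(condition = c("dysoxic", "anoxic")) {
  if (length(condition) != 1 || !condition %in% c("dysoxic", "anoxic")) {
    sq_error("sq_invalid_argument",
             "condition must be one of 'dysoxic', 'anoxic'")
  }
  cls <- organelle_classes()
  # atom% (mean, SD) per class: dysoxic then anoxic
  atom15 <- list(
    vacuole             = c(0.52, 0.09, 0.39, 0.04),
    food_vacuole        = c(1.25, 0.51, 0.50, 0.13),
    mitochondrion       = c(1.24, 0.20, 0.50, 0.03),
    peroxisome          = c(1.17, 0.17, 0.54, 0.05),
    plastid             = c(1.20, 0.30, 0.60, 0.10),
    lipid_droplet       = c(0.55, 0.07, 0.41, 0.05),
    possible_endobiont  = c(1.42, 0.52, 0.53, 0.06),
    electron_dense_body = c(1.64, 0.42, 0.79, 0.13),
    cytosome            = c(1.31, 0.22, 0.52, 0.03),
    organic_lining      = c(0.60, 0.06, 0.51, 0.09),
    resin               = c(0.39, 0.04, 0.37, 0.02)
  )
  atom34 <- list(
    vacuole             = c(6.03, 1.54, 4.15, 0.36),
    food_vacuole        = c(5.60, 0.72, 4.61, 0.36),
    mitochondrion       = c(6.16, 1.22, 4.54, 0.30),
    peroxisome          = c(5.03, 0.80, 4.58, 0.22),
    plastid             = c(6.00, 1.00, 4.50, 0.30),
    lipid_droplet       = c(4.79, 1.23, 4.41, 0.22),
    possible_endobiont  = c(5.70, 0.57, 4.34, 0.20),
    electron_dense_body = c(6.92, 3.38, 4.26, 0.23),
    cytosome            = c(6.13, 1.14, 4.63, 0.24),
    organic_lining      = c(7.12, 2.35, 4.30, 0.17),
    resin               = c(4.28, 0.29, 3.91, 0.30)
  )
  lambda_cn <- c(
    vacuole = 19.8, food_vacuole = 50, mitochondrion = 60, peroxisome = 55,
    plastid = 55, lipid_droplet = 19.8, possible_endobiont = 55,
    electron_dense_body = 80, cytosome = 45, organic_lining = 60,
    resin = 19.4
  )
  lambda_s <- c(
    vacuole = 2.4, food_vacuole = 8, mitochondrion = 8, peroxisome = 8,
    plastid = 8, lipid_droplet = 2.4, possible_endobiont = 8,
    electron_dense_body = 16, cytosome = 8, organic_lining = 16,
    resin = 2.4
  )
  idx <- if (condition == "dysoxic") 1:2 else 3:4
  a15 <- t(vapply(atom15[cls], function(v) v[idx], numeric(2)))
  a34 <- t(vapply(atom34[cls], function(v) v[idx], numeric(2)))
  data.frame(
    class = cls,
    f15 = a15[, 1] / 100, sd15 = a15[, 2] / 100,
    f34 = a34[, 1] / 100, sd34 = a34[, 2] / 100,
    lambda_cn = unname(lambda_cn[cls]),
    lambda_s = unname(lambda_s[cls]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Phantom field configuration
#'
#' Describes one simulated 10 x 10 um field: raster size, pixel pitch,
#' incubation condition, how many organelles of each class to place and at
#' what sizes, background ROI patches, and the seed.
#'
#' Default sizes (nm): electron dense bodies are 200-500 nm disks and
#' possible endobionts 100-300 nm x 600-1500 nm rods, per the imaged
#' ultrastructure; the remaining classes use typical protist organelle
#' dimensions. In anoxic mode electron dense bodies and possible
#' endobionts cluster in a peripheral band (default 1500 nm) adjacent to
#' the organic lining; in dysoxic mode they are placed uniformly over the
#' cytosome.
#'
#' @param rows,cols Raster dimensions in pixels (>= 16).
#' @param pixel_size Pixel pitch in nm; the default keeps a 10 um field
#'   width at any raster (39.06 nm at 256 px).
#' @param condition `"dysoxic"` or `"anoxic"`.
#' @param organelle_counts Named integer vector: placed organelles per
#'   class (names from the placed subset of [organelle_classes()]).
#' @param size_ranges Named list of `c(min, max)` diameters in nm; for
#'   `possible_endobiont`, `width` and `length` ranges.
#' @param band_nm Width of the peripheral clustering band (anoxic mode).
#' @param lining_px Width of the organic lining ring, in pixels.
#' @param background_patches Named vector: number of ROI patches carved
#'   out of the resin, cytosome and organic_lining background regions.
#' @param patch_nm Diameter of resin/cytosome background patches, nm.
#' @param jitter Logical; draw each ROI instance's true atom fractions
#'   from a normal with the class SD, truncated to `[0, 1)` (default TRUE).
#' @param seed Integer seed controlling geometry and jitter.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(rows = 256, cols = 256,
                           pixel_size = 10000 / cols,
                           condition = c("dysoxic", "anoxic"),
                           organelle_counts = NULL,
                           size_ranges = NULL,
                           band_nm = 1500,
                           lining_px = 1,
                           background_patches = c(resin = 7, cytosome = 6,
                                                  organic_lining = 4),
                           patch_nm = 700,
                           jitter = TRUE,
                           seed = 1L) {
  condition <- match.arg(condition)
  if (rows < 16 || cols < 16) {
    sq_error("sq_invalid_argument", "rows and cols must be >= 16")
  }
  counts <- c(
    vacuole = 5, food_vacuole = 3, mitochondrion = 10, peroxisome = 2,
    plastid = 2, lipid_droplet = 5, possible_endobiont = 5,
    electron_dense_body = 8
  )
  if (!is.null(organelle_counts)) {
    bad <- setdiff(names(organelle_counts), .placed_classes())
    if (length(bad)) {
      sq_error("sq_invalid_argument",
               paste("not a placeable organelle class:",
                     paste(bad, collapse = ", ")))
    }
    counts[names(organelle_counts)] <- organelle_counts
  }
  sizes <- list(
    vacuole = c(800, 2000), food_vacuole = c(800, 1500),
    mitochondrion = c(500, 1000), peroxisome = c(300, 600),
    plastid = c(600, 1200), lipid_droplet = c(400, 900),
    possible_endobiont = list(width = c(100, 300), length = c(600, 1500)),
    electron_dense_body = c(200, 500)
  )
  if (!is.null(size_ranges)) sizes[names(size_ranges)] <- size_ranges
  for (cl in setdiff(names(sizes), "possible_endobiont")) {
    if (any(sizes[[cl]] <= 0)) {
      sq_error("sq_invalid_argument", "size ranges must be positive")
    }
  }
  if (band_nm >= min(rows, cols) * pixel_size) {
    sq_error("sq_invalid_argument", "band width must be below the field size")
  }
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    pixel_size = pixel_size, condition = condition,
    organelle_counts = counts, size_ranges = sizes,
    band_nm = band_nm, lining_px = as.integer(lining_px),
    background_patches = background_patches, patch_nm = patch_nm,
    jitter = isTRUE(jitter), seed = as.integer(seed)
  ), class = "phantom_config")
}

# --- binary-mask morphology (3x3 erosion, iterated) -------------------------

.erode <- function(mask, iterations = 1L) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(iterations)) {
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    out <- p[2:(nr + 1), 2:(nc + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out & p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
    m <- out
  }
  m
}

.disk_offsets <- function(radius_px) {
  r <- max(0L, floor(radius_px))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

# Pixels of a capsule (rod): within half-width of the center segment.
.rod_offsets <- function(length_px, width_px, theta) {
  half_len <- length_px / 2
  half_w <- width_px / 2
  ext <- ceiling(half_len + half_w)
  g <- expand.grid(dr = -ext:ext, dc = -ext:ext)
  ux <- cos(theta); uy <- sin(theta)
  t_proj <- g$dc * ux + g$dr * uy
  t_clamp <- pmin(pmax(t_proj, -half_len + half_w), half_len - half_w)
  d2 <- (g$dc - t_clamp * ux)^2 + (g$dr - t_clamp * uy)^2
  g[d2 <= half_w^2, , drop = FALSE]
}

.truncnorm01 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- out < 0 | out >= 1
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  out[out < 0] <- 0
  out[out >= 1] <- 1 - 1e-12
  out
}

#' Build a phantom label map with instance-level ground truth
#'
#' Constructs a single elliptical cell (~60% of the field) bounded by a
#' closed organic-lining ring, embedded in resin, and places non-overlapping
#' organelles inside the cytosome by seeded rejection sampling (at most
#' 1000 attempts each, placement in class enumeration order). Background
#' classes additionally receive discrete ROI patches so that resin,
#' cytosome and organic lining are quantified as regions of interest like
#' the organelles. Each ROI instance carries its own true atom fractions
#' (class mean, optionally jittered by the class SD).
#'
#' @param config A [phantom_config()].
#' @param class_truth Per-class truth table; defaults to
#'   [default_class_truth()] for the configured condition.
#' @return Object of class `phantom_truth`: a list with `labels` (dense
#'   integer instance map, every pixel assigned), `table` (one row per
#'   instance: `label`, `class`, `is_roi`, `f15`, `f34`, `lambda_cn`,
#'   `lambda_s`), `config`, `condition` and `seed`.
#' @export
build_label_map <- function(config, class_truth = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(class_truth)) class_truth <- default_class_truth(config$condition)
  set.seed(config$seed)
  nr <- config$rows; nc <- config$cols
  px <- config$pixel_size

  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  b <- 0.42 * nr; a <- 0.45 * nc
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cell <- ((rr - cy) / b)^2 + ((cc - cx) / a)^2 <= 1
  interior <- .erode(cell, config$lining_px)
  lining <- cell & !interior

  labels <- matrix(0L, nr, nc)
  occupied <- matrix(FALSE, nr, nc)  # placed organelles + carved patches

  inst <- list()
  next_label <- 1L
  add_instance <- function(class, pix_idx, is_roi) {
    lbl <- next_label
    labels[pix_idx] <<- lbl
    inst[[length(inst) + 1L]] <<- data.frame(
      label = lbl, class = class, is_roi = is_roi,
      stringsAsFactors = FALSE)
    next_label <<- next_label + 1L
    lbl
  }

  # peripheral clustering band for anoxic mode
  band_px <- max(1L, round(config$band_nm / px))
  band <- interior & !.erode(interior, band_px)

  place_shape <- function(class, offsets, allowed) {
    cand <- which(allowed & !occupied)
    for (attempt in seq_len(1000L)) {
      ctr <- cand[sample.int(length(cand), 1L)]
      r0 <- ((ctr - 1L) %% nr) + 1L
      c0 <- ((ctr - 1L) %/% nr) + 1L
      pr <- r0 + offsets$dr
      pc <- c0 + offsets$dc
      if (any(pr < 1 | pr > nr | pc < 1 | pc > nc)) next
      idx <- pr + (pc - 1L) * nr
      if (all(allowed[idx]) && !any(occupied[idx])) {
        occupied[idx] <<- TRUE
        return(idx)
      }
    }
    sq_error("sq_placement_error",
             sprintf("could not place a '%s' without overlap in 1000 attempts",
                     class))
  }

  clustered <- c("possible_endobiont", "electron_dense_body")
  for (class in intersect(organelle_classes(), .placed_classes())) {
    n_place <- config$organelle_counts[[class]]
    if (is.null(n_place) || n_place < 1) next
    allowed <- if (config$condition == "anoxic" && class %in% clustered) {
      band
    } else {
      interior
    }
    for (i in seq_len(n_place)) {
      if (class == "possible_endobiont") {
        sr <- config$size_ranges$possible_endobiont
        w <- stats::runif(1, sr$width[1], sr$width[2]) / px
        l <- stats::runif(1, sr$length[1], sr$length[2]) / px
        off <- .rod_offsets(l, max(w, 1), stats::runif(1, 0, pi))
      } else {
        sr <- config$size_ranges[[class]]
        d <- stats::runif(1, sr[1], sr[2])
        off <- .disk_offsets(max(d / 2 / px, 0.5))
      }
      idx <- place_shape(class, off, allowed)
      add_instance(class, idx, TRUE)
    }
  }

  # background ROI patches: disks in resin / cytosome, arcs on the lining
  patches <- config$background_patches
  patch_r <- max(config$patch_nm / 2 / px, 1)
  pod <- .disk_offsets(patch_r)
  if (!is.na(patches["resin"]) && patches[["resin"]] > 0) {
    for (i in seq_len(patches[["resin"]])) {
      idx <- place_shape("resin", pod, !cell)
      add_instance("resin", idx, TRUE)
    }
  }
  if (!is.na(patches["cytosome"]) && patches[["cytosome"]] > 0) {
    for (i in seq_len(patches[["cytosome"]])) {
      idx <- place_shape("cytosome", pod, interior)
      add_instance("cytosome", idx, TRUE)
    }
  }
  n_arc <- if (is.na(patches["organic_lining"])) 0 else patches[["organic_lining"]]
  if (n_arc > 0) {
    lin_idx <- which(lining)
    ang <- atan2(((lin_idx - 1L) %% nr) + 1L - cy,
                 ((lin_idx - 1L) %/% nr) + 1L - cx)
    arc_half <- pi / 18  # 10 degrees half-width
    starts <- stats::runif(1, 0, 2 * pi) +
      seq(0, 2 * pi, length.out = n_arc + 1)[seq_len(n_arc)]
    for (th0 in starts) {
      d <- abs(((ang - th0 + pi) %% (2 * pi)) - pi)
      idx <- lin_idx[d <= arc_half]
      if (length(idx) == 0) next
      occupied[idx] <- TRUE
      add_instance("organic_lining", idx, TRUE)
    }
  }

  # remaining background regions (context, not ROIs)
  add_instance("resin", which(!cell & labels == 0L), FALSE)
  add_instance("organic_lining", which(lining & labels == 0L), FALSE)
  add_instance("cytosome", which(interior & labels == 0L), FALSE)

  tab <- do.call(rbind, inst)
  m <- match(tab$class, class_truth$class)
  tab$lambda_cn <- class_truth$lambda_cn[m]
  tab$lambda_s <- class_truth$lambda_s[m]
  if (config$jitter) {
    roi <- tab$is_roi
    tab$f15 <- ifelse(roi,
                      .truncnorm01(nrow(tab), class_truth$f15[m],
                                   class_truth$sd15[m]),
                      class_truth$f15[m])
    tab$f34 <- ifelse(roi,
                      .truncnorm01(nrow(tab), class_truth$f34[m],
                                   class_truth$sd34[m]),
                      class_truth$f34[m])
  } else {
    tab$f15 <- class_truth$f15[m]
    tab$f34 <- class_truth$f34[m]
  }

  structure(list(
    labels = labels, table = tab, config = config,
    condition = config$condition, seed = config$seed,
    class_truth = class_truth
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %dx%d px, %s, %d ROI instances, seed %d\n",
              nrow(x$labels), ncol(x$labels), x$condition,
              sum(x$table$is_roi), x$seed))
  invisible(x)
}

#' Acquisition specification
#'
#' @param planes Number of raster planes amalgamated per species
#'   (default 50; the reduced sulfur acquisition uses 25).
#' @param raster Raster width in pixels (256 or 128); if smaller than the
#'   label map the map is decimated by the integer stride.
#' @param species Species pairs to acquire: `"CN"` (12C14N-, 12C15N-),
#'   `"S"` (32S-, 34S-) or both.
#' @return Object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(planes = 50L, raster = 256L,
                             species = c("CN", "S")) {
  species <- match.arg(species, several.ok = TRUE)
  if (planes < 1) sq_error("sq_invalid_argument", "planes must be >= 1")
  structure(list(planes = as.integer(planes), raster = as.integer(raster),
                 species = species),
            class = "acquisition_spec")
}

#' Simulate a NanoSIMS measurement session from a phantom
#'
#' For every pixel and plane the total ion count of a species pair is drawn
#' Poisson with the class emission rate, then split Binomial(total, f) into
#' minor and major isotopologues using the pixel's instance-level true atom
#' fraction. Planes are independent; all stacks are co-registered.
#'
#' @param truth A [build_label_map()] result.
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed for the acquisition noise.
#' @param specimen_id Identifier recorded in the session metadata.
#' @return A `measurement_session`: list of per-species `planes x rows x
#'   cols` integer count arrays plus metadata.
#' @export
simulate_session <- function(truth, acq = acquisition_spec(), seed = 1L,
                             specimen_id = "phantom") {
  stopifnot(inherits(truth, "phantom_truth"), inherits(acq, "acquisition_spec"))
  labels <- truth$labels
  nr0 <- nrow(labels); nc0 <- ncol(labels)
  if (acq$raster != nr0 || acq$raster != nc0) {
    if (nr0 %% acq$raster != 0 || nc0 %% acq$raster != 0) {
      sq_error("sq_dimension_error",
               sprintf("raster %d does not divide label map %dx%d",
                       acq$raster, nr0, nc0))
    }
    stride <- nr0 %/% acq$raster
    labels <- labels[seq(1, nr0, by = stride), seq(1, nc0, by = stride)]
  }
  nr <- nrow(labels); nc <- ncol(labels)
  m <- match(as.vector(labels), truth$table$label)
  if (anyNA(m)) {
    sq_error("sq_invalid_argument", "label map contains unmapped labels")
  }
  set.seed(seed)
  planes <- acq$planes
  n <- planes * nr * nc
  draw_pair <- function(lambda_px, f_px) {
    lam <- rep(lambda_px, each = planes)
    f <- rep(f_px, each = planes)
    tot <- stats::rpois(n, lam)
    minor <- stats::rbinom(n, tot, f)
    list(minor = array(as.integer(minor), c(planes, nr, nc)),
         major = array(as.integer(tot - minor), c(planes, nr, nc)))
  }
  stacks <- list()
  if ("CN" %in% acq$species) {
    p <- draw_pair(truth$table$lambda_cn[m], truth$table$f15[m])
    stacks$CN15 <- p$minor
    stacks$CN14 <- p$major
  }
  if ("S" %in% acq$species) {
    p <- draw_pair(truth$table$lambda_s[m], truth$table$f34[m])
    stacks$S34 <- p$minor
    stacks$S32 <- p$major
  }
  pixel_size <- truth$config$pixel_size * (nr0 %/% nr)
  structure(list(
    stacks = stacks,
    pixel_size_nm = pixel_size,
    planes = planes,
    raster = nr,
    condition = truth$condition,
    specimen_id = specimen_id,
    seed = seed
  ), class = "measurement_session")
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf(
    "measurement_session '%s' (%s): %d planes, %dx%d px, species %s\n",
    x$specimen_id, x$condition, x$planes, x$raster, x$raster,
    paste(names(x$stacks), collapse = ", ")))
  invisible(x)
}

#' Extract the ROI label map from a phantom truth
#'
#' Keeps the discrete ROI instances (placed organelles and background
#' patches) and drops the residual background regions, yielding the label
#' map + class table pair consumed by [quantify_rois()].
#'
#' @param truth A [build_label_map()] result.
#' @param raster Optional raster width; the map is decimated by stride to
#'   match a reduced acquisition.
#' @return Object of class `roi_label_map`: `labels` matrix (0 = no ROI)
#'   and `table` with columns `label`, `roi_id`, `class`, `condition`,
#'   `chamber`.
#' @export
roi_label_map <- function(truth, raster = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  labels <- truth$labels
  keep <- truth$table$label[truth$table$is_roi]
  labels[!(labels %in% keep)] <- 0L
  if (!is.null(raster) && raster != nrow(labels)) {
    if (nrow(labels) %% raster != 0) {
      sq_error("sq_dimension_error", "raster does not divide label map")
    }
    stride <- nrow(labels) %/% raster
    labels <- labels[seq(1, nrow(labels), by = stride),
                     seq(1, ncol(labels), by = stride)]
  }
  tab <- truth$table[truth$table$is_roi, c("label", "class")]
  tab$roi_id <- sprintf("roi_%03d", tab$label)
  tab$condition <- truth$condition
  tab$chamber <- NA_character_
  rownames(tab) <- NULL
  structure(list(labels = labels,
                 table = tab[, c("label", "roi_id", "class", "condition",
                                 "chamber")]),
            class = "roi_label_map")
}
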