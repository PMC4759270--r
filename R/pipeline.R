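# End-to-end orchestration: simulate phantom specimens, write sessions,
# quantify both elements, summarise, and run the comparison battery,
# with a seeded, fully reproducible output bundle.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the run bundle.
#' @param seed Master seed; every specimen's geometry and acquisition
#'   seed is derived from it and recorded.
#' @param conditions Conditions to simulate and compare.
#' @param specimens_per_condition Number of phantom specimens (fields)
#'   per condition (default 2).
#' @param rows,cols,planes,raster Field and acquisition geometry.
#' @param method ROI estimator, `"pixelwise"` or `"pooled"`.
#' @param cn_min,s_min Mask thresholds.
#' @param jitter Per-ROI truth jitter (see [phantom_config()]).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            conditions = c("dysoxic", "anoxic"),
                            specimens_per_condition = 2L,
                            rows = 256L, cols = 256L,
                            planes = 50L, raster = 256L,
                            method = c("pixelwise", "pooled"),
                            cn_min = 1000, s_min = 60,
                            jitter = TRUE) {
  method <- match.arg(method)
  conditions <- match.arg(conditions, c("dysoxic", "anoxic"),
                          several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 conditions = conditions,
                 specimens_per_condition = as.integer(specimens_per_condition),
                 rows = as.integer(rows), cols = as.integer(cols),
                 planes = as.integer(planes), raster = as.integer(raster),
                 method = method, cn_min = cn_min, s_min = s_min,
                 jitter = isTRUE(jitter)),
            class = "pipeline_config")
}

#' Table-style condition comparison
#'
#' Per feature class, a two-sided Mann-Whitney comparison of ROI-level
#' atom percent between two conditions. The group named second in
#' `order` (by convention the anoxic group) is passed as the first
#' sample, so enrichment under the first condition yields negative Z.
#'
#' @param stats Combined `roi_stats` rows for one element.
#' @param order Character vector of the two condition names,
#'   c(reference, first-sample) — default `c("dysoxic", "anoxic")`.
#' @return Data frame: class, n and mean/sd atom% per condition, Z, p.
#' @export
compare_conditions <- function(stats, order = c("dysoxic", "anoxic")) {
  stats <- stats[!is.na(stats$f_mean), , drop = FALSE]
  rows <- lapply(intersect(organelle_classes(), unique(stats$class)),
                 function(cl) {
    g1 <- stats$f_mean[stats$class == cl & stats$condition == order[1]] * 100
    g2 <- stats$f_mean[stats$class == cl & stats$condition == order[2]] * 100
    if (length(g1) == 0 || length(g2) == 0) return(NULL)
    mw <- tryCatch(mann_whitney(g2, g1), simsquant_error = function(e) NULL)
    data.frame(
      class = cl,
      n_1 = length(g1), n_2 = length(g2),
      mean_1 = mean(g1), sd_1 = if (length(g1) > 1) stats::sd(g1) else NA_real_,
      mean_2 = mean(g2), sd_2 = if (length(g2) > 1) stats::sd(g2) else NA_real_,
      Z = if (is.null(mw)) NA_real_ else mw$Z,
      p = if (is.null(mw)) NA_real_ else mw$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(class = character(), n_1 = integer(), n_2 = integer(),
                      mean_1 = numeric(), sd_1 = numeric(),
                      mean_2 = numeric(), sd_2 = numeric(),
                      Z = numeric(), p = numeric(), stringsAsFactors = FALSE)
  }
  names(out) <- c("class",
                  paste0("n_", order[1]), paste0("n_", order[2]),
                  paste0("mean_", order[1]), paste0("sd_", order[1]),
                  paste0("mean_", order[2]), paste0("sd_", order[2]),
                  "Z", "p")
  out
}

.log_line <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full simulate-quantify-compare pipeline
#'
#' Simulates `specimens_per_condition` phantom fields per condition,
#' writes every session (TIFF + manifest) and ROI map, quantifies 15N and
#' 34S per ROI, and writes: per-ROI statistics, a class x condition
#' summary, Mann-Whitney condition comparisons per element, and per
#' condition x element a Kruskal-Wallis test plus the Steel-Dwass
#' all-pairs table. A machine-readable `run_manifest.json` records the
#' seed, configuration and package version. Outputs are deterministic
#' given `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory tables (`roi_stats`,
#'   `summary`, `comparisons`, `kruskal`, `steel_dwass`) and `files`.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir) ||
      file.access(config$out_dir, 2) != 0) {
    sq_error("sq_io_error",
             sprintf("output directory not writable: %s", config$out_dir))
  }
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)

  acq <- acquisition_spec(planes = config$planes, raster = config$raster)
  all_stats <- list()
  spec_idx <- 0L
  for (cond in config$conditions) {
    for (s in seq_len(config$specimens_per_condition)) {
      spec_idx <- spec_idx + 1L
      geo_seed <- config$seed + 7919L * spec_idx
      acq_seed <- geo_seed + 1L
      id <- sprintf("%s_%02d", cond, s)
      pc <- phantom_config(rows = config$rows, cols = config$cols,
                           condition = cond, jitter = config$jitter,
                           seed = geo_seed)
      truth <- build_label_map(pc)
      session <- simulate_session(truth, acq, seed = acq_seed,
                                  specimen_id = id)
      sdir <- file.path(config$out_dir, paste0("session_", id))
      write_session(session, sdir)
      rmap <- roi_label_map(truth, raster = config$raster)
      write_label_map(rmap, file.path(sdir, "roi"))
      .log_line(con, "simulate", id, ": seed ", geo_seed, ", ",
                sum(rmap$table$label > 0), " ROIs")
      for (el in c("N", "S")) {
        st <- quantify_rois(session, rmap, element = el,
                            method = config$method,
                            cn_min = config$cn_min, s_min = config$s_min)
        masked_pct <- 100 * sum(st$n_valid == 0) / nrow(st)
        .log_line(con, "quantify", id, " ", el, ": ",
                  sprintf("%.1f%% ROIs fully masked", masked_pct))
        all_stats[[paste(id, el)]] <- st
      }
    }
  }
  roi_stats <- do.call(rbind, all_stats)
  rownames(roi_stats) <- NULL
  write_table(roi_stats, file.path(config$out_dir, "roi_stats.csv"))

  summary_tab <- summarize_rois(roi_stats)
  write_table(summary_tab, file.path(config$out_dir, "summary.csv"))
  .log_line(con, "summarize", nrow(summary_tab), " class x condition rows")

  comparisons <- list(); kruskal <- list(); sd_tables <- list()
  for (el in c("N", "S")) {
    el_stats <- roi_stats[roi_stats$element == el, , drop = FALSE]
    if (length(config$conditions) == 2) {
      cmp <- compare_conditions(el_stats, order = config$conditions)
      comparisons[[el]] <- cmp
      write_table(cmp, file.path(config$out_dir,
                                 sprintf("comparison_%s.csv", el)))
    }
    for (cond in config$conditions) {
      cs <- el_stats[el_stats$condition == cond & !is.na(el_stats$f_mean), ]
      groups <- split(cs$f_mean * 100, cs$class)
      groups <- groups[lengths(groups) >= 2]
      if (length(groups) >= 2) {
        kw <- kruskal_wallis(groups)
        kruskal[[paste(el, cond)]] <- data.frame(
          element = el, condition = cond, chi_squared = kw$H, df = kw$df,
          p = kw$p, stringsAsFactors = FALSE)
        sdt <- steel_dwass(groups)
        sd_tables[[paste(el, cond)]] <- sdt
        write_table(as.data.frame(sdt),
                    file.path(config$out_dir,
                              sprintf("steel_dwass_%s_%s.csv", el, cond)))
        .log_line(con, "compare", el, " ", cond,
                  sprintf(": KW chi2 = %.2f (df %d)", kw$H, kw$df))
      }
    }
  }
  if (length(kruskal)) {
    write_table(do.call(rbind, kruskal),
                file.path(config$out_dir, "kruskal_wallis.csv"))
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    package = "simsquant",
    package_version = as.character(utils::packageVersion("simsquant")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(con, "done", "bundle written to ", config$out_dir)
  invisible(list(
    roi_stats = roi_stats, summary = summary_tab,
    comparisons = comparisons,
    kruskal = if (length(kruskal)) do.call(rbind, kruskal) else NULL,
    steel_dwass = sd_tables,
    files = list(out_dir = config$out_dir, log = log_path)
  ))
}

#' Mean +/- SD isotope composition scatter per condition
#'
#' For each condition, plots mean 34S atom% against mean 15N atom% per
#' feature class with SD error bars (a two-element composition summary
#' plot). One PDF per condition is written deterministically.
#'
#' @param summary A [summarize_rois()] table containing both elements.
#' @param out_dir Directory for the plot files.
#' @return Named list per condition: `file`, `xlim`, `ylim`.
#' @export
report_isotope_scatter <- function(summary, out_dir) {
  need <- c("class", "condition", "element", "n", "mean_atom_pct",
            "sd_atom_pct")
  if (!all(need %in% names(summary)) || nrow(summary) == 0 ||
      !all(c("N", "S") %in% summary$element)) {
    sq_error("sq_schema_error",
             "summary must contain both elements and the standard columns")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (cond in unique(summary$condition)) {
    n_tab <- summary[summary$condition == cond & summary$element == "N", ]
    s_tab <- summary[summary$condition == cond & summary$element == "S", ]
    cls <- intersect(n_tab$class, s_tab$class)
    if (length(cls) == 0) next
    xn <- n_tab$mean_atom_pct[match(cls, n_tab$class)]
    xs <- ifelse(is.na(n_tab$sd_atom_pct[match(cls, n_tab$class)]), 0,
                 n_tab$sd_atom_pct[match(cls, n_tab$class)])
    yn <- s_tab$mean_atom_pct[match(cls, s_tab$class)]
    ys <- ifelse(is.na(s_tab$sd_atom_pct[match(cls, s_tab$class)]), 0,
                 s_tab$sd_atom_pct[match(cls, s_tab$class)])
    xlim <- range(xn - xs, xn + xs)
    ylim <- range(yn - ys, yn + ys)
    fp <- file.path(out_dir, sprintf("isotope_scatter_%s.pdf", cond))
    grDevices::pdf(fp, width = 6, height = 5)
    graphics::plot(xn, yn, xlim = xlim, ylim = ylim, pch = 19,
                   xlab = "15N atom%", ylab = "34S atom%",
                   main = sprintf("Mean +/- SD isotopic composition (%s)",
                                  cond))
    graphics::arrows(xn - xs, yn, xn + xs, yn, angle = 90, code = 3,
                     length = 0.03)
    graphics::arrows(xn, yn - ys, xn, yn + ys, angle = 90, code = 3,
                     length = 0.03)
    graphics::text(xn, yn, labels = cls, pos = 3, cex = 0.6)
    grDevices::dev.off()
    out[[cond]] <- list(file = fp, xlim = xlim, ylim = ylim)
  }
  out
}
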