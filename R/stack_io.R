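# Disk formats: multi-page TIFF per ion species + JSON manifest for count
# stacks; label TIFF + class CSV for ROI maps; CSV result tables. All round
# trips are lossless for integer counts/labels, and 6 significant digits
# for floating-point table columns.

.stack_to_pages <- function(arr) {
  lapply(seq_len(dim(arr)[1]), function(p) arr[p, , ])
}

.write_count_tiff <- function(arr, path) {
  if (any(arr < 0)) sq_error("sq_format_error", "counts must be non-negative")
  if (max(arr) > 65535) {
    sq_error("sq_format_error", "counts exceed 16-bit TIFF range")
  }
  pages <- lapply(.stack_to_pages(arr), function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

.read_count_tiff <- function(path) {
  if (!file.exists(path)) {
    sq_error("sq_missing_file", sprintf("stack file not found: %s", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vals <- unlist(pages, use.names = FALSE)
  if (any(vals < 0) || any(vals != floor(vals))) {
    sq_error("sq_format_error",
             sprintf("non-integer or negative pixel values in %s", path))
  }
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  arr <- array(0L, c(length(pages), nr, nc))
  for (p in seq_along(pages)) arr[p, , ] <- as.integer(pages[[p]])
  arr
}

#' Write a measurement session to a directory
#'
#' Emits one multi-page 16-bit TIFF per ion species plus a
#' `manifest.json` recording species files, pixel size, planes, raster,
#' condition, specimen id and seed.
#'
#' @param session A `measurement_session`.
#' @param directory Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "measurement_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (sp in names(session$stacks)) {
    fn <- paste0(sp, ".tif")
    .write_count_tiff(session$stacks[[sp]], file.path(directory, fn))
    files[[sp]] <- fn
  }
  manifest <- list(
    species_files = files,
    pixel_size_nm = session$pixel_size_nm,
    planes = session$planes,
    raster = session$raster,
    condition = session$condition,
    specimen_id = session$specimen_id,
    seed = session$seed
  )
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a measurement session from a directory
#'
#' @param directory Directory containing `manifest.json` and the species
#'   TIFFs it references.
#' @return A `measurement_session`.
#' @export
read_session <- function(directory) {
  mp <- file.path(directory, "manifest.json")
  if (!file.exists(mp)) {
    sq_error("sq_missing_file", sprintf("no manifest.json in %s", directory))
  }
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  stacks <- list()
  for (sp in names(manifest$species_files)) {
    arr <- .read_count_tiff(file.path(directory, manifest$species_files[[sp]]))
    if (dim(arr)[1] != manifest$planes ||
        dim(arr)[2] != manifest$raster || dim(arr)[3] != manifest$raster) {
      sq_error("sq_consistency_error",
               sprintf("stack %s dims %s do not match manifest (%d planes, %d px)",
                       sp, paste(dim(arr), collapse = "x"),
                       manifest$planes, manifest$raster))
    }
    stacks[[sp]] <- arr
  }
  structure(list(
    stacks = stacks,
    pixel_size_nm = manifest$pixel_size_nm,
    planes = manifest$planes,
    raster = manifest$raster,
    condition = manifest$condition,
    specimen_id = manifest$specimen_id,
    seed = manifest$seed %||% NA_integer_
  ), class = "measurement_session")
}

#' Write an ROI label map
#'
#' Writes `<prefix>_labels.tif` (16-bit label image, 0 = no ROI) and
#' `<prefix>_classes.csv` (columns `label`, `roi_id`, `class`,
#' `condition`, `chamber`).
#'
#' @param map An `roi_label_map`.
#' @param prefix Path prefix for the file pair.
#' @return The prefix, invisibly.
#' @export
write_label_map <- function(map, prefix) {
  stopifnot(inherits(map, "roi_label_map"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  if (max(map$labels) > 65535) {
    sq_error("sq_format_error", "labels exceed 16-bit TIFF range")
  }
  tiff::writeTIFF(map$labels / 65535, paste0(prefix, "_labels.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(map$table, paste0(prefix, "_classes.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Read an ROI label map
#'
#' @param prefix Path prefix written by [write_label_map()].
#' @return An `roi_label_map`. Unknown class names and labels missing
#'   from the class table raise typed errors.
#' @export
read_label_map <- function(prefix) {
  lp <- paste0(prefix, "_labels.tif")
  cp <- paste0(prefix, "_classes.csv")
  if (!file.exists(lp) || !file.exists(cp)) {
    sq_error("sq_missing_file",
             sprintf("expected %s and %s", lp, cp))
  }
  labels <- tiff::readTIFF(lp, as.is = TRUE)
  storage.mode(labels) <- "integer"
  tab <- utils::read.csv(cp, stringsAsFactors = FALSE,
                         colClasses = c(chamber = "character"))
  bad_class <- setdiff(unique(tab$class), organelle_classes())
  if (length(bad_class)) {
    sq_error("sq_vocabulary_error",
             sprintf("unknown class name(s): %s; accepted: %s",
                     paste(bad_class, collapse = ", "),
                     paste(organelle_classes(), collapse = ", ")))
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  orphan <- setdiff(present, tab$label)
  if (length(orphan)) {
    sq_error("sq_orphan_label",
             sprintf("label(s) %s present in image but absent from class table",
                     paste(orphan, collapse = ", ")))
  }
  structure(list(labels = labels, table = tab), class = "roi_label_map")
}

# Canonical column order for ROI statistics tables.
.roi_stat_columns <- c("specimen", "condition", "class", "roi_id", "n_valid",
                       "f_mean", "f_sd", "f_se", "total_minor", "total_major")

#' Write a result table as CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal separator; floating-point columns are
#' serialised with 6 significant digits. ROI statistics tables are written
#' in the canonical column order
#' (specimen, condition, class, roi_id, n_valid, f_mean, f_sd, f_se,
#' total_minor, total_major).
#'
#' @param rows A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  if (all(.roi_stat_columns %in% names(rows))) {
    extra <- setdiff(names(rows), .roi_stat_columns)
    rows <- rows[, c(.roi_stat_columns, extra), drop = FALSE]
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         formatC(signif(out[[j]], 6), format = "g",
                                 digits = 6))
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) sq_error("sq_io_error", sprintf("cannot write %s", path))
  invisible(path)
}
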