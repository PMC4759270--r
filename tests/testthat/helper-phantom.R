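# Small phantom configurations used across tests: same 10 um field at a
# coarser 64 px raster, fewer organelles, so a full simulate-quantify
# cycle runs in well under a second.

small_config <- function(condition = "dysoxic", seed = 1L, ...) {
  phantom_config(
    rows = 64, cols = 64, pixel_size = 10000 / 64,
    condition = condition,
    organelle_counts = c(vacuole = 2, food_vacuole = 1, mitochondrion = 4,
                         peroxisome = 1, plastid = 1, lipid_droplet = 2,
                         possible_endobiont = 2, electron_dense_body = 4),
    background_patches = c(resin = 3, cytosome = 3, organic_lining = 2),
    seed = seed, ...)
}

small_session <- function(condition = "dysoxic", seed = 1L, planes = 50,
                          jitter = TRUE) {
  truth <- build_label_map(small_config(condition, seed, jitter = jitter))
  list(truth = truth,
       session = simulate_session(truth,
                                  acquisition_spec(planes = planes,
                                                   raster = nrow(truth$labels)),
                                  seed = seed + 1L),
       rois = roi_label_map(truth))
}

# Hand-built one-plane session around explicit count matrices.
manual_session <- function(minor, major, element = "N", planes = 1L) {
  sp <- if (element == "N") c("CN15", "CN14") else c("S34", "S32")
  to_stack <- function(m) array(as.integer(m), c(1L, nrow(m), ncol(m)))
  stacks <- stats::setNames(list(to_stack(minor), to_stack(major)), sp)
  structure(list(stacks = stacks, pixel_size_nm = 39.0625,
                 planes = 1L, raster = nrow(minor), condition = "dysoxic",
                 specimen_id = "manual", seed = NA_integer_),
            class = "measurement_session")
}

manual_roi_map <- function(labels, classes, condition = "dysoxic") {
  tab <- data.frame(label = sort(unique(labels[labels > 0])),
                    stringsAsFactors = FALSE)
  tab$roi_id <- sprintf("roi_%03d", tab$label)
  tab$class <- classes
  tab$condition <- condition
  tab$chamber <- NA_character_
  structure(list(labels = labels, table = tab), class = "roi_label_map")
}
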