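# Plain-text/binary on-disk container for epoch sets:
#   <dir>/data.f32   little-endian float32, C order (trials, channels, samples)
#   <dir>/meta.json  shape, fs, onset_index, channel names
#   <dir>/trials.csv per-trial metadata
# Deliberately vendor-neutral and diff-able; round-trips losslessly up to
# float32 precision, which is ample for microvolt-scale synthetic data.

#' Save an epoch set to a directory container
#'
#' @param epochs an [epoch_set()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [load_epochs()]
#' @export
save_epochs <- function(epochs, path) {
  validate_epoch_set(epochs)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_ag(sprintf("cannot create directory '%s'", path))
  d <- dim(epochs$data)
  meta <- list(
    shape = as.integer(d), fs = epochs$fs,
    onset_index = epochs$onset_index,
    channel_names = as.list(epochs$channel_names),
    byte_order = "little", dtype = "float32", order = "C"
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.f32"), "wb")
  on.exit(close(con), add = TRUE)
  # C order = samples fastest, trials slowest
  if (prod(d) > 0) {
    writeBin(as.vector(aperm(epochs$data, c(3, 2, 1))), con,
             size = 4, endian = "little")
  }
  readr::write_csv(epochs$trials, file.path(path, "trials.csv"),
                   progress = FALSE)
  invisible(path)
}

#' Load an epoch set saved by [save_epochs()]
#'
#' @param path container directory.
#' @return an [epoch_set()].
#' @export
load_epochs <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop_ag(sprintf("no meta.json sidecar found in '%s'", path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs <= 0) stop_ag("sidecar has invalid fs")
  d <- as.integer(meta$shape)
  if (length(d) != 3) stop_ag("sidecar shape must have 3 entries")
  bin_path <- file.path(path, "data.f32")
  expected <- prod(d) * 4
  found <- file.size(bin_path)
  if (is.na(found)) stop_ag("data.f32 payload missing")
  if (found != expected) {
    stop_ag(sprintf("data.f32 has %d bytes, expected %d for shape %s",
                    found, expected, paste(d, collapse = "x")))
  }
  raw <- if (expected > 0) {
    con <- file(bin_path, "rb")
    on.exit(close(con), add = TRUE)
    readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  } else numeric(0)
  data <- aperm(array(raw, dim = rev(d)), c(3, 2, 1))
  trials <- readr::read_csv(file.path(path, "trials.csv"),
                            show_col_types = FALSE, progress = FALSE)
  if (nrow(trials) == 0) trials <- blank_trials(0)
  epoch_set(data, meta$fs, meta$onset_index,
            unlist(meta$channel_names), trials)
}
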