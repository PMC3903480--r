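#' Write an epochs container to disk
#'
#' The container is a portable pair of files: `<path>` holds the numeric
#' payload as IEEE-754 doubles in forced little-endian byte order, and
#' `<path>.json` is a structured-text sidecar with the trial labels and
#' identifiers. Byte layout of the binary file:
#'
#' * bytes 1-4: magic `"TGD1"`;
#' * three little-endian int32: `n_trials`, `n_channels`, `n_samples`;
#' * one double: `sample_rate` (Hz);
#' * `n_samples` doubles: the time axis (seconds);
#' * `n_trials * n_channels * n_samples` doubles: the data array in R
#'   column-major order (trial index fastest, then channel, then sample).
#'
#' Because the byte order is fixed, containers round-trip bit-exactly across
#' platforms of either endianness.
#'
#' @param epochs an [epochs_set()].
#' @param path file path for the binary payload; the sidecar is written next to
#'   it as `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epochs_set"))
  d <- dim(epochs$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("TGD1"), con)
  writeBin(as.integer(d), con, size = 4L, endian = "little")
  writeBin(epochs$sample_rate, con, size = 8L, endian = "little")
  writeBin(epochs$times, con, size = 8L, endian = "little")
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  sidecar <- list(
    format = "tgdecode-epochs", version = 1L,
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    sample_rate = epochs$sample_rate,
    subject_id = epochs$subject_id,
    channel_ids = epochs$channel_ids,
    labels = epochs$labels)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an epochs container written by [save_epochs()]
#'
#' @param path path of the binary payload (the sidecar is expected at
#'   `paste0(path, ".json")`).
#' @return An [epochs_set()], bit-identical to the one saved.
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path)) stop("missing metadata sidecar: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (!identical(sc$format, "tgdecode-epochs"))
    stop("sidecar field `format`: not a tgdecode epochs container")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "TGD1")) stop("bad magic in binary payload: ", magic)
  d <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  for (f in c("n_trials", "n_channels", "n_samples")) {
    i <- match(f, c("n_trials", "n_channels", "n_samples"))
    if (!identical(as.integer(sc[[f]]), d[i]))
      stop(sprintf("%s mismatch between sidecar (%d) and binary payload (%d)",
                   f, as.integer(sc[[f]]), d[i]))
  }
  fs <- readBin(con, "double", 1L, size = 8L, endian = "little")
  times <- readBin(con, "double", d[3L], size = 8L, endian = "little")
  vals <- readBin(con, "double", prod(d), size = 8L, endian = "little")
  if (length(vals) != prod(d))
    stop("binary payload truncated: expected ", prod(d), " values, got ",
         length(vals))
  labels <- as.data.frame(sc$labels, stringsAsFactors = FALSE)
  if (nrow(labels) != d[1L])
    stop(sprintf("label/trial count mismatch: %d labels for %d trials",
                 nrow(labels), d[1L]))
  epochs_set(array(vals, dim = d), times, fs, labels,
             subject_id = sc$subject_id, channel_ids = sc$channel_ids)
}

#' Export per-trial labels as CSV
#'
#' @param epochs an [epochs_set()].
#' @param path output CSV path.
#' @export
export_labels_csv <- function(epochs, path) {
  stopifnot(inherits(epochs, "epochs_set"))
  write.csv(cbind(trial = seq_len(nrow(epochs$labels)), epochs$labels),
            path, row.names = FALSE)
  invisible(path)
}
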