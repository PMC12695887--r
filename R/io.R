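#' Read and write photoacoustic traces as delimited text
#'
#' Two-column tab-separated waveform files with a header
#' (`time_s`, `amplitude_mV`). The sampling rate is recovered from the
#' time column on read.
#'
#' @param signal A `pa_signal`.
#' @param path File path.
#' @param label Optional class label attached on read.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "pa_signal"))
  t <- (seq_along(signal$samples) - 1L) / signal$sampling_rate
  df <- data.frame(time_s = sprintf("%.10e", t),
                   amplitude_mV = sprintf("%.10e", signal$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path, label = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("time_s", "amplitude_mV") %in% names(df)))
    stop_pa("%s: expected columns time_s, amplitude_mV", path)
  tt <- suppressWarnings(as.numeric(df$time_s))
  amp <- suppressWarnings(as.numeric(df$amplitude_mV))
  bad <- which(!(is.finite(tt) & is.finite(amp)))
  if (length(bad))
    stop_pa("%s: malformed value near line %d", path, bad[1] + 1L)
  if (nrow(df) < 2L) stop_pa("%s: need >= 2 samples", path)
  fs <- 1 / stats::median(diff(tt))
  structure(
    list(samples = amp, sampling_rate = fs, trigger_time = 0,
         label = label, provenance = list(file = basename(path))),
    class = "pa_signal"
  )
}

#' Write and read a dataset directory with a JSON manifest
#'
#' One waveform file per signal plus `manifest.json` recording the class
#' inventory and, per file, its label, generation seed and md5 digest.
#' Reading verifies every digest and label.
#'
#' @param dataset A `pa_dataset`.
#' @param dir Output directory.
#' @param force Overwrite a non-empty existing directory.
#' @return `write_dataset()`: the manifest path, invisibly;
#'   `read_dataset()`: a `pa_dataset`.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  stopifnot(inherits(dataset, "pa_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop_pa("output directory '%s' is not empty (use force = TRUE)", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vector("list", length(dataset$signals))
  for (i in seq_along(dataset$signals)) {
    s <- dataset$signals[[i]]
    fn <- sprintf("signal_%04d_%s.tsv", i, s$label)
    write_signal(s, file.path(dir, fn))
    files[[i]] <- list(file = fn, label = s$label,
                       seed = s$provenance$seed %||% NA,
                       config_digest = s$provenance$config_digest %||% NA,
                       md5 = unname(tools::md5sum(file.path(dir, fn))))
  }
  manifest <- list(
    format = "pafingerprint-dataset",
    package_version = as.character(utils::packageVersion("pafingerprint")),
    class_names = dataset$class_names,
    files = files
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop_pa("no manifest.json in '%s'", dir)
  manifest <- jsonlite::fromJSON(mp, simplifyVector = FALSE)
  if (!identical(manifest$format, "pafingerprint-dataset"))
    stop_pa("%s: not a dataset manifest", mp)
  class_names <- as.character(unlist(manifest$class_names))
  signals <- lapply(manifest$files, function(fr) {
    fp <- file.path(dir, fr$file)
    if (!file.exists(fp)) stop_pa("manifest names missing file '%s'", fr$file)
    if (!is.null(fr$md5) && !is.na(fr$md5) &&
        !identical(unname(tools::md5sum(fp)), fr$md5))
      stop_pa("digest mismatch for '%s'", fr$file)
    if (!fr$label %in% class_names)
      stop_pa("file '%s' labelled '%s', outside the manifest classes",
              fr$file, fr$label)
    read_signal(fp, label = fr$label)
  })
  pa_dataset(signals, class_names = class_names)
}
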