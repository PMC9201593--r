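#' Write / read a recording container
#'
#' Two on-disk layouts share one schema (`signal` channels x samples,
#' `fs`, `channels` table with `id`, `area`, `layer`):
#'
#' * HDF5 (`.h5`/`.hdf5`; datasets `/signal`, `/fs`, `/channels`), via
#'   the rhdf5 package when available;
#' * delimited text (`.tsv`: samples as rows, channels as columns, full
#'   `%.17g` precision so the round trip is bit-exact) with a JSON
#'   sidecar `<stem>.meta.json` holding `fs` and the channel table.
#'
#' A ground-truth attribute (set by the synthetic generators) is written
#' to `<stem>.truth.json` alongside either layout.
#'
#' @param rec a [recording()].
#' @param path output path; the extension selects the layout.
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: a
#'   [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    stop_if(!requireNamespace("rhdf5", quietly = TRUE),
            "the rhdf5 package is required for HDF5 output; use a .tsv path instead")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(rec$signal, path, "signal")
    rhdf5::h5write(rec$fs, path, "fs")
    rhdf5::h5write(rec$channels, path, "channels")
    rhdf5::h5closeAll()
  } else if (ext == "tsv") {
    txt <- apply(rec$signal, 2L, function(col)
      paste(sprintf("%.17g", col), collapse = "\t"))
    writeLines(c(paste(rec$channels$id, collapse = "\t"), txt), path)
    jsonlite::write_json(list(fs = rec$fs, channels = rec$channels),
                         meta_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    stop_if(TRUE, "unsupported recording extension '.%s' (use .h5 or .tsv)", ext)
  }
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, truth_path(path), auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")
truth_path <- function(path) paste0(tools::file_path_sans_ext(path), ".truth.json")

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    stop_if(!requireNamespace("rhdf5", quietly = TRUE),
            "the rhdf5 package is required for HDF5 input")
    contents <- rhdf5::h5ls(path)$name
    for (field in c("signal", "fs", "channels")) {
      stop_if(!field %in% contents, "recording schema error: missing /%s", field)
    }
    sig <- rhdf5::h5read(path, "signal")
    fs <- as.numeric(rhdf5::h5read(path, "fs"))
    ch <- as.data.frame(rhdf5::h5read(path, "channels"),
                        stringsAsFactors = FALSE)
    ch[] <- lapply(ch, as.vector)     # drop HDF5 array dims on columns
    rhdf5::h5closeAll()
    recording(sig, fs, ch)
  } else if (ext == "tsv") {
    mp <- meta_path(path)
    stop_if(!file.exists(mp), "recording schema error: missing metadata file %s", mp)
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    stop_if(is.null(meta$fs), "recording schema error: missing field 'fs'")
    stop_if(is.null(meta$channels), "recording schema error: missing field 'channels'")
    lines <- readLines(path)
    sig <- vapply(lines[-1],
                  function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]),
                  numeric(nrow(meta$channels)), USE.NAMES = FALSE)
    if (is.vector(sig)) sig <- matrix(sig, nrow = 1L)
    rec <- recording(sig, meta$fs, as.data.frame(meta$channels))
    tp <- truth_path(path)
    if (file.exists(tp)) {
      attr(rec, "ground_truth") <- jsonlite::read_json(tp, simplifyVector = TRUE)
    }
    rec
  } else {
    stop_if(TRUE, "unsupported recording extension '.%s' (use .h5 or .tsv)", ext)
  }
}

#' Write a feature table / analysis table as TSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
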