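#' Read and write tabular spike and event files
#'
#' Spike tables are tab-separated with columns `neuron` (id) and `time_s`
#' (seconds); event tables have `time_s`, `direction` (integer index),
#' `condition`, and optionally `trial`. Readers validate and report
#' offending line numbers.
#'
#' @param path file path.
#' @return `read_spike_table()`: a named list of sorted spike-time
#'   vectors, one per neuron.
#' @export
read_spike_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty spike table: ", path)
    return(list())
  }
  if (!all(c("neuron", "time_s") %in% names(tab))) {
    stop("spike table needs `neuron` and `time_s` columns", call. = FALSE)
  }
  bad <- which(!is.finite(tab$time_s) | tab$time_s < 0)
  if (length(bad)) {
    stop("negative or non-finite spike times at line(s) ",
         paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
  }
  out <- split(tab$time_s, tab$neuron)
  lapply(out, sort)
}

#' @rdname read_spike_table
#' @param spikes data.frame with `neuron`, `time_s` columns.
#' @export
write_spike_table <- function(spikes, path) {
  utils::write.table(spikes[, c("neuron", "time_s")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spike_table
#' @export
read_event_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("time_s", "direction", "condition") %in% names(tab))) {
    stop("event table needs `time_s`, `direction`, `condition`",
         call. = FALSE)
  }
  tab[order(tab$time_s), ]
}

#' @rdname read_spike_table
#' @param events data.frame with `time_s`, `direction`, `condition`.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' HRIR grid container I/O
#'
#' Serializes an [hrir_grid()] to a single hierarchical JSON document
#' with entries `sample_rate`, `frame`, `band`, `directions` (N x 2) and
#' `ir` (`left`, `right`: N x L matrices); `read_hrir_grid()` restores
#' it. The layout mirrors the usual hierarchical-container organization
#' of measured HRIR archives.
#'
#' @param grid an [hrir_grid()].
#' @param path file path (`.json`).
#' @return `read_hrir_grid()`: an [hrir_grid()].
#' @export
write_hrir_grid <- function(grid, path) {
  stopifnot(inherits(grid, "hrir_grid"))
  obj <- list(sample_rate = grid$sample_rate, frame = grid$frame,
              band = grid$band,
              directions = as.matrix(grid$directions),
              ir = list(left = grid$left, right = grid$right))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hrir_grid
#' @export
read_hrir_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hrir_grid(obj$sample_rate,
            data.frame(azimuth = obj$directions[, 1],
                       elevation = obj$directions[, 2]),
            obj$ir$left, obj$ir$right,
            frame = obj$frame, band = obj$band)
}

#' Minimal RIFF/WAVE I/O for synthesized stimuli
#'
#' Writes a [synthesize_vas()] stereo stimulus (or any two equal-length
#' waveforms) as a 16-bit PCM stereo WAV file, and reads such files back.
#' Waveforms are scaled by `1/peak` full-scale on write (`peak` taken
#' over both channels) so interaural level relations are preserved.
#'
#' @param stimulus a `"stereo_stimulus"`.
#' @param path file path.
#' @export
write_wav <- function(stimulus, path) {
  l <- stimulus$left
  r <- stimulus$right
  fs <- round(stimulus$sample_rate)
  peak <- max(abs(c(l, r)), 1e-12)
  pcm <- as.integer(round(rbind(l, r) / peak * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little") # fmt chunk size
  writeBin(c(1L, 2L), con, size = 2, endian = "little") # PCM, stereo
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little") # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @return `read_wav()`: list with `left`, `right` (in [-1, 1]) and
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sample_rate <- NA_real_
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) stop("no data chunk", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", size / 2, size = 2, endian = "little",
                     signed = FALSE)
      sample_rate <- fmt[3] + fmt[4] * 65536
    } else if (tag == "data") {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      x <- matrix(pcm / 32767, nrow = 2)
      return(list(left = x[1, ], right = x[2, ], sample_rate = sample_rate))
    } else {
      seek(con, where = seek(con) + size)
    }
  }
}
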