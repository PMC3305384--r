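#' Phonocardiogram record
#'
#' Container for a single-channel heart-sound recording: a numeric sample
#' vector, its sampling rate, and a label. The detection pipeline needs at
#' least about two seconds of audio (one full cardiac cycle plus margin).
#'
#' @param samples numeric vector of finite sample values (arbitrary units;
#'   WAV input is scaled to \[-1, 1\]).
#' @param fs sampling rate in Hz (> 0).
#' @param record_id text label carried through annotations and reports.
#' @return An object of class `"pcg_record"` with elements `samples`, `fs`,
#'   `record_id`.
#' @export
#' @examples
#' rec <- pcg_record(sin(2 * pi * 50 * seq(0, 2, by = 1/1000)), fs = 1000)
#' rec
pcg_record <- function(samples, fs, record_id = "record") {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("samples contain non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 record_id = as.character(record_id)[1]),
            class = "pcg_record")
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("PCG record '%s': %d samples at %g Hz (%.2f s)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.pcg_record <- function(x) length(x$samples)

# ---- WAV I/O ---------------------------------------------------------------
# Minimal RIFF/WAVE codec. Supports PCM 16/24/32 bit and IEEE float 32/64,
# mono or multi-channel (first channel taken with a warning). Integer PCM is
# mapped to [-1, 1) by division by 2^(bits-1).

#' Read a WAV file into a [pcg_record()]
#'
#' Supports PCM 16/24/32-bit and IEEE float 32/64-bit encodings. For
#' multi-channel files only the first channel is used (with a warning);
#' heart-sound recordings come from a single stethoscope head. Integer PCM
#' samples are scaled by `2^(bits-1)` so full scale maps to \[-1, 1).
#'
#' @param path path to a WAV file.
#' @param record_id label for the record; defaults to the file name.
#' @return A `"pcg_record"`.
#' @export
read_wav <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", len)
      fmt <- list(
        audio_format = u16(body, 1), n_channels = u16(body, 3),
        fs = u32(body, 5), bits = u16(body, 15)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", len)
    } else {
      readBin(con, "raw", len)
    }
    if (len %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0)
    stop("WAV file has no audio data: ", path)

  bytes <- fmt$bits / 8
  n_tot <- floor(length(data_raw) / bytes)
  if (n_tot == 0) stop("WAV file has zero-length audio: ", path)

  x <- decode_wav_samples(data_raw, fmt$audio_format, fmt$bits, n_tot)
  if (fmt$n_channels > 1) {
    warning("multi-channel WAV: using channel 1 of ", fmt$n_channels)
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  }
  if (is.null(record_id)) record_id <- sub("\\.wav$", "", basename(path),
                                           ignore.case = TRUE)
  pcg_record(x, fs = fmt$fs, record_id = record_id)
}

u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1])
}
u32 <- function(raw, off) {
  as.numeric(raw[off]) + 256 * as.numeric(raw[off + 1]) +
    65536 * as.numeric(raw[off + 2]) + 16777216 * as.numeric(raw[off + 3])
}

decode_wav_samples <- function(data_raw, audio_format, bits, n_tot) {
  if (audio_format == 3L) {            # IEEE float
    if (!bits %in% c(32L, 64L)) stop("unsupported float bit depth: ", bits)
    return(readBin(data_raw, "double", n_tot, size = bits / 8,
                   endian = "little"))
  }
  if (audio_format != 1L) stop("unsupported WAV audio format code: ",
                               audio_format)
  if (bits == 16L) {
    v <- readBin(data_raw, "integer", n_tot, size = 2, signed = TRUE,
                 endian = "little")
    return(v / 32768)
  }
  if (bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_tot * 3)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    return(v / 8388608)
  }
  if (bits == 32L) {
    v <- readBin(data_raw, "integer", n_tot, size = 4, endian = "little")
    return(v / 2147483648)
  }
  stop("unsupported PCM bit depth: ", bits)
}

#' Write a [pcg_record()] to a WAV file
#'
#' @param rec a `"pcg_record"`. Samples outside \[-1, 1\] are clipped for
#'   integer encodings.
#' @param path output path.
#' @param bits one of 16 (PCM, default), 32 or 64 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "pcg_record"))
  x <- rec$samples
  if (bits == 16L) {
    fmt_code <- 1L
    v <- as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768))
    payload <- writeBin(v, raw(), size = 2, endian = "little")
  } else if (bits %in% c(32L, 64L)) {
    fmt_code <- 3L
    payload <- writeBin(as.numeric(x), raw(), size = bits / 8,
                        endian = "little")
  } else stop("bits must be 16, 32 or 64")

  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- bits / 8
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(payload)), con, size = 4,
           endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(payload), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

# ---- Annotations -----------------------------------------------------------

#' Heart-sound event annotations
#'
#' A set of labelled events (S1/S2/S3/S4) with onset times and cycle
#' indices, used both for simulator ground truth and for detector output.
#' Events are kept sorted by cycle then onset.
#'
#' @param label character vector with values among "S1", "S2", "S3", "S4".
#' @param onset_s event onset in seconds from record start.
#' @param cycle non-negative integer cardiac-cycle index.
#' @param record_id record label (recycled).
#' @param source `"truth"` or `"detected"`.
#' @return A data frame of class `"annotation_set"` with columns
#'   `record_id`, `cycle`, `label`, `onset_s` and attribute `source`.
#' @export
annotation_set <- function(label = character(), onset_s = numeric(),
                           cycle = integer(), record_id = "record",
                           source = c("truth", "detected")) {
  source <- match.arg(source)
  n <- length(label)
  if (length(onset_s) != n || length(cycle) != n)
    stop("label, onset_s and cycle must have equal length")
  if (n > 0 && !all(label %in% c("S1", "S2", "S3", "S4")))
    stop("labels must be among S1, S2, S3, S4")
  cycle <- as.integer(cycle)
  if (n > 0 && any(cycle < 0)) stop("cycle indices must be non-negative")
  df <- data.frame(record_id = rep_len(as.character(record_id), n),
                   cycle = cycle, label = as.character(label),
                   onset_s = as.numeric(onset_s),
                   stringsAsFactors = FALSE)
  df <- df[order(df$cycle, df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("annotation_set", "data.frame"), source = source)
}

#' Write annotations to CSV
#'
#' Onsets are serialized in seconds with six decimal places (microsecond
#' resolution, far below any matching tolerance in use), so that
#' write-then-read round-trips exactly at that resolution.
#'
#' @param annots an [annotation_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annots, path) {
  stopifnot(inherits(annots, "annotation_set"))
  lines <- c("record_id,cycle,label,onset_s",
             if (nrow(annots) > 0)
               sprintf("%s,%d,%s,%.6f", annots$record_id, annots$cycle,
                       annots$label, annots$onset_s))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write annotations to ", path)
  invisible(path)
}

#' Read annotations from CSV
#'
#' Inverse of [write_annotations()].
#'
#' @param path CSV path with header `record_id,cycle,label,onset_s`.
#' @param source `"truth"` or `"detected"` tag for the returned set.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, source = c("truth", "detected")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"))
  need <- c("record_id", "cycle", "label", "onset_s")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  annotation_set(df$label, df$onset_s, df$cycle, df$record_id, source)
}
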