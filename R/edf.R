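# Minimal European Data Format (EDF) support: a reader sufficient for
# importing continuous paired scalp/intracranial recordings, plus a writer
# used to build fixtures. 16-bit samples are mapped to physical units with
# the per-signal digital/physical calibration from the header.

edf_field <- function(bytes, offset, width) {
  trimws(rawToChar(bytes[(offset + 1L):(offset + width)]))
}

read_edf_header <- function(path) {
  hdr <- readBin(path, raw(), 256L)
  if (length(hdr) < 256L) stop("not an EDF file (truncated header): ", path)
  n_records <- as.integer(edf_field(hdr, 236, 8))
  record_dur <- as.numeric(edf_field(hdr, 244, 8))
  ns <- as.integer(edf_field(hdr, 252, 4))
  sig_bytes <- readBin(con <- file(path, "rb"), raw(), 256L + 256L * ns)
  close(con)
  sig <- sig_bytes[257:(256L + 256L * ns)]
  # per-signal field blocks: label 16, transducer 80, dim 8, phys_min 8,
  # phys_max 8, dig_min 8, dig_max 8, prefilter 80, n_samples 8
  at <- function(start_bytes, width) {
    vapply(seq_len(ns), function(i)
      trimws(rawToChar(sig[(start_bytes + (i - 1L) * width + 1L):
                             (start_bytes + i * width)])), character(1))
  }
  pos <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8)) * ns
  list(n_signals = ns, n_records = n_records, record_duration = record_dur,
       labels = at(pos[1], 16),
       phys_min = as.numeric(at(pos[4], 8)),
       phys_max = as.numeric(at(pos[5], 8)),
       dig_min = as.numeric(at(pos[6], 8)),
       dig_max = as.numeric(at(pos[7], 8)),
       samples_per_record = as.integer(at(pos[9], 8)),
       data_offset = 256L + 256L * ns)
}

read_edf_signals <- function(path) {
  h <- read_edf_header(path)
  sz <- file.info(path)$size
  raw_all <- readBin(path, raw(), sz)
  data <- raw_all[(h$data_offset + 1L):sz]
  vals <- readBin(data, integer(), length(data) %/% 2L, size = 2L,
                  endian = "little", signed = TRUE)
  spr <- h$samples_per_record
  rec_len <- sum(spr)
  out <- vector("list", h$n_signals)
  names(out) <- h$labels
  starts <- cumsum(c(0L, spr))
  for (i in seq_len(h$n_signals)) {
    idx <- unlist(lapply(seq_len(h$n_records) - 1L,
                         function(r) r * rec_len + starts[i] + seq_len(spr[i])))
    scale <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    out[[i]] <- h$phys_min[i] + (vals[idx] - h$dig_min[i]) * scale
  }
  list(header = h, signals = out)
}

#' Import a continuous paired recording from an EDF file
#'
#' Selects the named scalp and intracranial channels and returns two
#' synchronized continuous arrays ready for [preprocess_recording()]. All
#' requested channels must share one sampling rate; resampling is out of
#' scope.
#'
#' @param path EDF file path
#' @param scalp_channel_names,intracranial_channel_names channel label vectors
#' @return list with `scalp` (T x M matrix), `intracranial` (T x Mbar matrix)
#'   and `sampling_rate` (Hz)
#' @export
import_edf <- function(path, scalp_channel_names, intracranial_channel_names) {
  ed <- read_edf_signals(path)
  h <- ed$header
  wanted <- c(scalp_channel_names, intracranial_channel_names)
  missing <- setdiff(wanted, h$labels)
  if (length(missing))
    stop("channel(s) not in EDF file: ", paste(missing, collapse = ", "),
         "; available: ", paste(h$labels, collapse = ", "))
  idx <- match(wanted, h$labels)
  rates <- h$samples_per_record[idx] / h$record_duration
  if (length(unique(rates)) != 1L)
    stop("requested channels have different sampling rates (",
         paste(unique(rates), collapse = ", "),
         " Hz); resampling is not supported")
  grab <- function(nms) do.call(cbind, ed$signals[nms])
  list(scalp = grab(scalp_channel_names),
       intracranial = grab(intracranial_channel_names),
       sampling_rate = rates[1])
}

# fixed-width ASCII field, left-justified and space padded
edf_pad <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a simple EDF file (one data-record per second)
#'
#' Used for building test fixtures and for exporting simulated continuous
#' recordings. Signals are scaled to the full 16-bit digital range.
#'
#' @param signals named list of equal-length numeric vectors (one per channel)
#' @param path output path
#' @param sampling_rate sampling rate in Hz shared by all channels
#' @param sampling_rates optional per-channel rates (each channel's vector
#'   length must then be `rate * n_seconds`)
#' @return `path`, invisibly
#' @export
write_edf <- function(signals, path, sampling_rate = 200,
                      sampling_rates = NULL) {
  ns <- length(signals)
  if (is.null(sampling_rates)) sampling_rates <- rep(sampling_rate, ns)
  n_sec <- length(signals[[1]]) / sampling_rates[1]
  if (n_sec != round(n_sec)) stop("signal length must be a whole number of seconds")
  n_sec <- as.integer(n_sec)
  phys_min <- vapply(signals, function(s) min(s, -1e-6), numeric(1))
  phys_max <- vapply(signals, function(s) max(s, 1e-6), numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, width) writeBin(charToRaw(edf_pad(x, width)), con)
  w("0", 8); w("X X X X", 80); w("Startdate 01-JAN-2000", 80)
  w("01.01.00", 8); w("00.00.00", 8)
  w(as.character(256L + 256L * ns), 8); w("", 44)
  w(as.character(n_sec), 8); w("1", 8); w(as.character(ns), 4)
  for (nm in names(signals)) w(nm, 16)
  for (i in seq_len(ns)) w("", 80)                     # transducer
  for (i in seq_len(ns)) w("uV", 8)                    # physical dimension
  for (i in seq_len(ns)) w(sprintf("%.3f", phys_min[i]), 8)
  for (i in seq_len(ns)) w(sprintf("%.3f", phys_max[i]), 8)
  for (i in seq_len(ns)) w("-32768", 8)
  for (i in seq_len(ns)) w("32767", 8)
  for (i in seq_len(ns)) w("", 80)                     # prefilter
  for (i in seq_len(ns)) w(as.character(sampling_rates[i]), 8)
  for (i in seq_len(ns)) w("", 32)                     # reserved
  dig <- lapply(seq_len(ns), function(i) {
    s <- signals[[i]]
    as.integer(round(-32768 + (s - phys_min[i]) *
                       (32767 - (-32768)) / (phys_max[i] - phys_min[i])))
  })
  for (r in seq_len(n_sec) - 1L) {
    for (i in seq_len(ns)) {
      spr <- sampling_rates[i]
      writeBin(dig[[i]][r * spr + seq_len(spr)], con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
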