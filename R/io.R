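# Plain-text file formats: stimulus/spike/feature TSVs, confusion CSV,
# dendrogram merge tables, and minimal 16-bit PCM mono WAV support.

#' Write / read the stimulus table
#'
#' TSV with columns `stimulus_id`, `call_type`, `rendition`, `duration_s`
#' (plus `wav_path` when waveforms are exported).
#'
#' @param stim_table Stimulus table data.frame.
#' @param path File path.
#' @return `read_stimulus_table` returns the data.frame.
#' @export
write_stimulus_table <- function(stim_table, path) {
  data.table::fwrite(stim_table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_stimulus_table
#' @export
read_stimulus_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("stimulus_id", "call_type")
  if (!all(need %in% names(df)))
    voc_stop(sprintf("stimulus table missing column(s): %s",
                     paste(setdiff(need, names(df)), collapse = ", ")),
             "vocnet_format_error")
  if (anyDuplicated(df$stimulus_id))
    voc_stop("duplicate stimulus_id in stimulus table", "vocnet_format_error")
  df
}

#' Write / read the spike-time table
#'
#' TSV with one row per spike: `unit_id`, `stimulus_id`, `trial`,
#' `spike_time_s` (onset-relative, seconds).
#'
#' @param spikes Spike table.
#' @param path File path.
#' @param stim_table Optional stimulus table for window validation:
#'   spikes must lie in `[-0.5, duration + 0.5]` s.
#' @return `read_spikes` returns a data.table.
#' @export
write_spikes <- function(spikes, path) {
  data.table::fwrite(spikes, path, sep = "\t")
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, stim_table = NULL) {
  sp <- data.table::fread(path, sep = "\t")
  need <- c("unit_id", "stimulus_id", "trial", "spike_time_s")
  if (!all(need %in% names(sp)))
    voc_stop("spike table missing required columns", "vocnet_format_error")
  if (any(!is.finite(sp$spike_time_s)))
    voc_stop("non-finite spike times", "vocnet_format_error")
  if (!is.null(stim_table)) {
    dur <- stim_table$duration_s[match(sp$stimulus_id, stim_table$stimulus_id)]
    if (anyNA(dur))
      voc_stop("spike rows reference unknown stimulus ids", "vocnet_format_error")
    bad <- which(sp$spike_time_s < -0.5 | sp$spike_time_s > dur + 0.5)
    if (length(bad))
      voc_stop(sprintf("spike time outside recording window at row %d",
                       bad[1]), "vocnet_format_error")
  }
  sp
}

#' Write / read per-trial feature tables
#' @param features Feature table (`unit_id`, `stimulus_id`, `trial`, `Z`,
#'   `T1..Tn`).
#' @param path File path.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Write / read a confusion matrix as CSV
#'
#' Classes in the fixed repertoire order; rows re-sum to 1 after a
#' round-trip.
#'
#' @param confusion Square matrix with class dimnames.
#' @param path File path.
#' @export
write_confusion <- function(confusion, path) {
  conf <- if (inherits(confusion, "voc_ensemble_result")) confusion$confusion
          else confusion
  utils::write.csv(as.data.frame(conf), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write / read a dendrogram as a merge table
#'
#' TSV with `step`, `child_a`, `child_b`, `height` in the [stats::hclust()]
#' merge convention (negative = leaf index).
#'
#' @param dendro `voc_dendrogram` or `hclust`.
#' @param path File path.
#' @export
write_dendrogram <- function(dendro, path) {
  hc <- if (inherits(dendro, "voc_dendrogram")) dendro$hclust else dendro
  df <- data.frame(step = seq_len(nrow(hc$merge)),
                   child_a = hc$merge[, 1], child_b = hc$merge[, 2],
                   height = hc$height)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dendrogram
#' @export
read_dendrogram <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  n <- nrow(df) + 1L
  hc <- list(merge = cbind(df$child_a, df$child_b), height = df$height,
             order = seq_len(n), labels = NULL,
             method = "restored", call = match.call(),
             dist.method = "unknown")
  class(hc) <- "hclust"
  # recompute a valid leaf order from the merge structure
  ord <- integer(0)
  walk <- function(i) {
    if (i < 0) ord <<- c(ord, -i)
    else { walk(hc$merge[i, 1]); walk(hc$merge[i, 2]) }
  }
  walk(nrow(hc$merge))
  hc$order <- ord
  hc
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE support for exporting synthetic stimuli; samples are
#' clipped to `[-1, 1]` and scaled to 16-bit integers.
#'
#' @param waveform Numeric samples in `[-1, 1]` (scaled by `scale`).
#' @param path File path.
#' @param sample_rate_hz Sample rate (Hz).
#' @param scale Divisor applied before integer conversion (default: max
#'   absolute sample, so full scale).
#' @export
write_wav <- function(waveform, path, sample_rate_hz, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(waveform), 1e-12)
  x <- as.integer(round(pmax(-1, pmin(1, waveform / scale)) * 32767))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")  # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")  # block align
  writeBin(as.integer(16), con, size = 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) voc_stop("not a RIFF file", "vocnet_format_error")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    voc_stop("not a WAVE file", "vocnet_format_error")
  fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4)
      voc_stop("no data chunk found", "vocnet_format_error")
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1 || bits != 16)
        voc_stop("only mono 16-bit PCM supported", "vocnet_format_error")
      if (sz > 16) invisible(readBin(con, raw(), sz - 16))
    } else if (id == "data") {
      x <- readBin(con, integer(), sz / 2, size = 2, endian = "little",
                   signed = TRUE)
      return(list(waveform = x / 32767, sample_rate_hz = fs))
    } else {
      invisible(readBin(con, raw(), sz))
    }
  }
}

#' Export a stimulus set as WAV files plus a stimulus table
#'
#' @param stimuli A `voc_stimulus_set`.
#' @param dir Output directory (created if needed).
#' @return The stimulus table (with `wav_path`), invisibly written to
#'   `stimuli.tsv` in `dir`.
#' @export
export_stimuli <- function(stimuli, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- stimuli$table
  tab$wav_path <- file.path(dir, paste0(tab$stimulus_id, ".wav"))
  for (i in seq_len(nrow(tab))) {
    s <- stimuli$stimuli[[tab$stimulus_id[i]]]
    write_wav(s$waveform, tab$wav_path[i], s$sample_rate_hz)
  }
  write_stimulus_table(tab, file.path(dir, "stimuli.tsv"))
  invisible(tab)
}

#' Serialize simulation ground truth as plain text
#'
#' Writes the per-unit ground truth of [simulate_responses()] next to the
#' data so recovery tests never re-derive it: drives as TSV and tuning
#' templates as a long TSV (`unit_id`, `row`, `col`, `value`).
#'
#' @param units List of `voc_unit_spec`.
#' @param drives Ground-truth drive table.
#' @param dir Output directory.
#' @export
write_ground_truth <- function(units, drives, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(drives, file.path(dir, "drives.tsv"), sep = "\t")
  tpl <- data.table::rbindlist(lapply(units, function(u) {
    m <- u$tuning_template
    data.table::data.table(unit_id = u$unit_id,
                           row = rep(seq_len(nrow(m)), ncol(m)),
                           col = rep(seq_len(ncol(m)), each = nrow(m)),
                           value = as.numeric(m))
  }))
  data.table::fwrite(tpl, file.path(dir, "templates.tsv"), sep = "\t")
  meta <- data.frame(unit_id = vapply(units, `[[`, "", "unit_id"),
                     baseline_rate_hz = vapply(units, `[[`, 0, "baseline_rate_hz"),
                     gain = vapply(units, `[[`, 0, "gain"),
                     noise_sd = vapply(units, `[[`, 0, "noise_sd"))
  data.table::fwrite(meta, file.path(dir, "units.tsv"), sep = "\t")
  invisible(dir)
}
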