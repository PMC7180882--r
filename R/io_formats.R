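# Challenge label symbols <-> canonical class names (dataset convention)
SYMBOL_MAP <- c(N = "Normal", A = "AF", O = "Other", "~" = "Noisy")

#' Label table mapping record IDs to rhythm classes
#'
#' @param record_id Character vector of unique record identifiers.
#' @param label Character vector of classes (one of [af_classes()]).
#' @return An object of class `label_table` (data frame with columns
#'   `record_id`, `label`).
#' @export
label_table <- function(record_id, label) {
  record_id <- as.character(record_id)
  label <- as.character(label)
  stopifnot(length(record_id) == length(label))
  if (anyDuplicated(record_id)) {
    stop("record IDs must be unique", call. = FALSE)
  }
  check_labels(label)
  structure(data.frame(record_id = record_id, label = label,
                       stringsAsFactors = FALSE),
            class = c("label_table", "data.frame"))
}

#' Read a Challenge-style label CSV
#'
#' Rows are `record_id,symbol` with symbols N, A, O, `~` mapped to Normal,
#' AF, Other, Noisy. A `record_id,symbol` header row is accepted and
#' skipped; the real `REFERENCE.csv` has none.
#'
#' @param path CSV file path.
#' @return A [label_table()].
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("label file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 &&
      grepl("^\\s*record_id\\s*,", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) return(label_table(character(0), character(0)))
  parts <- strsplit(lines, ",")
  bad_shape <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad_shape) > 0) {
    stop(sprintf("malformed label row %d: %s", bad_shape[1],
                 lines[bad_shape[1]]), call. = FALSE)
  }
  ids <- trimws(vapply(parts, `[`, character(1), 1))
  syms <- trimws(vapply(parts, `[`, character(1), 2))
  unknown <- which(!syms %in% names(SYMBOL_MAP))
  if (length(unknown) > 0) {
    stop(sprintf("unknown class symbol '%s' in row %d (%s)",
                 syms[unknown[1]], unknown[1], ids[unknown[1]]),
         call. = FALSE)
  }
  label_table(ids, unname(SYMBOL_MAP[syms]))
}

#' Write a label table as a Challenge-style CSV
#'
#' Classes are mapped back to the symbols N, A, O, `~`; a header row is
#' written.
#'
#' @param labels A [label_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_label_table <- function(labels, path) {
  inv <- stats::setNames(names(SYMBOL_MAP), SYMBOL_MAP)
  lines <- c("record_id,symbol",
             if (nrow(labels) > 0)
               paste0(labels$record_id, ",", inv[labels$label]))
  writeLines(lines, path)
  invisible(path)
}

# ---- minimal MAT-v5 support -------------------------------------------
# The Challenge stores each record as a MAT-v5 file holding one int16 row
# vector named "val". Only that shape (one numeric matrix variable,
# uncompressed) is supported here.

MAT_INT8 <- 1L; MAT_UINT8 <- 2L; MAT_INT16 <- 3L; MAT_UINT16 <- 4L
MAT_INT32 <- 5L; MAT_UINT32 <- 6L; MAT_SINGLE <- 7L; MAT_DOUBLE <- 9L
MAT_MATRIX <- 14L

#' Write an integer vector as a MAT-v5 `val` array file
#'
#' @param path Output file path.
#' @param values Integer vector (int16 range).
#' @param name MATLAB variable name (default `"val"`).
#' @return Invisibly, `path`.
#' @export
write_mat_val <- function(path, values, name = "val") {
  values <- as.integer(values)
  n <- length(values)
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by afdetect1d")
  desc <- substr(paste0(desc, strrep(" ", 116)), 1, 116)
  writeBin(charToRaw(desc), con)
  writeBin(raw(8), con)                          # subsystem offset
  writeBin(as.integer(256), con, size = 2, endian = "little")  # 0x0100
  writeBin(charToRaw("IM"), con)                 # little-endian marker
  name_raw <- charToRaw(name)
  name_pad <- (8 - length(name_raw) %% 8) %% 8
  data_pad <- (8 - (2 * n) %% 8) %% 8
  total <- 16 + 16 + (8 + length(name_raw) + name_pad) + (8 + 2 * n + data_pad)
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w32(MAT_MATRIX); w32(total)
  w32(6L); w32(8L)                               # array flags (miUINT32 x2)
  w32(10L); w32(0L)                              # class mxINT16, no flags
  w32(5L); w32(8L)                               # dims (miINT32)
  w32(1L); w32(n)
  w32(MAT_INT8); w32(length(name_raw))           # name
  writeBin(name_raw, con)
  if (name_pad > 0) writeBin(raw(name_pad), con)
  w32(MAT_INT16); w32(2L * n)                    # int16 data
  writeBin(values, con, size = 2, endian = "little")
  if (data_pad > 0) writeBin(raw(data_pad), con)
  invisible(path)
}

#' Read the single numeric array of a MAT-v5 file
#'
#' Supports uncompressed MAT-v5 files holding one numeric matrix variable
#' (the PhysioNet 2017 `val` layout), with int8/16/32, uint8/16/32, single
#' or double storage, in either byte order, including the small-element name
#' encoding.
#'
#' @param path MAT file path.
#' @return Numeric vector of raw (ungained) sample values.
#' @export
read_mat_val <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("MAT file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 124))
  endmark <- rawToChar(c(readBin(con, "raw", 2), readBin(con, "raw", 2))[3:4])
  endian <- if (endmark == "IM") "little" else "big"
  r32 <- function() readBin(con, "integer", 1, size = 4, endian = endian)
  type <- r32()
  if (bitwAnd(type, -65536L) != 0L) {
    stop("unsupported MAT element at top level", call. = FALSE)
  }
  if (type != MAT_MATRIX) {
    stop(sprintf("expected a miMATRIX element, found type %d (compressed files are not supported)",
                 type), call. = FALSE)
  }
  invisible(r32())                               # total bytes
  read_sub <- function() {
    t <- r32()
    small_bytes <- bitwShiftR(bitwAnd(t, -65536L), 16L) # upper 16 bits
    if (small_bytes != 0L) {
      t <- bitwAnd(t, 65535L)
      data <- readBin(con, "raw", 4)
      list(type = t, bytes = small_bytes, raw = data[seq_len(small_bytes)])
    } else {
      nb <- r32()
      data <- readBin(con, "raw", nb)
      pad <- (8 - nb %% 8) %% 8
      if (pad > 0) invisible(readBin(con, "raw", pad))
      list(type = t, bytes = nb, raw = data)
    }
  }
  decode <- function(sub) {
    spec <- switch(as.character(sub$type),
                   "1" = list("integer", 1, TRUE), "2" = list("integer", 1, FALSE),
                   "3" = list("integer", 2, TRUE), "4" = list("integer", 2, FALSE),
                   "5" = list("integer", 4, TRUE), "6" = list("integer", 4, FALSE),
                   "7" = list("numeric", 4, TRUE), "9" = list("numeric", 8, TRUE),
                   stop(sprintf("unsupported MAT data type %d", sub$type),
                        call. = FALSE))
    n <- sub$bytes / spec[[2]]
    readBin(sub$raw, spec[[1]], n, size = spec[[2]], signed = spec[[3]],
            endian = endian)
  }
  invisible(read_sub())                          # array flags
  dims <- decode(read_sub())
  invisible(read_sub())                          # name
  values <- as.numeric(decode(read_sub()))
  if (length(values) != prod(dims)) {
    stop(sprintf("MAT data length %d does not match declared dims %s",
                 length(values), paste(dims, collapse = "x")), call. = FALSE)
  }
  values
}

# parse a WFDB-style .hea header: sampling rate, length, gain, baseline
read_wfdb_header <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("header file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed header record line", call. = FALSE)
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  gain_spec <- sig[3]
  gain_num <- sub("^([-0-9.eE+]+).*$", "\\1", gain_spec)
  baseline <- if (grepl("\\(", gain_spec)) {
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
  } else 0
  list(record = top[1], n_sig = as.integer(top[2]), fs = as.numeric(top[3]),
       n_samples = as.integer(top[4]),
       gain = as.numeric(gain_num), baseline = baseline)
}

#' Read one PhysioNet-2017-style record
#'
#' Loads the raw integer trace from the MAT-v5 `val` file, converts it to
#' millivolts with the header's gain and baseline, and attaches the sampling
#' rate from the WFDB header.
#'
#' @param data_path Path to the `.mat` file.
#' @param header_path Path to the matching `.hea` file.
#' @param label Class label for the recording.
#' @param millivolts Convert to millivolts using the header gain (default
#'   `TRUE`); set `FALSE` to keep raw ADC units.
#' @return An [ecg_recording()].
#' @export
read_recording <- function(data_path, header_path, label,
                           millivolts = TRUE) {
  hdr <- read_wfdb_header(header_path)
  raw_vals <- read_mat_val(data_path)
  if (length(raw_vals) != hdr$n_samples) {
    stop(sprintf(
      "header declares %d samples but data file holds %d",
      hdr$n_samples, length(raw_vals)), call. = FALSE)
  }
  samples <- if (millivolts) (raw_vals - hdr$baseline) / hdr$gain else raw_vals
  ecg_recording(hdr$record, samples, hdr$fs, label)
}

#' Read every labeled record in a directory
#'
#' @param dir Directory holding `<id>.mat` / `<id>.hea` pairs.
#' @param labels A [label_table()] (or path to a label CSV).
#' @param millivolts Passed to [read_recording()].
#' @return List of [ecg_recording()] objects in label-table order.
#' @export
read_ecg_dir <- function(dir, labels, millivolts = TRUE) {
  if (is.character(labels)) labels <- read_label_table(labels)
  lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$record_id[i]
    read_recording(file.path(dir, paste0(id, ".mat")),
                   file.path(dir, paste0(id, ".hea")),
                   labels$label[i], millivolts = millivolts)
  })
}

# ---- segment store ----------------------------------------------------

#' Persist a segment dataset to a single container file
#'
#' The store is an Apache Arrow IPC (Feather v2) file holding the segment
#' matrix as typed double columns plus label and provenance columns, so the
#' round trip is lossless (bit-identical samples, order preserved).
#'
#' @param dataset A `segment_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_segment_store <- function(dataset, path) {
  stopifnot(inherits(dataset, "segment_dataset"))
  if (nrow(dataset$samples) > 0 &&
      !all(rowSums(!is.na(dataset$samples)) == dataset$threshold_samples)) {
    stop("all segments must have exactly the threshold length", call. = FALSE)
  }
  df <- as.data.frame(dataset$samples)
  names(df) <- sprintf("s%05d", seq_len(ncol(dataset$samples)))
  df <- cbind(data.frame(source_id = as.character(dataset$info$source_id),
                         label = as.character(dataset$info$label),
                         start_index = as.integer(dataset$info$start_index),
                         stringsAsFactors = FALSE),
              df)
  arrow::write_feather(df, path)
  invisible(path)
}

#' Load a segment dataset from its container file
#'
#' @param path File written by [write_segment_store()].
#' @return A `segment_dataset`.
#' @export
read_segment_store <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("segment store not found: %s", path), call. = FALSE)
  }
  df <- as.data.frame(arrow::read_feather(path))
  meta_cols <- c("source_id", "label", "start_index")
  sample_cols <- setdiff(names(df), meta_cols)
  samples <- as.matrix(df[, sample_cols, drop = FALSE])
  dimnames(samples) <- NULL
  segment_dataset(samples,
                  data.frame(source_id = as.character(df$source_id),
                             label = as.character(df$label),
                             start_index = as.integer(df$start_index),
                             stringsAsFactors = FALSE),
                  ncol(samples))
}
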