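# Minimal FCS 3.0/3.1 list-mode reader/writer.
#
# Scope: $MODE L; $DATATYPE F (written) plus F/D/I (read); $BYTEORD
# little/big endian; $PnE log-amplifier de-scaling and $PnG gain applied on
# read so values come back on the acquisition's linear scale. This covers
# files the simulator writes and plain list-mode exports; analysis segments
# and FCS 2.0 are out of scope.

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort_format(paste0("not an FCS 3.0/3.1 file: ", path))
  }
  off <- function(i) {
    s <- trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8))
    if (s == "") 0 else as.numeric(s)
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)

  seek(con, text_beg)
  raw_text <- readChar(con, text_end - text_beg + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  parts <- strsplit(substr(raw_text, 2, nchar(raw_text)), delim,
                    fixed = TRUE)[[1]]
  parts <- parts[!(seq_along(parts) > length(parts))]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(
    trimws(parts[seq(2, length(parts), by = 2)]),
    toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  )
  get_kw <- function(key, default = NULL) {
    if (key %in% names(kw)) kw[[key]] else default
  }

  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  dtype <- get_kw("$DATATYPE", "F")
  byteord <- get_kw("$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (data_beg == 0) data_beg <- as.numeric(get_kw("$BEGINDATA", "0"))
  if (data_end == 0) data_end <- as.numeric(get_kw("$ENDDATA", "0"))

  ch_names <- vapply(seq_len(n_par), function(i) {
    nm <- get_kw(paste0("$P", i, "N"))
    if (is.null(nm) || nm == "") paste0("P", i) else nm
  }, character(1))
  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(get_kw(paste0("$P", i, "B"), "32")),
                 integer(1))
  ranges <- vapply(seq_len(n_par),
                   function(i) as.numeric(get_kw(paste0("$P", i, "R"), "262144")),
                   numeric(1))
  amps <- lapply(seq_len(n_par), function(i) {
    e <- get_kw(paste0("$P", i, "E"), "0,0")
    as.numeric(strsplit(e, ",", fixed = TRUE)[[1]])
  })
  gains <- vapply(seq_len(n_par),
                  function(i) as.numeric(get_kw(paste0("$P", i, "G"), "1")),
                  numeric(1))

  seek(con, data_beg)
  n_values <- n_par * n_tot
  if (n_values == 0) {
    mat <- matrix(numeric(0), nrow = 0, ncol = n_par)
  } else if (dtype == "F") {
    v <- readBin(con, "numeric", n = n_values, size = 4, endian = endian)
    mat <- matrix(v, ncol = n_par, byrow = TRUE)
  } else if (dtype == "D") {
    v <- readBin(con, "numeric", n = n_values, size = 8, endian = endian)
    mat <- matrix(v, ncol = n_par, byrow = TRUE)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1 || !unique(bits) %in% c(16L, 32L)) {
      abort_format("$DATATYPE I supported only for uniform 16- or 32-bit widths")
    }
    sz <- unique(bits) / 8L
    if (sz == 2) {
      v <- readBin(con, "integer", n = n_values, size = 2, signed = FALSE,
                   endian = endian)
    } else {
      v <- readBin(con, "integer", n = n_values, size = 4, endian = endian)
      v <- ifelse(v < 0, v + 2^32, as.numeric(v))
    }
    mat <- matrix(as.numeric(v), ncol = n_par, byrow = TRUE)
  } else {
    abort_format(paste0("unsupported $DATATYPE: ", dtype))
  }

  # undo log amplification ($PnE f1,f2 => value = f2 * 10^(f1 * x / range))
  for (i in seq_len(n_par)) {
    f <- amps[[i]]
    if (length(f) == 2 && is.finite(f[1]) && f[1] > 0) {
      f2 <- if (f[2] > 0) f[2] else 1
      mat[, i] <- f2 * 10^(f[1] * mat[, i] / ranges[i])
    }
    if (is.finite(gains[i]) && gains[i] > 0 && gains[i] != 1) {
      mat[, i] <- mat[, i] / gains[i]
    }
  }

  colnames(mat) <- ch_names
  list(values = mat, keywords = kw)
}

write_fcs <- function(mat, path) {
  mat <- as.matrix(mat)
  ch_names <- colnames(mat)
  if (is.null(ch_names)) ch_names <- paste0("P", seq_len(ncol(mat)))
  n_par <- ncol(mat)
  n_tot <- nrow(mat)
  n_bytes <- 4L * n_par * n_tot

  ranges <- vapply(seq_len(n_par), function(i) {
    r <- if (n_tot > 0) max(mat[, i], 0) else 0
    max(ceiling(r) + 1, 1024)
  }, numeric(1))

  d <- "/"
  kv <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BEGIN%", "$ENDDATA", "%END%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0",
    "$PAR", as.character(n_par), "$TOT", as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kv <- c(kv,
            paste0("$P", i, "N"), ch_names[i],
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), format(ranges[i], scientific = FALSE))
  }
  build_text <- function(begin_s, end_s) {
    vals <- kv
    vals[vals == "%BEGIN%"] <- begin_s
    vals[vals == "%END%"] <- end_s
    paste0(d, paste0(vals, collapse = d), d)
  }
  # fixed-width offsets keep TEXT length independent of the numbers
  text0 <- build_text(sprintf("%08d", 0), sprintf("%08d", 0))
  text_beg <- 58L
  text_end <- text_beg + nchar(text0, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- if (n_bytes > 0) data_beg + n_bytes - 1L else 0L
  text <- build_text(sprintf("%08d", data_beg), sprintf("%08d", data_end))

  hfield <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   hfield(text_beg), hfield(text_end),
                   hfield(data_beg), hfield(if (n_bytes > 0) data_end else 0),
                   hfield(0), hfield(0))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n_bytes > 0) {
    writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  }
  invisible(path)
}
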