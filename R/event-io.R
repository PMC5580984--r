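#' Read cytometry events from FCS or CSV
#'
#' Loads an event file and attaches channel roles. FCS 3.0/3.1 list-mode
#' files and CSV files with a header row of channel names are supported.
#' For FCS, log-amplifier keywords (`$PnE`) and gains (`$PnG`) are undone on
#' load, so returned values are on the acquisition's linear scale; all
#' downstream MFI statistics are computed on that scale. Rows with
#' non-finite or unparsable values are dropped and counted (see
#' [n_dropped()]).
#'
#' @param path Path to the event file.
#' @param role_map Named character vector, channel name -> role, e.g.
#'   `c("FSC-A" = "fsc_a", "FITC-A" = "dna_label")`. Matching is
#'   case-insensitive. The scatter roles `fsc_a`, `fsc_h` and `ssc_a` are
#'   required unless `require_scatter = FALSE` (e.g. bead files).
#' @param format `"auto"` (by extension), `"fcs"` or `"csv"`.
#' @param sample_id,timepoint_h Metadata stored with the table.
#' @param require_scatter Require the three scatter roles to be mapped?
#'
#' @return An [event_table()].
#' @export
read_events <- function(path, role_map = character(),
                        format = c("auto", "fcs", "csv"),
                        sample_id = NULL, timepoint_h = NULL,
                        require_scatter = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }

  if (format == "fcs") {
    parsed <- tryCatch(read_fcs(path), cytofect_format_error = function(e) {
      rlang::abort(conditionMessage(e), class = "cytofect_format_error")
    })
    values <- tibble::as_tibble(parsed$values, .name_repair = "minimal")
    dropped <- 0L
  } else {
    parsed <- parse_numeric_csv(path)
    values <- parsed$values
    dropped <- parsed$n_dropped
  }

  if (require_scatter) {
    need <- c("fsc_a", "fsc_h", "ssc_a")
    missing_roles <- setdiff(need, unname(role_map))
    if (length(missing_roles) > 0) {
      abort_config(paste0("role map must assign mandatory scatter role(s): ",
                          toString(missing_roles)))
    }
  }

  event_table(values, roles = role_map, sample_id = sample_id,
              timepoint_h = timepoint_h, n_dropped = dropped)
}

# CSV events: header row = channel names; rows with any cell that fails
# numeric parsing are dropped and counted.
parse_numeric_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) == 0) {
    return(list(values = tibble::tibble(), n_dropped = 0L))
  }
  num <- dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    ~ suppressWarnings(as.numeric(.x))
  ))
  bad <- rowSums(is.na(as.matrix(num))) > 0
  list(values = num[!bad, , drop = FALSE], n_dropped = sum(bad))
}

#' Write cytometry events to FCS or CSV
#'
#' The written file round-trips through [read_events()] (FCS stores 32-bit
#' floats, so values are preserved to single precision; CSV is written in
#' full double precision). The CSV header row equals the channel names in
#' order.
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"fcs"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("auto", "fcs", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  ok <- tryCatch({
    if (format == "fcs") {
      write_fcs(as.matrix(as.data.frame(table, check.names = FALSE)), path)
    } else {
      readr::write_csv(tibble::as_tibble(as.data.frame(table, check.names = FALSE)),
                       path, progress = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    rlang::abort(paste0("could not write ", path, ": ",
                        conditionMessage(ok)), class = "cytofect_io_error")
  }
  invisible(path)
}

#' Transform a channel for gating geometry or display
#'
#' Returns a new table with the channel mapped through a monotone transform;
#' the input is unmodified. Transforms are for gate geometry and plots only:
#' MFI statistics in this package are always computed on untransformed
#' linear-scale values, because MESF calibration is defined on
#' acquisition-scale MFI.
#'
#' @param table An [event_table()].
#' @param role Role of the channel to transform.
#' @param transform `"linear"` (identity), `"log10_floor"` (values below
#'   `floor` are clamped to `floor` before log10), or `"asinh"` with
#'   `cofactor` (`asinh(x / cofactor)`).
#' @param cofactor Positive asinh cofactor (default 150, a typical value
#'   for conventional cytometers).
#' @param floor Positive floor for `log10_floor` (default 1).
#' @return A new `event_tbl`.
#' @export
transform_channel <- function(table, role,
                              transform = c("linear", "log10_floor", "asinh"),
                              cofactor = 150, floor = 1) {
  transform <- match.arg(transform)
  ch <- channel_for_role(table, role)
  if (is.na(ch)) abort_config(paste0("no channel mapped to role '", role, "'"))
  x <- table[[ch]]
  y <- switch(transform,
    linear = x,
    log10_floor = {
      if (floor <= 0) abort_config("`floor` must be > 0")
      log10(pmax(x, floor))
    },
    asinh = {
      if (cofactor <= 0) abort_config("`cofactor` must be > 0")
      asinh(x / cofactor)
    }
  )
  out <- table
  out[[ch]] <- y
  restore_event_tbl(out, table)
}
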