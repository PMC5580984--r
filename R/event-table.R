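#' Event tables
#'
#' An event table is the universal unit of cytometry data in cytofect: a
#' tibble with one row per acquired event and one numeric column per detector
#' channel, carrying channel *roles* (the assay semantics of each detector)
#' as metadata. Roles connect detector names, which vary between instruments,
#' to what the pipeline needs: forward/side scatter for gating, the labeled
#' DNA channel, the protein channel and an optional viability-dye channel.
#'
#' Recognised roles are `"fsc_a"`, `"fsc_h"`, `"ssc_a"` (mandatory for
#' gating), `"dna_label"`, `"protein"`, `"viability"` and `"other"`. Each
#' role except `"other"` may be assigned to at most one channel.
#'
#' Rows containing non-finite values are dropped at construction and counted
#' in the `n_dropped` attribute, so `n_read = n_kept + n_dropped` always
#' holds downstream.
#'
#' @param values A data frame or matrix of event measurements, one column
#'   per channel, on the acquisition's linear scale.
#' @param roles Named character vector mapping channel names to roles,
#'   e.g. `c("FSC-A" = "fsc_a", "FITC-A" = "dna_label")`. Channels not named
#'   here get role `"other"`.
#' @param sample_id Sample identifier stored with the table.
#' @param timepoint_h Hours post transfection, or `NULL` when not part of a
#'   time course.
#' @param n_dropped Rows already dropped upstream (added to rows dropped
#'   here).
#'
#' @return A tibble of class `event_tbl` with attributes `channel_roles`,
#'   `sample_id`, `timepoint_h` and `n_dropped`.
#' @examples
#' tb <- event_table(
#'   data.frame("FSC-A" = c(1e4, 2e4), "FSC-H" = c(9e3, 1.9e4),
#'              "SSC-A" = c(5e3, 6e3), check.names = FALSE),
#'   roles = c("FSC-A" = "fsc_a", "FSC-H" = "fsc_h", "SSC-A" = "ssc_a")
#' )
#' n_events(tb)
#' @export
event_table <- function(values, roles = character(), sample_id = "sample",
                        timepoint_h = NULL, n_dropped = 0L) {
  values <- tibble::as_tibble(as.data.frame(values, check.names = FALSE),
                              .name_repair = "minimal")
  if (anyDuplicated(names(values)) > 0) {
    abort_config("channel names must be unique within an event table")
  }
  if (ncol(values) > 0 && !all(vapply(values, is.numeric, logical(1)))) {
    abort_format("all event-table columns must be numeric")
  }
  roles <- validate_roles(roles, names(values))

  kept <- values
  dropped_here <- 0L
  if (nrow(values) > 0 && ncol(values) > 0) {
    finite <- rowSums(!is.finite(as.matrix(values))) == 0
    dropped_here <- sum(!finite)
    kept <- values[finite, , drop = FALSE]
  }

  tibble::new_tibble(
    kept,
    channel_roles = roles,
    sample_id = sample_id,
    timepoint_h = timepoint_h,
    n_dropped = as.integer(n_dropped) + as.integer(dropped_here),
    class = "event_tbl"
  )
}

validate_roles <- function(roles, channel_names) {
  known <- c("fsc_a", "fsc_h", "ssc_a", "dna_label", "protein",
             "viability", "other")
  if (length(roles) == 0) {
    roles <- stats::setNames(rep("other", length(channel_names)), channel_names)
    return(roles)
  }
  if (is.null(names(roles)) || any(names(roles) == "")) {
    abort_config("`roles` must be a named character vector (channel -> role)")
  }
  bad <- setdiff(roles, known)
  if (length(bad) > 0) {
    abort_config(paste0("unknown channel role(s): ", toString(unique(bad))))
  }
  # case-insensitive match of role-map names onto actual channel names
  idx <- match(tolower(names(roles)), tolower(channel_names))
  if (anyNA(idx)) {
    abort_config(paste0("role map names not present among channels: ",
                        toString(names(roles)[is.na(idx)])))
  }
  names(roles) <- channel_names[idx]
  assigned <- roles[roles != "other"]
  if (anyDuplicated(assigned) > 0) {
    abort_config(paste0("role assigned to more than one channel: ",
                        toString(unique(assigned[duplicated(assigned)]))))
  }
  full <- stats::setNames(rep("other", length(channel_names)), channel_names)
  full[names(roles)] <- roles
  full
}

#' @rdname event_table
#' @param x An `event_tbl`.
#' @export
n_events <- function(x) nrow(x)

#' @rdname event_table
#' @export
channel_roles <- function(x) attr(x, "channel_roles")

#' @rdname event_table
#' @param role A single role string.
#' @export
channel_for_role <- function(x, role) {
  roles <- channel_roles(x)
  hit <- names(roles)[roles == role]
  if (length(hit) == 0) return(NA_character_)
  hit[[1]]
}

#' @rdname event_table
#' @export
role_values <- function(x, role) {
  ch <- channel_for_role(x, role)
  if (is.na(ch)) {
    abort_config(paste0("no channel mapped to role '", role, "'"))
  }
  x[[ch]]
}

has_role <- function(x, role) !is.na(channel_for_role(x, role))

#' @rdname event_table
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @rdname event_table
#' @export
timepoint_h <- function(x) attr(x, "timepoint_h")

#' @rdname event_table
#' @export
n_dropped <- function(x) attr(x, "n_dropped")

# rebuild an event_tbl from a plain tibble, inheriting metadata from `template`
restore_event_tbl <- function(data, template, n_dropped_extra = 0L) {
  tibble::new_tibble(
    tibble::as_tibble(data, .name_repair = "minimal"),
    channel_roles = channel_roles(template),
    sample_id = sample_id(template),
    timepoint_h = timepoint_h(template),
    n_dropped = n_dropped(template) + as.integer(n_dropped_extra),
    class = "event_tbl"
  )
}

#' Subset an event table by a logical mask
#'
#' Keeps the channel-role metadata, unlike bare `[` on the underlying tibble.
#'
#' @param x An `event_tbl`.
#' @param mask Logical vector of length `n_events(x)`.
#' @return An `event_tbl` with the selected events.
#' @export
filter_events <- function(x, mask) {
  stopifnot(is.logical(mask), length(mask) == n_events(x))
  restore_event_tbl(x[mask & !is.na(mask), , drop = FALSE], x)
}

#' @export
print.event_tbl <- function(x, ...) {
  roles <- channel_roles(x)
  assigned <- roles[roles != "other"]
  cat(sprintf("# Cytometry events: %d events x %d channels (sample '%s'%s)\n",
              nrow(x), ncol(x), sample_id(x),
              if (is.null(timepoint_h(x))) ""
              else sprintf(", t = %g h", timepoint_h(x))))
  if (length(assigned) > 0) {
    cat("# Roles: ",
        paste(sprintf("%s=%s", assigned, names(assigned)), collapse = ", "),
        "\n", sep = "")
  }
  if (n_dropped(x) > 0) cat(sprintf("# Dropped rows: %d\n", n_dropped(x)))
  NextMethod()
}

# condition helpers -----------------------------------------------------

abort_config <- function(msg) {
  rlang::abort(msg, class = "cytofect_config_error")
}
abort_format <- function(msg) {
  rlang::abort(msg, class = "cytofect_format_error")
}
abort_data <- function(msg) {
  rlang::abort(msg, class = "cytofect_data_error")
}
abort_insufficient <- function(msg) {
  rlang::abort(msg, class = "cytofect_insufficient_data_error")
}
abort_domain <- function(msg) {
  rlang::abort(msg, class = "cytofect_domain_error")
}
abort_usage <- function(msg) {
  rlang::abort(msg, class = "cytofect_usage_error")
}
warn_cytofect <- function(msg) {
  rlang::warn(msg, class = "cytofect_warning")
}
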