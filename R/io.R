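#' Read a monitoring measurements table
#'
#' Reads a long-format delimited text file with one row per observation and
#' groups rows into [indicator_series()] objects by (water body, indicator,
#' year), preserving file order within each series.
#'
#' Mandatory columns: `wb_id`, `indicator`, `year`, `value` (a token as
#' understood by [parse_observation()]). Optional columns: `date` (ISO-8601,
#' used to align sum-group members) and `unit`, which if present must equal
#' `"ug/l"` (or the mu-spelled equivalent) on every row — concentrations are
#' never converted.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, default comma.
#' @return A list of `indicator_series`, in order of first appearance.
#' @export
read_measurements <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, quote = "\"",
                          fileEncoding = "UTF-8")
  measurements_from_df(df)
}

#' Build indicator series from a long-format data frame
#'
#' Same contract as [read_measurements()] but starting from an in-memory
#' data frame (e.g. the output of [generate_monitoring()]).
#'
#' @param df Data frame with columns `wb_id`, `indicator`, `year`, `value`
#'   and optionally `date`, `unit`.
#' @return A list of `indicator_series`.
#' @export
measurements_from_df <- function(df) {
  needed <- c("wb_id", "indicator", "year", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurements table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  if ("unit" %in% names(df)) {
    ok <- df$unit %in% c("ug/l", "µg/l", "μg/l")
    if (!all(ok)) {
      stop("unit column must be 'ug/l' everywhere; offending rows: ",
           paste(utils::head(which(!ok), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  year <- suppressWarnings(as.integer(df$year))
  if (anyNA(year)) {
    stop("non-integer year in rows: ",
         paste(utils::head(which(is.na(year)), 5L), collapse = ", "),
         call. = FALSE)
  }
  has_date <- "date" %in% names(df)
  if (has_date) {
    key <- paste(df$wb_id, df$indicator, year, df$date, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      stop("duplicate (wb_id, indicator, year, date) rows: ",
           paste(utils::head(which(dup), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  parsed <- parse_tokens(as.character(df$value), rows = seq_len(nrow(df)))
  grp <- paste(df$wb_id, df$indicator, year, sep = "\r")
  idx_by_grp <- split(seq_len(nrow(df)), factor(grp, levels = unique(grp)))
  lapply(idx_by_grp, function(idx) {
    indicator_series(
      water_body_id = df$wb_id[idx[1L]],
      indicator_id = df$indicator[idx[1L]],
      year = year[idx[1L]],
      values = parsed$value[idx],
      censored = parsed$censored[idx],
      dates = if (has_date) df$date[idx] else NULL
    )
  })
}

#' Write indicator series back to a measurements table
#'
#' Inverse of [read_measurements()]. Tokens are written at full precision so
#' a round trip reproduces every numeric value and censoring flag exactly.
#'
#' @param series_list List of `indicator_series`.
#' @param path Output file path.
#' @param sep Field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series_list, path, sep = ",") {
  rows <- lapply(series_list, function(s) {
    data.frame(
      wb_id = s$water_body_id, indicator = s$indicator_id, year = s$year,
      date = if (is.null(s$dates)) NA_character_ else as.character(s$dates),
      value = format_observation(s$values, s$censored),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(wb_id = character(), indicator = character(),
                      year = integer(), date = character(),
                      value = character())
  }
  if (all(is.na(out$date))) out$date <- NULL
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an environmental-quality-standards table
#'
#' Reads a delimited text file with one row per indicator (or per sum
#' group), columns `indicator`, `aa_eqs`, `mac_eqs` and optionally
#' `sum_group`. Thresholds are in ug/l. A pesticide sum group (e.g.
#' aldrin/dieldrin/endrin/isodrin) is declared by tagging each member row
#' with the group's label in `sum_group` and providing one row whose
#' `indicator` equals that label, carrying the group's thresholds for the
#' sum of concentrations.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, default comma.
#' @return A data frame of class `"eqs_table"` with columns `indicator`,
#'   `aa_eqs`, `mac_eqs`, `is_sum_group` and a list column `members`
#'   (member indicator ids for sum-group rows, `character(0)` otherwise).
#' @export
read_eqs <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, fileEncoding = "UTF-8")
  eqs_from_df(df)
}

#' Build an EQS table from a data frame
#'
#' @param df Data frame with columns `indicator`, `aa_eqs`, `mac_eqs` and
#'   optionally `sum_group`.
#' @return An `"eqs_table"` data frame; see [read_eqs()].
#' @export
eqs_from_df <- function(df) {
  needed <- c("indicator", "aa_eqs", "mac_eqs")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("EQS table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  aa <- suppressWarnings(as.numeric(df$aa_eqs))
  mac <- suppressWarnings(as.numeric(df$mac_eqs))
  bad <- is.na(aa) | is.na(mac)
  if (any(bad)) {
    stop("missing or non-numeric threshold for indicator(s): ",
         paste(df$indicator[bad], collapse = ", "), call. = FALSE)
  }
  if (any(aa <= 0) || any(mac <= 0)) {
    stop("EQS thresholds must be positive; offending indicator(s): ",
         paste(df$indicator[aa <= 0 | mac <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(mac < aa)) {
    stop("MAC-EQS below AA-EQS for indicator(s): ",
         paste(df$indicator[mac < aa], collapse = ", "), call. = FALSE)
  }
  group <- if ("sum_group" %in% names(df)) df$sum_group else
    rep("", nrow(df))
  group[is.na(group)] <- ""
  labels <- unique(group[nzchar(group)])
  members <- rep(list(character(0)), nrow(df))
  is_sum <- df$indicator %in% labels
  for (lab in labels) {
    mem <- df$indicator[group == lab]
    if (length(mem) < 2L) {
      stop("sum group '", lab, "' has fewer than 2 members", call. = FALSE)
    }
    row <- which(df$indicator == lab)
    if (length(row) != 1L) {
      stop("sum group '", lab,
           "' needs exactly one threshold row with indicator = '", lab, "'",
           call. = FALSE)
    }
    members[[row]] <- mem
  }
  out <- data.frame(indicator = as.character(df$indicator),
                    aa_eqs = aa, mac_eqs = mac,
                    is_sum_group = is_sum, stringsAsFactors = FALSE)
  out$members <- members
  out$member_of <- ifelse(nzchar(group), group, NA_character_)
  class(out) <- c("eqs_table", "data.frame")
  out
}
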