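# Table I/O and schema validation for the standard CSV interchange formats.

#' Built-in table schemas
#'
#' Column and constraint definitions for the package's CSV interchange
#' formats: `trace` (`time_s, roi, side, dff`), `trajectory`
#' (`frame, fly_id, x_mm, y_mm, orientation_deg`), `treadmill`
#' (`frame, forward, lateral, rotational`) and `synapse`
#' (`pre_type, post_type, pre_id, post_id, roi, side, weight`).
#'
#' @param name schema name.
#' @return a schema list with `columns` (name -> type) and `checks`.
#' @export
table_schema <- function(name = c("trace", "trajectory", "treadmill",
                                  "synapse")) {
  name <- match.arg(name)
  switch(name,
    trace = list(
      name = "trace",
      columns = c(time_s = "numeric", roi = "character",
                  side = "character", dff = "numeric"),
      checks = list(
        side_values = function(df) bad_rows(
          !df$side %in% c("left", "right", "none"), "side",
          "side must be one of left, right, none"),
        time_monotone = function(df) {
          bad <- unlist(lapply(split(seq_len(nrow(df)),
                                     paste(df$roi, df$side)), function(i) {
            i[c(FALSE, diff(df$time_s[i]) <= 0)]
          }), use.names = FALSE)
          data.frame(row = bad, column = rep("time_s", length(bad)),
                     message = rep("time_s must be strictly increasing per roi/side",
                                   length(bad)))
        })),
    trajectory = list(
      name = "trajectory",
      columns = c(frame = "numeric", fly_id = "character",
                  x_mm = "numeric", y_mm = "numeric",
                  orientation_deg = "numeric"),
      checks = list(
        frame_monotone = function(df) {
          bad <- unlist(lapply(split(seq_len(nrow(df)), df$fly_id),
                               function(i) i[c(FALSE, diff(df$frame[i]) <= 0)]),
                        use.names = FALSE)
          data.frame(row = bad, column = rep("frame", length(bad)),
                     message = rep("frame must be strictly increasing per fly",
                                   length(bad)))
        })),
    treadmill = list(
      name = "treadmill",
      columns = c(frame = "numeric", forward = "numeric",
                  lateral = "numeric", rotational = "numeric"),
      checks = list(
        frame_monotone = function(df) bad_rows(
          c(FALSE, diff(df$frame) <= 0), "frame",
          "frame must be strictly increasing"))),
    synapse = list(
      name = "synapse",
      columns = c(pre_type = "character", post_type = "character",
                  pre_id = "character", post_id = "character",
                  roi = "character", side = "character",
                  weight = "numeric"),
      checks = list(
        side_values = function(df) bad_rows(
          !df$side %in% c("ipsi", "contra", "unknown"), "side",
          "side must be one of ipsi, contra, unknown"),
        weight_integer = function(df) bad_rows(
          !is.finite(df$weight) | df$weight < 1 |
            df$weight != round(df$weight), "weight",
          "weight must be a positive integer"))))
}

bad_rows <- function(flag, column, message) {
  rows <- which(flag)
  data.frame(row = rows, column = rep(column, length(rows)),
             message = rep(message, length(rows)))
}

#' Validate a CSV table against a schema
#'
#' Checks column presence, column types, and schema-specific constraints
#' (value sets, monotone time/frame columns, integer synapse weights).
#'
#' @param path CSV file path.
#' @param schema a schema name understood by [table_schema()], or a schema
#'   list of the same shape.
#' @return list of class `validation_report`: `pass` (logical), `schema`,
#'   `n_rows`, and a `problems` data.frame with `row`, `column`, `message`
#'   (`row = NA` for file/column-level problems).
#' @export
validate_tables <- function(path, schema) {
  if (is.character(schema)) schema <- table_schema(schema)
  if (!file.exists(path)) stop("unreadable file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) e)
  if (inherits(df, "error")) stop("unreadable file: ", conditionMessage(df))
  problems <- list()
  missing_cols <- setdiff(names(schema$columns), names(df))
  if (length(missing_cols) > 0) {
    problems[[length(problems) + 1]] <- data.frame(
      row = NA_integer_, column = missing_cols,
      message = paste0("missing required column '", missing_cols, "'"))
  }
  for (col in setdiff(names(schema$columns), missing_cols)) {
    want <- schema$columns[[col]]
    ok <- if (want == "numeric") is.numeric(df[[col]]) else
      is.character(df[[col]]) || is.factor(df[[col]])
    if (!ok) {
      problems[[length(problems) + 1]] <- data.frame(
        row = NA_integer_, column = col,
        message = sprintf("column '%s' must be %s", col, want))
    }
  }
  if (length(problems) == 0 && nrow(df) > 0) {
    for (check in schema$checks) {
      res <- check(df)
      if (nrow(res) > 0) problems[[length(problems) + 1]] <- res
    }
  }
  problems <- if (length(problems) > 0) {
    do.call(rbind, problems)
  } else {
    data.frame(row = integer(), column = character(), message = character())
  }
  structure(list(pass = nrow(problems) == 0, schema = schema$name,
                 n_rows = nrow(df), problems = problems),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s table: %s (%d rows)\n", x$schema,
              if (x$pass) "PASS" else "FAIL", x$n_rows))
  if (!x$pass) print(head(x$problems, 20), row.names = FALSE)
  invisible(x)
}

#' Write a trace table to CSV
#'
#' @param traces a [dff_trace()] or list of them.
#' @param path output CSV path (columns `time_s`, `roi`, `side`, `dff`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "dff_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "dff_trace"))
    data.frame(time_s = trace_times(tr),
               roi = if (is.null(tr$roi) || is.na(tr$roi)) "roi1" else tr$roi,
               side = if (is.null(tr$side) || is.na(tr$side)) "none" else
                 tr$side,
               dff = tr$samples)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write receiver/stimulus trajectories to CSV
#'
#' @param pair a [tracked_pair()].
#' @param path output CSV path (columns `frame`, `fly_id`, `x_mm`, `y_mm`,
#'   `orientation_deg`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(pair, path) {
  stopifnot(inherits(pair, "tracked_pair"))
  f <- pair$frames
  df <- rbind(
    data.frame(frame = f$frame, fly_id = "receiver", x_mm = f$rx,
               y_mm = f$ry, orientation_deg = f$rori),
    data.frame(frame = f$frame, fly_id = "stimulus", x_mm = f$sx,
               y_mm = f$sy, orientation_deg = f$sori))
  df <- df[order(df$fly_id, df$frame), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synapse table to CSV
#' @param table a [synapse_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_synapse_csv <- function(table, path) {
  stopifnot(inherits(table, "synapse_table"))
  cols <- c("pre_type", "post_type", "pre_id", "post_id", "roi", "side",
            "weight")
  write.csv(as.data.frame(table)[, cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a synapse table from CSV
#' @param path CSV path in the `synapse` schema.
#' @return a [synapse_table()].
#' @export
read_synapse_csv <- function(path) {
  rep <- validate_tables(path, "synapse")
  if (!rep$pass) {
    stop("invalid synapse table: ", rep$problems$message[1],
         if (!is.na(rep$problems$row[1]))
           sprintf(" (row %d)", rep$problems$row[1]) else "")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$weight <- as.numeric(df$weight)
  synapse_table(df)
}
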