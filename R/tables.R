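# Table I/O: truth tables, picks, provenance sidecars, STAR reading,
# IMOD-style point lists. CSV is the canonical format; units Angstrom.

truth_columns <- c("id", "class", "x", "y", "z",
                   "axis_x", "axis_y", "axis_z", "separation")
pick_columns <- c("x", "y", "z", "class", "separation", "score")

write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write/read a ground-truth particle table
#'
#' Columns: id, class, x, y, z, axis_x, axis_y, axis_z, separation
#' (Angstrom). Optional provenance (e.g. seed, config hash) is written
#' as `#`-comment header lines.
#'
#' @param truth Truth data frame.
#' @param path File path.
#' @param provenance Optional named list written as comment lines.
#' @return The table (read) or the path (write, invisibly).
#' @export
write_truth <- function(truth, path, provenance = NULL) {
  stopifnot(all(truth_columns %in% names(truth)))
  write_csv_provenance(truth[, truth_columns], path, provenance)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_csv_checked(path, truth_columns)
}

#' Write/read a classified-particle (picks) table
#'
#' Columns: x, y, z (Angstrom), class, separation, score.
#'
#' @param picks Data frame (output of [classify_volume()] is accepted
#'   and renamed).
#' @inheritParams write_truth
#' @export
write_picks <- function(picks, path, provenance = NULL) {
  if ("dumbbell_score" %in% names(picks) && !"score" %in% names(picks)) {
    picks$score <- picks$dumbbell_score
  }
  stopifnot(all(pick_columns %in% names(picks)))
  write_csv_provenance(picks[, pick_columns], path, provenance)
}

#' @rdname write_picks
#' @export
read_picks <- function(path) {
  read_csv_checked(path, pick_columns)
}

#' Write coordinates as an IMOD-style point list
#'
#' One point per line, three whitespace-separated coordinates in
#' Angstrom, suitable for visual overlay tools.
#'
#' @param coords Matrix or data frame with x, y, z.
#' @param path File path.
#' @export
write_point_list <- function(coords, path) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  writeLines(apply(coords, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
             path)
  invisible(path)
}

#' Read a (single data block) STAR file
#'
#' Minimal reader for the common `loop_` layout used for particle and
#' class metadata: returns the first loop block as a data frame with
#' column names stripped of the leading underscore.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_star <- function(path) {
  lines <- trimws(readLines(path))
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stop("no loop_ block found in STAR file")
  i <- loop_at[1] + 1
  cols <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_", "", sub("\\s*#.*$", "", lines[i])))
    i <- i + 1
  }
  if (!length(cols)) stop("loop_ block has no column labels")
  rows <- list()
  while (i <= length(lines) && nzchar(lines[i]) &&
         !startsWith(lines[i], "data_") && !startsWith(lines[i], "loop_")) {
    fields <- strsplit(lines[i], "\\s+")[[1]]
    if (length(fields) != length(cols)) {
      stop(sprintf("STAR row %d has %d fields, expected %d",
                   i, length(fields), length(cols)))
    }
    rows[[length(rows) + 1]] <- fields
    i <- i + 1
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    suppressWarnings(num <- as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}
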