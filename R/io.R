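# Readers and writers for landmark data: the TPS dialect produced by the
# tpsUtil/tpsDig tool chain (LM=, coordinate lines, IMAGE=, ID=, SCALE=)
# and a long-format CSV. Coordinates are stored in um; a SCALE= factor is
# applied multiplicatively on read. Writers are deterministic; readers
# reject malformed input rather than silently coercing it.

#' Read a TPS landmark file
#'
#' Parses tpsDig-style records: an `LM=` count followed by whitespace-
#' separated coordinate lines, with optional `IMAGE=`, `ID=` and `SCALE=`
#' keys. Keys are case-insensitive and CRLF line endings are tolerated.
#' When present, the scale factor multiplies the coordinates.
#'
#' @param path File path.
#' @return List of records, each with `coords` (k x 2 matrix), `image`,
#'   `id`, `scale`.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop_cm("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  records <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^lm\\s*=", line, ignore.case = TRUE))
      stop_cm("line ", i, ": expected LM= record header, got '", line, "'")
    lm_count <- suppressWarnings(as.integer(sub("^lm\\s*=\\s*", "", line,
                                                ignore.case = TRUE)))
    if (is.na(lm_count) || lm_count < 1L)
      stop_cm("line ", i, ": invalid landmark count")
    i <- i + 1L
    coords <- matrix(NA_real_, lm_count, 2L)
    for (j in seq_len(lm_count)) {
      if (i > n_lines) stop_cm("unexpected end of file inside record")
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(fields) != 2L)
        stop_cm("line ", i, ": expected 2 coordinates, got ", length(fields))
      vals <- suppressWarnings(as.numeric(fields))
      if (any(is.na(vals))) stop_cm("line ", i, ": non-numeric coordinate")
      coords[j, ] <- vals
      i <- i + 1L
    }
    rec <- list(coords = coords, image = "", id = "", scale = NA_real_)
    while (i <= n_lines) {
      line <- trimws(lines[i])
      if (line == "") { i <- i + 1L; next }
      if (grepl("^lm\\s*=", line, ignore.case = TRUE)) break
      if (grepl("^image\\s*=", line, ignore.case = TRUE)) {
        rec$image <- sub("^image\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^id\\s*=", line, ignore.case = TRUE)) {
        rec$id <- sub("^id\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^scale\\s*=", line, ignore.case = TRUE)) {
        sc <- suppressWarnings(as.numeric(sub("^scale\\s*=\\s*", "", line,
                                              ignore.case = TRUE)))
        if (is.na(sc) || sc <= 0) stop_cm("line ", i, ": invalid SCALE value")
        rec$scale <- sc
      } else {
        rec$extra <- c(rec$extra, line)  # unknown keys preserved on round trip
      }
      i <- i + 1L
    }
    if (!is.na(rec$scale)) rec$coords <- rec$coords * rec$scale
    records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L) warning("empty TPS file: ", path)
  records
}

#' Write records to a TPS file
#'
#' Canonical dialect: `LM=` first, coordinates with six decimals, then
#' `IMAGE=`, `ID=`, `SCALE=` in that order (written only when non-empty).
#' Coordinates are written un-scaled (SCALE defaults to 1 on read), so a
#' write/read round trip reproduces them.
#'
#' @param records List of records (`coords`, optional `image`, `id`) or a
#'   `landmark_dataset`.
#' @param path Output path.
#' @export
write_tps <- function(records, path) {
  if (inherits(records, "landmark_dataset")) {
    d <- dim(records$coords)
    recs <- list()
    for (i in seq_len(d[1])) for (r in seq_len(d[2])) {
      recs[[length(recs) + 1L]] <- list(
        coords = records$coords[i, r, , ],
        id = sprintf("%s_rep%d", records$specimen_id[i], r))
    }
    records <- recs
  }
  out <- character(0)
  for (rec in records) {
    coords <- rec$coords
    if (is.null(coords) || nrow(coords) < 1L)
      stop_cm("record with zero landmarks cannot be written")
    out <- c(out, sprintf("LM=%d", nrow(coords)),
             sprintf("%.6f %.6f", coords[, 1], coords[, 2]))
    if (!is.null(rec$image) && nzchar(rec$image))
      out <- c(out, paste0("IMAGE=", rec$image))
    if (!is.null(rec$id) && nzchar(rec$id))
      out <- c(out, paste0("ID=", rec$id))
    if (!is.null(rec$scale) && !is.na(rec$scale))
      out <- c(out, sprintf("SCALE=%g", rec$scale))
    if (!is.null(rec$extra)) out <- c(out, rec$extra)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a landmark dataset from long-format CSV
#'
#' Expected columns: `specimen_id`, `host_id`, `replicate`, `landmark`
#' (labels `L1..L8`), `x`, `y`. Row order is irrelevant; missing or
#' duplicated cells are rejected with a message naming the offending
#' (specimen, replicate, landmark) combinations.
#'
#' @param path CSV path.
#' @return A `landmark_dataset`.
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "host_id", "replicate", "landmark", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop_cm("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(df$landmark %in% LM_LABELS))
    stop_cm("landmark labels must be L1..L8")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop_cm("non-numeric coordinates in CSV")
  key <- paste(df$specimen_id, df$replicate, df$landmark, sep = "|")
  if (anyDuplicated(key))
    stop_cm("duplicate rows for: ",
            paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  specs <- sort(unique(df$specimen_id))
  reps <- sort(unique(df$replicate))
  full <- expand.grid(specimen_id = specs, replicate = reps,
                      landmark = LM_LABELS, stringsAsFactors = FALSE)
  full_key <- paste(full$specimen_id, full$replicate, full$landmark, sep = "|")
  absent <- setdiff(full_key, key)
  if (length(absent))
    stop_cm("missing cells: ", paste(utils::head(absent, 5L), collapse = "; "))
  n <- length(specs); r <- length(reps)
  coords <- array(NA_real_, c(n, r, 8L, 2L))
  si <- match(df$specimen_id, specs)
  ri <- match(df$replicate, reps)
  li <- match(df$landmark, LM_LABELS)
  coords[cbind(si, ri, li, 1L)] <- df$x
  coords[cbind(si, ri, li, 2L)] <- df$y
  host <- df$host_id[match(specs, df$specimen_id)]
  landmark_dataset(coords, host_id = host, specimen_id = specs)
}

#' Write a landmark dataset to long-format CSV
#'
#' @param dataset A `landmark_dataset`.
#' @param path Output path.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  d <- dim(dataset$coords)
  rows <- expand.grid(landmark = seq_len(d[3]), replicate = seq_len(d[2]),
                      specimen = seq_len(d[1]))
  df <- data.frame(
    specimen_id = dataset$specimen_id[rows$specimen],
    host_id = as.character(dataset$host_id)[rows$specimen],
    replicate = rows$replicate,
    landmark = LM_LABELS[rows$landmark],
    x = dataset$coords[cbind(rows$specimen, rows$replicate, rows$landmark, 1L)],
    y = dataset$coords[cbind(rows$specimen, rows$replicate, rows$landmark, 2L)]
  )
  df <- df[order(df$specimen_id, df$replicate, df$landmark), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a specimen set's ground truth to CSV
#'
#' Sidecar table with the latent quantities of a synthetic cohort: host,
#' true mode scores and true size factor per specimen.
#'
#' @param specimens A `specimen_set`.
#' @param path Output path.
#' @export
write_ground_truth <- function(specimens, path) {
  stopifnot(inherits(specimens, "specimen_set"))
  df <- data.frame(
    specimen_id = sprintf("spec%04d", seq_along(specimens$true_sizes)),
    host_id = as.integer(specimens$host_id),
    true_mode1 = specimens$true_mode_scores[, 1L],
    true_mode2 = specimens$true_mode_scores[, 2L],
    true_size = specimens$true_sizes
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
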