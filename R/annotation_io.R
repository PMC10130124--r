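#' Read per-frame hand-detection annotations from a JSON-lines file
#'
#' Parses and validates a JSON-lines interchange file in which each line is one
#' hand detection (or one hand-absent frame marker) from an egocentric
#' hand-object detector. Every record carries its own frame geometry so streams
#' with mixed resolutions remain well defined.
#'
#' Each line must be a JSON object with keys `participant_id` (string),
#' `video_id` (string), `frame_index` (integer >= 0), `frame_width` and
#' `frame_height` (integers >= 1) and `side` (`"left"`, `"right"` or `null`).
#' When `side` is non-null the keys `bbox_left`, `bbox_top`, `bbox_width`,
#' `bbox_height` (pixels, image coordinates with the origin at the top-left
#' corner and y increasing downward) and `contact_state` (one of `"portable"`,
#' `"stationary"`, `"no_contact"`, `"self_contact"`) are required. A `null`
#' side marks a frame containing no hands; such records are what make
#' hand-presence rates computable.
#'
#' Validation is record-level: a malformed or invariant-violating line is
#' rejected with a reason and a line number, and later duplicates of an
#' already-seen (participant, video, frame, side) key are rejected rather than
#' merged, since the upstream detector emits at most one box per side.
#'
#' @param path Path to a JSON-lines annotation file.
#' @param strict If `TRUE`, the first invalid line aborts the read with an
#'   error naming the line; if `FALSE` (default) invalid lines are dropped and
#'   reported through [ingest_summary()].
#' @return A tibble with one row per accepted record and columns
#'   `participant_id`, `video_id`, `frame_index`, `frame_width`,
#'   `frame_height`, `side` (`NA` for hand-absent frame markers), `bbox_left`,
#'   `bbox_top`, `bbox_width`, `bbox_height`, `contact_state`. The attributes
#'   `n_lines` and `rejections` (a tibble of `line`, `reason`) carry the
#'   ingest accounting; accepted rows + rejected rows always equal `n_lines`.
#' @seealso [write_annotations()], [ingest_summary()], [explode_hands()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' stream <- generate_annotations(synthetic_config(
#'   n_participants = 2, videos_per_participant = 1, frames_per_video = 20
#' ))
#' write_annotations(stream$annotations, f)
#' ann <- read_annotations(f)
#' ingest_summary(ann)
read_annotations <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  # tolerate a single trailing blank line; interior blanks are malformed
  if (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  n <- length(lines)
  if (n == 0) {
    out <- empty_annotations()
    attr(out, "n_lines") <- 0L
    attr(out, "rejections") <- tibble::tibble(line = integer(), reason = character())
    return(out)
  }

  parsed <- vector("list", n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) {
      reason[i] <- "malformed JSON"
    } else {
      parsed[[i]] <- rec
    }
  }

  get_chr <- function(rec, key) {
    v <- rec[[key]]
    if (is.null(v) || length(v) != 1 || is.na(v)) NA_character_ else as.character(v)
  }
  get_num <- function(rec, key) {
    v <- rec[[key]]
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || is.na(v)) NA_real_ else as.numeric(v)
  }

  df <- tibble::tibble(
    line = seq_len(n),
    participant_id = vapply(parsed, function(r) if (is.null(r)) NA_character_ else get_chr(r, "participant_id"), character(1)),
    video_id = vapply(parsed, function(r) if (is.null(r)) NA_character_ else get_chr(r, "video_id"), character(1)),
    frame_index_raw = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "frame_index"), numeric(1)),
    frame_width_raw = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "frame_width"), numeric(1)),
    frame_height_raw = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "frame_height"), numeric(1)),
    side = vapply(parsed, function(r) if (is.null(r)) NA_character_ else get_chr(r, "side"), character(1)),
    side_present = vapply(parsed, function(r) !is.null(r) && !is.null(r$side) && !identical(r["side"], list(side = NULL)), logical(1)),
    side_key_given = vapply(parsed, function(r) !is.null(r) && "side" %in% names(r), logical(1)),
    bbox_left = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "bbox_left"), numeric(1)),
    bbox_top = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "bbox_top"), numeric(1)),
    bbox_width = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "bbox_width"), numeric(1)),
    bbox_height = vapply(parsed, function(r) if (is.null(r)) NA_real_ else get_num(r, "bbox_height"), numeric(1)),
    contact_state = vapply(parsed, function(r) if (is.null(r)) NA_character_ else get_chr(r, "contact_state"), character(1)),
    reason = reason
  )

  need <- function(cond, why) {
    hit <- is.na(df$reason) & !cond
    df$reason[hit] <<- why
    invisible(NULL)
  }

  need(!is.na(df$participant_id), "missing participant_id")
  need(!is.na(df$video_id), "missing video_id")
  need(is.finite(df$frame_index_raw) & df$frame_index_raw >= 0 &
         df$frame_index_raw == floor(df$frame_index_raw), "invalid frame_index")
  need(is.finite(df$frame_width_raw) & df$frame_width_raw >= 1 &
         df$frame_width_raw == floor(df$frame_width_raw), "invalid frame_width")
  need(is.finite(df$frame_height_raw) & df$frame_height_raw >= 1 &
         df$frame_height_raw == floor(df$frame_height_raw), "invalid frame_height")
  need(df$side_key_given, "missing side")
  need(is.na(df$side) | df$side %in% SIDE_LEVELS, "invalid side")

  has_hand <- !is.na(df$side) & is.na(df$reason)
  bbox_ok <- is.finite(df$bbox_left) & is.finite(df$bbox_top) &
    is.finite(df$bbox_width) & is.finite(df$bbox_height)
  need(!has_hand | bbox_ok, "missing or non-numeric bbox")
  has_hand <- !is.na(df$side) & is.na(df$reason)
  need(!has_hand | (df$bbox_width > 0 & df$bbox_height > 0), "non-positive bbox size")
  need(!has_hand | (df$bbox_left >= 0 & df$bbox_top >= 0), "negative bbox origin")
  has_hand <- !is.na(df$side) & is.na(df$reason)
  cx <- df$bbox_left + df$bbox_width / 2
  cy <- df$bbox_top + df$bbox_height / 2
  need(!has_hand | (cx >= 0 & cx <= df$frame_width_raw &
                      cy >= 0 & cy <= df$frame_height_raw), "bbox centre outside frame")
  has_hand <- !is.na(df$side) & is.na(df$reason)
  need(!has_hand | df$contact_state %in% CONTACT_LEVELS, "invalid contact_state")

  # Later duplicates of a (participant, video, frame, side) key are rejected;
  # a hand-absent marker and a detection for the same frame contradict each
  # other, so whichever comes later is rejected too.
  ok <- is.na(df$reason)
  key <- paste(df$participant_id, df$video_id, df$frame_index_raw,
               ifelse(is.na(df$side), "<none>", df$side), sep = "\r")
  dup <- ok & duplicated(ifelse(ok, key, paste0("bad\r", df$line)))
  df$reason[dup] <- "duplicate detection for (participant, video, frame, side)"

  ok <- is.na(df$reason)
  fkey <- paste(df$participant_id, df$video_id, df$frame_index_raw, sep = "\r")
  first_line_of <- function(sel) {
    res <- tapply(df$line[sel], fkey[sel], min)
    unname(res[match(fkey, names(res))])
  }
  first_det <- first_line_of(ok & !is.na(df$side))
  first_empty <- first_line_of(ok & is.na(df$side))
  conflict_empty <- ok & is.na(df$side) & !is.na(first_det) & df$line > first_det
  conflict_det <- ok & !is.na(df$side) & !is.na(first_empty) & df$line > first_empty
  df$reason[conflict_empty] <- "hand-absent marker conflicts with earlier detection"
  df$reason[conflict_det] <- "detection conflicts with earlier hand-absent marker"

  rejections <- tibble::tibble(
    line = df$line[!is.na(df$reason)],
    reason = df$reason[!is.na(df$reason)]
  )
  if (strict && nrow(rejections) > 0) {
    abort(paste0("invalid annotation at line ", rejections$line[1], ": ",
                 rejections$reason[1], " (strict mode)"))
  }

  keep <- is.na(df$reason)
  out <- tibble::tibble(
    participant_id = df$participant_id[keep],
    video_id = df$video_id[keep],
    frame_index = as.integer(df$frame_index_raw[keep]),
    frame_width = as.integer(df$frame_width_raw[keep]),
    frame_height = as.integer(df$frame_height_raw[keep]),
    side = df$side[keep],
    bbox_left = ifelse(is.na(df$side[keep]), NA_real_, df$bbox_left[keep]),
    bbox_top = ifelse(is.na(df$side[keep]), NA_real_, df$bbox_top[keep]),
    bbox_width = ifelse(is.na(df$side[keep]), NA_real_, df$bbox_width[keep]),
    bbox_height = ifelse(is.na(df$side[keep]), NA_real_, df$bbox_height[keep]),
    contact_state = ifelse(is.na(df$side[keep]), NA_character_, df$contact_state[keep])
  )
  attr(out, "n_lines") <- n
  attr(out, "rejections") <- rejections
  out
}

empty_annotations <- function() {
  tibble::tibble(
    participant_id = character(), video_id = character(),
    frame_index = integer(), frame_width = integer(), frame_height = integer(),
    side = character(), bbox_left = double(), bbox_top = double(),
    bbox_width = double(), bbox_height = double(), contact_state = character()
  )
}

#' Summarise the accounting of an annotation read
#'
#' @param annotations A tibble returned by [read_annotations()].
#' @return A one-row tibble with `accepted`, `rejected` and `total` line
#'   counts, plus a `rejections` list-column holding the per-line reasons.
#' @export
ingest_summary <- function(annotations) {
  rej <- attr(annotations, "rejections")
  if (is.null(rej)) rej <- tibble::tibble(line = integer(), reason = character())
  total <- attr(annotations, "n_lines")
  if (is.null(total)) total <- nrow(annotations) + nrow(rej)
  tibble::tibble(
    accepted = nrow(annotations),
    rejected = nrow(rej),
    total = as.integer(total),
    rejections = list(rej)
  )
}

#' Write annotations to a JSON-lines interchange file
#'
#' Serialises an annotation tibble so that [read_annotations()] reproduces it
#' record for record: numeric bounding-box coordinates are written at full
#' double precision and hand-absent frame markers come out as objects with
#' `side` null and no bbox keys.
#'
#' @param annotations Annotation tibble (see [read_annotations()] for the
#'   column contract).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  check_annotation_columns(annotations)
  con <- tryCatch(suppressWarnings(file(path, open = "wb")), error = function(e) {
    abort(paste0("cannot open '", path, "' for writing: ", conditionMessage(e)))
  })
  on.exit(close(con))
  if (nrow(annotations) == 0) return(invisible(path))
  rows <- vapply(seq_len(nrow(annotations)), function(i) {
    r <- annotations[i, ]
    rec <- list(
      participant_id = r$participant_id,
      video_id = r$video_id,
      frame_index = as.integer(r$frame_index),
      frame_width = as.integer(r$frame_width),
      frame_height = as.integer(r$frame_height)
    )
    if (is.na(r$side)) {
      rec$side <- NULL
      line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17))
      # side must be explicitly null for hand-absent markers
      line <- sub("\\}$", ",\"side\":null}", line)
      return(line)
    }
    rec$side <- r$side
    rec$bbox_left <- r$bbox_left
    rec$bbox_top <- r$bbox_top
    rec$bbox_width <- r$bbox_width
    rec$bbox_height <- r$bbox_height
    rec$contact_state <- r$contact_state
    # I(17) significant digits: doubles survive the round trip bit-exactly
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17)))
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

check_annotation_columns <- function(annotations, need_bbox = TRUE) {
  cols <- c("participant_id", "video_id", "frame_index", "frame_width",
            "frame_height", "side")
  if (need_bbox) {
    cols <- c(cols, "bbox_left", "bbox_top", "bbox_width", "bbox_height",
              "contact_state")
  }
  missing <- setdiff(cols, names(annotations))
  if (length(missing) > 0) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(annotations)
}
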