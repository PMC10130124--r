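# Builders for tiny in-memory annotation fixtures; everything is generated
# in code, no stored data.

ann_row <- function(participant = "P01", video = "P01_V01", frame = 0L,
                    side = "left", left = 100, top = 40, width = 56,
                    height = 20, contact = "portable", fw = 456L, fh = 256L) {
  if (is.na(side)) {
    return(tibble::tibble(
      participant_id = participant, video_id = video, frame_index = frame,
      frame_width = fw, frame_height = fh, side = NA_character_,
      bbox_left = NA_real_, bbox_top = NA_real_, bbox_width = NA_real_,
      bbox_height = NA_real_, contact_state = NA_character_
    ))
  }
  tibble::tibble(
    participant_id = participant, video_id = video, frame_index = frame,
    frame_width = fw, frame_height = fh, side = side,
    bbox_left = left, bbox_top = top, bbox_width = width,
    bbox_height = height, contact_state = contact
  )
}

jsonl_line <- function(...) {
  jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA, null = "null")
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".jsonl")
  writeLines(unlist(lines), f)
  f
}

# Records built straight from Cartesian centres (bypassing bbox plumbing)
# for occupancy/stats unit tests.
make_records <- function(participant, side, x, y, contact = "portable",
                         fw = 456, fh = 256) {
  cls <- classify_location(x, y, fw, fh, side = side)
  tibble::tibble(
    participant_id = participant,
    video_id = paste0(participant, "_V01"),
    frame_index = seq_along(x) - 1L,
    side = side, contact_state = contact,
    frame_width = fw, frame_height = fh,
    x = x, y = y,
    vertical = cls$vertical, horizontal = cls$horizontal,
    quadrant = cls$quadrant, laterality = cls$laterality
  )
}

# Mirror an annotation stream about the vertical midline of the frame
# (boxes reflected, sides preserved).
mirror_annotations <- function(ann) {
  det <- !is.na(ann$side)
  ann$bbox_left[det] <- ann$frame_width[det] -
    (ann$bbox_left[det] + ann$bbox_width[det])
  ann
}
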