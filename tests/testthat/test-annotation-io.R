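test_that("valid JSONL lines parse into detections and frame markers", {
  lines <- list(
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 0,
               frame_width = 456, frame_height = 256, side = "left",
               bbox_left = 10, bbox_top = 20, bbox_width = 50, bbox_height = 40,
               contact_state = "portable"),
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 0,
               frame_width = 456, frame_height = 256, side = "right",
               bbox_left = 300, bbox_top = 100, bbox_width = 60, bbox_height = 50,
               contact_state = "no_contact"),
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 1,
               frame_width = 456, frame_height = 256, side = "right",
               bbox_left = 200, bbox_top = 150, bbox_width = 40, bbox_height = 30,
               contact_state = "stationary"),
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 2,
               frame_width = 456, frame_height = 256, side = NULL)
  )
  ann <- read_annotations(write_lines_tmp(lines))
  expect_equal(nrow(ann), 4)
  expect_equal(sum(!is.na(ann$side)), 3)       # 3 detections
  fkey <- paste(ann$participant_id, ann$video_id, ann$frame_index)
  expect_equal(length(unique(fkey)), 3)        # 3 distinct frames
  s <- ingest_summary(ann)
  expect_equal(s$accepted, 4)
  expect_equal(s$rejected, 0)
})

test_that("invalid records are rejected line-by-line with reasons", {
  lines <- list(
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 0,
               frame_width = 456, frame_height = 256, side = "both",
               bbox_left = 10, bbox_top = 20, bbox_width = 50, bbox_height = 40,
               contact_state = "portable"),
    "not json at all {{{",
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 1,
               frame_width = 456, frame_height = 256, side = "left",
               bbox_left = 10, bbox_top = 20, bbox_width = 50, bbox_height = 40,
               contact_state = "gripping"),
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 2,
               frame_width = 456, frame_height = 256, side = "left",
               bbox_left = 10, bbox_top = 20, bbox_width = 0, bbox_height = 40,
               contact_state = "portable"),
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 3,
               frame_width = 456, frame_height = 256, side = "left",
               bbox_left = 440, bbox_top = 20, bbox_width = 60, bbox_height = 40,
               contact_state = "portable"),
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 4,
               frame_width = 456, frame_height = 256, side = "right",
               bbox_left = 100, bbox_top = 100, bbox_width = 40, bbox_height = 40,
               contact_state = "self_contact")
  )
  ann <- read_annotations(write_lines_tmp(lines))
  rej <- attr(ann, "rejections")
  expect_equal(nrow(ann), 1)
  expect_equal(nrow(rej), 5)
  expect_equal(rej$reason[rej$line == 1], "invalid side")
  expect_equal(rej$reason[rej$line == 2], "malformed JSON")
  expect_equal(rej$reason[rej$line == 3], "invalid contact_state")
  expect_equal(rej$reason[rej$line == 4], "non-positive bbox size")
  expect_equal(rej$reason[rej$line == 5], "bbox centre outside frame")
})

test_that("rejection accounting always balances: accepted + rejected = lines", {
  lines <- list(
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 0,
               frame_width = 456, frame_height = 256, side = "left",
               bbox_left = 1, bbox_top = 1, bbox_width = 5, bbox_height = 5,
               contact_state = "portable"),
    "garbage",
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 0,
               frame_width = 456, frame_height = 256, side = "left",
               bbox_left = 9, bbox_top = 9, bbox_width = 5, bbox_height = 5,
               contact_state = "portable")
  )
  ann <- read_annotations(write_lines_tmp(lines))
  s <- ingest_summary(ann)
  expect_equal(s$accepted + s$rejected, s$total)
  expect_equal(s$total, 3L)
})

test_that("duplicate and conflicting records are rejected, keeping the earlier", {
  det <- function(frame, side, left = 10) {
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = frame,
               frame_width = 456, frame_height = 256, side = side,
               bbox_left = left, bbox_top = 20, bbox_width = 50,
               bbox_height = 40, contact_state = "portable")
  }
  empty <- function(frame) {
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = frame,
               frame_width = 456, frame_height = 256, side = NULL)
  }
  ann <- read_annotations(write_lines_tmp(list(
    det(0, "left", left = 10),   # kept
    det(0, "left", left = 99),   # duplicate -> rejected
    det(1, "left"), empty(1),    # marker conflicts with detection
    empty(2), det(2, "right")    # detection conflicts with marker
  )))
  rej <- attr(ann, "rejections")
  expect_equal(sort(rej$line), c(2L, 4L, 6L))
  expect_equal(ann$bbox_left[ann$frame_index == 0], 10)  # earlier record kept
  expect_true(grepl("duplicate", rej$reason[rej$line == 2]))
})

test_that("strict mode aborts on the first invalid line, naming it", {
  lines <- list(
    jsonl_line(participant_id = "P01", video_id = "V01", frame_index = 0,
               frame_width = 456, frame_height = 256, side = NULL),
    "broken"
  )
  expect_error(read_annotations(write_lines_tmp(lines), strict = TRUE),
               "line 2")
})

test_that("empty file reads as empty collection with zero rejections", {
  f <- tempfile(fileext = ".jsonl")
  file.create(f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 0)
  expect_equal(ingest_summary(ann)$rejected, 0)
})

test_that("write/read round-trip reproduces a synthetic stream exactly", {
  cfg <- synthetic_config(n_participants = 2, videos_per_participant = 1,
                          frames_per_video = 50, seed = 11)
  ann <- generate_annotations(cfg)$annotations
  f <- tempfile(fileext = ".jsonl")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(ingest_summary(back)$rejected, 0)
  attr(back, "n_lines") <- NULL
  attr(back, "rejections") <- NULL
  expect_identical(as.data.frame(back), as.data.frame(ann))
})

test_that("round-trip preserves fractional bbox coordinates at full precision", {
  ann <- ann_row(left = 123.4567891234, top = 0.000123456789,
                 width = 56.789012345678, height = 20.111111111111)
  f <- tempfile(fileext = ".jsonl")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_identical(back$bbox_left, ann$bbox_left)
  expect_identical(back$bbox_top, ann$bbox_top)
  expect_identical(back$bbox_width, ann$bbox_width)
  expect_identical(back$bbox_height, ann$bbox_height)
})

test_that("an empty collection writes a valid empty file", {
  ann <- ann_row()[0, ]
  f <- tempfile(fileext = ".jsonl")
  write_annotations(ann, f)
  expect_true(file.exists(f))
  expect_equal(nrow(read_annotations(f)), 0)
})

test_that("unwritable output path raises an I/O error", {
  ann <- ann_row()
  expect_error(write_annotations(ann, file.path(tempdir(), "no/such/dir/x.jsonl")),
               "cannot open")
})
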