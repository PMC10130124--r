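test_that("explode_hands yields one record per detection", {
  ann <- dplyr::bind_rows(
    ann_row(frame = 0L, side = "left"),
    ann_row(frame = 0L, side = "right", left = 300),
    ann_row(frame = 1L, side = "right", left = 250),
    ann_row(frame = 2L, side = NA)
  )
  rec <- explode_hands(ann)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$side == "left") + sum(rec$side == "right"), nrow(rec))
  expect_true(all(c("x", "y", "quadrant", "laterality") %in% names(rec)))

  empty <- explode_hands(ann_row(side = NA))
  expect_equal(nrow(empty), 0)
})

test_that("left + right record counts sum to the analysis total on any stream", {
  cfg <- synthetic_config(n_participants = 3, videos_per_participant = 1,
                          frames_per_video = 300, seed = 5)
  ann <- generate_annotations(cfg)$annotations
  rec <- explode_hands(ann)
  expect_equal(sum(rec$side == "left") + sum(rec$side == "right"), nrow(rec))
  expect_equal(nrow(rec), sum(!is.na(ann$side)))
})

test_that("hand presence rate counts frames, not detections", {
  ann <- dplyr::bind_rows(
    ann_row(frame = 0L, side = "left"),
    ann_row(frame = 0L, side = "right", left = 300),  # same frame, bimanual
    ann_row(frame = 1L, side = NA),
    ann_row(frame = 2L, side = NA),
    ann_row(frame = 3L, side = "right", left = 200)
  )
  expect_equal(hand_presence_rate(ann), 50)  # 2 of 4 frames

  all_absent <- dplyr::bind_rows(ann_row(frame = 0L, side = NA),
                                 ann_row(frame = 1L, side = NA))
  expect_equal(hand_presence_rate(all_absent), 0)
  expect_equal(hand_presence_rate(ann_row(frame = 0L, side = "left")), 100)
  expect_error(hand_presence_rate(ann_row()[0, ]), "zero frames")
  expect_error(presence_rate_from_counts(5, 0), "zero frames")
  expect_error(presence_rate_from_counts(7, 5), "n_present")
})

test_that("occupancy proportions follow the zone counts", {
  rec <- make_records("P01", "left",
                      x = c(100, 120, 140, 90),
                      y = c(50, 60, 70, 200))  # 3 lower, 1 upper
  occ <- occupancy(rec, "vertical")
  expect_equal(occ$pooled$pct[occ$pooled$zone == "lower"], 75)
  expect_equal(occ$pooled$pct[occ$pooled$zone == "upper"], 25)
  expect_equal(sum(occ$pooled$n), 4)
  expect_equal(tidy(occ)$pct[tidy(occ)$zone == "lower"], 75)
})

test_that("per-participant percentages sum to 100 and pool consistently", {
  set.seed(77)
  rec <- dplyr::bind_rows(lapply(1:5, function(i) {
    n <- sample(20:60, 1)
    make_records(sprintf("P%02d", i), sample(c("left", "right"), n, TRUE),
                 x = runif(n, 0, 456), y = runif(n, 0, 256),
                 contact = sample(c("portable", "stationary", "no_contact",
                                    "self_contact"), n, TRUE))
  }))
  occ <- occupancy(rec, "quadrant")
  sums <- tidy(occ) |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(s = sum(pct))
  expect_equal(sums$s, rep(100, 5), tolerance = 1e-9)

  # pooled percentage = record-count-weighted mean of participant percentages
  weighted <- tidy(occ) |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(w = sum(n)) |>
    dplyr::group_by(zone) |>
    dplyr::summarise(pct = sum(pct * w) / sum(w))
  expect_equal(occ$pooled$pct, weighted$pct, tolerance = 1e-9)

  # participant-average pooling instead takes the unweighted mean
  occ_p <- occupancy(rec, "quadrant", pooling = "participants")
  unweighted <- tidy(occ) |>
    dplyr::group_by(zone) |>
    dplyr::summarise(pct = mean(pct))
  expect_equal(occ_p$pooled$pct, unweighted$pct, tolerance = 1e-9)
})

test_that("stratifiers nest: either = left + right, contact states partition all", {
  set.seed(88)
  n <- 400
  rec <- make_records("P01", sample(c("left", "right"), n, TRUE),
                      x = runif(n, 0, 456), y = runif(n, 0, 256),
                      contact = sample(c("portable", "stationary", "no_contact",
                                         "self_contact"), n, TRUE,
                                       prob = c(.6, .2, .15, .05)))
  for (part in c("vertical", "horizontal", "quadrant", "laterality")) {
    all_tab <- occupancy(rec, part)$pooled
    left_tab <- occupancy(rec, part, hand = "left")$pooled
    right_tab <- occupancy(rec, part, hand = "right")$pooled
    expect_equal(all_tab$n, left_tab$n + right_tab$n)

    by_contact <- sapply(c("portable", "stationary", "no_contact",
                           "self_contact"), function(cs) {
      suppressWarnings(occupancy(rec, part, contact = cs))$pooled$n
    })
    expect_equal(all_tab$n, unname(rowSums(by_contact)))
    expect_equal(sum(all_tab$n), n)  # conservation across partitions
  }
})

test_that("laterality occupancy mirrors and pools as expected", {
  # all left-hand records in the left hemiscene: fully ipsilateral
  rec <- make_records("P01", "left", x = runif(20, 0, 200), y = runif(20, 0, 256))
  occ <- laterality_occupancy(rec)
  expect_equal(occ$pooled$pct[occ$pooled$zone == "ipsilateral"], 100)

  # two participants at 9 ipsi / 1 contra each pool to 90%
  rec2 <- dplyr::bind_rows(
    make_records("P01", "left", x = c(rep(100, 9), 300), y = runif(10, 0, 256)),
    make_records("P02", "right", x = c(rep(300, 9), 100), y = runif(10, 0, 256))
  )
  occ2 <- laterality_occupancy(rec2)
  expect_equal(occ2$pooled$pct[occ2$pooled$zone == "ipsilateral"], 90)

  # mirror-swap of x coordinates swaps ipsi/contra percentages exactly
  set.seed(99)
  n <- 200
  rec3 <- make_records("P01", sample(c("left", "right"), n, TRUE),
                       x = runif(n, 0, 456), y = runif(n, 0, 256))
  mirrored <- rec3
  mirrored$x <- 456 - rec3$x
  cls <- classify_location(mirrored$x, mirrored$y, 456, 256, side = mirrored$side)
  mirrored[, c("vertical", "horizontal", "quadrant", "laterality")] <- cls
  a <- laterality_occupancy(rec3)$pooled
  b <- laterality_occupancy(mirrored)$pooled
  expect_equal(a$pct[a$zone == "ipsilateral"], b$pct[b$zone == "contralateral"])
  expect_equal(a$n[a$zone == "contralateral"], b$n[b$zone == "ipsilateral"])
})

test_that("participants without in-scope records are omitted and flagged", {
  rec <- dplyr::bind_rows(
    make_records("P01", "left", x = runif(10, 0, 456), y = runif(10, 0, 256)),
    make_records("P02", "right", x = runif(10, 0, 456), y = runif(10, 0, 256))
  )
  occ <- occupancy(rec, "vertical", hand = "left")
  expect_equal(occ$participants_omitted, "P02")
  expect_false("P02" %in% tidy(occ)$participant_id)
  expect_warning(occupancy(rec[0, ], "vertical"), "empty")
})

test_that("density grid conserves counts and matches 1D marginals", {
  rec <- make_records("P01", "left", x = rep(10, 10), y = rep(10, 10))
  g <- density_grid(rec, nx = 4, ny = 4)
  expect_equal(sum(g$counts), 10)
  expect_equal(g$counts[1, 1], 10)        # all mass in the bottom-left bin
  expect_equal(sum(g$counts != 0), 1)

  set.seed(303)
  n <- 2000
  rec2 <- make_records("P01", "left", x = runif(n, 0, 456), y = runif(n, 0, 256))
  g2 <- density_grid(rec2, nx = 8, ny = 5)
  expect_equal(sum(g2$counts), n)
  m <- grid_marginals(g2)
  expect_equal(as.numeric(m$x),
               as.numeric(table(cut(rec2$x, g2$xbreaks, include.lowest = TRUE))))
  expect_equal(as.numeric(m$y),
               as.numeric(table(cut(rec2$y, g2$ybreaks, include.lowest = TRUE))))
  expect_equal(tidy(g2) |> dplyr::pull(count) |> sum(), n)

  expect_error(density_grid(rec2, nx = 0, ny = 4), "degenerate")
  mixed <- dplyr::bind_rows(rec2, make_records("P02", "left", x = 1, y = 1,
                                               fw = 100, fh = 100))
  expect_error(density_grid(mixed), "single frame geometry")
})

test_that("uniform points spread over the grid within multinomial error", {
  set.seed(404)
  n <- 16000
  rec <- make_records("P01", "left", x = runif(n, 0, 456), y = runif(n, 0, 256))
  g <- density_grid(rec, nx = 4, ny = 4)
  p <- 1 / 16
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(g$counts - n * p) <= 3 * se))
})
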