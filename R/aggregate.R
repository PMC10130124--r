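#' Expand frame annotations into per-hand records with spatial classes
#'
#' A frame containing both hands contributes one record per hand, so a
#' bimanual frame is counted once for the left hand and once for the right —
#' mirroring the bookkeeping in which left-hand and right-hand frame totals
#' sum to the analysis total. Hand-absent frame markers contribute no records
#' (but still count toward [hand_presence_rate()]). Each record carries the
#' box-centre location in Cartesian screen coordinates and its hemiscene,
#' quadrant and laterality classification.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param tie Midline tie-break rule, see [classify_location()].
#' @return A tibble with one row per hand detection: `participant_id`,
#'   `video_id`, `frame_index`, `side`, `contact_state`, `frame_width`,
#'   `frame_height`, `x`, `y` (Cartesian pixels), `vertical`, `horizontal`,
#'   `quadrant`, `laterality`.
#' @export
explode_hands <- function(annotations, tie = c("lower_left", "upper_right")) {
  tie <- match.arg(tie)
  check_annotation_columns(annotations)
  det <- annotations[!is.na(annotations$side), , drop = FALSE]
  if (nrow(det) == 0) {
    return(tibble::tibble(
      participant_id = character(), video_id = character(),
      frame_index = integer(), side = character(), contact_state = character(),
      frame_width = integer(), frame_height = integer(),
      x = double(), y = double(), vertical = character(),
      horizontal = character(), quadrant = character(), laterality = character()
    ))
  }
  ctr <- bbox_centre(det$bbox_left, det$bbox_top, det$bbox_width, det$bbox_height)
  x <- ctr$cx
  y <- to_cartesian(ctr$cy_image, det$frame_height)
  cls <- classify_location(x, y, det$frame_width, det$frame_height,
                           side = det$side, tie = tie)
  tibble::tibble(
    participant_id = det$participant_id,
    video_id = det$video_id,
    frame_index = det$frame_index,
    side = det$side,
    contact_state = det$contact_state,
    frame_width = det$frame_width,
    frame_height = det$frame_height,
    x = x, y = y,
    vertical = cls$vertical,
    horizontal = cls$horizontal,
    quadrant = cls$quadrant,
    laterality = cls$laterality
  )
}

#' Percentage of frames containing at least one hand
#'
#' Requires the annotation stream to include hand-absent frame markers (rows
#' with `side` `NA`); otherwise frames without hands are invisible and the
#' rate would be trivially 100.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return Percentage in `[0, 100]`.
#' @export
hand_presence_rate <- function(annotations) {
  check_annotation_columns(annotations, need_bbox = FALSE)
  fkey <- paste(annotations$participant_id, annotations$video_id,
                annotations$frame_index, sep = "\r")
  total <- length(unique(fkey))
  present <- length(unique(fkey[!is.na(annotations$side)]))
  presence_rate_from_counts(present, total)
}

#' Presence rate from raw frame counts
#'
#' @param n_present Number of frames containing at least one hand.
#' @param n_total Total number of frames.
#' @return `100 * n_present / n_total`.
#' @export
#' @examples
#' presence_rate_from_counts(15761306, 20076005)  # 78.51 (2 d.p.)
presence_rate_from_counts <- function(n_present, n_total) {
  if (n_total == 0) abort("undefined rate: zero frames")
  if (n_present < 0 || n_present > n_total) {
    abort("n_present must lie in [0, n_total]")
  }
  100 * n_present / n_total
}

#' Frame-occupancy table over a spatial partition
#'
#' Tabulates how often hand centres fall in each zone of a spatial partition
#' of the visual scene — vertical hemiscenes (upper/lower), horizontal
#' hemiscenes (left/right), quadrants (UL/LL/UR/LR) or laterality
#' (ipsilateral/contralateral) — optionally restricted to one hand side and/or
#' one hand-object contact state. Two aggregation levels are produced: a
#' per-participant table (each participant's zone percentages over their own
#' in-scope records, the input to within-subject inference) and a pooled
#' table. By default the pooled percentages are frame-weighted over all
#' records; `pooling = "participants"` instead averages the participant
#' percentages with equal weight.
#'
#' @param records Hand-record tibble from [explode_hands()].
#' @param partition `"vertical"`, `"horizontal"`, `"quadrant"` or
#'   `"laterality"`.
#' @param hand `"either"` (default), `"left"` or `"right"`.
#' @param contact `"all"` (default) or one of `"portable"`, `"stationary"`,
#'   `"no_contact"`, `"self_contact"`.
#' @param pooling `"frames"` (default) or `"participants"`.
#' @return An object of class `occupancy_table`: a list with tibbles `pooled`
#'   (`zone`, `n`, `pct`) and `by_participant` (`participant_id`, `zone`, `n`,
#'   `pct`), plus the stratifier metadata, the in-scope record count and the
#'   ids of participants present in `records` but with no in-scope record.
#'   `tidy()` returns the per-participant table; `print()` shows the pooled
#'   percentages to one decimal place.
#' @export
occupancy <- function(records, partition = c("vertical", "horizontal",
                                             "quadrant", "laterality"),
                      hand = c("either", "left", "right"),
                      contact = c("all", CONTACT_LEVELS),
                      pooling = c("frames", "participants")) {
  partition <- match.arg(partition)
  hand <- match.arg(hand)
  contact <- match.arg(contact)
  pooling <- match.arg(pooling)
  zones <- partition_zones(partition)

  all_participants <- unique(records$participant_id)
  scope <- records
  if (hand != "either") scope <- scope[scope$side == hand, , drop = FALSE]
  if (contact != "all") scope <- scope[scope$contact_state == contact, , drop = FALSE]

  if (nrow(scope) == 0) {
    warn("no in-scope records; occupancy table is empty")
    empty <- tibble::tibble(zone = factor(zones, levels = zones),
                            n = integer(length(zones)),
                            pct = rep(NA_real_, length(zones)))
    res <- list(
      pooled = empty,
      by_participant = tibble::tibble(participant_id = character(),
                                      zone = factor(levels = zones),
                                      n = integer(), pct = double()),
      partition = partition, hand = hand, contact = contact,
      pooling = pooling, n_records = 0L,
      participants_omitted = all_participants
    )
    class(res) <- "occupancy_table"
    return(res)
  }

  zone <- factor(scope[[partition]], levels = zones)
  by_participant <- tibble::tibble(participant_id = scope$participant_id,
                                   zone = zone) |>
    dplyr::count(.data$participant_id, .data$zone, .drop = FALSE) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  counts <- by_participant |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  if (pooling == "frames") {
    pooled <- counts |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
  } else {
    pooled <- by_participant |>
      dplyr::group_by(.data$zone) |>
      dplyr::summarise(pct = mean(.data$pct), .groups = "drop") |>
      dplyr::left_join(counts, by = "zone") |>
      dplyr::select("zone", "n", "pct")
  }

  res <- list(
    pooled = pooled,
    by_participant = by_participant,
    partition = partition, hand = hand, contact = contact,
    pooling = pooling, n_records = nrow(scope),
    participants_omitted = setdiff(all_participants,
                                   unique(scope$participant_id))
  )
  class(res) <- "occupancy_table"
  res
}

#' Occupancy over ipsilateral/contralateral zones
#'
#' Convenience wrapper around [occupancy()] with `partition = "laterality"`:
#' a hand in the horizontal hemiscene matching its own side is ipsilateral.
#'
#' @inheritParams occupancy
#' @return An `occupancy_table`, see [occupancy()].
#' @export
laterality_occupancy <- function(records, hand = c("either", "left", "right"),
                                 contact = c("all", CONTACT_LEVELS),
                                 pooling = c("frames", "participants")) {
  occupancy(records, partition = "laterality", hand = match.arg(hand),
            contact = match.arg(contact), pooling = match.arg(pooling))
}

#' @exportS3Method generics::tidy
tidy.occupancy_table <- function(x, ...) x$by_participant

#' @exportS3Method generics::glance
glance.occupancy_table <- function(x, ...) {
  tibble::tibble(partition = x$partition, hand = x$hand, contact = x$contact,
                 pooling = x$pooling, n_records = x$n_records,
                 n_participants = length(unique(x$by_participant$participant_id)))
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("Occupancy over %s zones (hand: %s, contact: %s, pooling: %s)\n",
              x$partition, x$hand, x$contact, x$pooling))
  cat(sprintf("  %d in-scope records\n", x$n_records))
  tab <- x$pooled
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %12d  %6.1f%%\n", as.character(tab$zone[i]),
                tab$n[i], tab$pct[i]))
  }
  if (length(x$participants_omitted) > 0) {
    cat("  participants with no in-scope records: ",
        paste(x$participants_omitted, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Rectangular 2D density grid of hand-centre locations
#'
#' Bins Cartesian hand centres into an `nx` by `ny` rectangular grid spanning
#' the frame. Bin counts conserve the number of binned points exactly, and the
#' grid's row/column marginal sums equal the corresponding 1D histograms. All
#' records must share one frame geometry.
#'
#' @param records Hand-record tibble from [explode_hands()].
#' @param nx,ny Number of grid bins along x and y (each >= 1).
#' @return An object of class `density_grid`: list with `counts` (`ny` x `nx`
#'   matrix, rows from the bottom of the frame up), `xbreaks`, `ybreaks`, `n`,
#'   and the frame geometry. `tidy()` gives one row per bin with bin-centre
#'   coordinates.
#' @export
density_grid <- function(records, nx = 24, ny = 16) {
  if (nx < 1 || ny < 1) abort("degenerate grid: nx and ny must be >= 1")
  w <- unique(records$frame_width)
  h <- unique(records$frame_height)
  if (length(w) > 1 || length(h) > 1) {
    abort("density_grid requires records with a single frame geometry")
  }
  if (nrow(records) == 0) abort("no records to bin")
  xbreaks <- seq(0, w, length.out = nx + 1)
  ybreaks <- seq(0, h, length.out = ny + 1)
  xi <- pmin(pmax(findInterval(records$x, xbreaks, rightmost.closed = TRUE), 1L), nx)
  yi <- pmin(pmax(findInterval(records$y, ybreaks, rightmost.closed = TRUE), 1L), ny)
  counts <- matrix(0L, nrow = ny, ncol = nx)
  tab <- table(factor(yi, levels = seq_len(ny)), factor(xi, levels = seq_len(nx)))
  counts[] <- as.integer(tab)
  res <- list(counts = counts, xbreaks = xbreaks, ybreaks = ybreaks,
              n = nrow(records), frame_width = w, frame_height = h)
  class(res) <- "density_grid"
  res
}

#' @exportS3Method generics::tidy
tidy.density_grid <- function(x, ...) {
  xmid <- (x$xbreaks[-1] + x$xbreaks[-length(x$xbreaks)]) / 2
  ymid <- (x$ybreaks[-1] + x$ybreaks[-length(x$ybreaks)]) / 2
  tidyr::expand_grid(y_mid = ymid, x_mid = xmid) |>
    dplyr::mutate(count = as.vector(t(x$counts))) |>
    dplyr::select("x_mid", "y_mid", "count")
}

#' Marginal histograms of a density grid
#'
#' @param grid A `density_grid`.
#' @return List with `x` (column sums, left to right) and `y` (row sums,
#'   bottom to top); each sums to `grid$n`.
#' @export
grid_marginals <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  list(x = colSums(grid$counts), y = rowSums(grid$counts))
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid %d x %d over a %d x %d frame; %d points\n",
              ncol(x$counts), nrow(x$counts), x$frame_width, x$frame_height, x$n))
  invisible(x)
}
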