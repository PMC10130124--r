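with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full hand-location mapping pipeline
#'
#' Orchestrates every analysis stage over one annotation stream: ingest and
#' validation, hand-presence rate, per-hand expansion and spatial
#' classification, pooled and per-participant occupancy tables over every
#' partition and contact-state stratum, density grids and hex maps, the
#' paired-comparison battery, and (when handedness observations are supplied)
#' handedness scoring with handedness-stratified occupancy tables. All tables
#' are written as CSV, figures as PNG, and a machine-readable JSON manifest
#' records the configuration, the counts, and an MD5 digest of every output
#' file. Running the pipeline twice on identical inputs produces
#' byte-identical tables and manifest.
#'
#' @param annotations A JSON-lines annotation file path or an annotation
#'   tibble (see [read_annotations()]).
#' @param out_dir Output directory; created if missing.
#' @param handedness Optional handedness observation CSV path or tibble
#'   (`participant_id`, `activity`, `hand_used`). When absent,
#'   handedness-stratified tables are skipped with a warning.
#' @param strict Abort on the first invalid annotation line (file input only).
#' @param tie Midline tie-break rule, see [classify_location()].
#' @param pooling Pooled-table aggregation, see [occupancy()].
#' @param grid_nx,grid_ny Density-grid resolution.
#' @param alpha,family_size Significance level and Bonferroni divisor for the
#'   comparison battery.
#' @param figures Write PNG density maps (requires a working png device).
#' @return Invisibly, a list with `annotations`, `records`, `presence`,
#'   `occupancy` (pooled long table), `battery`, `handedness_scores` (or
#'   `NULL`) and `manifest`.
#' @export
run_pipeline <- function(annotations, out_dir, handedness = NULL,
                         strict = FALSE, tie = "lower_left",
                         pooling = "frames", grid_nx = 24, grid_ny = 16,
                         alpha = 0.05, family_size = 8, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  skipped <- character()
  files <- character()
  emit_csv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, name)
  }

  ann <- with_stage("ingest", {
    if (is.character(annotations)) read_annotations(annotations, strict = strict)
    else check_annotation_columns(annotations)
  })
  summ <- ingest_summary(ann)
  emit_csv(dplyr::select(summ, -"rejections"), "ingest_summary.csv")
  rej <- summ$rejections[[1]]
  if (nrow(rej) > 0) emit_csv(rej, "ingest_rejections.csv")

  presence <- with_stage("presence", {
    fkey <- paste(ann$participant_id, ann$video_id, ann$frame_index, sep = "\r")
    tibble::tibble(
      n_frames = length(unique(fkey)),
      frames_with_hand = length(unique(fkey[!is.na(ann$side)])),
      presence_pct = hand_presence_rate(ann)
    )
  })
  emit_csv(presence, "presence.csv")

  records <- with_stage("explode", explode_hands(ann, tie = tie))

  occ_long <- with_stage("occupancy", {
    grid <- tidyr::expand_grid(
      partition = c("vertical", "horizontal", "quadrant", "laterality"),
      hand = c("either", "left", "right"),
      contact = c("all", CONTACT_LEVELS)
    )
    purrr::pmap_dfr(grid, function(partition, hand, contact) {
      tab <- suppressWarnings(
        occupancy(records, partition = partition, hand = hand,
                  contact = contact, pooling = pooling))
      dplyr::mutate(tab$pooled, partition = partition, hand = hand,
                    contact = contact, zone = as.character(.data$zone),
                    .before = 1)
    })
  })
  emit_csv(occ_long, "pooled_occupancy.csv")

  part_long <- with_stage("participant occupancy", {
    grid <- tidyr::expand_grid(
      partition = c("vertical", "horizontal", "quadrant", "laterality"),
      hand = c("either", "left", "right")
    )
    purrr::pmap_dfr(grid, function(partition, hand) {
      tab <- suppressWarnings(
        occupancy(records, partition = partition, hand = hand,
                  pooling = pooling))
      dplyr::mutate(tab$by_participant, partition = partition, hand = hand,
                    zone = as.character(.data$zone), .before = 1)
    })
  })
  emit_csv(part_long, "participant_occupancy.csv")

  hand_scores <- NULL
  if (!is.null(handedness)) {
    hand_scores <- with_stage("handedness", {
      obs <- if (is.character(handedness)) read_handedness(handedness) else handedness
      score_handedness(obs)
    })
    emit_csv(hand_scores, "handedness_scores.csv")
    strat <- with_stage("handedness-stratified occupancy", {
      usable <- hand_scores[hand_scores$handedness != "undetermined", ]
      purrr::map_dfr(c("right", "left"), function(group) {
        ids <- usable$participant_id[usable$handedness == group]
        sub <- records[records$participant_id %in% ids, , drop = FALSE]
        if (nrow(sub) == 0) return(NULL)
        purrr::map_dfr(c("vertical", "quadrant"), function(partition) {
          tab <- suppressWarnings(
            occupancy(sub, partition = partition, pooling = pooling))
          dplyr::mutate(tab$pooled, handedness = group,
                        partition = partition,
                        zone = as.character(.data$zone), .before = 1)
        })
      })
    })
    if (nrow(strat) > 0) emit_csv(strat, "pooled_occupancy_by_handedness.csv")
  } else {
    warn("no handedness observations supplied; handedness-stratified tables skipped")
    skipped <- c(skipped, "handedness-stratified occupancy")
  }

  geom_uniform <- length(unique(records$frame_width)) == 1 &&
    length(unique(records$frame_height)) == 1 && nrow(records) > 0
  if (geom_uniform) {
    with_stage("density", {
      for (hand in c("either", "left", "right")) {
        sub <- if (hand == "either") records else records[records$side == hand, ]
        if (nrow(sub) == 0) next
        grid <- density_grid(sub, nx = grid_nx, ny = grid_ny)
        emit_csv(tidy(grid), paste0("density_grid_", hand, ".csv"))
        if (figures) {
          fig <- file.path(out_dir, paste0("density_", hand, ".png"))
          ok <- tryCatch({
            ggplot2::ggsave(fig, plot_hand_density(sub, bins = 40),
                            width = 6, height = 4, dpi = 150)
            TRUE
          }, error = function(e) FALSE)
          if (ok) files <- c(files, basename(fig))
          else skipped <- c(skipped, paste0("figure ", basename(fig)))
        }
      }
    })
  } else {
    skipped <- c(skipped, "density (mixed or empty frame geometry)")
  }

  battery <- with_stage("stats", {
    suppressWarnings(
      comparison_battery(records, alpha = alpha, family_size = family_size))
  })
  emit_csv(battery, "comparisons.csv")

  manifest <- list(
    package = "handscape",
    version = as.character(utils::packageVersion("handscape")),
    config = list(strict = strict, tie = tie, pooling = pooling,
                  grid_nx = grid_nx, grid_ny = grid_ny, alpha = alpha,
                  family_size = family_size,
                  bonferroni_alpha = bonferroni(alpha, family_size)),
    counts = list(
      lines_total = summ$total, lines_accepted = summ$accepted,
      lines_rejected = summ$rejected,
      n_frames = presence$n_frames,
      frames_with_hand = presence$frames_with_hand,
      n_hand_records = nrow(records),
      comparisons_skipped = attr(battery, "skipped")
    ),
    stages_skipped = skipped,
    files = lapply(sort(unique(files)), function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(annotations = ann, records = records, presence = presence,
                 occupancy = occ_long, battery = battery,
                 handedness_scores = hand_scores, manifest = manifest))
}
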