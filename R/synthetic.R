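#' Spatial models for synthetic hand centres
#'
#' Two generative spatial models are available per hand side. A *mixture*
#' model draws Cartesian centres from a weighted mixture of axis-aligned 2D
#' Gaussians truncated to the frame by rejection sampling (clipping would pile
#' mass on the frame edges and distort quadrant proportions). A *quadrant*
#' model draws a quadrant from a 4-probability vector and places the centre
#' uniformly inside it, which makes the generating quadrant occupancy exact —
#' convenient for parameter-recovery checks.
#'
#' @param components A data frame with columns `weight`, `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y` (Cartesian pixels); weights must sum to 1 and sds be
#'   positive.
#' @return A spatial model object for use in [synthetic_config()].
#' @export
mixture_spatial_model <- function(components) {
  components <- tibble::as_tibble(components)
  need <- c("weight", "mean_x", "mean_y", "sd_x", "sd_y")
  missing <- setdiff(need, names(components))
  if (length(missing) > 0) {
    abort(paste0("mixture components lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (abs(sum(components$weight) - 1) > 1e-8) {
    abort("mixture weights must sum to 1")
  }
  if (any(components$sd_x <= 0) || any(components$sd_y <= 0)) {
    abort("mixture sds must be positive")
  }
  structure(list(type = "mixture", components = components),
            class = "spatial_model")
}

#' @rdname mixture_spatial_model
#' @param probs Named or ordered probabilities over quadrants
#'   `c(UL, LL, UR, LR)`, summing to 1.
#' @export
quadrant_spatial_model <- function(probs) {
  if (length(probs) != 4) abort("quadrant model needs 4 probabilities")
  if (is.null(names(probs))) names(probs) <- QUADRANT_LEVELS
  probs <- probs[QUADRANT_LEVELS]
  if (anyNA(probs) || any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("quadrant probabilities must be non-negative and sum to 1")
  }
  structure(list(type = "quadrant", probs = probs), class = "spatial_model")
}

#' Mirror a spatial model about the vertical midline of the frame
#'
#' @param model A spatial model.
#' @param frame_width Frame width in pixels.
#' @return The reflected model (x means mapped to `frame_width - x`; quadrant
#'   probabilities swapped left/right).
#' @export
mirror_spatial_model <- function(model, frame_width) {
  stopifnot(inherits(model, "spatial_model"))
  if (model$type == "mixture") {
    comp <- model$components
    comp$mean_x <- frame_width - comp$mean_x
    mixture_spatial_model(comp)
  } else {
    p <- model$probs
    quadrant_spatial_model(c(UL = unname(p["UR"]), LL = unname(p["LR"]),
                             UR = unname(p["UL"]), LR = unname(p["LL"])))
  }
}

default_spatial_models <- function(frame_width, frame_height) {
  # Left hand concentrated in the lower-left (ipsilateral lower) image space,
  # with a broad secondary component reaching toward the centre; the right
  # hand is its mirror image.
  left <- mixture_spatial_model(tibble::tibble(
    weight = c(0.80, 0.20),
    mean_x = c(0.33, 0.55) * frame_width,
    mean_y = c(0.30, 0.48) * frame_height,
    sd_x = c(0.18, 0.22) * frame_width,
    sd_y = c(0.20, 0.26) * frame_height
  ))
  list(left = left, right = mirror_spatial_model(left, frame_width))
}

#' Configuration for the synthetic annotation generator
#'
#' Bundles and validates every parameter of the generative model for a
#' synthetic per-frame annotation stream: frames are i.i.d.; each frame
#' contains at least one hand with probability `p_hand_present`; a
#' hand-containing frame is bimanual with probability
#' `p_bimanual_given_present`, otherwise the single hand is left with
#' probability `p_left_given_unimanual`; each detection gets a centre from its
#' side's spatial model, a box drawn around the centre and clipped so the
#' centre stays in frame, and a contact state from `contact_probs`.
#' Participants are right-handed with probability `handedness_mix` and their
#' four scored activities are performed with the dominant hand.
#'
#' Defaults follow the study conditions of the source data where those are
#' known: 37 participants, 456 x 256 frames, a hand present in 78.51% of
#' frames, contact states distributed (portable, stationary, no-contact,
#' self-contact) = (0.832, 0.029, 0.127, 0.012), and a 32:5 right:left
#' handedness mix. See the package vignette for how the remaining defaults
#' were chosen.
#'
#' @param n_participants,videos_per_participant,frames_per_video Stream size.
#' @param frame_width,frame_height Frame geometry in pixels.
#' @param p_hand_present Probability a frame contains at least one hand.
#' @param p_bimanual_given_present Probability a hand-containing frame has
#'   both hands.
#' @param p_left_given_unimanual Probability a single-hand frame shows the
#'   left hand.
#' @param handedness_mix Probability a participant is right-handed.
#' @param contact_probs Probabilities over
#'   `c(portable, stationary, no_contact, self_contact)`, summing to 1.
#' @param spatial_model List with elements `left` and `right`, each a
#'   [mixture_spatial_model()] or [quadrant_spatial_model()].
#' @param bbox_size_model List with `mean_width`, `sd_width`, `mean_height`,
#'   `sd_height`, `min_size` (pixels).
#' @param participant_jitter Standard deviation (pixels) of a per-participant
#'   shift of mixture component means; 0 (default) disables between-participant
#'   spatial heterogeneity.
#' @param seed Integer master seed; per-participant sub-streams use seeds
#'   derived from it, so adding a participant never perturbs earlier
#'   participants' data.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 37,
                             videos_per_participant = 2,
                             frames_per_video = 400,
                             frame_width = 456, frame_height = 256,
                             p_hand_present = 0.7851,
                             p_bimanual_given_present = 0.9,
                             p_left_given_unimanual = 0.25,
                             handedness_mix = 32 / 37,
                             contact_probs = c(portable = 0.832,
                                               stationary = 0.029,
                                               no_contact = 0.127,
                                               self_contact = 0.012),
                             spatial_model = NULL,
                             bbox_size_model = list(mean_width = 90,
                                                    sd_width = 25,
                                                    mean_height = 85,
                                                    sd_height = 25,
                                                    min_size = 8),
                             participant_jitter = 0,
                             seed = 1L) {
  chk_count <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || x < min || x != floor(x)) {
      abort(paste0(name, " must be an integer >= ", min))
    }
  }
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0(name, " must be a probability in [0, 1]"))
    }
  }
  chk_count(n_participants, "n_participants", 0)
  chk_count(videos_per_participant, "videos_per_participant", 0)
  chk_count(frames_per_video, "frames_per_video", 0)
  chk_count(frame_width, "frame_width", 1)
  chk_count(frame_height, "frame_height", 1)
  chk_prob(p_hand_present, "p_hand_present")
  chk_prob(p_bimanual_given_present, "p_bimanual_given_present")
  chk_prob(p_left_given_unimanual, "p_left_given_unimanual")
  chk_prob(handedness_mix, "handedness_mix")
  if (length(contact_probs) != 4 || any(contact_probs < 0) ||
      abs(sum(contact_probs) - 1) > 1e-8) {
    abort("contact_probs must be 4 non-negative values summing to 1")
  }
  if (is.null(names(contact_probs))) names(contact_probs) <- CONTACT_LEVELS
  contact_probs <- contact_probs[CONTACT_LEVELS]
  if (anyNA(contact_probs)) {
    abort(paste0("contact_probs must be named by ",
                 paste(CONTACT_LEVELS, collapse = ", ")))
  }
  if (is.null(spatial_model)) {
    spatial_model <- default_spatial_models(frame_width, frame_height)
  }
  if (!all(c("left", "right") %in% names(spatial_model)) ||
      !inherits(spatial_model$left, "spatial_model") ||
      !inherits(spatial_model$right, "spatial_model")) {
    abort("spatial_model must be a list with spatial models 'left' and 'right'")
  }
  for (nm in c("mean_width", "sd_width", "mean_height", "sd_height", "min_size")) {
    if (!is.numeric(bbox_size_model[[nm]]) || length(bbox_size_model[[nm]]) != 1) {
      abort(paste0("bbox_size_model$", nm, " must be a single number"))
    }
  }
  if (bbox_size_model$min_size <= 0) abort("bbox_size_model$min_size must be > 0")
  if (!is.numeric(participant_jitter) || participant_jitter < 0) {
    abort("participant_jitter must be >= 0")
  }
  chk_count(seed, "seed", 0)
  res <- list(
    n_participants = as.integer(n_participants),
    videos_per_participant = as.integer(videos_per_participant),
    frames_per_video = as.integer(frames_per_video),
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    p_hand_present = p_hand_present,
    p_bimanual_given_present = p_bimanual_given_present,
    p_left_given_unimanual = p_left_given_unimanual,
    handedness_mix = handedness_mix,
    contact_probs = contact_probs,
    spatial_model = spatial_model,
    bbox_size_model = bbox_size_model,
    participant_jitter = participant_jitter,
    seed = as.integer(seed)
  )
  class(res) <- "synthetic_config"
  res
}

sample_spatial <- function(model, n, w, h, jitter_x = 0, jitter_y = 0) {
  if (n == 0) return(list(x = double(), y = double()))
  if (model$type == "quadrant") {
    q <- sample.int(4, n, replace = TRUE, prob = unname(model$probs))
    # order UL, LL, UR, LR
    xlo <- c(0, 0, w / 2, w / 2)[q]
    ylo <- c(h / 2, 0, h / 2, 0)[q]
    return(list(x = xlo + runif(n) * (w / 2),
                y = ylo + runif(n) * (h / 2)))
  }
  comp <- model$components
  k <- nrow(comp)
  mx <- comp$mean_x + jitter_x
  my <- comp$mean_y + jitter_y
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  # rejection sampling: resample (component and point) until inside the frame
  while (length(todo) > 0) {
    ci <- sample.int(k, length(todo), replace = TRUE, prob = comp$weight)
    xs <- rnorm(length(todo), mx[ci], comp$sd_x[ci])
    ys <- rnorm(length(todo), my[ci], comp$sd_y[ci])
    ok <- xs >= 0 & xs <= w & ys >= 0 & ys <= h
    x[todo[ok]] <- xs[ok]
    y[todo[ok]] <- ys[ok]
    todo <- todo[!ok]
  }
  list(x = x, y = y)
}

participant_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * i) %% 2147483647)
}

#' Generate a synthetic annotation stream
#'
#' Draws an annotation stream, per-participant handedness observations and a
#' generation report from a [synthetic_config()]. Generation is deterministic
#' given the config (including its seed): re-running yields a bit-identical
#' stream. Each participant uses a seed derived from the master seed, so
#' enlarging `n_participants` leaves earlier participants' data unchanged.
#' Frames with no hands are emitted as hand-absent marker rows so that
#' presence rates stay computable downstream.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `annotations` (tibble in the
#'   [read_annotations()] column contract), `handedness` (tibble of
#'   `participant_id`, `activity`, `hand_used`) and `report` (realized counts:
#'   frames, frames with hands, bimanual frames, detections by side, contact
#'   states, quadrant occupancy of the generated centres, handedness mix).
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$frame_width; h <- config$frame_height
  fpv <- config$frames_per_video
  npv <- config$videos_per_participant
  n_frames_pp <- fpv * npv

  ann <- vector("list", config$n_participants)
  hand_obs <- vector("list", config$n_participants)
  dominant <- character(config$n_participants)

  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    set.seed(participant_seed(config$seed, i))
    dominant[i] <- if (runif(1) < config$handedness_mix) "right" else "left"
    hand_obs[[i]] <- tibble::tibble(
      participant_id = pid,
      activity = ACTIVITY_LEVELS,
      hand_used = dominant[i]
    )
    jx_l <- jy_l <- jx_r <- jy_r <- 0
    if (config$participant_jitter > 0) {
      jx_l <- rnorm(1, 0, config$participant_jitter)
      jy_l <- rnorm(1, 0, config$participant_jitter)
      jx_r <- rnorm(1, 0, config$participant_jitter)
      jy_r <- rnorm(1, 0, config$participant_jitter)
    }
    if (n_frames_pp == 0) {
      ann[[i]] <- empty_annotations()
      next
    }

    video_id <- sprintf("%s_V%02d", pid, rep(seq_len(npv), each = fpv))
    frame_index <- rep(seq_len(fpv) - 1L, times = npv)

    present <- runif(n_frames_pp) < config$p_hand_present
    bim <- present & (runif(n_frames_pp) < config$p_bimanual_given_present)
    uni <- present & !bim
    uni_left <- uni & (runif(n_frames_pp) < config$p_left_given_unimanual)
    has_left <- bim | uni_left
    has_right <- bim | (uni & !uni_left)

    per_side <- function(flag, side, jx, jy) {
      n_det <- sum(flag)
      if (n_det == 0) return(NULL)
      ctr <- sample_spatial(config$spatial_model[[side]], n_det, w, h, jx, jy)
      bs <- config$bbox_size_model
      bw <- pmax(rnorm(n_det, bs$mean_width, bs$sd_width), bs$min_size)
      bh <- pmax(rnorm(n_det, bs$mean_height, bs$sd_height), bs$min_size)
      half_w <- pmin(bw / 2, ctr$x, w - ctr$x)
      half_h <- pmin(bh / 2, ctr$y, h - ctr$y)
      cy_image <- h - ctr$y
      list(
        participant_id = rep(pid, n_det),
        video_id = video_id[flag],
        frame_index = frame_index[flag],
        frame_width = rep(w, n_det), frame_height = rep(h, n_det),
        side = rep(side, n_det),
        bbox_left = ctr$x - half_w,
        bbox_top = cy_image - half_h,
        bbox_width = 2 * half_w,
        bbox_height = 2 * half_h,
        contact_state = sample(CONTACT_LEVELS, n_det, replace = TRUE,
                               prob = unname(config$contact_probs))
      )
    }
    left_cols <- per_side(has_left, "left", jx_l, jy_l)
    right_cols <- per_side(has_right, "right", jx_r, jy_r)
    n_empty <- sum(!present)
    empty_cols <- if (n_empty == 0) NULL else list(
      participant_id = rep(pid, n_empty),
      video_id = video_id[!present],
      frame_index = frame_index[!present],
      frame_width = rep(w, n_empty), frame_height = rep(h, n_empty),
      side = rep(NA_character_, n_empty),
      bbox_left = rep(NA_real_, n_empty), bbox_top = rep(NA_real_, n_empty),
      bbox_width = rep(NA_real_, n_empty), bbox_height = rep(NA_real_, n_empty),
      contact_state = rep(NA_character_, n_empty)
    )
    parts <- Filter(Negate(is.null), list(left_cols, right_cols, empty_cols))
    if (length(parts) == 0) {
      ann[[i]] <- empty_annotations()
      next
    }
    cols <- if (length(parts) == 1) parts[[1]] else do.call(Map, c(list(c), parts))
    # deterministic stream order: by video, frame, then left/right/absent
    ord <- order(cols$video_id, cols$frame_index,
                 ifelse(is.na(cols$side), "z", cols$side), method = "radix")
    cols <- lapply(cols, `[`, ord)
    cols$frame_width <- as.integer(cols$frame_width)
    cols$frame_height <- as.integer(cols$frame_height)
    ann[[i]] <- tibble::new_tibble(cols, nrow = length(ord))
  }

  annotations <- if (length(ann) > 0) dplyr::bind_rows(ann) else empty_annotations()
  handedness <- if (length(hand_obs) > 0) {
    dplyr::bind_rows(hand_obs)
  } else {
    tibble::tibble(participant_id = character(), activity = character(),
                   hand_used = character())
  }

  det <- annotations[!is.na(annotations$side), , drop = FALSE]
  report <- list(
    n_frames = config$n_participants * n_frames_pp,
    frames_with_hand = 0L, bimanual_frames = 0L,
    n_detections = nrow(det),
    detections_by_side = c(left = sum(det$side == "left"),
                           right = sum(det$side == "right")),
    contact_counts = table(factor(det$contact_state, levels = CONTACT_LEVELS)),
    quadrant_counts = table(factor(character(), levels = QUADRANT_LEVELS)),
    handedness_counts = table(factor(dominant, levels = SIDE_LEVELS))
  )
  if (nrow(det) > 0) {
    fkey <- paste(det$participant_id, det$video_id, det$frame_index, sep = "\r")
    report$frames_with_hand <- length(unique(fkey))
    report$bimanual_frames <- sum(table(fkey) == 2)
    cx <- det$bbox_left + det$bbox_width / 2
    cy <- det$frame_height - (det$bbox_top + det$bbox_height / 2)
    cls <- classify_location(cx, cy, det$frame_width, det$frame_height)
    report$quadrant_counts <- table(factor(cls$quadrant, levels = QUADRANT_LEVELS))
  }
  list(annotations = annotations, handedness = handedness, report = report)
}

# Probability mass of a spatial model in each quadrant / the lower hemiscene,
# exact for quadrant models and via truncated-normal interval probabilities
# for mixtures (participant jitter, if any, is ignored: with jitter the
# marginals below are the jitter-free approximation).
spatial_model_quadrants <- function(model, w, h) {
  if (model$type == "quadrant") return(unname(model$probs[QUADRANT_LEVELS]))
  comp <- model$components
  mass <- function(lo, hi, mean, sd) pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  q <- c(UL = 0, LL = 0, UR = 0, LR = 0)
  z <- 0
  for (k in seq_len(nrow(comp))) {
    px_lo <- mass(0, w / 2, comp$mean_x[k], comp$sd_x[k])
    px_hi <- mass(w / 2, w, comp$mean_x[k], comp$sd_x[k])
    py_lo <- mass(0, h / 2, comp$mean_y[k], comp$sd_y[k])
    py_hi <- mass(h / 2, h, comp$mean_y[k], comp$sd_y[k])
    wk <- comp$weight[k]
    q <- q + wk * c(UL = px_lo * py_hi, LL = px_lo * py_lo,
                    UR = px_hi * py_hi, LR = px_hi * py_lo)
    z <- z + wk * (px_lo + px_hi) * (py_lo + py_hi)
  }
  unname(q / z)
}

#' Analytic marginals implied by a synthetic configuration
#'
#' Computes the population-level quantities that the pipeline should recover
#' from a stream generated under `config`: hand-presence rate, bimanuality,
#' the left-hand share of detections, the pooled quadrant vector
#' (UL, LL, UR, LR), the lower-hemiscene mass and the contact-state vector.
#'
#' @param config A [synthetic_config()].
#' @return A list of expected proportions.
#' @export
expected_marginals <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pb <- config$p_bimanual_given_present
  pl <- config$p_left_given_unimanual
  e_left <- pb + (1 - pb) * pl
  e_right <- pb + (1 - pb) * (1 - pl)
  share_left <- e_left / (e_left + e_right)
  q_left <- spatial_model_quadrants(config$spatial_model$left,
                                    config$frame_width, config$frame_height)
  q_right <- spatial_model_quadrants(config$spatial_model$right,
                                     config$frame_width, config$frame_height)
  quadrant <- share_left * q_left + (1 - share_left) * q_right
  names(quadrant) <- QUADRANT_LEVELS
  list(
    p_hand_present = config$p_hand_present,
    p_bimanual_given_present = pb,
    share_left = share_left,
    quadrant = quadrant,
    lvs = unname(quadrant["LL"] + quadrant["LR"]),
    contact = config$contact_probs
  )
}

#' Check that the pipeline recovers a synthetic configuration
#'
#' Runs the analysis pipeline over a generated stream and compares each
#' recovered marginal (hand-presence rate, bimanuality, pooled lower-hemiscene
#' and quadrant occupancy, contact-state proportions) with the value implied
#' by the generating configuration, requiring agreement within
#' `z_max` binomial standard errors at the realized sample size.
#'
#' @param annotations Annotation tibble generated under `config`.
#' @param config The generating [synthetic_config()].
#' @param z_max Allowed absolute z score per marginal (default 3).
#' @return A tibble with one row per marginal: `marginal`, `expected`,
#'   `observed` (both proportions), `n`, `se`, `z`, `pass`; the attribute
#'   `pass` gives the conjunction. For an empty stream the tibble has zero
#'   rows and attribute `empty` is `TRUE` (nothing is asserted).
#' @export
recovery_check <- function(annotations, config, z_max = 3) {
  stopifnot(inherits(config, "synthetic_config"))
  exp_m <- expected_marginals(config)
  fkey <- paste(annotations$participant_id, annotations$video_id,
                annotations$frame_index, sep = "\r")
  n_frames <- length(unique(fkey))
  if (n_frames == 0) {
    out <- tibble::tibble(marginal = character(), expected = double(),
                          observed = double(), n = double(), se = double(),
                          z = double(), pass = logical())
    attr(out, "empty") <- TRUE
    attr(out, "pass") <- NA
    warn("empty stream: nothing to check")
    return(out)
  }
  records <- explode_hands(annotations)
  n_det <- nrow(records)
  present_frames <- length(unique(fkey[!is.na(annotations$side)]))

  rows <- list()
  add <- function(marginal, expected, observed, n) {
    se <- sqrt(expected * (1 - expected) / n)
    z <- if (se == 0) ifelse(observed == expected, 0, Inf) else (observed - expected) / se
    rows[[length(rows) + 1]] <<- tibble::tibble(
      marginal = marginal, expected = expected, observed = observed,
      n = n, se = se, z = z, pass = abs(z) <= z_max)
  }

  add("p_hand_present", exp_m$p_hand_present, present_frames / n_frames, n_frames)
  if (present_frames > 0) {
    bimanual <- sum(table(fkey[!is.na(annotations$side)]) == 2)
    add("p_bimanual_given_present", exp_m$p_bimanual_given_present,
        bimanual / present_frames, present_frames)
  }
  if (n_det > 0) {
    add("share_left", exp_m$share_left, mean(records$side == "left"), n_det)
    add("lvs", exp_m$lvs, mean(records$vertical == "lower"), n_det)
    for (q in QUADRANT_LEVELS) {
      add(paste0("quadrant_", q), unname(exp_m$quadrant[q]),
          mean(records$quadrant == q), n_det)
    }
    for (cs in CONTACT_LEVELS) {
      add(paste0("contact_", cs), unname(exp_m$contact[cs]),
          mean(records$contact_state == cs), n_det)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "empty") <- FALSE
  attr(out, "pass") <- all(out$pass)
  out
}
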