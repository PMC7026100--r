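#' Parameters of the synthetic vocalization timeline generator
#'
#' Vocal activity of each partner is a renewal process: exponential
#' inter-onset gaps at the given events-per-minute rate, exponential segment
#' durations. On top of the mother's stream, interactional synchrony is
#' planted explicitly: after each mother vocalization the infant initiates a
#' response with probability \code{p_sync}, with the response onset uniform
#' in the 3-s window following the mother's offset. Category and motherese
#' labels are realized by independent coin flips at the given fractions
#' (planted responses are always plain vocalizations so that the response
#' probability remains the quantity the synchrony ratio estimates).
#'
#' @param mother_voc_rate,infant_voc_rate Events per minute.
#' @param mother_voc_dur_mean_ms,infant_voc_dur_mean_ms Mean segment
#'   durations in ms.
#' @param p_sync Probability that a mother vocalization receives an infant
#'   response within the synchrony window.
#' @param motherese_fraction Fraction of mother vocalizations labeled
#'   motherese (the rest are labeled other_speech).
#' @param atypical_fraction Fraction of spontaneous infant vocalizations that
#'   are atypical.
#' @param other_noise_fraction Fraction of mother events that are
#'   non-speech noise.
#' @return A list of class \code{"timeline_params"}.
#' @export
timeline_params <- function(mother_voc_rate = 10, mother_voc_dur_mean_ms = 1500,
                            infant_voc_rate = 5, infant_voc_dur_mean_ms = 800,
                            p_sync = 0.5, motherese_fraction = 0.5,
                            atypical_fraction = 0.05,
                            other_noise_fraction = 0.1) {
  p <- list(mother_voc_rate = mother_voc_rate,
            mother_voc_dur_mean_ms = mother_voc_dur_mean_ms,
            infant_voc_rate = infant_voc_rate,
            infant_voc_dur_mean_ms = infant_voc_dur_mean_ms,
            p_sync = p_sync, motherese_fraction = motherese_fraction,
            atypical_fraction = atypical_fraction,
            other_noise_fraction = other_noise_fraction)
  stopifnot(p$mother_voc_rate >= 0, p$infant_voc_rate >= 0,
            p$mother_voc_dur_mean_ms > 0, p$infant_voc_dur_mean_ms > 0)
  for (nm in c("p_sync", "motherese_fraction", "atypical_fraction",
               "other_noise_fraction")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0,1]")
  }
  class(p) <- "timeline_params"
  p
}

#' Parameters of the synthetic hand-motion generator
#'
#' Hand position follows a first-order (persistent-velocity) random walk in
#' the unit scene box with reflection at the borders. The velocity is redrawn
#' with per-frame probability \code{turn_abruptness}, producing the abrupt
#' direction/speed changes a real infant hand shows. Pause episodes (speed
#' dropped to near zero) and occlusion gaps (visibility lost) are planted as
#' Poisson-count episodes with exponential-tailed durations. Pause durations
#' are floored slightly above the 4-s detection minimum so that the planted
#' per-minute pause rate is directly recoverable by the pause detector.
#'
#' @param step_sd SD of each velocity component draw, scene units/frame.
#' @param pause_rate Planted pauses per minute.
#' @param pause_dur_mean_s Mean pause duration, seconds (must exceed the
#'   4.5-s floor to have an exponential tail; smaller values fall back to a
#'   near-constant duration at the floor).
#' @param turn_abruptness Per-frame probability of redrawing the velocity.
#' @param occlusion_rate Occlusion gaps per minute.
#' @param occlusion_dur_mean_s Mean occlusion duration, seconds.
#' @return A list of class \code{"motion_params"}.
#' @export
motion_params <- function(step_sd = 0.01, pause_rate = 1, pause_dur_mean_s = 6,
                          turn_abruptness = 0.1, occlusion_rate = 1,
                          occlusion_dur_mean_s = 2) {
  p <- list(step_sd = step_sd, pause_rate = pause_rate,
            pause_dur_mean_s = pause_dur_mean_s,
            turn_abruptness = turn_abruptness,
            occlusion_rate = occlusion_rate,
            occlusion_dur_mean_s = occlusion_dur_mean_s)
  if (any(unlist(p) < 0)) stop("motion_params must be non-negative")
  class(p) <- "motion_params"
  p
}

PAUSE_DUR_FLOOR_S <- 4.5

#' Generate a synthetic two-speaker vocalization timeline
#'
#' @param params A [timeline_params()] list.
#' @param duration_ms Total interaction duration in ms (default 3 min).
#' @param seed Integer seed; the same seed reproduces the timeline.
#' @param synchrony_window_ms Window after a mother vocalization offset in
#'   which planted responses land. Default 3000.
#' @return An \code{annotations} table within \code{[0, duration_ms]}, free
#'   of same-speaker self-overlap.
#' @export
make_timeline <- function(params, duration_ms = 180000, seed = 1,
                          synchrony_window_ms = 3000) {
  stopifnot(inherits(params, "timeline_params"), duration_ms > 0)
  set.seed(seed)
  renewal <- function(rate_per_min, dur_mean_ms) {
    if (rate_per_min <= 0) return(NULL)
    n_max <- max(10, stats::qpois(1 - 1e-9, rate_per_min * duration_ms / 60000))
    gaps <- stats::rexp(n_max, rate = rate_per_min / 60000)
    on <- cumsum(gaps)
    on <- on[on < duration_ms]
    if (length(on) == 0) return(NULL)
    dur <- pmax(stats::rexp(length(on), rate = 1 / dur_mean_ms), 80)
    cbind(onset = on, offset = on + dur)
  }

  assemble <- function(iv, cat, mot, speaker) {
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    keep <- iv[, "onset"] < duration_ms
    iv <- iv[keep, , drop = FALSE]; cat <- cat[keep]; mot <- mot[keep]
    if (nrow(iv) == 0) return(NULL)
    iv[, "offset"] <- pmin(iv[, "offset"], duration_ms)
    o <- order(iv[, "onset"])
    iv <- iv[o, , drop = FALSE]; cat <- cat[o]; mot <- mot[o]
    # truncate earlier segments at the next onset: onsets are preserved
    n <- nrow(iv)
    if (n > 1) {
      iv[-n, "offset"] <- pmin(iv[-n, "offset"], iv[-1, "onset"])
    }
    keep <- iv[, "offset"] - iv[, "onset"] >= 1
    data.frame(speaker = speaker, category = cat[keep],
               onset_ms = round(iv[keep, "onset"]),
               offset_ms = round(iv[keep, "offset"]),
               motherese = mot[keep], stringsAsFactors = FALSE)
  }

  mother <- renewal(params$mother_voc_rate, params$mother_voc_dur_mean_ms)
  m_cat <- m_mot <- character(0)
  if (!is.null(mother)) {
    n <- nrow(mother)
    m_cat <- ifelse(stats::runif(n) < params$other_noise_fraction,
                    "other_noise", "vocalization")
    m_mot <- ifelse(m_cat == "vocalization",
                    ifelse(stats::runif(n) < params$motherese_fraction,
                           "motherese", "other_speech"),
                    "unlabeled")
  }
  mo <- assemble(mother, m_cat, m_mot, "mother")

  # planted responses are anchored at the final (truncated, rounded) mother
  # vocalization offsets so the response probability is exactly what the
  # synchrony ratio downstream estimates
  resp <- NULL
  if (!is.null(mo)) {
    voc_off <- mo$offset_ms[mo$category == "vocalization"]
    hit <- voc_off[stats::runif(length(voc_off)) < params$p_sync]
    if (length(hit) > 0) {
      r_on <- hit + stats::runif(length(hit), min = 1,
                                 max = synchrony_window_ms)
      r_dur <- pmax(stats::rexp(length(hit),
                                rate = 1 / params$infant_voc_dur_mean_ms), 80)
      resp <- cbind(onset = r_on, offset = r_on + r_dur)
    }
  }

  spont <- renewal(params$infant_voc_rate, params$infant_voc_dur_mean_ms)
  s_cat <- if (is.null(spont)) character(0) else
    ifelse(stats::runif(nrow(spont)) < params$atypical_fraction,
           "atypical_vocalization", "vocalization")
  infant <- rbind(resp, spont)
  i_cat <- c(rep("vocalization", if (is.null(resp)) 0 else nrow(resp)), s_cat)
  inf <- assemble(infant, i_cat, rep("unlabeled", length(i_cat)), "infant")

  both <- rbind(mo, inf)
  if (is.null(both) || nrow(both) == 0) return(annotations())
  both$offset_ms <- pmax(both$offset_ms, both$onset_ms + 1)
  # rounding can reintroduce a 0/1-ms same-speaker overlap; re-truncate
  for (sp in SPEAKERS) {
    idx <- which(both$speaker == sp)
    idx <- idx[order(both$onset_ms[idx])]
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        a <- idx[k]; b <- idx[k + 1]
        if (both$offset_ms[a] > both$onset_ms[b]) {
          both$offset_ms[a] <- both$onset_ms[b]
        }
      }
    }
  }
  both <- both[both$offset_ms > both$onset_ms, , drop = FALSE]
  annotations(both$speaker, both$category, both$onset_ms, both$offset_ms,
              both$motherese)
}

#' Generate a synthetic hand trajectory
#'
#' @param params A [motion_params()] list.
#' @param duration_s Duration in seconds (default 60).
#' @param fps Frames per second (default 25).
#' @param seed Integer seed.
#' @return A \code{trajectory} of \code{round(duration_s * fps)} frames with
#'   attributes \code{pause_truth} and \code{occlusion_truth} (data frames of
#'   planted episode intervals, in seconds).
#' @export
make_trajectory <- function(params, duration_s = 60, fps = 25, seed = 1) {
  stopifnot(inherits(params, "motion_params"), duration_s > 0, fps > 0)
  set.seed(seed)
  n <- round(duration_s * fps)

  redraw <- stats::runif(n) < params$turn_abruptness
  redraw[1] <- TRUE
  vx <- rep(NA_real_, n); vy <- rep(NA_real_, n)
  vx[redraw] <- stats::rnorm(sum(redraw), sd = params$step_sd)
  vy[redraw] <- stats::rnorm(sum(redraw), sd = params$step_sd)
  idx <- cummax(ifelse(redraw, seq_len(n), 0L))
  vx <- vx[idx]; vy <- vy[idx]

  # Poisson count of episodes placed uniformly in the free space so every
  # episode fits whole (separated by min_gap_s, clear of both ends); the
  # planted count is then exactly the Poisson draw. Episodes are shed only
  # in the rare case the draw cannot fit at all.
  episodes <- function(rate_per_min, dur_fn, min_gap_s = 1) {
    k <- stats::rpois(1, rate_per_min * duration_s / 60)
    if (k == 0) {
      return(data.frame(start_s = numeric(), end_s = numeric()))
    }
    dur <- dur_fn(k)
    repeat {
      free <- duration_s - sum(dur) - (k - 1) * min_gap_s - 0.4
      if (free >= 0 || k == 0) break
      k <- k - 1L
      dur <- dur[seq_len(k)]
    }
    if (k == 0) {
      return(data.frame(start_s = numeric(), end_s = numeric()))
    }
    slack <- sort(stats::runif(k, 0, free))
    start <- 0.2 + slack + (seq_len(k) - 1) * min_gap_s +
      c(0, cumsum(dur))[seq_len(k)]
    data.frame(start_s = start, end_s = start + dur)
  }

  pauses <- episodes(params$pause_rate, function(k) {
    tail_mean <- max(params$pause_dur_mean_s - PAUSE_DUR_FLOOR_S, 0.1)
    PAUSE_DUR_FLOOR_S + stats::rexp(k, rate = 1 / tail_mean)
  })
  occl <- episodes(params$occlusion_rate,
                   function(k) stats::rexp(k, 1 / params$occlusion_dur_mean_s),
                   min_gap_s = 0.5)

  t_s <- (seq_len(n) - 1) / fps
  in_pause <- rep(FALSE, n)
  for (i in seq_len(nrow(pauses))) {
    in_pause <- in_pause | (t_s >= pauses$start_s[i] & t_s < pauses$end_s[i])
  }
  jit <- params$step_sd * 1e-4
  vx[in_pause] <- stats::rnorm(sum(in_pause), sd = jit)
  vy[in_pause] <- stats::rnorm(sum(in_pause), sd = jit)

  reflect01 <- function(p) {
    r <- p %% 2
    ifelse(r > 1, 2 - r, r)
  }
  x <- reflect01(0.5 + cumsum(vx))
  y <- reflect01(0.5 + cumsum(vy))

  visible <- rep(TRUE, n)
  for (i in seq_len(nrow(occl))) {
    visible[t_s >= occl$start_s[i] & t_s < occl$end_s[i]] <- FALSE
  }

  tr <- trajectory(seq_len(n) - 1L, x, y, visible, fps = fps)
  attr(tr, "pause_truth") <- pauses
  attr(tr, "occlusion_truth") <- occl
  tr
}

#' Render a trajectory as a sequence of synthetic video frames
#'
#' Each visible frame shows a colored disk (the wristband stand-in) at the
#' true scene position on a noisy gray background; occluded frames contain no
#' disk. Scene coordinates in the unit box map linearly onto the pixel grid.
#'
#' @param traj A \code{trajectory}.
#' @param blob_color Length-3 RGB in \code{[0,1]}; default a wristband yellow.
#' @param noise_sd Background pixel noise SD. Default 0.05.
#' @param seed Integer seed.
#' @param width,height Frame size in pixels. Default 64.
#' @param blob_radius_px Disk radius in pixels. Default 3.
#' @return A list of class \code{"frame_sequence"}: \code{frames} (list of
#'   height x width x 3 arrays), frame geometry, and the truth trajectory.
#' @export
make_video <- function(traj, blob_color = c(0.95, 0.85, 0.1), noise_sd = 0.05,
                       seed = 1, width = 64, height = 64, blob_radius_px = 3) {
  stopifnot(inherits(traj, "trajectory"))
  set.seed(seed)
  n <- nrow(traj)
  px <- 1 + traj$x * (width - 1)
  py <- 1 + traj$y * (height - 1)
  cols <- matrix(rep(seq_len(width), each = height), nrow = height)
  rows <- matrix(rep(seq_len(height), width), nrow = height)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    img <- array(pmin(pmax(
      stats::rnorm(height * width * 3, mean = 0.5, sd = noise_sd), 0), 1),
      dim = c(height, width, 3))
    if (traj$visible[i]) {
      mask <- (cols - px[i])^2 + (rows - py[i])^2 <= blob_radius_px^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- pmin(pmax(
          blob_color[ch] + stats::rnorm(sum(mask), sd = 0.02), 0), 1)
        img[, , ch] <- plane
      }
    }
    frames[[i]] <- img
  }
  structure(list(frames = frames, width = width, height = height,
                 blob_radius_px = blob_radius_px, fps = traj_fps(traj),
                 blob_color = blob_color, truth = traj),
            class = "frame_sequence")
}

#' Specification of a synthetic dyad cohort
#'
#' Mirrors the three-group study design (typically developing controls, and
#' an at-risk group split by developmental outcome into WS- and WS+).
#'
#' @param n_td,n_ws_minus,n_ws_plus Dyad counts per group.
#' @param group_params Named list (\code{TD}, \code{WSminus}, \code{WSplus}),
#'   each a list with elements \code{timeline} ([timeline_params()]) and
#'   \code{motion} ([motion_params()]). Default [default_group_params()].
#' @param audio_duration_s Timeline duration, seconds (default 180: one 3-min
#'   free-play sequence).
#' @param motion_duration_s Trajectory duration, seconds (default 60: the
#'   analyzed 1-min window).
#' @param seed Integer seed.
#' @return A list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_td = 19, n_ws_minus = 22, n_ws_plus = 10,
                        group_params = default_group_params(),
                        audio_duration_s = 180, motion_duration_s = 60,
                        seed = 1) {
  stopifnot(n_td >= 0, n_ws_minus >= 0, n_ws_plus >= 0)
  for (g in c("TD", "WSminus", "WSplus")) {
    if (!inherits(group_params[[g]]$timeline, "timeline_params") ||
        !inherits(group_params[[g]]$motion, "motion_params")) {
      stop("group_params$", g, " must have timeline_params and motion_params")
    }
  }
  structure(list(n_td = n_td, n_ws_minus = n_ws_minus, n_ws_plus = n_ws_plus,
                 group_params = group_params,
                 audio_duration_s = audio_duration_s,
                 motion_duration_s = motion_duration_s,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default per-group generator parameters
#'
#' The three groups differ in the directions reported for real cohorts:
#' at-risk infants (and most strongly those with a poor outcome) vocalize
#' less, respond to their mother less often within the synchrony window,
#' move with lower velocity/acceleration variability, and spend more time
#' motionless. Effect sizes are deliberately in the strong-signal regime so
#' the full pipeline separates the groups well at a 51-dyad cohort; they are
#' package defaults, not estimates of real effect magnitudes.
#'
#' @return Named list of per-group \code{timeline}/\code{motion} parameters.
#' @export
default_group_params <- function() {
  list(
    TD = list(
      timeline = timeline_params(mother_voc_rate = 10, infant_voc_rate = 5,
                                 p_sync = 0.6, motherese_fraction = 0.55),
      motion = motion_params(step_sd = 0.010, pause_rate = 1,
                             pause_dur_mean_s = 6, turn_abruptness = 0.10,
                             occlusion_rate = 1, occlusion_dur_mean_s = 2)
    ),
    WSminus = list(
      timeline = timeline_params(mother_voc_rate = 11, infant_voc_rate = 3,
                                 p_sync = 0.40, motherese_fraction = 0.45),
      motion = motion_params(step_sd = 0.006, pause_rate = 3,
                             pause_dur_mean_s = 7, turn_abruptness = 0.08,
                             occlusion_rate = 1, occlusion_dur_mean_s = 2)
    ),
    WSplus = list(
      timeline = timeline_params(mother_voc_rate = 11, infant_voc_rate = 1.2,
                                 p_sync = 0.12, motherese_fraction = 0.45),
      motion = motion_params(step_sd = 0.0035, pause_rate = 4.5,
                             pause_dur_mean_s = 8, turn_abruptness = 0.05,
                             occlusion_rate = 1, occlusion_dur_mean_s = 2)
    )
  )
}

#' Generate a cohort of synthetic dyads
#'
#' @param spec A [cohort_spec()].
#' @return A list of class \code{"dyad_cohort"} whose elements each hold
#'   \code{dyad_id}, \code{group}, \code{timeline} (annotations),
#'   \code{trajectory}, and \code{truth} (the generating parameters).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("TD", spec$n_td), rep("WSminus", spec$n_ws_minus),
              rep("WSplus", spec$n_ws_plus))
  cohort <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    gp <- spec$group_params[[g]]
    seed_i <- (spec$seed + 7919L * i) %% .Machine$integer.max
    cohort[[i]] <- list(
      dyad_id = sprintf("dyad%03d", i),
      group = g,
      timeline = make_timeline(gp$timeline,
                               duration_ms = spec$audio_duration_s * 1000,
                               seed = seed_i),
      trajectory = make_trajectory(gp$motion,
                                   duration_s = spec$motion_duration_s,
                                   seed = seed_i + 1L),
      truth = gp
    )
  }
  structure(cohort, class = "dyad_cohort", spec = spec)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits, per dyad, the annotation TSV and trajectory CSV, plus a
#' \code{labels.csv} (dyad_id, group) and a \code{truth.json} with the
#' generating parameters.
#'
#' @param cohort A \code{dyad_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(dyad_id = character(), group = character())
  truth <- list()
  for (d in cohort) {
    write_annotations(d$timeline,
                      file.path(dir, paste0(d$dyad_id, "_annotations.tsv")))
    write_trajectory(d$trajectory,
                     file.path(dir, paste0(d$dyad_id, "_trajectory.csv")))
    labels <- rbind(labels, data.frame(dyad_id = d$dyad_id, group = d$group))
    truth[[d$dyad_id]] <- lapply(d$truth, unclass)
  }
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dyad_log("wrote %d dyad(s) to %s", length(cohort), dir)
  invisible(dir)
}
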