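#' Select the analysis window of a trajectory
#'
#' Real protocols extract one minute from each longer recording, choosing the
#' part where the hand is visible. This picks the contiguous window of
#' \code{window_s} seconds maximizing the visible-frame fraction; ties go to
#' the earliest start.
#'
#' @param traj A \code{trajectory}.
#' @param window_s Window length in seconds. Default 60.
#' @return The windowed \code{trajectory} (frames re-indexed from 0); the
#'   whole trajectory with a warning when it is shorter than the window.
#' @export
select_window <- function(traj, window_s = 60) {
  fps <- traj_fps(traj)
  win <- round(window_s * fps)
  n <- nrow(traj)
  if (n < win) {
    warning("trajectory shorter than the requested window; returning whole")
    return(traj)
  }
  cs <- c(0, cumsum(as.numeric(traj$visible)))
  counts <- cs[(win + 1):(n + 1)] - cs[1:(n - win + 1)]
  start <- which.max(counts) # earliest maximum
  idx <- start:(start + win - 1)
  trajectory(seq_len(win) - 1L, traj$x[idx], traj$y[idx], traj$visible[idx],
             fps = fps,
             normalization_factor = attr(traj, "normalization_factor"))
}

# indices of maximal runs of consecutive visible frames
visible_runs <- function(traj, min_len = 1) {
  vis <- which(traj$visible)
  if (length(vis) == 0) return(list())
  brk <- c(0, which(diff(traj$frame[vis]) != 1), length(vis))
  runs <- lapply(seq_len(length(brk) - 1),
                 function(i) vis[(brk[i] + 1):brk[i + 1]])
  runs[vapply(runs, length, 1L) >= min_len]
}

# centered moving average with shrinking windows at the edges
moving_average <- function(v, k) {
  if (k <= 1 || length(v) < 2) return(v)
  h <- floor(k / 2)
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Spatial descriptors of the explored area
#'
#' Computed over visible frames only: coordinate ranges and SDs, and the
#' exact farthest-pair distance between any two points of the trajectory.
#'
#' @param traj A \code{trajectory}.
#' @return Named numeric vector \code{xRange, yRange, xSd, ySd, maxPairDist};
#'   all \code{NA} with fewer than 2 visible frames.
#' @export
spatial_descriptors <- function(traj) {
  x <- traj$x[traj$visible]; y <- traj$y[traj$visible]
  if (length(x) < 2) {
    return(c(xRange = NA_real_, yRange = NA_real_, xSd = NA_real_,
             ySd = NA_real_, maxPairDist = NA_real_))
  }
  c(xRange = max(x) - min(x), yRange = max(y) - min(y),
    xSd = stats::sd(x), ySd = stats::sd(y),
    maxPairDist = farthest_pair_distance(x, y))
}

#' Farthest-pair distance of a 2D point set
#'
#' @param x,y Coordinate vectors.
#' @return Maximum Euclidean distance between any two points (0 for a single
#'   point).
#' @export
farthest_pair_distance <- function(x, y) {
  if (length(x) < 2) return(0)
  max(stats::dist(cbind(x, y)))
}

#' Velocity and acceleration of a trajectory
#'
#' Coordinates are smoothed with a short centered moving average, then
#' differentiated by central finite differences inside maximal runs of
#' consecutive visible frames (one-sided differences at run ends for the
#' first derivative); derivatives never cross an invisibility gap. Speeds
#' and acceleration magnitudes are in scene units per second (squared).
#'
#' @param traj A \code{trajectory}.
#' @param config A [run_config()] (for the smoothing window).
#' @return List with full-length \code{speed} and \code{acc} series (NA where
#'   undefined), summary statistics \code{velMean, velSd, velMax, accMean,
#'   accSd, accMax}, and \code{pathLength} (sum of raw steps between
#'   consecutive visible frames).
#' @export
kinematics <- function(traj, config = run_config()) {
  fps <- traj_fps(traj)
  n <- nrow(traj)
  speed <- rep(NA_real_, n)
  acc <- rep(NA_real_, n)
  path <- 0
  any_run <- FALSE
  for (run in visible_runs(traj)) {
    x <- traj$x[run]; y <- traj$y[run]
    m <- length(run)
    if (m >= 2) {
      path <- path + sum(sqrt(diff(x)^2 + diff(y)^2))
    }
    if (m < 3) next
    any_run <- TRUE
    xs <- moving_average(x, config$smooth_frames)
    ys <- moving_average(y, config$smooth_frames)
    i <- 2:(m - 1)
    dx <- c(xs[2] - xs[1], (xs[i + 1] - xs[i - 1]) / 2, xs[m] - xs[m - 1])
    dy <- c(ys[2] - ys[1], (ys[i + 1] - ys[i - 1]) / 2, ys[m] - ys[m - 1])
    speed[run] <- sqrt(dx^2 + dy^2) * fps
    ax <- (xs[i + 1] - 2 * xs[i] + xs[i - 1]) * fps^2
    ay <- (ys[i + 1] - 2 * ys[i] + ys[i - 1]) * fps^2
    acc[run[i]] <- sqrt(ax^2 + ay^2)
  }
  summ <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_, NA_real_)
    else c(mean(v), stats::sd(v), max(v))
  }
  sv <- summ(speed); sa <- summ(acc)
  list(speed = speed, acc = acc,
       velMean = sv[1], velSd = sv[2], velMax = sv[3],
       accMean = sa[1], accSd = sa[2], accMax = sa[3],
       pathLength = if (any(traj$visible)) path else NA_real_,
       defined = any_run)
}

resolve_pause_threshold <- function(speed, config) {
  if (!is.na(config$pause_speed_absolute)) {
    return(config$pause_speed_absolute)
  }
  mx <- suppressWarnings(max(speed, na.rm = TRUE))
  if (!is.finite(mx)) return(NA_real_)
  max(config$pause_speed_threshold * mx, .Machine$double.eps)
}

#' Detect hand-movement pauses in a speed series
#'
#' A pause is a maximal run of frames whose speed stays strictly below the
#' threshold for at least \code{min_dur_s} seconds; runs never span frames
#' where the speed is undefined (invisibility gaps).
#'
#' @param speed Speed series in scene units/s, \code{NA} where undefined.
#' @param fps Frames per second.
#' @param threshold Speed threshold.
#' @param min_dur_s Minimum pause duration in seconds. Default 4.
#' @param visible_duration_s Denominator for the relative pause time;
#'   defaults to the defined-speed duration.
#' @return List: \code{intervals} (data.frame \code{start_s}, \code{end_s}),
#'   \code{pauseCount}, \code{pauseTotalDur_s}, \code{pauseRelTime},
#'   \code{pauseMeanDur_s}.
#' @export
detect_pauses <- function(speed, fps, threshold, min_dur_s = 4,
                          visible_duration_s = NULL) {
  if (is.null(visible_duration_s)) {
    visible_duration_s <- sum(!is.na(speed)) / fps
  }
  below <- !is.na(speed) & speed < threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths / fps >= min_dur_s
  intervals <- data.frame(start_s = (starts[keep] - 1) / fps,
                          end_s = ends[keep] / fps)
  total <- sum(intervals$end_s - intervals$start_s)
  list(intervals = intervals,
       pauseCount = nrow(intervals),
       pauseTotalDur_s = total,
       pauseRelTime = if (visible_duration_s > 0) total / visible_duration_s
                      else NA_real_,
       pauseMeanDur_s = if (nrow(intervals) > 0) total / nrow(intervals)
                        else 0)
}

#' Curvature of a planar trajectory
#'
#' Standard plane-curve curvature \eqn{\kappa = |x'y'' - y'x''| /
#' (x'^2+y'^2)^{3/2}} from finite differences of the smoothed coordinates,
#' computed inside maximal visible runs of at least 5 frames. Samples moving
#' slower than \code{eps_speed} are excluded (curvature is numerically
#' meaningless at near-zero speed).
#'
#' @param traj A \code{trajectory}.
#' @param config A [run_config()].
#' @param eps_speed Speed (units/s) below which curvature is undefined;
#'   defaults to the trajectory's pause threshold.
#' @return List with the full-length \code{kappa} series and
#'   \code{curvMean, curvSd, curvMax}.
#' @export
curvature <- function(traj, config = run_config(), eps_speed = NULL) {
  fps <- traj_fps(traj)
  n <- nrow(traj)
  kappa <- rep(NA_real_, n)
  if (is.null(eps_speed)) {
    kin <- kinematics(traj, config)
    eps_speed <- resolve_pause_threshold(kin$speed, config)
  }
  h <- floor(config$smooth_frames / 2)
  for (run in visible_runs(traj, min_len = max(5, 2 * h + 3))) {
    x <- moving_average(traj$x[run], config$smooth_frames)
    y <- moving_average(traj$y[run], config$smooth_frames)
    m <- length(run)
    # skip run edges where the smoothing window was truncated: the
    # asymmetric average there distorts the second derivative
    i <- (h + 2):(m - h - 1)
    d1x <- (x[i + 1] - x[i - 1]) / 2
    d1y <- (y[i + 1] - y[i - 1]) / 2
    d2x <- x[i + 1] - 2 * x[i] + x[i - 1]
    d2y <- y[i + 1] - 2 * y[i] + y[i - 1]
    sp2 <- d1x^2 + d1y^2
    k <- abs(d1x * d2y - d1y * d2x) / sp2^1.5
    slow <- sqrt(sp2) * fps < eps_speed
    k[slow] <- NA_real_
    kappa[run[i]] <- k
  }
  v <- kappa[!is.na(kappa)]
  list(kappa = kappa,
       curvMean = if (length(v)) mean(v) else NA_real_,
       curvSd = if (length(v) > 1) stats::sd(v) else NA_real_,
       curvMax = if (length(v)) max(v) else NA_real_)
}

#' The 21 hand-movement descriptors of a trajectory
#'
#' Assembles the full motion feature vector: explored space (ranges, SDs,
#' farthest pair), path length and visibility, velocity and acceleration
#' summaries, curvature summaries, pause statistics (threshold crossings of
#' at least 4 s), and the movement-unit count (maximal supra-threshold speed
#' runs). Fields that cannot be computed (too few visible frames) are
#' \code{NA} and propagate to the classifier's missing-value handling.
#'
#' @param traj A normalized \code{trajectory}.
#' @param config A [run_config()].
#' @return Named numeric vector of length 21.
#' @export
motion_features <- function(traj, config = run_config()) {
  sp <- spatial_descriptors(traj)
  kin <- kinematics(traj, config)
  thr <- resolve_pause_threshold(kin$speed, config)
  pauses <- if (is.na(thr)) {
    list(pauseCount = NA_real_, pauseTotalDur_s = NA_real_,
         pauseRelTime = NA_real_, pauseMeanDur_s = NA_real_)
  } else {
    detect_pauses(kin$speed, traj_fps(traj), thr, config$pause_min_s,
                  visible_duration_s = sum(traj$visible) / traj_fps(traj))
  }
  crv <- curvature(traj, config, eps_speed = thr)
  mu <- if (is.na(thr)) NA_real_ else {
    above <- !is.na(kin$speed) & kin$speed >= thr
    r <- rle(above)
    sum(r$values)
  }
  out <- c(sp,
           pathLength = kin$pathLength,
           visibleFraction = mean(traj$visible),
           velMean = kin$velMean, velSd = kin$velSd, velMax = kin$velMax,
           accMean = kin$accMean, accSd = kin$accSd, accMax = kin$accMax,
           curvMean = crv$curvMean, curvSd = crv$curvSd,
           curvMax = crv$curvMax,
           pauseCount = as.numeric(pauses$pauseCount),
           pauseTotalDur_s = pauses$pauseTotalDur_s,
           pauseRelTime = pauses$pauseRelTime,
           pauseMeanDur_s = pauses$pauseMeanDur_s,
           movementUnitCount = as.numeric(mu))
  stopifnot(length(out) == 21)
  out
}
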