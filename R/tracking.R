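#' Configuration of the bootstrap particle-filter tracker
#'
#' The tracker follows a colored wristband through a frame sequence with the
#' classic predict / observe (weigh) / estimate cycle, using a first-order
#' (constant-velocity) motion model so abrupt changes in direction and speed
#' are absorbed by the process noise, and a per-particle visibility boolean
#' so occlusion is part of the state rather than a failure mode.
#'
#' @param n_particles Number of particles. Default 500.
#' @param pos_noise_sd Process noise SD on position, pixels/frame. Default 1.5.
#' @param vel_noise_sd Process noise SD on velocity, pixels/frame. Default 0.8.
#' @param color Target RGB color in \code{[0,1]} (wristband yellow default).
#' @param color_tolerance Kernel width of the color model over RGB space.
#'   Default 0.15.
#' @param likelihood_floor Bhattacharyya similarity below which the target
#'   counts as unseen, in \code{(0,1)}. Default 0.3.
#' @param occlusion_likelihood Constant observation likelihood assigned to
#'   particles whose visibility flag is off. Default 0.08.
#' @param visibility_flip_prob Per-frame probability of flipping a particle's
#'   visibility flag. Default 0.05.
#' @param resample_ess_fraction Resample when the effective sample size drops
#'   below this fraction of \code{n_particles}. Default 0.5.
#' @param patch_half_px Half-width of the square observation patch. Default 2.
#' @param seed Integer seed used by [track()].
#' @return A list of class \code{"tracker_config"}.
#' @export
tracker_config <- function(n_particles = 500, pos_noise_sd = 1.5,
                           vel_noise_sd = 0.8,
                           color = c(0.95, 0.85, 0.1), color_tolerance = 0.15,
                           likelihood_floor = 0.3, occlusion_likelihood = 0.08,
                           visibility_flip_prob = 0.05,
                           resample_ess_fraction = 0.5, patch_half_px = 2,
                           seed = 1) {
  stopifnot(n_particles >= 1, likelihood_floor > 0, likelihood_floor < 1,
            resample_ess_fraction > 0, resample_ess_fraction <= 1)
  structure(list(n_particles = as.integer(n_particles),
                 pos_noise_sd = pos_noise_sd, vel_noise_sd = vel_noise_sd,
                 color = color, color_tolerance = color_tolerance,
                 likelihood_floor = likelihood_floor,
                 occlusion_likelihood = occlusion_likelihood,
                 visibility_flip_prob = visibility_flip_prob,
                 resample_ess_fraction = resample_ess_fraction,
                 patch_half_px = as.integer(patch_half_px),
                 seed = as.integer(seed)),
            class = "tracker_config")
}

#' Create a particle set
#'
#' Particles live in pixel coordinates and carry position, velocity, a
#' visibility flag and a normalized weight.
#'
#' @param x,y,vx,vy Numeric state components.
#' @param visible Logical flags.
#' @param weight Non-negative weights (normalized to sum to 1).
#' @return A data.frame of class \code{"particles"}.
#' @export
particles <- function(x, y, vx, vy, visible, weight = NULL) {
  n <- length(x)
  if (is.null(weight)) weight <- rep(1 / n, n)
  stopifnot(all(weight >= 0), sum(weight) > 0)
  df <- data.frame(x = x, y = y, vx = vx, vy = vy,
                   visible = as.logical(visible),
                   weight = weight / sum(weight))
  class(df) <- c("particles", "data.frame")
  df
}

#' Prediction step of the particle filter
#'
#' Advances each particle by its velocity, adds Gaussian process noise to
#' position and velocity (the first-order model), and flips the visibility
#' flag with a small transition probability. Weights are untouched. Uses R's
#' global RNG: seed beforehand for reproducibility.
#'
#' @param p A \code{particles} set with normalized weights.
#' @param config A [tracker_config()].
#' @return The advanced \code{particles} set.
#' @export
pf_predict <- function(p, config) {
  n <- nrow(p)
  vx <- p$vx + stats::rnorm(n, sd = config$vel_noise_sd)
  vy <- p$vy + stats::rnorm(n, sd = config$vel_noise_sd)
  x <- p$x + vx + stats::rnorm(n, sd = config$pos_noise_sd)
  y <- p$y + vy + stats::rnorm(n, sd = config$pos_noise_sd)
  flip <- stats::runif(n) < config$visibility_flip_prob
  particles(x, y, vx, vy, xor(p$visible, flip), p$weight)
}

#' Bhattacharyya coefficient between two histograms
#'
#' \eqn{BC(h, q) = \sum_b \sqrt{h_b q_b}}; equals 1 iff the normalized
#' histograms are identical.
#'
#' @param h,q Non-negative histograms (normalized internally).
#' @return The coefficient in \code{[0, 1]}.
#' @export
bhattacharyya_coefficient <- function(h, q) {
  stopifnot(length(h) == length(q), all(h >= 0), all(q >= 0))
  if (sum(h) == 0 || sum(q) == 0) return(0)
  sum(sqrt((h / sum(h)) * (q / sum(q))))
}

# Color-model histogram over a 4x4x4 RGB quantization: Gaussian kernel
# around the target color evaluated at bin centers.
color_model_hist <- function(color, tolerance, levels = 4L) {
  centers <- (seq_len(levels) - 0.5) / levels
  g <- expand.grid(r = centers, g = centers, b = centers)
  d2 <- (g$r - color[1])^2 + (g$g - color[2])^2 + (g$b - color[3])^2
  q <- exp(-d2 / (2 * tolerance^2))
  q / sum(q)
}

# Box sum of a matrix over (2h+1)^2 windows via an integral image,
# zero-padded at the borders.
box_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2 * h, nc + 2 * h)
  pad[(h + 1):(h + nr), (h + 1):(h + nc)] <- m
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum) # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  w <- 2 * h + 1
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  ii[r1 + w, c1 + w, drop = FALSE] - ii[r1, c1 + w, drop = FALSE] -
    ii[r1 + w, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

#' Per-pixel patch similarity map for one frame
#'
#' For every pixel, the Bhattacharyya coefficient between the color
#' histogram of the surrounding square patch (4 quantization levels per RGB
#' channel) and the target color model. Computed with per-bin box filters so
#' the whole map costs a few passes over the image.
#'
#' @param img A height x width x 3 array in \code{[0,1]}.
#' @param config A [tracker_config()].
#' @return A height x width similarity matrix in \code{[0,1]}.
#' @export
similarity_map <- function(img, config) {
  levels <- 4L
  q <- color_model_hist(config$color, config$color_tolerance, levels)
  lv <- function(ch) pmin(floor(img[, , ch] * levels), levels - 1)
  bin <- lv(1) + levels * lv(2) + levels^2 * lv(3) # 0-based bin index
  support <- which(q > 1e-4) - 1L
  h <- config$patch_half_px
  area <- (2 * h + 1)^2
  bc <- matrix(0, nrow(bin), ncol(bin))
  for (b in support) {
    hb <- box_sum((bin == b) * 1, h) / area
    bc <- bc + sqrt(hb * q[b + 1L])
  }
  bc
}

lookup_map <- function(map, x, y) {
  ix <- pmin(pmax(round(x), 1), ncol(map))
  iy <- pmin(pmax(round(y), 1), nrow(map))
  map[cbind(iy, ix)]
}

#' Observation (weighing) step of the particle filter
#'
#' Visible-flagged particles are weighted by the patch color similarity at
#' their position; occluded-flagged particles receive the constant occlusion
#' likelihood. Weights are renormalized; an all-zero weight vector falls back
#' to uniform weights with a warning.
#'
#' @param p A \code{particles} set.
#' @param frame_image A height x width x 3 array, or a precomputed
#'   similarity matrix.
#' @param config A [tracker_config()].
#' @return \code{p} with updated normalized weights and attribute
#'   \code{best_likelihood} (largest raw similarity among visible-flagged
#'   particles; 0 if none).
#' @export
pf_weigh <- function(p, frame_image, config) {
  map <- if (is.matrix(frame_image)) frame_image
         else similarity_map(frame_image, config)
  sim <- lookup_map(map, p$x, p$y)
  w <- ifelse(p$visible, sim, config$occlusion_likelihood)
  best <- if (any(p$visible)) max(sim[p$visible]) else 0
  if (sum(w) <= 0) {
    warning("all particle weights zero; falling back to uniform")
    w <- rep(1, nrow(p))
  }
  out <- particles(p$x, p$y, p$vx, p$vy, p$visible, w)
  attr(out, "best_likelihood") <- best
  out
}

#' Systematic resampling step
#'
#' Resamples (systematically, for low variance) only when the effective
#' sample size \eqn{1/\sum w_i^2} falls below the configured fraction of the
#' particle count; output weights are uniform after resampling.
#'
#' @param p A \code{particles} set with normalized weights.
#' @param config A [tracker_config()].
#' @return A \code{particles} set.
#' @export
pf_resample <- function(p, config) {
  n <- nrow(p)
  ess <- 1 / sum(p$weight^2)
  if (ess >= config$resample_ess_fraction * n) return(p)
  idx <- systematic_resample_index(p$weight)
  particles(p$x[idx], p$y[idx], p$vx[idx], p$vy[idx], p$visible[idx],
            rep(1 / n, n))
}

systematic_resample_index <- function(w) {
  n <- length(w)
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(w) / sum(w)) + 1L
}

#' Track the wristband through a frame sequence
#'
#' Runs the full bootstrap filter. The per-frame estimate is the
#' weight-averaged position of the visible-flagged particles; a frame is
#' emitted as missing when the weighted visible fraction or the best raw
#' similarity drops below the likelihood floor. Tracking is combined with
#' detection: when the filter has lost the target but the frame contains a
#' strong color response, half of the particles are re-seeded at the
#' detection. Deterministic given \code{config$seed}.
#'
#' @param frames A \code{frame_sequence} from [make_video()] or a plain list
#'   of height x width x 3 arrays.
#' @param config A [tracker_config()].
#' @param fps Frame rate recorded on the output (taken from the
#'   \code{frame_sequence} when available). Default 25.
#' @return A \code{trajectory} in scene coordinates (unit box).
#' @export
track <- function(frames, config = tracker_config(), fps = 25) {
  if (inherits(frames, "frame_sequence")) {
    fps <- frames$fps
    frames <- frames$frames
  }
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  set.seed(config$seed)
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  n <- config$n_particles

  map1 <- similarity_map(frames[[1]], config)
  det <- which(map1 == max(map1), arr.ind = TRUE)[1, ]
  if (max(map1) >= config$likelihood_floor) {
    p <- particles(stats::rnorm(n, det["col"], 2),
                   stats::rnorm(n, det["row"], 2),
                   stats::rnorm(n, 0, config$vel_noise_sd),
                   stats::rnorm(n, 0, config$vel_noise_sd),
                   rep(TRUE, n))
  } else {
    p <- particles(stats::runif(n, 1, w), stats::runif(n, 1, h),
                   stats::rnorm(n, 0, config$vel_noise_sd),
                   stats::rnorm(n, 0, config$vel_noise_sd),
                   rep(FALSE, n))
  }

  est <- matrix(NA_real_, length(frames), 2)
  vis <- logical(length(frames))
  n_missing <- 0L
  for (t in seq_along(frames)) {
    map <- if (t == 1) map1 else similarity_map(frames[[t]], config)
    if (t > 1) p <- pf_predict(p, config)
    p$x <- pmin(pmax(p$x, 1), w)
    p$y <- pmin(pmax(p$y, 1), h)
    p <- pf_weigh(p, map, config)
    best <- attr(p, "best_likelihood")
    # detection-driven re-acquisition
    if (best < config$likelihood_floor &&
        max(map) >= config$likelihood_floor) {
      d <- which(map == max(map), arr.ind = TRUE)[1, ]
      k <- seq_len(floor(n / 2))
      p$x[k] <- stats::rnorm(length(k), d["col"], 2)
      p$y[k] <- stats::rnorm(length(k), d["row"], 2)
      p$vx[k] <- stats::rnorm(length(k), 0, config$vel_noise_sd)
      p$vy[k] <- stats::rnorm(length(k), 0, config$vel_noise_sd)
      p$visible[k] <- TRUE
      p <- pf_weigh(p, map, config)
      best <- attr(p, "best_likelihood")
    }
    vis_frac <- sum(p$weight[p$visible])
    if (any(p$visible) && vis_frac >= 0.5 &&
        best >= config$likelihood_floor) {
      wv <- p$weight[p$visible] / vis_frac
      est[t, 1] <- sum(p$x[p$visible] * wv)
      est[t, 2] <- sum(p$y[p$visible] * wv)
      vis[t] <- TRUE
    } else {
      n_missing <- n_missing + 1L
    }
    p <- pf_resample(p, config)
  }
  dyad_log("tracked %d frame(s), %d missing", length(frames), n_missing)
  trajectory(seq_along(frames) - 1L,
             (est[, 1] - 1) / (w - 1), (est[, 2] - 1) / (h - 1),
             vis, fps = fps)
}

#' Rescale a trajectory with a fixed reference length
#'
#' Camera zoom differs across recordings; a reference object of known
#' physical size present in every scene gives a per-recording scale. All
#' coordinates are multiplied by \code{reference_canonical /
#' reference_measured} and the factor is stored on the trajectory.
#'
#' @param traj A \code{trajectory}.
#' @param reference_measured Measured reference length in trajectory units.
#' @param reference_canonical Canonical reference length.
#' @return The rescaled \code{trajectory}.
#' @export
normalize_trajectory <- function(traj, reference_measured,
                                 reference_canonical) {
  if (!is.numeric(reference_measured) || reference_measured <= 0 ||
      !is.numeric(reference_canonical) || reference_canonical <= 0) {
    stop("reference lengths must be positive", call. = FALSE)
  }
  f <- reference_canonical / reference_measured
  out <- trajectory(traj$frame, traj$x * f, traj$y * f, traj$visible,
                    fps = traj_fps(traj),
                    normalization_factor = attr(traj, "normalization_factor") * f)
  out
}
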