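#' Pipeline run configuration
#'
#' Bundles every tunable constant of the analysis pipeline in one validated
#' list. Durations are integer milliseconds for annotation arithmetic and
#' seconds for trajectory-level quantities; the only conversion between
#' annotation time and frame indices goes through \code{fps}.
#'
#' @param fps Video frame rate in frames per second. Default 25.
#' @param turn_gap_ms Maximum within-speaker silence, in ms, that still joins
#'   two vocal segments into one speech turn (strictly less than). Default 150.
#' @param silence_min_ms Minimum duration, in ms, for a joint silence to be
#'   counted (strictly greater than). Default 150.
#' @param synchrony_window_ms Response window after a mother vocalization
#'   offset within which an infant vocalization onset counts as a response.
#'   Default 3000.
#' @param pause_min_s Minimum duration, in seconds, of a hand-movement pause.
#'   Default 4.
#' @param pause_speed_threshold Speed threshold below which the hand counts as
#'   motionless, expressed as a fraction of the trajectory's own maximum
#'   smoothed speed. Default 0.02. See also \code{pause_speed_absolute}.
#' @param pause_speed_absolute Optional absolute speed threshold (scene
#'   units/s) overriding the relative one when not \code{NA}.
#' @param smooth_frames Width, in frames, of the centered moving average
#'   applied before differentiating trajectories (200 ms at 25 fps). Default 5.
#' @param fusion_lambda Weight of the segmental (cepstral) stream in the
#'   motherese score fusion; the prosodic stream gets \code{1 - fusion_lambda}.
#'   Default 0.4.
#' @param gmm_components_segmental Gaussians per class for the segmental
#'   stream. Default 12.
#' @param gmm_components_suprasegmental Gaussians per class for the prosodic
#'   stream. Default 15.
#' @param pca_variance_kept Fraction of variance the retained principal
#'   components must explain. Default 0.95.
#' @param pca_outside_loo If \code{TRUE}, fit the PCA once on the full table
#'   instead of refitting inside every leave-one-out fold. Default \code{FALSE}.
#' @param classify_on Feature space consumed by the decision stump:
#'   \code{"pca"} (default) or \code{"raw"}.
#' @param missing_policy Either \code{"impute"} (training-fold mean imputation,
#'   default) or \code{"drop_incomplete"} (discard rows with missing features).
#' @param count_atypical_as_response Whether atypical infant vocalizations
#'   count as synchrony responses. Default \code{FALSE}.
#' @param random_seed Integer seed used by any stochastic stage. Default 1.
#'
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(fps = 25,
                       turn_gap_ms = 150,
                       silence_min_ms = 150,
                       synchrony_window_ms = 3000,
                       pause_min_s = 4,
                       pause_speed_threshold = 0.02,
                       pause_speed_absolute = NA_real_,
                       smooth_frames = 5,
                       fusion_lambda = 0.4,
                       gmm_components_segmental = 12,
                       gmm_components_suprasegmental = 15,
                       pca_variance_kept = 0.95,
                       pca_outside_loo = FALSE,
                       classify_on = c("pca", "raw"),
                       missing_policy = c("impute", "drop_incomplete"),
                       count_atypical_as_response = FALSE,
                       random_seed = 1L) {
  classify_on <- match.arg(classify_on)
  missing_policy <- match.arg(missing_policy)
  cfg <- list(
    fps = fps, turn_gap_ms = turn_gap_ms, silence_min_ms = silence_min_ms,
    synchrony_window_ms = synchrony_window_ms, pause_min_s = pause_min_s,
    pause_speed_threshold = pause_speed_threshold,
    pause_speed_absolute = pause_speed_absolute,
    smooth_frames = smooth_frames,
    fusion_lambda = fusion_lambda,
    gmm_components_segmental = gmm_components_segmental,
    gmm_components_suprasegmental = gmm_components_suprasegmental,
    pca_variance_kept = pca_variance_kept,
    pca_outside_loo = isTRUE(pca_outside_loo),
    classify_on = classify_on,
    missing_policy = missing_policy,
    count_atypical_as_response = isTRUE(count_atypical_as_response),
    random_seed = as.integer(random_seed)
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  pos <- c("fps", "turn_gap_ms", "silence_min_ms", "synchrony_window_ms",
           "pause_min_s", "pause_speed_threshold", "smooth_frames",
           "gmm_components_segmental", "gmm_components_suprasegmental")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("run_config: '", nm, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$fusion_lambda < 0 || cfg$fusion_lambda > 1) {
    stop("run_config: 'fusion_lambda' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$pca_variance_kept <= 0 || cfg$pca_variance_kept > 1) {
    stop("run_config: 'pca_variance_kept' must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read or write a run configuration as a YAML key/value file
#'
#' Only keys that are arguments of [run_config()] are accepted; missing keys
#' fall back to the defaults.
#'
#' @param path File path.
#' @return For \code{read_config}, a \code{run_config}; \code{write_config}
#'   returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("read_config: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config A \code{run_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

dyad_log <- function(...) {
  message("[dyadimaging] ", sprintf(...))
}
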