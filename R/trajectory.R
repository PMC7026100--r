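#' 2D hand trajectory with per-frame visibility
#'
#' A trajectory is a data frame with columns \code{frame} (strictly
#' increasing integer index), \code{x}, \code{y} (scene coordinates, defined
#' only where \code{visible} is \code{TRUE}) and \code{visible}. The frame
#' rate and the zoom-normalization factor travel as attributes. At the
#' standard 25 fps a 60-s recording yields 1500 coordinate pairs.
#'
#' @param frame Integer frame indices.
#' @param x,y Numeric coordinates; \code{NA} where not visible.
#' @param visible Logical visibility flags.
#' @param fps Frames per second (default 25).
#' @param normalization_factor Scale factor already applied (1 until
#'   [normalize_trajectory()] is used).
#' @return A \code{data.frame} of class \code{"trajectory"}.
#' @export
trajectory <- function(frame, x, y, visible, fps = 25,
                       normalization_factor = 1) {
  frame <- as.integer(frame)
  if (anyDuplicated(frame)) stop("duplicate frame index", call. = FALSE)
  o <- order(frame)
  df <- data.frame(frame = frame[o], x = as.numeric(x)[o],
                   y = as.numeric(y)[o], visible = as.logical(visible)[o])
  df$x[!df$visible] <- NA_real_
  df$y[!df$visible] <- NA_real_
  if (any(df$visible & (is.na(df$x) | is.na(df$y)))) {
    stop("visible frames must have defined coordinates", call. = FALSE)
  }
  attr(df, "fps") <- fps
  attr(df, "normalization_factor") <- normalization_factor
  class(df) <- c("trajectory", "data.frame")
  df
}

traj_fps <- function(traj) attr(traj, "fps")

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "2D trajectory: %d frames at %g fps (%.1f s), %.1f%% visible, norm %.3g\n",
    nrow(x), traj_fps(x), nrow(x) / traj_fps(x),
    100 * mean(x$visible), attr(x, "normalization_factor")))
  invisible(x)
}

#' Read or write a trajectory CSV
#'
#' The on-disk format has columns \code{frame,x,y,visible}; invisible frames
#' carry empty coordinate fields. The frame rate and normalization factor are
#' stored in \code{#}-prefixed header comments so a written file reads back
#' identically.
#'
#' @param path CSV file.
#' @param fps Frame rate to assume when the file carries no header comment.
#' @return A \code{trajectory} (reader); \code{path} invisibly (writer).
#' @export
read_trajectory <- function(path, fps = 25) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  norm <- 1
  for (m in meta) {
    kv <- strsplit(sub("^#\\s*", "", m), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] == "fps") fps <- as.numeric(kv[2])
    if (length(kv) == 2 && kv[1] == "normalization_factor") {
      norm <- as.numeric(kv[2])
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("frame", "x", "y", "visible")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV needs columns frame,x,y,visible", call. = FALSE)
  }
  trajectory(df$frame, df$x, df$y, as.logical(df$visible),
             fps = fps, normalization_factor = norm)
}

#' @rdname read_trajectory
#' @param traj A \code{trajectory}.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fps=%.10g", traj_fps(traj)),
    sprintf("# normalization_factor=%.17g",
            attr(traj, "normalization_factor")),
    "frame,x,y,visible",
    sprintf("%d,%s,%s,%s", traj$frame,
            ifelse(traj$visible, sprintf("%.17g", traj$x), ""),
            ifelse(traj$visible, sprintf("%.17g", traj$y), ""),
            ifelse(traj$visible, "TRUE", "FALSE"))
  ), con)
  invisible(path)
}
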