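#' Extract the multimodal feature table of a cohort
#'
#' Runs the audio and vision feature stages on every dyad: speech turns are
#' merged from the annotation timeline and summarized into the 16
#' speech-turn-taking features (prefixed \code{stt_}); the 60-s analysis
#' window is selected from the trajectory and summarized into the 21
#' hand-movement descriptors (prefixed \code{hm_}).
#'
#' @param cohort A \code{dyad_cohort} from [make_cohort()].
#' @param config A [run_config()].
#' @return A data frame with \code{dyad_id}, \code{group} and 37 feature
#'   columns.
#' @export
cohort_features <- function(cohort, config = run_config()) {
  spec <- attr(cohort, "spec")
  rows <- lapply(cohort, function(d) {
    tl <- merge_turns(d$timeline,
                      duration_ms = if (!is.null(spec)) {
                        spec$audio_duration_s * 1000
                      } else NULL,
                      gap_ms = config$turn_gap_ms, dyad_id = d$dyad_id)
    stt <- stt_features(tl, config)
    hm <- motion_features(select_window(d$trajectory), config)
    cbind(data.frame(dyad_id = d$dyad_id, group = d$group,
                     stringsAsFactors = FALSE),
          as.data.frame(t(c(stats::setNames(stt, paste0("stt_", names(stt))),
                            stats::setNames(hm, paste0("hm_", names(hm)))))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dyad_log("extracted %d feature(s) for %d dyad(s)", ncol(out) - 2, nrow(out))
  out
}

#' Binary labels for the two study contrasts
#'
#' \code{"ws_vs_td"} labels every at-risk dyad (WSminus or WSplus) "WS"
#' against "TD"; \code{"wsplus_vs_wsminus"} keeps only the at-risk dyads.
#'
#' @param groups Character vector of group labels ("TD", "WSminus",
#'   "WSplus").
#' @param mode The contrast.
#' @return List: \code{labels} (factor) and \code{keep} (logical row mask).
#' @export
contrast_labels <- function(groups, mode = c("ws_vs_td",
                                             "wsplus_vs_wsminus")) {
  mode <- match.arg(mode)
  if (mode == "ws_vs_td") {
    keep <- rep(TRUE, length(groups))
    labels <- factor(ifelse(groups == "TD", "TD", "WS"),
                     levels = c("TD", "WS"))
  } else {
    keep <- groups %in% c("WSminus", "WSplus")
    labels <- factor(groups[keep], levels = c("WSminus", "WSplus"))
  }
  list(labels = labels, keep = keep)
}

#' Run classification on a feature table
#'
#' Convenience wrapper: selects the contrast, runs [loo_evaluate()] on the
#' feature columns and [feature_class_correlations()] on the raw features.
#'
#' @param features A feature table from [cohort_features()] (or any data
#'   frame with \code{dyad_id}, \code{group} and feature columns).
#' @param mode Contrast, see [contrast_labels()].
#' @param config A [run_config()].
#' @return List: \code{result} (a \code{classification_result}) and
#'   \code{correlations}.
#' @export
classify_cohort <- function(features, mode = "ws_vs_td",
                            config = run_config()) {
  cl <- contrast_labels(features$group, mode)
  feat_cols <- setdiff(names(features), c("dyad_id", "group"))
  x <- features[cl$keep, feat_cols, drop = FALSE]
  list(
    result = loo_evaluate(x, cl$labels, config,
                          dyad_id = features$dyad_id[cl$keep]),
    correlations = feature_class_correlations(x, cl$labels)
  )
}
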