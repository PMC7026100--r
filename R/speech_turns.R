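#' Speech-turn timeline of one dyad
#'
#' Holds the merged speech turns of both partners: a turn is a maximal
#' same-speaker, same-category vocal stream containing no internal silence of
#' 150 ms or more. Intervals are half-open \code{[onset, offset)} integer ms.
#'
#' @param turns An \code{annotations}-shaped data frame of merged turns.
#' @param duration_ms Total interaction duration.
#' @param dyad_id Identifier.
#' @return A list of class \code{"speech_timeline"}.
#' @export
speech_timeline <- function(turns, duration_ms, dyad_id = "") {
  stopifnot(duration_ms >= 0)
  if (nrow(turns) > 0 && any(turns$offset_ms > duration_ms)) {
    stop("turns extend beyond duration_ms", call. = FALSE)
  }
  structure(list(dyad_id = dyad_id, duration_ms = duration_ms,
                 turns = turns),
            class = "speech_timeline")
}

#' @export
print.speech_timeline <- function(x, ...) {
  cat(sprintf("Speech timeline%s: %.1f s, %d turn(s)\n",
              if (nzchar(x$dyad_id)) paste0(" ", x$dyad_id) else "",
              x$duration_ms / 1000, nrow(x$turns)))
  invisible(x)
}

#' Merge raw vocal segments into speech turns
#'
#' Same-speaker, same-category segments separated by strictly less than
#' \code{gap_ms} of silence are merged into one turn (overlapping raw
#' segments merge too); categories are never merged across each other. A
#' merged turn inherits the motherese label of its longest constituent.
#'
#' @param records An \code{annotations} table.
#' @param duration_ms Interaction duration; defaults to the latest offset.
#' @param gap_ms Merge threshold in ms (strict \code{<}). Default 150.
#' @param dyad_id Identifier carried onto the timeline.
#' @return A \code{speech_timeline}.
#' @export
merge_turns <- function(records, duration_ms = NULL, gap_ms = 150,
                        dyad_id = "") {
  validate_annotations(records)
  if (is.null(duration_ms)) {
    duration_ms <- if (nrow(records) > 0) max(records$offset_ms) else 0
  }
  mot <- if ("motherese" %in% names(records)) records$motherese
         else rep("unlabeled", nrow(records))
  out <- NULL
  for (sp in SPEAKERS) {
    sp_all <- which(records$speaker == sp)
    for (cat in CATEGORIES) {
      idx <- which(records$speaker == sp & records$category == cat)
      if (length(idx) == 0) next
      # a gap is only silence if no other segment of this speaker sits in it
      other <- setdiff(sp_all, idx)
      gap_blocked <- function(from, to) {
        length(other) > 0 &&
          any(records$onset_ms[other] < to & records$offset_ms[other] > from)
      }
      idx <- idx[order(records$onset_ms[idx], records$offset_ms[idx])]
      on <- records$onset_ms[idx]; off <- records$offset_ms[idx]
      lab <- mot[idx]
      g_on <- on[1]; g_off <- off[1]
      g_lab <- lab[1]; g_len <- off[1] - on[1]
      flush <- function() {
        out <<- rbind(out, data.frame(
          speaker = sp, category = cat, onset_ms = g_on, offset_ms = g_off,
          motherese = g_lab, stringsAsFactors = FALSE))
      }
      for (k in seq_along(idx)[-1]) {
        if (on[k] - g_off < gap_ms && !gap_blocked(g_off, on[k])) {
          g_off <- max(g_off, off[k])
          if (off[k] - on[k] > g_len) {
            g_len <- off[k] - on[k]; g_lab <- lab[k]
          }
        } else {
          flush()
          g_on <- on[k]; g_off <- off[k]; g_lab <- lab[k]
          g_len <- off[k] - on[k]
        }
      }
      flush()
    }
  }
  if (is.null(out)) {
    out <- data.frame(speaker = character(), category = character(),
                      onset_ms = integer(), offset_ms = integer(),
                      motherese = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$onset_ms, out$offset_ms, out$speaker), , drop = FALSE]
  rownames(out) <- NULL
  speech_timeline(out, duration_ms, dyad_id)
}

# --- interval helpers (matrices with columns onset, offset; half-open) ----

union_intervals <- function(on, off) {
  if (length(on) == 0) return(cbind(onset = numeric(), offset = numeric()))
  o <- order(on, off)
  on <- on[o]; off <- off[o]
  res_on <- on[1]; res_off <- off[1]
  for (k in seq_along(on)[-1]) {
    if (on[k] <= res_off[length(res_off)]) {
      res_off[length(res_off)] <- max(res_off[length(res_off)], off[k])
    } else {
      res_on <- c(res_on, on[k]); res_off <- c(res_off, off[k])
    }
  }
  cbind(onset = res_on, offset = res_off)
}

complement_intervals <- function(iv, duration) {
  if (nrow(iv) == 0) {
    return(cbind(onset = 0, offset = duration)[duration > 0, , drop = FALSE])
  }
  on <- c(0, iv[, "offset"])
  off <- c(iv[, "onset"], duration)
  keep <- off > on
  cbind(onset = on[keep], offset = off[keep])
}

intersect_duration <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, "onset"], b[, "onset"])
    hi <- pmin(a[i, "offset"], b[, "offset"])
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}

speaker_union <- function(timeline, speaker) {
  t <- timeline$turns
  idx <- t$speaker == speaker
  union_intervals(t$onset_ms[idx], t$offset_ms[idx])
}

#' Pauses of one speaker
#'
#' The complement of the speaker's vocal activity within the interaction:
#' every moment this partner is not producing any sound.
#'
#' @param timeline A \code{speech_timeline}.
#' @param speaker "mother" or "infant".
#' @return List: \code{intervals} (ms matrix) and \code{ratio} = total pause
#'   time / interaction duration.
#' @export
speaker_pauses <- function(timeline, speaker) {
  speaker <- match.arg(speaker, SPEAKERS)
  iv <- complement_intervals(speaker_union(timeline, speaker),
                             timeline$duration_ms)
  list(intervals = iv,
       ratio = if (timeline$duration_ms > 0) {
         sum(iv[, "offset"] - iv[, "onset"]) / timeline$duration_ms
       } else NA_real_)
}

#' Dyadic silences
#'
#' Maximal intervals during which neither partner vocalizes for strictly
#' more than \code{min_ms} milliseconds.
#'
#' @param timeline A \code{speech_timeline}.
#' @param min_ms Minimum silence duration (strict \code{>}). Default 150.
#' @return List: \code{intervals} and \code{silenceRatio} (total counted
#'   silence / duration).
#' @export
silences <- function(timeline, min_ms = 150) {
  t <- timeline$turns
  occupied <- union_intervals(t$onset_ms, t$offset_ms)
  iv <- complement_intervals(occupied, timeline$duration_ms)
  iv <- iv[iv[, "offset"] - iv[, "onset"] > min_ms, , drop = FALSE]
  list(intervals = iv,
       silenceRatio = if (timeline$duration_ms > 0) {
         sum(iv[, "offset"] - iv[, "onset"]) / timeline$duration_ms
       } else NA_real_)
}

#' Vocal overlap ratio of the dyad
#'
#' Fraction of the interaction during which both partners vocalize
#' simultaneously.
#'
#' @param timeline A \code{speech_timeline}.
#' @return A real in \code{[0, 1]}.
#' @export
overlap_ratio <- function(timeline) {
  if (timeline$duration_ms <= 0) return(NA_real_)
  intersect_duration(speaker_union(timeline, "mother"),
                     speaker_union(timeline, "infant")) / timeline$duration_ms
}

#' Infant synchrony ratio
#'
#' Fraction of mother vocalizations answered by an infant vocalization onset
#' within the response window: a mother vocalization counts as responded iff
#' an infant vocalization starts in \code{(offset, offset + window_ms]}.
#' Each infant onset is attributed to the earliest mother vocalization whose
#' window contains it (so an onset lying in two overlapping windows answers
#' only the earlier one), and each mother vocalization is counted at most
#' once however many responses it receives. Subsets restrict the mother
#' vocalizations to those labeled motherese or other speech; attribution is
#' always computed against all mother vocalizations first, which keeps the
#' overall ratio a count-weighted mean of the subset ratios.
#'
#' @param timeline A \code{speech_timeline} (motherese labels required for
#'   the subsets).
#' @param window_ms Response window in ms. Default 3000.
#' @param subset "all", "motherese" or "non_motherese".
#' @param count_atypical Whether atypical infant vocalizations count as
#'   responses. Default FALSE.
#' @return Responded fraction in \code{[0,1]}; \code{NA} when the subset
#'   contains no mother vocalization.
#' @export
synchrony_ratio <- function(timeline, window_ms = 3000,
                            subset = c("all", "motherese", "non_motherese"),
                            count_atypical = FALSE) {
  subset <- match.arg(subset)
  t <- timeline$turns
  mv <- t[t$speaker == "mother" & t$category == "vocalization", , drop = FALSE]
  in_subset <- switch(subset,
    all = rep(TRUE, nrow(mv)),
    motherese = mv$motherese == "motherese",
    non_motherese = mv$motherese == "other_speech")
  if (sum(in_subset) == 0) return(NA_real_)
  resp_cat <- c("vocalization", if (count_atypical) "atypical_vocalization")
  onsets <- t$onset_ms[t$speaker == "infant" & t$category %in% resp_cat]
  ord <- order(mv$offset_ms)
  responded <- rep(FALSE, nrow(mv))
  for (on in onsets) {
    hit <- ord[which(mv$offset_ms[ord] < on &
                     on <= mv$offset_ms[ord] + window_ms)]
    if (length(hit) > 0) responded[hit[1]] <- TRUE
  }
  sum(responded & in_subset) / sum(in_subset)
}

#' The 16 speech-turn-taking features of a dyad
#'
#' Counts and occupancy ratios per partner and category, the three dyadic
#' features (silence, overlap, infant synchrony), and the motherese-split
#' ratios. Motherese-dependent fields are \code{NA} when no mother
#' vocalization carries a motherese label.
#'
#' @param timeline A \code{speech_timeline}.
#' @param config A [run_config()].
#' @return Named numeric vector of length 16.
#' @export
stt_features <- function(timeline, config = run_config()) {
  dur <- timeline$duration_ms
  if (dur <= 0) stop("zero-duration timeline", call. = FALSE)
  t <- timeline$turns
  dsum <- function(idx) sum(t$offset_ms[idx] - t$onset_ms[idx])
  m_voc <- t$speaker == "mother" & t$category == "vocalization"
  m_noise <- t$speaker == "mother" & t$category == "other_noise"
  i_voc <- t$speaker == "infant" & t$category == "vocalization"
  i_atyp <- t$speaker == "infant" & t$category == "atypical_vocalization"
  labeled <- any(m_voc & t$motherese != "unlabeled")
  sync <- function(sub) {
    synchrony_ratio(timeline, config$synchrony_window_ms, sub,
                    config$count_atypical_as_response)
  }
  out <- c(
    motherVocCount = sum(m_voc),
    motherVocRatio = dsum(m_voc) / dur,
    motherNoiseRatio = dsum(m_noise) / dur,
    motherInterventionRatio = dsum(m_voc | m_noise) / dur,
    infantVocCount = sum(i_voc),
    infantVocRatio = dsum(i_voc) / dur,
    infantAtypicalRatio = dsum(i_atyp) / dur,
    motherPauseRatio = speaker_pauses(timeline, "mother")$ratio,
    infantPauseRatio = speaker_pauses(timeline, "infant")$ratio,
    silenceRatio = silences(timeline, config$silence_min_ms)$silenceRatio,
    overlapRatio = overlap_ratio(timeline),
    infantSynchronyRatio = sync("all"),
    mothereseRatio = if (labeled) {
      dsum(m_voc & t$motherese == "motherese") / dur
    } else NA_real_,
    nonMothereseRatio = if (labeled) {
      dsum(m_voc & t$motherese == "other_speech") / dur
    } else NA_real_,
    synchronyMothereseRatio = if (labeled) sync("motherese") else NA_real_,
    synchronyNonMothereseRatio = if (labeled) sync("non_motherese")
                                 else NA_real_
  )
  stopifnot(length(out) == 16)
  out
}
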