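#' Dyadic vocal annotation records
#'
#' An annotation table holds one row per labeled vocal segment of a
#' mother-infant interaction: \code{speaker} ("mother" or "infant"),
#' \code{category} ("vocalization", "other_noise" for mother non-speech
#' sounds, "atypical_vocalization" for unusual infant productions),
#' half-open interval \code{[onset_ms, offset_ms)} in integer milliseconds,
#' and an optional \code{motherese} label ("motherese", "other_speech" or
#' "unlabeled") carried only by mother vocalizations.
#'
#' @param speaker Character vector, "mother" or "infant".
#' @param category Character vector of segment categories.
#' @param onset_ms,offset_ms Integer millisecond interval endpoints.
#' @param motherese Optional motherese labels; defaults to "unlabeled".
#' @return A \code{data.frame} of class \code{"annotations"}, sorted by onset.
#' @export
annotations <- function(speaker = character(), category = character(),
                        onset_ms = integer(), offset_ms = integer(),
                        motherese = NULL) {
  if (is.null(motherese)) motherese <- rep("unlabeled", length(speaker))
  df <- data.frame(
    speaker = as.character(speaker),
    category = as.character(category),
    onset_ms = as.integer(round(onset_ms)),
    offset_ms = as.integer(round(offset_ms)),
    motherese = as.character(motherese),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$onset_ms, df$offset_ms, df$speaker), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotations", "data.frame")
  validate_annotations(df)
}

SPEAKERS <- c("mother", "infant")
CATEGORIES <- c("vocalization", "other_noise", "atypical_vocalization")
MOTHERESE_LABELS <- c("motherese", "other_speech", "unlabeled")

#' Validate an annotation table's invariants
#'
#' Checks speaker/category domains, strictly positive durations,
#' non-negative onsets, and the speaker-category pairing rules
#' (other_noise is mother-only, atypical_vocalization infant-only).
#'
#' @param df An annotation table.
#' @return \code{df} invisibly if valid; otherwise an error.
#' @export
validate_annotations <- function(df) {
  need <- c("speaker", "category", "onset_ms", "offset_ms")
  if (!all(need %in% names(df))) {
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (!all(df$speaker %in% SPEAKERS)) {
    stop("unknown speaker label(s): ",
         paste(unique(setdiff(df$speaker, SPEAKERS)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$category %in% CATEGORIES)) {
    stop("unknown category label(s): ",
         paste(unique(setdiff(df$category, CATEGORIES)), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$onset_ms < 0)) stop("negative onset_ms", call. = FALSE)
  if (any(df$offset_ms <= df$onset_ms)) {
    stop("every record needs offset_ms > onset_ms", call. = FALSE)
  }
  if (any(df$category == "other_noise" & df$speaker != "mother")) {
    stop("'other_noise' is a mother-only category", call. = FALSE)
  }
  if (any(df$category == "atypical_vocalization" & df$speaker != "infant")) {
    stop("'atypical_vocalization' is an infant-only category", call. = FALSE)
  }
  if ("motherese" %in% names(df) &&
      !all(df$motherese %in% MOTHERESE_LABELS)) {
    stop("unknown motherese label(s)", call. = FALSE)
  }
  invisible(df)
}

#' Read dyadic vocal annotations
#'
#' Parses either the canonical tab-separated dialect (columns
#' \code{speaker}, \code{category}, \code{onset_ms}, \code{offset_ms},
#' optional \code{motherese}) or a small subset of ELAN's EAF XML in which
#' the tier id names the speaker and the annotation value the category.
#' Records are returned sorted by onset. Raw same-speaker overlaps are
#' tolerated here; they are merged downstream by [merge_turns()].
#'
#' @param path File to read.
#' @param dialect \code{"tsv"} (default) or \code{"eaf_subset"}.
#' @return An \code{annotations} table.
#' @export
read_annotations <- function(path, dialect = c("tsv", "eaf_subset")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- switch(dialect,
    tsv = read_annotations_tsv(path),
    eaf_subset = read_annotations_eaf(path)
  )
  dyad_log("read %d annotation record(s) from %s", nrow(rec), path)
  rec
}

read_annotations_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(annotations())
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:4],
                 c("speaker", "category", "onset_ms", "offset_ms"))) {
    stop("malformed TSV header at line 1 of ", path, call. = FALSE)
  }
  has_mot <- length(header) >= 5 && header[5] == "motherese"
  body <- lines[-1]
  if (length(body) == 0) return(annotations())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- 4L + as.integer(has_mot)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != nf) {
      stop("malformed TSV row at line ", i + 1, " of ", path, call. = FALSE)
    }
  }
  m <- do.call(rbind, parts)
  on <- suppressWarnings(as.integer(m[, 3]))
  off <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(on) | is.na(off))
  if (length(bad) > 0) {
    stop("non-integer time at line ", bad[1] + 1, " of ", path, call. = FALSE)
  }
  annotations(
    speaker = m[, 1], category = m[, 2], onset_ms = on, offset_ms = off,
    motherese = if (has_mot) m[, 5] else NULL
  )
}

# EAF subset: TIER elements whose TIER_ID is "mother" or "infant";
# ALIGNABLE_ANNOTATIONs point into the TIME_ORDER slot table; the
# ANNOTATION_VALUE text is "<category>" or "<category>|<motherese>".
read_annotations_eaf <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed EAF XML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_ms <- stats::setNames(
    as.integer(xml2::xml_attr(slots, "TIME_VALUE")),
    xml2::xml_attr(slots, "TIME_SLOT_ID")
  )
  speaker <- character(); category <- character()
  onset <- integer(); offset <- integer(); mot <- character()
  for (tier in xml2::xml_find_all(doc, ".//TIER")) {
    sp <- xml2::xml_attr(tier, "TIER_ID")
    anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
    for (a in anns) {
      t1 <- slot_ms[[xml2::xml_attr(a, "TIME_SLOT_REF1")]]
      t2 <- slot_ms[[xml2::xml_attr(a, "TIME_SLOT_REF2")]]
      val <- xml2::xml_text(xml2::xml_find_first(a, ".//ANNOTATION_VALUE"))
      bits <- strsplit(val, "|", fixed = TRUE)[[1]]
      speaker <- c(speaker, sp)
      category <- c(category, bits[[1]])
      onset <- c(onset, t1); offset <- c(offset, t2)
      mot <- c(mot, if (length(bits) > 1) bits[[2]] else "unlabeled")
    }
  }
  annotations(speaker, category, onset, offset, mot)
}

#' Write dyadic vocal annotations
#'
#' Inverse of [read_annotations()]: TSV is the canonical on-disk dialect; the
#' EAF-subset writer emits just enough ELAN XML for the subset reader.
#' Reading a written file back yields identical records.
#'
#' @param records An \code{annotations} table.
#' @param path Output file.
#' @param dialect \code{"tsv"} (default) or \code{"eaf_subset"}.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(records, path, dialect = c("tsv", "eaf_subset")) {
  dialect <- match.arg(dialect)
  validate_annotations(records)
  if (dialect == "tsv") {
    header <- "speaker\tcategory\tonset_ms\toffset_ms\tmotherese"
    mot <- if ("motherese" %in% names(records)) records$motherese
           else rep("unlabeled", nrow(records))
    rows <- sprintf("%s\t%s\t%d\t%d\t%s", records$speaker, records$category,
                    records$onset_ms, records$offset_ms, mot)
    writeLines(c(header, rows), path)
  } else {
    write_annotations_eaf(records, path)
  }
  invisible(path)
}

write_annotations_eaf <- function(records, path) {
  mot <- if ("motherese" %in% names(records)) records$motherese
         else rep("unlabeled", nrow(records))
  times <- sort(unique(c(records$onset_ms, records$offset_ms)))
  slot_id <- stats::setNames(sprintf("ts%d", seq_along(times)), times)
  slot_xml <- sprintf('    <TIME_SLOT TIME_SLOT_ID="%s" TIME_VALUE="%d"/>',
                      slot_id, times)
  tier_xml <- character()
  for (sp in SPEAKERS) {
    idx <- which(records$speaker == sp)
    ann <- sprintf(paste0(
      '      <ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a%d" ',
      'TIME_SLOT_REF1="%s" TIME_SLOT_REF2="%s">',
      '<ANNOTATION_VALUE>%s</ANNOTATION_VALUE>',
      '</ALIGNABLE_ANNOTATION></ANNOTATION>'),
      idx,
      slot_id[as.character(records$onset_ms[idx])],
      slot_id[as.character(records$offset_ms[idx])],
      ifelse(mot[idx] == "unlabeled", records$category[idx],
             paste0(records$category[idx], "|", mot[idx])))
    tier_xml <- c(tier_xml,
                  sprintf('  <TIER TIER_ID="%s">', sp), ann, "  </TIER>")
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT>',
    '  <TIME_ORDER>', slot_xml, '  </TIME_ORDER>',
    tier_xml,
    '</ANNOTATION_DOCUMENT>'
  ), path)
  invisible(path)
}
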