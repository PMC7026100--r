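# Independent brute-force oracles used to validate the package's
# implementations on small random instances. Deliberately naive.

as_num_mat <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  unname(m)
}

oracle_farthest_pair <- function(x, y) {
  best <- 0
  n <- length(x)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d > best) best <- d
    }
  }
  best
}

# maximal sub-threshold runs by a frame-by-frame scan
oracle_pause_runs <- function(speed, fps, threshold, min_dur_s) {
  below <- !is.na(speed) & speed < threshold
  out <- NULL
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      if ((j - i + 1) / fps >= min_dur_s) {
        out <- rbind(out, c(start_s = (i - 1) / fps, end_s = j / fps))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) matrix(numeric(), ncol = 2,
                           dimnames = list(NULL, c("start_s", "end_s")))
  else out
}

# transitive closure of the "separated by < gap of true silence" relation,
# per speaker/category, by repeated pairwise merging until a fixed point; a
# gap is not silence if another same-speaker segment (any category)
# intersects it
oracle_merge <- function(records, gap_ms) {
  segs <- split(seq_len(nrow(records)),
                paste(records$speaker, records$category))
  out <- NULL
  for (idx in segs) {
    sp <- records$speaker[idx[1]]
    other <- setdiff(which(records$speaker == sp), idx)
    blocked <- function(from, to) {
      length(other) > 0 &&
        any(records$onset_ms[other] < to & records$offset_ms[other] > from)
    }
    iv <- cbind(records$onset_ms[idx], records$offset_ms[idx])
    repeat {
      merged <- FALSE
      for (i in seq_len(nrow(iv))) {
        for (j in seq_len(nrow(iv))) {
          if (i == j || is.na(iv[i, 1]) || is.na(iv[j, 1])) next
          lo <- min(iv[i, 2], iv[j, 2]); hi <- max(iv[i, 1], iv[j, 1])
          if (iv[j, 1] - iv[i, 2] < gap_ms && iv[i, 1] - iv[j, 2] < gap_ms &&
              !(hi > lo && blocked(lo, hi))) {
            iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
            iv[j, ] <- NA
            merged <- TRUE
          }
        }
      }
      if (!merged) break
    }
    iv <- iv[!is.na(iv[, 1]), , drop = FALSE]
    out <- rbind(out, cbind(iv, sp = match(sp, c("mother", "infant"))))
  }
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# overlap ratio by millisecond-grid occupancy counting
oracle_overlap_ratio <- function(timeline) {
  dur <- timeline$duration_ms
  m <- rep(FALSE, dur); i <- rep(FALSE, dur)
  t <- timeline$turns
  for (r in seq_len(nrow(t))) {
    idx <- (t$onset_ms[r] + 1):t$offset_ms[r]
    if (t$speaker[r] == "mother") m[idx] <- TRUE else i[idx] <- TRUE
  }
  sum(m & i) / dur
}

# exhaustive decision-stump training error over all features, all
# thresholds (every midpoint and the two outside positions), both polarities
oracle_stump_error <- function(x, y1) {
  best <- length(y1)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    cand <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
    for (thr in cand) {
      pred <- as.integer(x[, j] > thr)
      best <- min(best, sum(pred != y1), sum((1 - pred) != y1))
    }
  }
  best
}

random_annotations <- function(n, duration_ms = 60000) {
  on <- sort(sample.int(duration_ms - 1000, n))
  off <- pmin(on + sample(50:2000, n, replace = TRUE), duration_ms)
  speaker <- sample(c("mother", "infant"), n, replace = TRUE)
  # truncate same-speaker overlaps (onsets kept), as valid timelines require
  for (sp in c("mother", "infant")) {
    idx <- which(speaker == sp)
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        off[idx[k]] <- min(off[idx[k]], on[idx[k + 1]])
      }
    }
  }
  keep <- off > on
  on <- on[keep]; off <- off[keep]; speaker <- speaker[keep]
  n <- length(on)
  category <- ifelse(speaker == "mother",
                     sample(c("vocalization", "other_noise"), n, TRUE,
                            prob = c(0.8, 0.2)),
                     sample(c("vocalization", "atypical_vocalization"),
                            n, TRUE, prob = c(0.8, 0.2)))
  annotations(speaker, category, on, off,
              motherese = ifelse(
                speaker == "mother" & category == "vocalization",
                sample(c("motherese", "other_speech"), n, TRUE),
                "unlabeled"))
}
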