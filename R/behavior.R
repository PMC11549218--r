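#' Operant session accuracy
#'
#' Accuracy is 100 x correct-side nose pokes over all nose pokes (both
#' sides).  With zero pokes the value is undefined (`NA`).
#'
#' @param log A session log data frame with columns `time_s`, `event`
#'   (`poke_correct`, `poke_incorrect`, `pellet`, ...).
#' @return Percent accuracy, or `NA` if the session has no pokes.
#' @export
session_accuracy <- function(log) {
  stopifnot(is.data.frame(log), all(c("time_s", "event") %in% names(log)))
  nc <- sum(log$event == "poke_correct")
  ni <- sum(log$event == "poke_incorrect")
  if (nc + ni == 0) return(NA_real_)
  100 * nc / (nc + ni)
}

#' Acquisition day of an operant task
#'
#' The first training day on which accuracy reaches the criterion
#' (default 70%, inclusive).  A mouse that never reaches criterion by
#' `max_day` (default the fourteenth session) is a non-learner and gets
#' `NA`.
#'
#' @param daily_accuracies Ordered per-day percent accuracies.
#' @param criterion Percent criterion (default 70).
#' @param max_day Last session considered (default 14).
#' @return Integer day, or `NA` for a non-learner.
#' @export
acquisition_day <- function(daily_accuracies, criterion = 70, max_day = 14) {
  days <- seq_len(min(length(daily_accuracies), max_day))
  hit <- which(daily_accuracies[days] >= criterion)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1])
}

#' Progressive-ratio response schedule
#'
#' The escalating response requirements of the progressive-ratio
#' session: the n-th pellet requires `pr_schedule()[n]` correct pokes.
#'
#' @return Integer vector of 24 response requirements.
#' @export
pr_schedule <- function() {
  c(1, 2, 4, 6, 9, 12, 15, 20, 25, 32, 40, 50, 62, 77, 95, 118, 145, 178,
    219, 268, 328, 402, 492, 603)
}

#' Progressive-ratio breakpoint
#'
#' The last successfully completed response requirement: with `n` pellets
#' earned, `pr_schedule()[n]`.  Zero pellets give the 0 sentinel.
#'
#' @param log A PR session log data frame (events include `pellet`), or a
#'   single pellet count.
#' @param schedule Response-requirement sequence.
#' @return Integer breakpoint.
#' @export
pr_breakpoint <- function(log, schedule = pr_schedule()) {
  n <- if (is.data.frame(log)) sum(log$event == "pellet") else as.integer(log)
  if (n == 0) return(0L)
  if (n > length(schedule))
    stop("pr_breakpoint: ", n, " pellets exceeds the ", length(schedule),
         "-step schedule")
  as.integer(schedule[n])
}

#' Attentional gating index per 3-trial bin
#'
#' For a compound-cue test session, the index in each bin of trials is
#' the mean head-entry latency on novel-compound trials minus the mean
#' latency on familiar reward-cue trials (positive values mean the novel
#' distractor slowed retrieval).  Bins with a missing retrieval are
#' excluded and flagged.
#'
#' @param latencies Data frame with columns `cs` (`"novel"`/`"high"`) and
#'   `latency_s` (`NA` = no retrieval), trials in presentation order
#'   within each condition.
#' @param bin Trials per bin and condition (default 3).
#' @return Data frame: `bin`, `index_s`, `excluded`.
#' @export
attention_index <- function(latencies, bin = 3) {
  stopifnot(is.data.frame(latencies),
            all(c("cs", "latency_s") %in% names(latencies)))
  nov <- latencies$latency_s[latencies$cs == "novel"]
  hig <- latencies$latency_s[latencies$cs == "high"]
  if (length(nov) != length(hig))
    stop("attention_index: unequal trial counts per condition")
  n_bins <- length(nov) %/% bin
  out <- data.frame(bin = seq_len(n_bins), index_s = NA_real_,
                    excluded = FALSE)
  for (b in seq_len(n_bins)) {
    i <- ((b - 1) * bin + 1):(b * bin)
    if (anyNA(nov[i]) || anyNA(hig[i])) {
      out$excluded[b] <- TRUE
    } else {
      out$index_s[b] <- mean(nov[i]) - mean(hig[i])
    }
  }
  out
}

#' Centre occupancy of an open-field arena
#'
#' Fraction of samples whose x and y positions both fall in the middle
#' 10 of 16 infrared beams (the interior ~39% of the arena area).
#' Positions are accepted either as integer beam indices (1-16) or as
#' continuous coordinates, which are mapped to the beam grid by equal
#' partition of `arena_extent`.
#'
#' @param path Data frame with columns `x` and `y`.
#' @param n_beams Beams per axis (default 16).
#' @param center_beams Beams counted as centre per axis (default 10).
#' @param arena_extent Length-2 range of continuous coordinates
#'   (defaults to `c(0, n_beams)` for pre-binned integer input).
#' @return A list of class `center_occupancy`: `fraction`,
#'   `geometric_fraction` (`(10/16)^2`), `n_samples`.
#' @export
center_occupancy <- function(path, n_beams = 16, center_beams = 10,
                             arena_extent = NULL) {
  stopifnot(is.data.frame(path), all(c("x", "y") %in% names(path)))
  to_beam <- function(v) {
    if (is.null(arena_extent)) {
      if (any(v < 1 | v > n_beams))
        stop("center_occupancy: beam indices outside 1..", n_beams)
      as.integer(v)
    } else {
      w <- (v - arena_extent[1]) / diff(arena_extent)
      if (any(w < 0 | w > 1))
        stop("center_occupancy: coordinates outside the arena extent")
      pmin(n_beams, floor(w * n_beams) + 1L)
    }
  }
  bx <- to_beam(path$x); by <- to_beam(path$y)
  lo <- (n_beams - center_beams) / 2 + 1
  hi <- lo + center_beams - 1
  inside <- bx >= lo & bx <= hi & by >= lo & by <= hi
  structure(list(fraction = mean(inside),
                 geometric_fraction = (center_beams / n_beams)^2,
                 n_samples = nrow(path)),
            class = "center_occupancy")
}

#' @export
print.center_occupancy <- function(x, ...) {
  cat(sprintf("<center_occupancy> %.3f of %d samples (geometric %.1f%%)\n",
              x$fraction, x$n_samples, 100 * x$geometric_fraction))
  invisible(x)
}
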