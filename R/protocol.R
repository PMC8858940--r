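#' Define a Tabata work/rest protocol
#'
#' A Tabata session is a fixed number of stages, each consisting of an
#' all-out exercise bout followed by a standing interval. The classic
#' protocol is 8 stages of 20 s exercise + 10 s interval (4 min total),
#' analysed in non-overlapping 10-s windows.
#'
#' @param n_stages Number of stages (exercise + interval pairs).
#' @param exercise_s Exercise bout length in seconds.
#' @param interval_s Standing-interval length in seconds.
#' @param window_s Analysis window length in seconds; must divide both
#'   `exercise_s` and `interval_s`.
#'
#' @return An object of class `tabata_protocol`: a list with the four
#'   fields plus `duration_s`, the total session length.
#' @examples
#' tabata_protocol() # classic 8 x (20 + 10)
#' @export
tabata_protocol <- function(n_stages = 8, exercise_s = 20, interval_s = 10,
                            window_s = 10) {
  stopifnot(
    length(n_stages) == 1, length(exercise_s) == 1,
    length(interval_s) == 1, length(window_s) == 1
  )
  if (n_stages < 1 || exercise_s <= 0 || interval_s <= 0 || window_s <= 0) {
    stop("all protocol fields must be positive", call. = FALSE)
  }
  if (exercise_s %% window_s != 0 || interval_s %% window_s != 0) {
    stop("exercise_s and interval_s must each be divisible by window_s",
         call. = FALSE)
  }
  structure(
    list(
      n_stages = as.integer(n_stages),
      exercise_s = as.integer(exercise_s),
      interval_s = as.integer(interval_s),
      window_s = as.integer(window_s),
      duration_s = as.integer(n_stages * (exercise_s + interval_s))
    ),
    class = "tabata_protocol"
  )
}

#' @export
print.tabata_protocol <- function(x, ...) {
  cat(sprintf(
    "<tabata_protocol> %d stages x (%d s exercise + %d s interval), %d-s windows, %d s total\n",
    x$n_stages, x$exercise_s, x$interval_s, x$window_s, x$duration_s
  ))
  invisible(x)
}

#' Partition a protocol into labelled analysis windows
#'
#' Windows are contiguous, non-overlapping and half-open `[start_s, end_s)`,
#' aligned to stage boundaries: each stage contributes its exercise windows
#' first, then its interval windows. The classic protocol yields 24 windows
#' per subject in the pattern (exercise, exercise, interval) x 8.
#'
#' @param protocol A [tabata_protocol()].
#' @return A tibble with columns `window_index` (1-based), `stage_index`,
#'   `period` (`"exercise"` or `"interval"`), `start_s`, `end_s`.
#' @examples
#' build_window_plan(tabata_protocol())
#' @export
build_window_plan <- function(protocol) {
  stopifnot(inherits(protocol, "tabata_protocol"))
  n_ex <- protocol$exercise_s %/% protocol$window_s
  n_in <- protocol$interval_s %/% protocol$window_s
  per_stage <- n_ex + n_in
  stage <- rep(seq_len(protocol$n_stages), each = per_stage)
  period <- rep(c(rep("exercise", n_ex), rep("interval", n_in)),
                times = protocol$n_stages)
  idx <- seq_along(stage)
  tibble(
    window_index = idx,
    stage_index = stage,
    period = period,
    start_s = (idx - 1L) * protocol$window_s,
    end_s = idx * protocol$window_s
  )
}

# seconds (1-based indices into a per-second series) covered by one window
window_seconds <- function(start_s, end_s) seq.int(start_s + 1L, end_s)

# sample indices covered by one window at `rate` Hz
window_samples <- function(start_s, end_s, rate) {
  seq.int(start_s * rate + 1L, end_s * rate)
}
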