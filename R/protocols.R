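#' Stress protocols
#'
#' A stress protocol is a piecewise-constant lysozyme input `L(t)`:
#' an ordered set of segments `(start_time, L)` with the first segment
#' starting at 0, plus a total duration.
#'
#' `step_protocol()` describes the standard experiment: no stress until
#' `t_on`, then constant stress `L_level` until the end.
#'
#' `memory_protocol()` describes the stress-memory experiment: stress is
#' applied at `t_on`, removed at `t_off`, and re-applied after a recovery
#' `gap`, running for `post_duration` after the second onset.
#'
#' @param t_on Time of (first) stress onset (min), `0 <= t_on < duration`.
#' @param L_level Lysozyme level during stress (>= 0).
#' @param duration Total protocol duration (min).
#' @return A tibble of segments (`start`, `L`) with class `"sigv_protocol"`
#'   and a `duration` attribute.
#' @examples
#' step_protocol(500, 1, 1500)
#' memory_protocol(500, 1500, gap = 800, L_level = 1, post_duration = 1000)
#' @export
step_protocol <- function(t_on, L_level, duration) {
  if (!is.numeric(t_on) || t_on < 0 || t_on >= duration)
    abort("t_on must satisfy 0 <= t_on < duration")
  if (L_level < 0) abort("L_level must be >= 0")
  segs <- if (t_on == 0) tibble(start = 0, L = L_level)
          else tibble(start = c(0, t_on), L = c(0, L_level))
  new_protocol(segs, duration)
}

#' @rdname step_protocol
#' @param t_off Time stress is removed (min), `t_on < t_off`.
#' @param gap Recovery interval without stress before re-application
#'   (min, non-negative). A zero gap makes the stress effectively continuous
#'   from `t_on`.
#' @param post_duration Simulated time after the second stress onset (min).
#' @export
memory_protocol <- function(t_on, t_off, gap, L_level, post_duration) {
  if (gap < 0) abort("gap must be >= 0")
  if (t_on < 0 || t_off <= t_on) abort("need 0 <= t_on < t_off")
  if (L_level < 0) abort("L_level must be >= 0")
  if (post_duration <= 0) abort("post_duration must be > 0")
  duration <- t_off + gap + post_duration
  segs <- tibble(start = c(0, t_on, t_off, t_off + gap),
                 L = c(0, L_level, 0, L_level))
  new_protocol(segs, duration)
}

#' @rdname step_protocol
#' @param L Constant lysozyme level for [constant_protocol()].
#' @export
constant_protocol <- function(L, duration) {
  if (L < 0) abort("L must be >= 0")
  new_protocol(tibble(start = 0, L = L), duration)
}

new_protocol <- function(segments, duration) {
  # collapse zero-length / duplicated-start segments, keep the last definition
  segments <- segments[segments$start < duration, , drop = FALSE]
  segments <- segments[!duplicated(segments$start, fromLast = TRUE), ]
  segments <- arrange(segments, .data$start)
  if (segments$start[1] != 0) abort("first segment must start at 0")
  if (any(diff(segments$start) <= 0))
    abort("segment start times must be strictly increasing")
  structure(segments, duration = duration,
            class = c("sigv_protocol", class(segments)))
}

protocol_duration <- function(protocol) attr(protocol, "duration")

protocol_segments <- function(protocol) {
  stopifnot(inherits(protocol, "sigv_protocol"))
  d <- protocol_duration(protocol)
  tibble(start = protocol$start,
         end = c(protocol$start[-1], d),
         L = protocol$L)
}

#' Lysozyme level at given times
#'
#' @param protocol A protocol object.
#' @param times Times (min).
#' @return Numeric vector of `L` values.
#' @export
protocol_L_at <- function(protocol, times) {
  stopifnot(inherits(protocol, "sigv_protocol"))
  idx <- findInterval(times, protocol$start)
  protocol$L[pmax(idx, 1)]
}

#' @export
print.sigv_protocol <- function(x, ...) {
  cat("<sigv_protocol> duration", protocol_duration(x), "min\n")
  NextMethod()
}
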