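#' Convert a frame interval to milliseconds
#'
#' Durations in videofluoroscopy are measured on the acquisition frame grid,
#' so at 30 frames per second every interval is a multiple of 1000/30 ms.
#' Printed durations in this tradition are the ceiling of `frames * 1000/fps`,
#' giving the value grid 0, 34, 67, 100, 134, ... ms at 30 fps.
#'
#' @param start,end Frame indices (0-based, closed-open interval
#'   `[start, end)`); `end >= start`.
#' @param fps Frames per second of the recording (default 30).
#' @param convention Rounding convention, `"ceiling"` (default), `"round"` or
#'   `"floor"`.
#' @param .events Optional character vector of length 2 naming the start/end
#'   events, used only to make ordering errors readable.
#' @return Integer number of milliseconds.
#' @export
#' @examples
#' frames_to_ms(0, 15, 30) # 500
#' frames_to_ms(0, 2, 30)  # 67
frames_to_ms <- function(start, end, fps = 30, convention = c("ceiling", "round", "floor"),
                         .events = NULL) {
  convention <- match.arg(convention)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("configuration error: fps must be a positive number, got ", fps)
  if (any(is.na(start)) || any(is.na(end))) return(NA_integer_)
  if (any(end < start)) {
    lab <- if (!is.null(.events)) paste0(" (", .events[1L], " .. ", .events[2L], ")") else ""
    stop("event ordering error", lab, ": end frame ", end, " precedes start frame ", start)
  }
  x <- (end - start) * 1000 / fps
  # guard against binary representation pushing an exact multiple just above
  # the integer before taking the ceiling
  ms <- switch(convention,
    ceiling = ceiling(x - 1e-9),
    round   = round(x),
    floor   = floor(x + 1e-9)
  )
  as.integer(ms)
}

#' Signed frame interval in milliseconds
#'
#' Like [frames_to_ms()] but permits `end < start`, returning a negative
#' duration of the same magnitude. Used for swallow reaction time, where the
#' hyoid burst may precede the bolus passing the mandibular ramus.
#' @inheritParams frames_to_ms
#' @return Signed integer milliseconds.
#' @export
signed_frames_to_ms <- function(start, end, fps = 30, convention = "ceiling") {
  if (any(is.na(start)) || any(is.na(end))) return(NA_integer_)
  s <- if (end >= start) 1L else -1L
  s * frames_to_ms(0L, abs(end - start), fps = fps, convention = convention)
}

#' Snap a millisecond value onto the frame timing grid
#'
#' Finds the nearest whole number of frames and returns the duration that
#' [frames_to_ms()] would print for that many frames. Negative inputs snap
#' symmetrically (signed intervals).
#' @param ms Numeric milliseconds (may be negative).
#' @inheritParams frames_to_ms
#' @return List with `frames` (signed integer) and `ms` (signed grid value).
#' @export
snap_ms_to_grid <- function(ms, fps = 30, convention = "ceiling") {
  k <- as.integer(round(ms * fps / 1000))
  list(frames = k,
       ms = as.integer(sign(k)) * frames_to_ms(0L, abs(k), fps = fps,
                                               convention = convention))
}
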