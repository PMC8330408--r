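#' Cervical spine landmarks
#'
#' The anterior-inferior corners of the C2 and C4 vertebrae, in image pixel
#' coordinates (y increasing downward). The C2-C4 distance defines the
#' per-participant anatomical scalar: all distances are reported as a
#' percentage of it (%(C2-4)) and areas as a percentage of its square.
#'
#' @param c2ai,c4ai Numeric length-2 pixel points `c(x, y)`.
#' @return Object of class `spine_landmarks`.
#' @export
spine_landmarks <- function(c2ai, c4ai) {
  stopifnot(is.numeric(c2ai), length(c2ai) == 2L, is.numeric(c4ai), length(c4ai) == 2L,
            all(is.finite(c2ai)), all(is.finite(c4ai)))
  if (isTRUE(all(c2ai == c4ai)))
    stop("geometry error: C2 and C4 landmarks coincide (zero spine length)")
  structure(list(c2ai = as.numeric(c2ai), c4ai = as.numeric(c4ai)),
            class = "spine_landmarks")
}

#' Spine length in pixels
#' @param landmarks A [spine_landmarks()] object.
#' @return Euclidean pixel distance C2-C4.
#' @export
spine_length <- function(landmarks) {
  d <- landmarks$c2ai - landmarks$c4ai
  sqrt(sum(d^2))
}

# Orthonormal anatomical basis: u points from C4 toward C2 (superior),
# v is u rotated so that anterior is positive. In image coordinates
# (y downward) a patient facing image-left has anterior at negative pixel x,
# hence v = rotate(u, -90 deg) for anterior = "left".
anat_basis <- function(landmarks, anterior = c("left", "right")) {
  anterior <- match.arg(anterior)
  L <- spine_length(landmarks)
  if (L <= 0) stop("geometry error: degenerate spine landmarks")
  u <- (landmarks$c2ai - landmarks$c4ai) / L
  v <- if (anterior == "left") c(u[2L], -u[1L]) else c(-u[2L], u[1L])
  list(u = u, v = v, L = L)
}

#' Transform a pixel point into anatomically scaled coordinates
#'
#' Re-expresses a pixel point in the participant-specific anatomical frame:
#' origin at the anterior-inferior corner of C4, Y-axis along the C2-C4 spine
#' (superior positive), X-axis perpendicular with anterior positive, both
#' divided by the C2-C4 length and multiplied by 100, i.e. %(C2-4) units.
#'
#' @param landmarks A [spine_landmarks()] object.
#' @param p Pixel point `c(x, y)` or an n-by-2 matrix of points.
#' @param anterior Which image side the patient faces (`"left"` default);
#'   flips the sign of the anatomical X-axis.
#' @return Scaled point(s), same shape as `p`, in %(C2-4).
#' @export
#' @examples
#' lm <- spine_landmarks(c2ai = c(0, -30), c4ai = c(0, 0))
#' anatomical_transform(lm, c(0, -30)) # c(0, 100)
anatomical_transform <- function(landmarks, p, anterior = "left") {
  b <- anat_basis(landmarks, anterior)
  one <- is.null(dim(p))
  pm <- if (one) matrix(as.numeric(p), ncol = 2L) else as.matrix(p)
  if (!all(is.finite(pm))) stop("input error: non-finite pixel coordinates")
  d <- sweep(pm, 2L, landmarks$c4ai)
  out <- cbind(x = (d %*% b$v) * 100 / b$L,
               y = (d %*% b$u) * 100 / b$L)
  colnames(out) <- c("x", "y")
  if (one) stats::setNames(c(out), c("x", "y")) else out
}

#' Inverse anatomical transform
#'
#' Maps %(C2-4) coordinates back into image pixels; exact inverse of
#' [anatomical_transform()] for the same landmarks and orientation.
#' @inheritParams anatomical_transform
#' @param q Scaled point `c(x, y)` or n-by-2 matrix in %(C2-4).
#' @return Pixel point(s).
#' @export
anatomical_untransform <- function(landmarks, q, anterior = "left") {
  b <- anat_basis(landmarks, anterior)
  one <- is.null(dim(q))
  qm <- if (one) matrix(as.numeric(q), ncol = 2L) else as.matrix(q)
  px <- qm[, 1L, drop = FALSE] %*% rbind(b$v) + qm[, 2L, drop = FALSE] %*% rbind(b$u)
  px <- sweep(px * b$L / 100, 2L, landmarks$c4ai, `+`)
  colnames(px) <- c("x", "y")
  if (one) c(px) else px
}

#' Polygon area by the shoelace formula
#'
#' @param vertices n-by-2 matrix (or data.frame) of ordered vertices, or
#'   `NULL`/empty for an absent region.
#' @return Absolute area in the square of the input units; 0 for empty or
#'   degenerate (< 3 vertex) input. Invariant under vertex-order reversal and
#'   cyclic rotation.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # 1
polygon_area <- function(vertices) {
  if (is.null(vertices) || length(vertices) == 0L) return(0)
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) stop("input error: vertices must be an n-by-2 numeric matrix")
  if (!all(is.finite(v))) stop("input error: non-finite polygon coordinates")
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}
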