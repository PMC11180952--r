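#' 2D similarity transform (uniform scale + rotation + translation)
#'
#' Maps source-image pixel coordinates `p` into reference coordinates
#' `q = scale * R(rotation) * p + translation`, with `R` the usual
#' counter-clockwise rotation matrix in the image coordinate frame
#' (x rightward, y downward, so positive angles turn from +x towards +y,
#' i.e. clockwise on screen). Reflections are excluded: a paraffin block
#' cannot flip between consecutive cuts, so `scale > 0` always.
#'
#' @param scale Positive uniform scale factor.
#' @param rotation Rotation angle in radians; normalized into `(-pi, pi]`.
#' @param translation Length-2 numeric `(tx, ty)` in px.
#' @return An object of class `blockface_transform`.
#' @examples
#' t1 <- similarity_transform(scale = 2, rotation = pi / 6, translation = c(5, -3))
#' st_apply(t1, cbind(1, 0))
#' st_apply(st_compose(st_invert(t1), t1), cbind(1, 0)) # identity
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(rotation), length(rotation) == 1L, is.finite(rotation),
            is.numeric(translation), length(translation) == 2L,
            all(is.finite(translation)))
  if (scale <= 0)
    stop("`scale` must be strictly positive (reflections are not allowed)")
  # normalize into (-pi, pi]
  rotation <- rotation - 2 * pi * ceiling((rotation - pi) / (2 * pi))
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "blockface_transform")
}

#' @export
print.blockface_transform <- function(x, ...) {
  cat(sprintf(
    "<blockface_transform> scale %.6g, rotation %.6g deg, t (%.4g, %.4g) px\n",
    x$scale, x$rotation * 180 / pi, x$translation[1], x$translation[2]))
  res <- attr(x, "rms_residual")
  if (!is.null(res)) cat(sprintf("  fit RMS residual %.4g px\n", res))
  invisible(x)
}

#' @rdname similarity_transform
#' @param t,t1,t2 `blockface_transform` objects.
#' @param points Numeric `n x 2` matrix of `(x, y)` coordinates.
#' @return `st_apply` returns the transformed `n x 2` matrix.
#' @export
st_apply <- function(t, points) {
  stopifnot(inherits(t, "blockface_transform"))
  points <- rbind(points)
  cs <- cos(t$rotation); sn <- sin(t$rotation)
  x <- points[, 1]; y <- points[, 2]
  cbind(t$scale * (cs * x - sn * y) + t$translation[1],
        t$scale * (sn * x + cs * y) + t$translation[2])
}

#' @rdname similarity_transform
#' @return `st_compose(t2, t1)` returns the transform applying `t1` first,
#'   then `t2`.
#' @export
st_compose <- function(t2, t1) {
  stopifnot(inherits(t2, "blockface_transform"),
            inherits(t1, "blockface_transform"))
  # q = s2 R2 (s1 R1 p + d1) + d2
  similarity_transform(
    scale = t2$scale * t1$scale,
    rotation = t2$rotation + t1$rotation,
    translation = drop(st_apply(t2, rbind(t1$translation)))
  )
}

#' @rdname similarity_transform
#' @return `st_invert` returns the inverse transform.
#' @export
st_invert <- function(t) {
  stopifnot(inherits(t, "blockface_transform"))
  s <- 1 / t$scale
  cs <- cos(-t$rotation); sn <- sin(-t$rotation)
  tx <- t$translation[1]; ty <- t$translation[2]
  similarity_transform(
    scale = s, rotation = -t$rotation,
    translation = c(-s * (cs * tx - sn * ty), -s * (sn * tx + cs * ty))
  )
}
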