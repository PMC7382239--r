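#' Build a weighted 2D segment set
#'
#' The common currency of the quantification layer: 2D segments with an
#' orientation angle (degrees from +x, nematic, mapped to (-90, 90]) and a
#' positive weight (the segment length unless stated otherwise).
#'
#' @param x1,y1,x2,y2 segment endpoints (recycled as usual), or pass `angle`
#'   and `weight` directly.
#' @param angle,weight alternative construction from angles (degrees) and
#'   weights; endpoints are then synthesized as unit segments.
#' @return a data frame of class `mt_segments` with columns `x1, y1, x2, y2,
#'   angle, weight`.
#' @export
mt_segments <- function(x1 = NULL, y1 = NULL, x2 = NULL, y2 = NULL,
                        angle = NULL, weight = NULL) {
  if (is.null(angle)) {
    dx <- x2 - x1; dy <- y2 - y1
    weight <- sqrt(dx^2 + dy^2)
    angle <- ifelse(weight > 0, atan2(dy, dx) * 180 / pi, 0)
  } else {
    angle <- as.numeric(angle)
    if (is.null(weight)) weight <- rep(1, length(angle))
    rad <- angle * pi / 180
    if (is.null(x1)) {
      x1 <- rep(0, length(angle)); y1 <- rep(0, length(angle))
      x2 <- weight * cos(rad); y2 <- weight * sin(rad)
    }
  }
  angle <- wrap_angle(angle)
  structure(data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                       angle = angle, weight = weight),
            class = c("mt_segments", "data.frame"))
}

# map any angle in degrees to the nematic interval (-90, 90]
wrap_angle <- function(theta) {
  out <- (theta + 90) %% 180 - 90
  out[out == -90] <- 90
  out
}

#' Project simulation elements onto an analysis face
#'
#' Selects the microtubule elements whose midpoint lies within `shell_depth`
#' of the face (for the planar faces of boxes and prisms: a z-slab; for the
#' spherical/cylindrical kinds: within `shell_depth` of the curved-or-flat
#' boundary on that face's side of z = 0) and orthogonally projects them into
#' the face frame.  Weights are projected (2D) lengths, so elements
#' perpendicular to the face carry no weight.  Element-level selection is
#' adequate because the element length (default 0.2 um) is small against the
#' default 0.5 um shell.
#'
#' @param state a `sim_state` from [sim_state()].
#' @param face a `domain_face` from [analysis_faces()].
#' @param shell_depth shell thickness in um.
#' @return an [mt_segments()] data frame (possibly empty).
#' @export
face_projection <- function(state, face, shell_depth = 0.5) {
  stopifnot(inherits(state, "sim_state"), inherits(face, "domain_face"),
            shell_depth > 0)
  dom <- state$domain
  segs <- list()
  for (mt in state$mts) {
    v <- mt$vertices
    if (nrow(v) < 2) next
    a <- v[-nrow(v), , drop = FALSE]
    b <- v[-1, , drop = FALSE]
    mid <- (a + b) / 2
    keep <- switch(dom$kind,
      box = ,
      triangular_prism = abs(mid[, 3] - face$z) < shell_depth,
      sphere = {
        r <- dom$dimensions[1]
        (r - sqrt(rowSums(mid^2)) < shell_depth) & (sign(mid[, 3]) == sign(face$z))
      },
      cylinder = {
        r <- dom$dimensions[1]
        side <- sign(mid[, 3]) == sign(face$z)
        near_cap <- abs(mid[, 3] - face$z) < shell_depth
        near_wall <- (r - sqrt(mid[, 1]^2 + mid[, 2]^2)) < shell_depth
        side & (near_cap | near_wall)
      })
    if (!any(keep)) next
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    segs[[length(segs) + 1L]] <- data.frame(
      x1 = a %*% face$ex, y1 = a %*% face$ey,
      x2 = b %*% face$ex, y2 = b %*% face$ey)
  }
  if (!length(segs))
    return(mt_segments(x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0)))
  d <- do.call(rbind, segs)
  mt_segments(d$x1, d$y1, d$x2, d$y2)
}

#' Weighted 2D nematic order parameter
#'
#' S2 is the magnitude of the weighted nematic resultant of segment
#' orientations, `S2 = sqrt(<cos 2theta>_w^2 + <sin 2theta>_w^2)`, with
#' weights the segment lengths; `theta_S2 = atan2(<sin 2theta>_w,
#' <cos 2theta>_w) / 2` is the dominant axis in degrees in (-90, 90].
#' S2 = 0 for an isotropic set, 1 for perfect alignment; the statistic is
#' invariant under per-segment orientation flips (theta -> theta + 180).
#' When S2 is below `tol` the axis is undefined and `theta_S2` is NA.
#'
#' @param segments an [mt_segments()] data frame, or anything with `angle`
#'   (degrees) and `weight` columns.
#' @param tol resultant magnitude below which the axis is flagged undefined.
#' @return an `order_parameter` object: `S2`, `theta_S2` (degrees),
#'   `n_segments`, `total_weight`.
#' @examples
#' s2_order(mt_segments(angle = c(0, 0, 90), weight = c(1, 1, 1)))  # S2 = 1/3
#' @export
s2_order <- function(segments, tol = 1e-12) {
  ang <- segments$angle
  w <- segments$weight
  keep <- is.finite(ang) & is.finite(w) & w > 0
  ang <- ang[keep]; w <- w[keep]
  if (!length(ang) || sum(w) <= 0) {
    return(structure(list(S2 = NA_real_, theta_S2 = NA_real_,
                          n_segments = 0L, total_weight = 0,
                          undefined = TRUE),
                     class = "order_parameter"))
  }
  # cospi/sinpi keep the right-angle cases exact (sin(180 deg) == 0), so
  # symmetric sets like an orthogonal grid cancel to S2 = 0 identically
  c2 <- sum(w * cospi(ang / 90)) / sum(w)
  s2 <- sum(w * sinpi(ang / 90)) / sum(w)
  S2 <- sqrt(c2^2 + s2^2)
  theta <- if (S2 > tol) wrap_angle(atan2(s2, c2) / 2 * 180 / pi) else NA_real_
  structure(list(S2 = S2, theta_S2 = theta, n_segments = length(ang),
                 total_weight = sum(w), undefined = S2 <= tol),
            class = "order_parameter")
}

#' @export
print.order_parameter <- function(x, ...) {
  cat(sprintf("<order_parameter> S2 = %.4f, theta_S2 = %s deg (%d segments, weight %.3g um)\n",
              x$S2, if (is.na(x$theta_S2)) "undefined" else sprintf("%.2f", x$theta_S2),
              x$n_segments, x$total_weight))
  invisible(x)
}

#' Order parameter of a simulation state on its opposite faces
#'
#' Convenience wrapper: projects the state onto both analysis faces and
#' reports per-face order parameters plus a weight-weighted mean S2 and the
#' axis of the pooled segments.
#'
#' @inheritParams face_projection
#' @param domain the confining domain (defaults to the one in the state).
#' @return list with `top`, `bottom` (per-face `order_parameter`), `pooled`
#'   (both faces pooled), and `mean_S2` (weight-weighted mean of the faces).
#' @export
state_order_parameter <- function(state, domain = state$domain,
                                  shell_depth = 0.5) {
  faces <- analysis_faces(domain)
  top <- face_projection(state, faces$top, shell_depth)
  bottom <- face_projection(state, faces$bottom, shell_depth)
  op_t <- s2_order(top)
  op_b <- s2_order(bottom)
  pooled <- s2_order(rbind(top, bottom))
  wt <- c(op_t$total_weight, op_b$total_weight)
  s2s <- c(op_t$S2, op_b$S2)
  mean_S2 <- if (sum(wt, na.rm = TRUE) > 0)
    sum(wt * s2s, na.rm = TRUE) / sum(wt[!is.na(s2s)]) else NA_real_
  list(top = op_t, bottom = op_b, pooled = pooled, mean_S2 = mean_S2)
}

#' Image anisotropy from the intensity-gradient nematic tensor
#'
#' FibrilTool-style quantification of a grayscale image: per-pixel intensity
#' gradients by central differences, fibril orientation taken perpendicular
#' to the gradient, and the unit-trace nematic tensor formed as the
#' intensity-weighted average of the fibril direction outer products.
#' Anisotropy is the difference of the tensor eigenvalues (0 isotropic, 1
#' perfectly striped); the angle is the principal axis in degrees in
#' (-90, 90] from +x.  The statistic is invariant under affine intensity
#' rescaling I -> a I + b (a > 0).
#'
#' Image convention: a numeric matrix with `image[i, j]` the pixel at
#' x = j, y = i (row index increases with y).
#'
#' @param image numeric matrix of finite intensities.
#' @param roi optional polygon (matrix with columns x, y in pixel
#'   coordinates) restricting the analysis; default is the whole image.
#' @param eps gradient magnitudes at or below `eps` times the maximum
#'   gradient are treated as flat and ignored.
#' @return an `image_anisotropy` object: `anisotropy`, `angle` (degrees),
#'   `n_pixels`, `roi`; `anisotropy` is NA with `flat = TRUE` for an
#'   all-constant image.
#' @export
nematic_tensor_image <- function(image, roi = NULL, eps = 1e-8) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image must be at least 3 x 3")
  inner_i <- 2:(nr - 1); inner_j <- 2:(nc - 1)
  gx <- (image[inner_i, inner_j + 1] - image[inner_i, inner_j - 1]) / 2
  gy <- (image[inner_i + 1, inner_j] - image[inner_i - 1, inner_j]) / 2
  inten <- image[inner_i, inner_j]
  use <- matrix(TRUE, length(inner_i), length(inner_j))
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    px <- matrix(rep(inner_j, each = length(inner_i)), length(inner_i))
    py <- matrix(rep(inner_i, times = length(inner_j)), length(inner_i))
    use <- matrix(point_in_polygon(as.vector(px), as.vector(py),
                                   roi[, 1], roi[, 2]),
                  length(inner_i))
    if (sum(use) < 9) stop("roi must cover at least 9 interior pixels")
  }
  g2 <- gx^2 + gy^2
  gmax <- max(g2[use])
  if (gmax <= 0) {
    return(structure(list(anisotropy = NA_real_, angle = NA_real_,
                          n_pixels = sum(use), roi = roi, flat = TRUE),
                     class = "image_anisotropy"))
  }
  sel <- use & g2 > eps * gmax
  if (!any(sel)) {
    return(structure(list(anisotropy = NA_real_, angle = NA_real_,
                          n_pixels = sum(use), roi = roi, flat = TRUE),
                     class = "image_anisotropy"))
  }
  # fibril direction = gradient rotated 90 degrees: (-gy, gx)/|g|
  g <- sqrt(g2[sel])
  fx <- -gy[sel] / g
  fy <- gx[sel] / g
  w <- inten[sel] - min(inten[sel])   # affine-invariant intensity weight
  if (sum(w) <= 0) w <- rep(1, length(fx))
  txx <- sum(w * fx * fx) / sum(w)
  tyy <- sum(w * fy * fy) / sum(w)
  txy <- sum(w * fx * fy) / sum(w)
  # eigen-decomposition of the 2x2 unit-trace tensor in closed form
  half_diff <- sqrt(((txx - tyy) / 2)^2 + txy^2)
  anis <- 2 * half_diff          # lambda1 - lambda2 with lambda1+lambda2 = 1
  angle <- wrap_angle(atan2(2 * txy, txx - tyy) / 2 * 180 / pi)
  structure(list(anisotropy = anis, angle = angle, n_pixels = sum(sel),
                 roi = roi, flat = FALSE),
            class = "image_anisotropy")
}

#' @export
print.image_anisotropy <- function(x, ...) {
  if (isTRUE(x$flat)) cat("<image_anisotropy> flat image, anisotropy undefined\n")
  else cat(sprintf("<image_anisotropy> anisotropy = %.4f, angle = %.2f deg (%d pixels)\n",
                   x$anisotropy, x$angle, x$n_pixels))
  invisible(x)
}

# even-odd ray casting; vertices on edges count as inside (adequate here)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Render a synthetic fluorescence image
#'
#' Maximum-intensity-projection analogue: rasterizes the projected elements
#' as unit-intensity lines on a pixel grid, convolves with a Gaussian
#' point-spread function, and optionally adds Poisson shot noise.
#' Deterministic given `seed`.
#'
#' @param x an [mt_segments()] set (2D, um coordinates) or a `sim_state`.
#' @param face for a `sim_state`: which analysis face to project on
#'   (`"top"`/`"bottom"`); the whole depth is projected (shell = Inf slab).
#' @param psf_sigma Gaussian PSF sigma in um.
#' @param pixel_size pixel edge in um.
#' @param noise `"none"` or `"poisson"`.
#' @param photons expected photon count at unit line intensity (Poisson mode).
#' @param pad image padding in um around the segment bounding box.
#' @param seed integer seed for the noise draw.
#' @param ... passed to methods.
#' @return numeric matrix (see [nematic_tensor_image()] for the convention),
#'   with attributes `pixel_size` and `origin` (um of pixel (1,1) center).
#' @export
render_image <- function(x, ...) UseMethod("render_image")

#' @rdname render_image
#' @export
render_image.mt_segments <- function(x, psf_sigma = 0.15, pixel_size = 0.1,
                                     noise = c("none", "poisson"),
                                     photons = 50, pad = 1, seed = 1L, ...) {
  noise <- match.arg(noise)
  if (nrow(x) == 0) {
    img <- matrix(0, 32, 32)
  } else {
    x0 <- min(x$x1, x$x2) - pad; x1 <- max(x$x1, x$x2) + pad
    y0 <- min(x$y1, x$y2) - pad; y1 <- max(x$y1, x$y2) + pad
    nc <- max(8L, ceiling((x1 - x0) / pixel_size))
    nr <- max(8L, ceiling((y1 - y0) / pixel_size))
    img <- matrix(0, nr, nc)
    step <- pixel_size / 4
    xs_all <- vector("list", nrow(x))
    ys_all <- vector("list", nrow(x))
    dep_all <- vector("list", nrow(x))
    for (k in seq_len(nrow(x))) {
      len <- sqrt((x$x2[k] - x$x1[k])^2 + (x$y2[k] - x$y1[k])^2)
      if (len == 0) next
      n <- max(2L, ceiling(len / step))
      t <- seq(0, 1, length.out = n)
      xs_all[[k]] <- x$x1[k] + t * (x$x2[k] - x$x1[k])
      ys_all[[k]] <- x$y1[k] + t * (x$y2[k] - x$y1[k])
      # deposit intensity proportional to sampled arc length
      dep_all[[k]] <- rep(len / n, n)
    }
    xs <- unlist(xs_all); ys <- unlist(ys_all); dep <- unlist(dep_all)
    if (length(xs)) {
      # bilinear (anti-aliased) splatting onto the four nearest pixels:
      # nearest-pixel deposition aliases oblique lines into staircases and
      # biases the gradient-tensor angle toward the diagonals
      fx <- (xs - x0) / pixel_size - 0.5
      fy <- (ys - y0) / pixel_size - 0.5
      j0 <- floor(fx); i0 <- floor(fy)
      wx <- fx - j0; wy <- fy - i0
      for (corner in 1:4) {
        jj <- j0 + (corner == 2 | corner == 4)
        ii <- i0 + (corner == 3 | corner == 4)
        w <- (if (corner %in% c(2, 4)) wx else 1 - wx) *
             (if (corner %in% c(3, 4)) wy else 1 - wy)
        ok <- jj >= 0 & jj < nc & ii >= 0 & ii < nr & w > 0
        if (!any(ok)) next
        idx <- jj[ok] * nr + ii[ok] + 1
        tot <- rowsum(dep[ok] * w[ok], group = idx)
        ridx <- as.integer(rownames(tot))
        img[ridx] <- img[ridx] + tot
      }
    }
    attr(img, "origin") <- c(x0 + pixel_size / 2, y0 + pixel_size / 2)
  }
  img <- gaussian_blur(img, psf_sigma / pixel_size)
  if (noise == "poisson") {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    img <- matrix(rpois(length(img), img * photons) / photons,
                  nrow(img), ncol(img))
  }
  attr(img, "pixel_size") <- pixel_size
  img
}

#' @rdname render_image
#' @export
render_image.sim_state <- function(x, face = c("top", "bottom"), ...) {
  face <- match.arg(face)
  f <- analysis_faces(x$domain)[[face]]
  depth <- switch(x$domain$kind,
    box = x$domain$dimensions[3],
    triangular_prism = x$domain$dimensions[2],
    sphere = 2 * x$domain$dimensions[1],
    cylinder = x$domain$dimensions[2])
  segs <- face_projection(x, f, shell_depth = depth + 1)
  render_image(segs, ...)
}

# separable Gaussian convolution with zero padding
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve each column with k, zero padded
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in -r:r) {
      src <- seq_len(nr) + o
      ok <- src >= 1 & src <= nr
      out[ok, ] <- out[ok, ] + k[o + r + 1] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Read or write a grayscale TIFF image
#'
#' Thin wrappers over the `tiff` package using this package's matrix
#' convention (`image[i, j]`, row = y).
#'
#' @param path file path.
#' @param image numeric matrix with values in [0, 1] (rescaled on write).
#' @return `read_image_tiff` returns a numeric matrix.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF input")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m[rev(seq_len(nrow(m))), , drop = FALSE]  # TIFF rows top-down -> y up
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF output")
  rng <- range(image)
  m <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(m[rev(seq_len(nrow(m))), , drop = FALSE], path)
  invisible(path)
}
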