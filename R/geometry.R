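#' Confining domain geometries
#'
#' A `confinement_domain` is a bounded convex 3D region, centered at the
#' origin, inside which microtubules are simulated.  Supported kinds are
#' `sphere` (radius), `box` (Lx, Ly, Lz), `triangular_prism` (equilateral
#' side, height) and `cylinder` (radius, height).  All dimensions are in
#' micrometres.  Conventions: right-handed axes, the rectangle's long axis is
#' +x, and the imaging/analysis axis is z.  Containment is closed-set: the
#' boundary belongs to the domain, so a deflected tip sliding on the membrane
#' is a valid position.
#'
#' @param kind one of `"sphere"`, `"box"`, `"triangular_prism"`, `"cylinder"`.
#' @param dimensions numeric vector of strictly positive lengths in um:
#'   radius for a sphere; `c(Lx, Ly, Lz)` for a box; `c(side, height)` for a
#'   triangular prism or cylinder (radius, height).
#' @return an object of class `confinement_domain`.
#' @examples
#' confinement_domain("box", c(40, 15, 15))
#' domain_sphere(10)
#' @export
confinement_domain <- function(kind = c("sphere", "box", "triangular_prism",
                                        "cylinder"),
                               dimensions) {
  kind <- match.arg(kind)
  n_expected <- switch(kind, sphere = 1L, box = 3L,
                       triangular_prism = 2L, cylinder = 2L)
  dimensions <- as.numeric(dimensions)
  if (length(dimensions) != n_expected)
    stop(sprintf("domain kind '%s' needs %d dimension(s)", kind, n_expected))
  if (!all(is.finite(dimensions)) || any(dimensions <= 0))
    stop("all dimensions must be finite and strictly positive")
  structure(list(kind = kind, dimensions = dimensions,
                 center = c(0, 0, 0)),
            class = "confinement_domain")
}

#' @rdname confinement_domain
#' @param Lx,Ly,Lz box edge lengths (um)
#' @export
domain_box <- function(Lx, Ly, Lz) confinement_domain("box", c(Lx, Ly, Lz))

#' @rdname confinement_domain
#' @param radius sphere/cylinder radius (um)
#' @export
domain_sphere <- function(radius) confinement_domain("sphere", radius)

#' @rdname confinement_domain
#' @param height prism/cylinder height along z (um)
#' @export
domain_cylinder <- function(radius, height)
  confinement_domain("cylinder", c(radius, height))

#' @rdname confinement_domain
#' @param side equilateral triangle side (um); one side is parallel to +x
#' @export
domain_prism <- function(side, height)
  confinement_domain("triangular_prism", c(side, height))

#' @export
print.confinement_domain <- function(x, ...) {
  cat("<confinement_domain> ", x$kind, " [",
      paste(format(x$dimensions), collapse = " x "), " um]\n", sep = "")
  invisible(x)
}

is_domain <- function(x) inherits(x, "confinement_domain")

stop_if_not_domain <- function(x) {
  if (!is_domain(x)) stop("expected a 'confinement_domain' object")
  invisible(x)
}

#' Point containment test
#'
#' Closed-set containment: points on the boundary count as inside (within a
#' 1e-9 um tolerance).  Because every supported domain is convex, a segment
#' lies inside iff both endpoints do.
#'
#' @param domain a [confinement_domain()].
#' @param p numeric length-3 point, or an n x 3 matrix of points.
#' @return logical scalar (or vector for a matrix of points).
#' @examples
#' d <- domain_box(40, 15, 15)
#' domain_contains(d, c(0, 0, 0))   # TRUE
#' domain_contains(d, c(25, 0, 0))  # FALSE
#' @export
domain_contains <- function(domain, p) {
  stop_if_not_domain(domain)
  if (is.matrix(p)) {
    if (ncol(p) != 3) stop("point matrix must have 3 columns")
    return(vapply(seq_len(nrow(p)),
                  function(i) cpp_contains(domain, p[i, ]), logical(1)))
  }
  cpp_contains(domain, as.numeric(p))
}

#' First boundary intersection of a growth step
#'
#' Casts a ray of length `step_len` from an interior point and reports the
#' first boundary crossing, the outward unit normal there, and the incidence
#' angle measured from the tangent plane (0 deg = grazing, 90 deg = head-on).
#' Returns `NULL` when the full step stays inside.
#'
#' @param domain a [confinement_domain()].
#' @param p interior starting point (um).
#' @param dir unit direction vector.
#' @param step_len positive step length (um).
#' @return `NULL`, or a list with `point`, `normal`, `incidence` (degrees).
#' @examples
#' d <- domain_box(40, 15, 15)
#' boundary_hit(d, c(19.95, 0, 0), c(1, 0, 0), 0.1)
#' @export
boundary_hit <- function(domain, p, dir, step_len) {
  stop_if_not_domain(domain)
  res <- cpp_boundary_hit(domain, as.numeric(p), as.numeric(dir),
                          as.numeric(step_len))
  if (!res$hit) return(NULL)
  list(point = res$point, normal = res$normal, incidence = res$incidence)
}

#' Tangent-plane deflection of a growth direction
#'
#' Removes the outward-normal component of `dir` and renormalizes, i.e. the
#' in-plane continuation used when a growing tip meets the membrane without
#' catastrophe.  A head-on hit (tangential component below 1e-9) has no
#' defined deflection; `NULL` is returned and the caller must trigger a
#' catastrophe instead.
#'
#' @param dir unit direction vector.
#' @param normal outward unit normal at the hit point.
#' @return unit 3-vector in the tangent plane, or `NULL` when degenerate.
#' @examples
#' deflect(c(1, 0, 1) / sqrt(2), c(0, 0, 1))  # c(1, 0, 0)
#' deflect(c(0, 0, 1), c(0, 0, 1))            # NULL (head-on)
#' @export
deflect <- function(dir, normal) {
  res <- cpp_deflect(as.numeric(dir), as.numeric(normal))
  if (!res$ok) return(NULL)
  res$dir
}

#' Opposite analysis faces of a domain
#'
#' The two faces perpendicular to the imaging (z) axis on which 2D network
#' order is quantified: the z-extremal planar faces for boxes and prisms, and
#' the upper/lower caps (hemispheres for the sphere) split at z = 0 for the
#' curved kinds.  Each descriptor carries the face's signed z extent and an
#' in-plane orthonormal frame whose first axis (`ex` = +x) is the 0-degree
#' reference -- the rectangle's long axis.
#'
#' @param domain a [confinement_domain()].
#' @return a list of two `domain_face` objects (`"top"`, `"bottom"`).
#' @examples
#' analysis_faces(domain_box(40, 15, 15))
#' @export
analysis_faces <- function(domain) {
  stop_if_not_domain(domain)
  half_z <- switch(domain$kind,
    sphere = domain$dimensions[1],
    box = domain$dimensions[3] / 2,
    triangular_prism = domain$dimensions[2] / 2,
    cylinder = domain$dimensions[2] / 2)
  face <- function(side) {
    structure(list(side = side,
                   z = if (side == "top") half_z else -half_z,
                   normal = c(0, 0, if (side == "top") 1 else -1),
                   ex = c(1, 0, 0), ey = c(0, 1, 0),
                   kind = domain$kind),
              class = "domain_face")
  }
  list(top = face("top"), bottom = face("bottom"))
}

#' @export
print.domain_face <- function(x, ...) {
  cat("<domain_face> ", x$side, " (", x$kind, "), z = ", format(x$z),
      " um, 0-deg axis = +x\n", sep = "")
  invisible(x)
}

#' Uniform random interior points (rejection sampling)
#'
#' Utility for tests and fixtures: i.i.d. uniform points inside the domain.
#'
#' @inheritParams domain_contains
#' @param n number of points.
#' @return an n x 3 matrix.
#' @export
domain_runif <- function(domain, n) {
  stop_if_not_domain(domain)
  bb <- switch(domain$kind,
    sphere = {
      r <- domain$dimensions[1]
      rbind(c(-r, -r, -r), c(r, r, r))
    },
    box = rbind(-domain$dimensions / 2, domain$dimensions / 2),
    triangular_prism = {
      s <- domain$dimensions[1]; h <- domain$dimensions[2]
      H <- s * sqrt(3) / 2
      rbind(c(-s / 2, -H / 3, -h / 2), c(s / 2, 2 * H / 3, h / 2))
    },
    cylinder = {
      r <- domain$dimensions[1]; h <- domain$dimensions[2]
      rbind(c(-r, -r, -h / 2), c(r, r, h / 2))
    })
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]),
                  runif(m, bb[1, 2], bb[2, 2]),
                  runif(m, bb[1, 3], bb[2, 3]))
    keep <- domain_contains(domain, cand)
    k <- min(sum(keep), n - got)
    if (k > 0) out[(got + 1):(got + k), ] <- cand[keep, , drop = FALSE][seq_len(k), ]
    got <- got + k
  }
  out
}
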