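#' Write microtubules as legacy VTK polylines
#'
#' Serializes a simulation state to legacy ASCII VTK PolyData: POINTS (um),
#' one LINES polyline per microtubule, and CELL_DATA scalars `mt_id` and
#' `plus_state` (0 growing, 1 shrinking).  Coordinates are printed with
#' enough digits to round-trip losslessly to well below 1e-6 um, and a
#' write-read-write cycle is byte-identical.
#'
#' @param state a `sim_state` (or any list with an `mts` field of the same
#'   shape).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_polylines <- function(state, path) {
  mts <- state$mts
  npts <- sum(vapply(mts, function(m) nrow(m$vertices), integer(1)))
  con <- file(path, open = "wb")  # binary mode: stable \n on every platform
  on.exit(close(con), add = TRUE)
  wl <- function(...) writeLines(c(...), con, sep = "\n")
  wl("# vtk DataFile Version 3.0",
     "microtubule polylines",
     "ASCII",
     "DATASET POLYDATA",
     sprintf("POINTS %d double", npts))
  for (m in mts) {
    v <- m$vertices
    wl(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]))
  }
  sizes <- vapply(mts, function(m) nrow(m$vertices), integer(1))
  wl(sprintf("LINES %d %d", length(mts), length(mts) + npts))
  offset <- 0L
  for (k in seq_along(mts)) {
    idx <- offset + seq_len(sizes[k]) - 1L
    wl(paste(c(sizes[k], idx), collapse = " "))
    offset <- offset + sizes[k]
  }
  wl(sprintf("CELL_DATA %d", length(mts)),
     "SCALARS mt_id int 1",
     "LOOKUP_TABLE default")
  if (length(mts)) wl(sprintf("%d", vapply(mts, `[[`, integer(1), "id")))
  wl("SCALARS plus_state int 1",
     "LOOKUP_TABLE default")
  if (length(mts))
    wl(sprintf("%d", vapply(mts, function(m)
      if (identical(m$plus_state, "growing")) 0L else 1L, integer(1))))
  invisible(path)
}

#' Read legacy VTK polylines
#'
#' Inverse of [write_vtk_polylines()]: reconstructs the microtubule list
#' (vertices, ids, plus-end states) from a legacy ASCII VTK PolyData file.
#' States other than the plus-end state are not stored in the file; minus
#' ends read back as `"static"` and `birth_step` as NA.
#'
#' @param path file path.
#' @return a `sim_state`-like list with fields `mts` and `step = NA`.
#' @export
read_vtk_polylines <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 5, grepl("^# vtk DataFile", lines[1]))
  ip <- grep("^POINTS ", lines)[1]
  npts <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- matrix(NA_real_, npts, 3)
  if (npts > 0) {
    vals <- scan(text = lines[(ip + 1):(ip + npts)], quiet = TRUE)
    pts <- matrix(vals, ncol = 3, byrow = TRUE)
  }
  il <- grep("^LINES ", lines)[1]
  nlines <- as.integer(strsplit(lines[il], " ")[[1]][2])
  conn <- vector("list", nlines)
  if (nlines > 0) {
    for (k in seq_len(nlines)) {
      v <- as.integer(strsplit(lines[il + k], " ")[[1]])
      conn[[k]] <- v[-1] + 1L
    }
  }
  ids <- seq_len(nlines) - 1L
  pstate <- rep(0L, nlines)
  ic <- grep("^SCALARS mt_id", lines)
  if (length(ic) && nlines > 0)
    ids <- as.integer(lines[(ic[1] + 2):(ic[1] + 1 + nlines)])
  is2 <- grep("^SCALARS plus_state", lines)
  if (length(is2) && nlines > 0)
    pstate <- as.integer(lines[(is2[1] + 2):(is2[1] + 1 + nlines)])
  mts <- lapply(seq_len(nlines), function(k) {
    list(id = ids[k],
         vertices = pts[conn[[k]], , drop = FALSE],
         plus_state = if (pstate[k] == 0L) "growing" else "shrinking",
         minus_state = "static",
         birth_step = NA_integer_)
  })
  structure(list(step = NA_integer_, mts = mts,
                 crossovers = data.frame(), events = NULL),
            class = "sim_state")
}
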