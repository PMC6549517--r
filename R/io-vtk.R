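#' Export pathlines as VTK polydata
#'
#' Writes the traced pathlines as legacy-ASCII VTK polydata: one polyline
#' per pathline, with per-point `time` and `speed` arrays and a per-line
#' integer `component` array (0 = direct flow .. 3 = residual volume,
#' -1 = excluded), loadable by any standard VTK reader. Samples with
#' undefined positions are dropped per line.
#'
#' @param pathlines a [trace_pathlines()] result.
#' @param labels tibble from [classify_components()] (optional; without it
#'   all component codes are -1).
#' @param path output `.vtk` file path.
#' @return `path`, invisibly.
#' @export
write_pathlines_vtk <- function(pathlines, labels = NULL, path) {
  stopifnot(inherits(pathlines, "pathline_set"))
  ns <- length(pathlines$times)
  n_seed <- nrow(pathlines$status)
  code <- rep(-1L, n_seed)
  if (!is.null(labels)) {
    m <- match(pathlines$status$seed, labels$seed)
    code <- as.integer(labels$label[m]) - 1L
    code[is.na(code)] <- -1L
  }
  # flatten to seed-major point order (all samples of seed 1, then seed 2, ...)
  pp <- aperm(pathlines$positions, c(2, 1, 3))
  dim(pp) <- c(ns * n_seed, 3)
  vv <- aperm(pathlines$velocities, c(2, 1, 3))
  dim(vv) <- c(ns * n_seed, 3)
  keep <- is.finite(pp[, 1])
  pts <- pp[keep, , drop = FALSE]
  ptime <- rep(pathlines$times, n_seed)[keep]
  pspeed <- sqrt(rowSums(vv[keep, , drop = FALSE]^2))
  pspeed[!is.finite(pspeed)] <- 0
  counts <- colSums(matrix(keep, ns, n_seed))
  ends <- cumsum(counts)
  lines <- lapply(seq_len(n_seed), function(i)
    if (counts[i] > 0) (ends[i] - counts[i]):(ends[i] - 1L) else integer(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "LV flow pathlines", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  writeLines(apply(round(pts, 6), 1, paste, collapse = " "), con)
  sizes <- lengths(lines)
  writeLines(sprintf("LINES %d %d", n_seed, sum(sizes + 1L)), con)
  writeLines(vapply(lines, function(ix) paste(c(length(ix), ix), collapse = " "),
                    character(1)), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
               "SCALARS time float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(ptime, digits = 7, trim = TRUE, scientific = FALSE), con)
  writeLines(c("SCALARS speed float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(pspeed, digits = 7, trim = TRUE, scientific = FALSE), con)
  writeLines(c(sprintf("CELL_DATA %d", n_seed),
               "SCALARS component int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(code), con)
  invisible(path)
}

#' Minimal VTK polydata reader (points, lines, cell scalars)
#'
#' Reads back files written by [write_pathlines_vtk()]; intended for
#' round-trip validation, not as a general VTK parser.
#'
#' @param path `.vtk` file.
#' @return list with `points` (matrix), `lines` (list of 0-based point
#'   indices), `component` (integer per line).
#' @export
read_pathlines_vtk <- function(path) {
  txt <- readLines(path)
  ip <- grep("^POINTS", txt)[1]
  np <- as.integer(strsplit(txt[ip], " ")[[1]][2])
  pts <- matrix(as.numeric(unlist(strsplit(txt[(ip + 1):(ip + np)], " "))),
                ncol = 3, byrow = TRUE)
  il <- grep("^LINES", txt)[1]
  nl <- as.integer(strsplit(txt[il], " ")[[1]][2])
  lines <- lapply(strsplit(txt[(il + 1):(il + nl)], " "), function(v) {
    v <- as.integer(v)
    v[-1]
  })
  comp <- NULL
  ic <- grep("^SCALARS component", txt)
  if (length(ic)) {
    comp <- as.integer(txt[(ic[1] + 2):(ic[1] + 1 + nl)])
  }
  list(points = pts, lines = lines, component = comp)
}
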