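#' Labelled 3-D point cloud
#'
#' Container for a set of 3-D points in millimetres in the patient
#' coordinate system (LPS, Z along the superior-inferior axis). Used for
#' tumor-surface contours, body-surface/offset shells, and candidate
#' implantation sites.
#'
#' @param points Numeric matrix (or coercible) with 3 columns `x`, `y`, `z`
#'   in mm, one row per point.
#' @param label Role tag, one of `"tumor-surface"`, `"body-surface"`,
#'   `"candidate"`.
#' @param frame Coordinate-system tag (free text, default `"patient-LPS"`).
#' @return An object of class `point_cloud`: a list with elements `points`
#'   (n x 3 matrix), `label`, `frame`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 2, 3)))
#' centroid(pc)
#' @export
point_cloud <- function(points, label = "tumor-surface", frame = "patient-LPS") {
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3L) {
    stop("'points' must be an n x 3 matrix of (x, y, z) coordinates in mm")
  }
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) {
    stop("a point cloud must contain at least one point")
  }
  if (!all(is.finite(points))) {
    stop("all point coordinates must be finite")
  }
  label <- match.arg(label, c("tumor-surface", "body-surface", "candidate"))
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  structure(list(points = points, label = label, frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, label '%s', frame '%s'\n",
              nrow(x$points), x$label, x$frame))
  invisible(x)
}

#' Centroid of a point cloud
#'
#' Arithmetic mean of the points. Serves as the tumor reference point for
#' the 50 mm proximity constraint and as the origin of the oblique
#' projection views.
#'
#' @param cloud A [point_cloud] or an n x 3 numeric matrix.
#' @return Numeric length-3 vector (x, y, z) in mm.
#' @export
centroid <- function(cloud) {
  pts <- as_points(cloud)
  if (nrow(pts) < 1L) stop("cannot compute the centroid of an empty cloud")
  colMeans(pts)
}

# Coerce a point_cloud or bare matrix to an n x 3 double matrix.
as_points <- function(x) {
  if (inherits(x, "point_cloud")) return(x$points)
  if (is.null(dim(x)) && length(x) == 3L) x <- matrix(x, nrow = 1L)
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("expected 3-column point coordinates")
  storage.mode(m) <- "double"
  m
}

#' Read a point cloud from a CSV or ascii-PLY file
#'
#' Reads structure geometry exported as a plain point list: comma-separated
#' `x,y,z` rows (header optional) or ascii PLY with a vertex element.
#' Binary DICOM structure sets are detected and rejected with an
#' informative error; export contours to CSV/PLY first.
#'
#' @param path Path to the file.
#' @param structure_name Optional name recorded as provenance; also used as
#'   the cloud label when it matches a known role tag.
#' @param label Role tag for the returned cloud.
#' @return A [point_cloud] with coordinates in mm, row order as read.
#' @seealso [write_points()]
#' @export
read_structure_points <- function(path, structure_name = NULL,
                                  label = "tumor-surface") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path))
  }
  if (is_dicom_file(path)) {
    stop(sprintf(paste0(
      "'%s' looks like a binary DICOM file; DICOM structure sets are not ",
      "supported - export the contour of interest as a CSV or ascii-PLY ",
      "point list"), path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  pts <- if (length(first) == 1L && identical(trimws(first), "ply")) {
    read_ply_points(path)
  } else {
    read_csv_points(path)
  }
  pc <- point_cloud(pts, label = label)
  if (!is.null(structure_name)) attr(pc, "structure_name") <- structure_name
  pc
}

is_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 132L)
  length(hdr) >= 132L && rawToChar(hdr[129:132]) == "DICM"
}

read_csv_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop(sprintf("no data rows in '%s'", path))
  start <- keep[1L]
  # optional single header row
  fields <- strsplit(trimws(lines[start]), ",")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(fields))))) {
    keep <- keep[-1L]
    if (length(keep) == 0L) stop(sprintf("no data rows in '%s'", path))
  }
  parse_row <- function(ln) suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), ",")[[1L]]))
  rows <- lapply(keep, parse_row)
  bad <- which(vapply(rows, function(r) length(r) != 3L || anyNA(r), logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("line %d of '%s' is not a numeric x,y,z row: '%s'",
                 keep[bad[1L]], path, lines[keep[bad[1L]]]))
  }
  do.call(rbind, rows)
}

read_ply_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop(sprintf("'%s': ascii PLY header has no end_header", path))
  hdr <- trimws(lines[seq_len(end_hdr)])
  if (!any(grepl("^format\\s+ascii", hdr))) {
    stop(sprintf("'%s': only ascii PLY is supported", path))
  }
  vline <- grep("^element\\s+vertex\\s+\\d+", hdr, value = TRUE)
  if (length(vline) != 1L) stop(sprintf("'%s': PLY vertex element not found", path))
  n <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*$", "\\1", vline))
  body <- lines[(end_hdr + 1L):(end_hdr + n)]
  rows <- lapply(seq_along(body), function(i) {
    r <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1L]]))
    if (length(r) < 3L || anyNA(r[1:3])) {
      stop(sprintf("line %d of '%s' is not a numeric vertex row: '%s'",
                   end_hdr + i, path, body[i]))
    }
    r[1:3]
  })
  do.call(rbind, rows)
}

#' Write a point cloud to CSV or ascii-PLY
#'
#' Coordinates are written with enough digits that a write/read round trip
#' is lossless to well below 1e-6 mm.
#'
#' @param cloud A [point_cloud] or n x 3 matrix.
#' @param path Output path.
#' @param format `"csv"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(cloud, path, format = c("csv", "ply")) {
  format <- match.arg(format)
  pts <- as_points(cloud)
  dirp <- dirname(path)
  if (!dir.exists(dirp)) stop(sprintf("directory does not exist: '%s'", dirp))
  fmt3 <- function(row) paste(sprintf("%.10g", row), collapse = ",")
  if (format == "csv") {
    body <- apply(pts, 1L, fmt3)
    writeLines(c("x,y,z", body), path)
  } else {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(pts)),
                "property double x", "property double y", "property double z",
                "end_header")
    body <- apply(pts, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
    writeLines(c(header, body), path)
  }
  invisible(path)
}
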