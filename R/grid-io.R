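#' @include AllClasses.R
NULL

#' Construct a density grid
#' @param values 3D numeric array.
#' @param origin Cartesian origin (Angstrom) of voxel (1,1,1).
#' @param step 3x3 matrix, columns = Cartesian axis steps (Angstrom), or a
#'   length-3 vector for an axis-aligned grid.
#' @param periodic Logical.
#' @param unit Value unit tag.
#' @return A \code{DensityGrid}.
#' @export
densityGrid <- function(values, origin = c(0, 0, 0), step,
                        periodic = FALSE, unit = "e/A^3") {
  if (is.null(dim(step))) step <- diag(as.numeric(step), 3)
  new("DensityGrid", values = values, origin = as.numeric(origin),
      step = step, periodic = periodic, unit = unit)
}

#' Voxel volume of a grid
#' @param grid A \code{DensityGrid}.
#' @return Volume in cubic Angstrom.
#' @export
voxelVolume <- function(grid) abs(det(grid@step))

#' Write a Gaussian cube file
#'
#' @param grid A \code{DensityGrid}.
#' @param path Output path.
#' @param atoms Optional data frame with columns element, x, y, z
#'   (Cartesian Angstrom) written to the header.
#' @return Invisibly, the path.
#' @export
writeCube <- function(grid, path, atoms = NULL) {
  b <- .bohrToAngstrom
  d <- dim(grid@values)
  na <- if (is.null(atoms)) 0 else nrow(atoms)
  lines <- c("TaamKin density grid",
             sprintf("values in %s", grid@unit),
             sprintf("%5d %11.6f %11.6f %11.6f", na, grid@origin[1] / b,
                     grid@origin[2] / b, grid@origin[3] / b))
  for (ax in 1:3)
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f", d[ax],
                              grid@step[1, ax] / b, grid@step[2, ax] / b,
                              grid@step[3, ax] / b))
  if (na > 0)
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                              atomicNumber(atoms$element),
                              atomicNumber(atoms$element),
                              atoms$x / b, atoms$y / b, atoms$z / b))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(lines, con)
  # z fastest, then y, then x
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- grid@values[i, j, ]
    writeLines(paste(sprintf("%13.5e", v), collapse = " "), con)
  }
  invisible(path)
}

#' Read a Gaussian cube file
#' @param path File path.
#' @return List with \code{grid} (a \code{DensityGrid}) and \code{atoms}
#'   (data frame of element, x, y, z in Angstrom, or NULL).
#' @export
readCube <- function(path) {
  b <- .bohrToAngstrom
  lines <- readLines(path)
  unit <- sub("^values in ", "", lines[2])
  hdr <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  na <- abs(hdr[1])
  origin <- hdr[2:4] * b
  dims <- integer(3); step <- matrix(0, 3, 3)
  for (ax in 1:3) {
    v <- as.numeric(strsplit(trimws(lines[3 + ax]), "\\s+")[[1]])
    dims[ax] <- v[1]; step[, ax] <- v[2:4] * b
  }
  atoms <- NULL
  if (na > 0) {
    am <- do.call(rbind, lapply(lines[7:(6 + na)], function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
    zmap <- names(.elementZ)[match(am[, 1], .elementZ)]
    atoms <- data.frame(element = zmap, x = am[, 3] * b, y = am[, 4] * b,
                        z = am[, 5] * b)
  }
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(7 + na):length(lines)]), "\\s+")))
  if (length(vals) != prod(dims)) stop("cube value count mismatch")
  arr <- aperm(array(vals, dim = rev(dims)), 3:1)
  list(grid = densityGrid(arr, origin, step,
                          unit = if (grepl("^values", lines[2])) unit else "e/A^3"),
       atoms = atoms)
}

#' Read an XYZ molecular geometry file
#' @param path File path.
#' @return Data frame with element, x, y, z (Angstrom).
#' @export
readXyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  data.frame(element = vapply(rows, `[[`, "", 1),
             x = as.numeric(vapply(rows, `[[`, "", 2)),
             y = as.numeric(vapply(rows, `[[`, "", 3)),
             z = as.numeric(vapply(rows, `[[`, "", 4)))
}

#' Write an XYZ molecular geometry file
#' @param atoms Data frame with element, x, y, z (Angstrom).
#' @param path Output path.
#' @param comment Second-line comment.
#' @return Invisibly, the path.
#' @export
writeXyz <- function(atoms, path, comment = "") {
  writeLines(c(nrow(atoms), comment,
               sprintf("%-2s %12.6f %12.6f %12.6f", atoms$element, atoms$x,
                       atoms$y, atoms$z)), path)
  invisible(path)
}
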