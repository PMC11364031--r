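#' @include cell-symmetry.R
NULL

#' Read a SHELX HKLF4 reflection file
#'
#' Fixed-width records (3I4, 2F8.2): h k l F^2 sigma(F^2).  Reading stops
#' at the all-zero termination record.  Negative intensities are kept
#' (weak data); non-positive sigmas are rejected.
#'
#' @param path File path.
#' @param cell \code{UnitCell} used to derive resolutions.
#' @return A \code{ReflectionSet}.
#' @export
readHklf4 <- function(path, cell) {
  lines <- readLines(path)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (nchar(ln) < 28) stop("malformed HKLF4 record at line ", i)
    v <- suppressWarnings(as.numeric(c(substr(ln, 1, 4), substr(ln, 5, 8),
                                       substr(ln, 9, 12), substr(ln, 13, 20),
                                       substr(ln, 21, 28))))
    if (anyNA(v)) stop("malformed HKLF4 record at line ", i)
    if (all(v[1:3] == 0)) break  # termination record
    if (v[5] <= 0) stop("non-positive sigma at line ", i)
    recs[[length(recs) + 1]] <- v
  }
  if (length(recs) == 0) stop("no reflections in ", path)
  m <- do.call(rbind, recs)
  reflectionSet(m[, 1:3], m[, 4], m[, 5], cell)
}

#' Write a SHELX HKLF4 reflection file
#'
#' @param refl A \code{ReflectionSet}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeHklf4 <- function(refl, path) {
  if (any(abs(refl@fobs2) > 9999999 | refl@sigma > 9999999))
    stop("intensities too large for HKLF4 fixed-width fields; rescale first")
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", refl@hkl[, 1], refl@hkl[, 2],
                   refl@hkl[, 3], refl@fobs2, refl@sigma)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)), path)
  invisible(path)
}
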