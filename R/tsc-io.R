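#' @include AllGenerics.R
NULL

#' Write a .tsc form-factor table
#'
#' Plain-text dialect: a header with TITLE, SYMM and SCATTERERS records,
#' a DATA: marker, then one line per reflection with whitespace-separated
#' h k l followed by one "re,im" pair per scatterer.
#'
#' @param table A \code{FormFactorTable}.
#' @param path Output path.
#' @param title Title string for the header.
#' @return Invisibly, the path.
#' @export
writeTsc <- function(table, path, title = "TaamKin scattering factors") {
  vals <- table@values
  pairs <- matrix(sprintf("%.8e,%.8e", Re(vals), Im(vals)), nrow = nrow(vals))
  lines <- c(
    paste0("TITLE: ", title),
    "SYMM: expanded",
    paste0("AD: ", if (table@radiation == "electron") "TRUE" else "FALSE"),
    paste0("SCATTERERS: ", paste(table@atoms, collapse = " ")),
    "DATA:",
    paste(table@hkl[, 1], table@hkl[, 2], table@hkl[, 3],
          apply(pairs, 1, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a .tsc form-factor table
#'
#' Accepts both "re,im" pairs and plain real values; lines starting with
#' "#" are ignored.
#'
#' @param path File path.
#' @param radiation Radiation tag to attach ("electron" by default; the
#'   format itself does not record it beyond the AD flag).
#' @return A \code{FormFactorTable}.
#' @export
readTsc <- function(path, radiation = "electron") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  scatLine <- grep("^SCATTERERS:", lines, value = TRUE)
  if (length(scatLine) == 0) stop("missing SCATTERERS: header in ", path)
  atoms <- strsplit(trimws(sub("^SCATTERERS:", "", scatLine[1])), "\\s+")[[1]]
  dataAt <- grep("^DATA:", lines)
  if (length(dataAt) == 0) stop("missing DATA: marker in ", path)
  body <- lines[(dataAt[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("no reflection records in ", path)
  n <- length(body); na <- length(atoms)
  hkl <- matrix(0L, n, 3)
  vals <- matrix(complex(1), n, na)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != 3 + na)
      stop("line ", dataAt[1] + i, ": expected ", 3 + na, " fields, got ",
           length(f))
    hkl[i, ] <- as.integer(f[1:3])
    for (j in seq_len(na)) {
      pr <- strsplit(f[3 + j], ",")[[1]]
      vals[i, j] <- if (length(pr) == 2)
        complex(real = as.numeric(pr[1]), imaginary = as.numeric(pr[2]))
      else complex(real = as.numeric(pr[1]))
    }
    if (anyNA(c(hkl[i, ], vals[i, ])))
      stop("line ", dataAt[1] + i, ": unparseable numeric field")
  }
  new("FormFactorTable", hkl = hkl, atoms = atoms, values = vals,
      radiation = radiation)
}
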