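#' Read a RIDME time trace from disk
#'
#' Two dialects: \code{"ascii2col"}, whitespace- or comma-separated two-column
#' text (time in ns, amplitude; '#' comments), and \code{"bes3t"}, a minimal
#' reader for Bruker BES3T descriptor/data pairs (.DSC/.DTA): the X axis is
#' reconstructed from XMIN/XWID/XPTS and the real part of the data is taken.
#'
#' @param path input file. For \code{bes3t}, either member of the pair.
#' @param dialect \code{"ascii2col"} (default) or \code{"bes3t"}.
#' @return A \code{\link{time_trace}} (time converted to microseconds).
#' @export
read_trace <- function(path, dialect = c("ascii2col", "bes3t")) {
  dialect <- match.arg(dialect)
  if (dialect == "bes3t") return(.read_bes3t(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("no data lines in ", path)
  parts <- strsplit(trimws(lines[rows]), "[,;[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d of %s: expected two columns",
                 rows[bad[1]], path))
  t_ns <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  nn <- which(is.na(t_ns) | is.na(v))
  if (length(nn) > 0)
    stop(sprintf("parse error at line %d of %s: non-numeric value",
                 rows[nn[1]], path))
  if (any(diff(t_ns) <= 0)) stop("non-monotone time axis in ", path)
  time_trace(t_ns / 1000, v)
}

.read_bes3t <- function(path) {
  base <- tools::file_path_sans_ext(path)
  dsc <- paste0(base, ".DSC")
  dta <- paste0(base, ".DTA")
  if (!file.exists(dsc)) dsc <- paste0(base, ".dsc")
  if (!file.exists(dta)) dta <- paste0(base, ".dta")
  if (!file.exists(dsc) || !file.exists(dta))
    stop("BES3T pair not found for ", path)
  txt <- readLines(dsc, warn = FALSE)
  getkey <- function(key, default = NULL) {
    ln <- grep(paste0("^", key, "\\b"), txt, value = TRUE)
    if (length(ln) == 0) {
      if (is.null(default)) stop("BES3T descriptor missing key ", key)
      return(default)
    }
    trimws(sub(paste0("^", key, "\\s+"), "", ln[1]))
  }
  npts <- as.integer(getkey("XPTS"))
  xmin <- as.numeric(getkey("XMIN"))
  xwid <- as.numeric(getkey("XWID"))
  irfmt <- getkey("IRFMT", "D")
  ikkf <- getkey("IKKF", "REAL")
  bseq <- getkey("BSEQ", "BIG")
  endian <- if (toupper(bseq) == "BIG") "big" else "little"
  size <- if (toupper(irfmt) %in% c("D", "F64")) 8L else 4L
  nvals <- if (toupper(ikkf) == "CPLX") 2L * npts else npts
  raw <- readBin(dta, "numeric", n = nvals, size = size, endian = endian)
  v <- if (toupper(ikkf) == "CPLX") raw[seq(1, 2 * npts, by = 2)] else raw
  t_ns <- xmin + xwid * seq(0, npts - 1) / (npts - 1)
  time_trace(t_ns / 1000, v)
}

#' Write a time trace as two-column ASCII (ns, amplitude)
#'
#' @param trace a \code{\link{time_trace}}.
#' @param path output file.
#' @param header comment lines written with a '#' prefix (provenance).
#' @export
write_trace <- function(trace, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines("# t_ns amplitude", con)
  writeLines(sprintf("%.17g %.17g", trace$t * 1000, trace$v), con)
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration is a JSON-serializable list (g-values, mode, bounds,
#' Monte-Carlo budget, seeds, background options, paths). A saved
#' configuration re-runs to identical outputs because every stochastic path
#' is seed-controlled.
#'
#' @param config a named list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Quadrature decomposition of an angular width
#'
#' When two independent Gaussian mechanisms contribute to an angular spread,
#' the total width obeys total^2 = part1^2 + part2^2. Given the total and one
#' part, returns the other part — e.g. separating the g-axes orientation
#' spread within the porphyrin plane from the linker-motion contribution to
#' the azimuthal width.
#'
#' @param total total Gaussian width, degrees.
#' @param part one contribution, degrees (<= total).
#' @return The complementary width sqrt(total^2 - part^2), degrees.
#' @export
#' @examples
#' width_quadrature_complement(30, 14)  # about 26.5 degrees
width_quadrature_complement <- function(total, part) {
  if (any(part > total)) stop("part exceeds total width")
  sqrt(total^2 - part^2)
}
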