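#' Construct a spectrum
#'
#' A spectrum is the universal currency of this package: a strictly
#' increasing wavelength grid (nm) paired with per-wavelength values and a
#' unit tag. Reflectance, transmittance and sensitivity spectra are
#' `"dimensionless"` and must lie in \[0, 1\]; light fields are tagged
#' `"irradiance"` (photons m^-2 s^-1 nm^-1) or `"radiance"` (the same per
#' steradian).
#'
#' @param wl Numeric vector of wavelengths in nanometres, strictly
#'   increasing, at least two points.
#' @param value Numeric vector of the same length as `wl`.
#' @param unit One of `"dimensionless"`, `"irradiance"`, `"radiance"`.
#' @param bounded If `TRUE` (the default for dimensionless spectra),
#'   values are checked to lie in \[0, 1\].
#' @return An object of class `lc_spectrum` with fields `wl`, `value`,
#'   `unit`.
#' @examples
#' s <- lc_spectrum(300:700, rep(0.5, 401))
#' band_mean(s, 300, 400)
#' @export
lc_spectrum <- function(wl, value,
                        unit = c("dimensionless", "irradiance", "radiance"),
                        bounded = NULL) {
  unit <- match.arg(unit)
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) < 2L)
    stop("a spectrum needs at least two wavelength points", call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (length(value) != length(wl))
    stop("`value` must have the same length as `wl`", call. = FALSE)
  if (any(!is.finite(value)))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(value < 0))
    stop("physical spectra are non-negative", call. = FALSE)
  if (is.null(bounded)) bounded <- identical(unit, "dimensionless")
  if (bounded && any(value > 1 + 1e-9))
    stop("dimensionless spectra (reflectance/transmittance/sensitivity) must lie in [0, 1]",
         call. = FALSE)
  structure(list(wl = wl, value = value, unit = unit), class = "lc_spectrum")
}

#' Default wavelength grid
#'
#' 300-700 nm at 1-nm steps, covering the full avian UV-visible range.
#'
#' @param from,to,by Grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(from = 300, to = 700, by = 1) seq(from, to, by = by)

#' @export
print.lc_spectrum <- function(x, ...) {
  cat(sprintf("<lc_spectrum> %d points, %.0f-%.0f nm, unit: %s\n",
              length(x$wl), min(x$wl), max(x$wl), x$unit))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.lc_spectrum <- function(x, ..., xlab = "wavelength (nm)", ylab = x$unit,
                             type = "l") {
  graphics::plot(x$wl, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "lc_spectrum")

same_grid <- function(a, b) {
  length(a$wl) == length(b$wl) && all(a$wl == b$wl)
}

stop_if_grid_mismatch <- function(...) {
  ss <- list(...)
  for (i in seq_along(ss)[-1])
    if (!same_grid(ss[[1]], ss[[i]]))
      stop("spectra are defined on different wavelength grids", call. = FALSE)
  invisible(TRUE)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the source range get value 0.
#' The unit tag is preserved.
#'
#' @param spectrum An [lc_spectrum].
#' @param wl Target wavelength grid (strictly increasing numeric vector).
#' @return An [lc_spectrum] on `wl`.
#' @export
resample <- function(spectrum, wl) {
  stopifnot(is_spectrum(spectrum))
  wl <- as.numeric(wl)
  if (max(wl) < min(spectrum$wl) || min(wl) > max(spectrum$wl))
    stop("target grid does not overlap the source spectrum", call. = FALSE)
  v <- stats::approx(spectrum$wl, spectrum$value, xout = wl,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  lc_spectrum(wl, v, unit = spectrum$unit, bounded = FALSE)
}

# trapezoid quadrature weights for an arbitrary increasing grid
trapz_weights <- function(wl) {
  n <- length(wl)
  d <- diff(wl)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Trapezoid-weighted mean of a spectrum over a band
#'
#' Integrates the spectrum over `[lo, hi]` by the trapezoid rule (splitting
#' the boundary intervals exactly) and divides by the band width.
#'
#' @param spectrum An [lc_spectrum].
#' @param lo,hi Band limits in nm, `lo < hi`; the band must overlap the grid.
#' @return Scalar band mean.
#' @export
band_mean <- function(spectrum, lo, hi) {
  stopifnot(is_spectrum(spectrum))
  if (lo >= hi) stop("`lo` must be less than `hi`", call. = FALSE)
  if (hi < min(spectrum$wl) || lo > max(spectrum$wl))
    stop("band [lo, hi] does not overlap the spectrum's grid", call. = FALSE)
  lo <- max(lo, min(spectrum$wl))
  hi <- min(hi, max(spectrum$wl))
  keep <- spectrum$wl > lo & spectrum$wl < hi
  wl <- c(lo, spectrum$wl[keep], hi)
  v <- stats::approx(spectrum$wl, spectrum$value, xout = wl)$y
  sum(trapz_weights(wl) * v) / (hi - lo)
}

#' Trapezoid integral of a pointwise product of spectra
#'
#' The integration kernel behind every quantum catch: all factors must
#' share one wavelength grid; their pointwise product is integrated by the
#' trapezoid rule.
#'
#' @param ... Two or more [lc_spectrum] objects (or a single list of them).
#' @return Scalar integral.
#' @export
integrate_product <- function(...) {
  ss <- list(...)
  if (length(ss) == 1L && !is_spectrum(ss[[1]])) ss <- ss[[1]]
  stopifnot(length(ss) >= 1L, all(vapply(ss, is_spectrum, logical(1))))
  do.call(stop_if_grid_mismatch, ss)
  v <- Reduce(`*`, lapply(ss, `[[`, "value"))
  sum(trapz_weights(ss[[1]]$wl) * v)
}

#' Read a spectrum from a two-column delimited text file
#'
#' Expected layout: wavelength in nm in the first column, value in the
#' second; `#` starts a comment; a single header line is tolerated and
#' skipped automatically. Whitespace, comma and tab delimiters all work.
#'
#' @param path File path.
#' @param unit Unit tag for the resulting spectrum.
#' @return An [lc_spectrum].
#' @export
read_spectrum <- function(path,
                          unit = c("dimensionless", "irradiance", "radiance")) {
  unit <- match.arg(unit)
  tab <- read_numeric_table(path, min_cols = 2)
  lc_spectrum(tab[[1]], tab[[2]], unit = unit, bounded = FALSE)
}

#' Write a spectrum to a two-column delimited text file
#'
#' @param spectrum An [lc_spectrum].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(is_spectrum(spectrum))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", spectrum$unit), con)
  writeLines("wavelength_nm\tvalue", con)
  utils::write.table(data.frame(spectrum$wl, spectrum$value), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Shared reader for small numeric tables: '#' comments, optional single
# header row, whitespace/comma/tab delimited.
read_numeric_table <- function(path, min_cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data in ", path, call. = FALSE)
  first <- strsplit(lines[1], "[,\t ]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) lines <- lines[-1]
  tab <- utils::read.table(text = lines, sep = "", header = FALSE,
                           comment.char = "", dec = ".",
                           colClasses = "numeric",
                           fill = FALSE, strip.white = TRUE)
  if (ncol(tab) == 1) # retry comma-delimited
    tab <- utils::read.table(text = gsub(",", " ", lines), sep = "",
                             header = FALSE, colClasses = "numeric")
  if (ncol(tab) < min_cols)
    stop("expected at least ", min_cols, " numeric columns in ", path,
         call. = FALSE)
  tab
}
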