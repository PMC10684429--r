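#' Construct a Raman spectrum
#'
#' The canonical in-memory representation of a one-dimensional Raman
#' spectrum: a strictly increasing wavenumber axis in cm^-1 and an intensity
#' vector in arbitrary counts, plus optional acquisition metadata. All
#' downstream functions (cropping, hard-model fitting, pH prediction) accept
#' this class.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1. If the axis is
#'   strictly decreasing both vectors are silently reversed, matching the
#'   descending storage convention of many instrument exports.
#' @param intensity Numeric vector of intensities (arbitrary counts), same
#'   length as `wavenumber`.
#' @param temperature Optional sample temperature in kelvin (273.15-373.15).
#' @param reference_ph Optional reference-electrode pH reading.
#' @param label Character identifier.
#' @return An object of class `raman_spectrum` with fields `wavenumber`,
#'   `intensity`, `temperature`, `reference_ph`, `label`.
#' @examples
#' s <- raman_spectrum(2700:2710, rnorm(11, 100), temperature = 308.15)
#' crop(s, 2702, 2705)
#' @export
raman_spectrum <- function(wavenumber, intensity, temperature = NULL,
                           reference_ph = NULL, label = "") {
  if (!is.numeric(wavenumber) || !is.numeric(intensity)) {
    gp_validation_error("wavenumber and intensity must be numeric vectors")
  }
  if (length(wavenumber) != length(intensity)) {
    gp_validation_error(sprintf(
      "wavenumber (%d) and intensity (%d) lengths differ",
      length(wavenumber), length(intensity)))
  }
  if (length(wavenumber) < 2L) {
    gp_validation_error("a spectrum needs at least 2 points")
  }
  if (anyNA(wavenumber) || anyNA(intensity)) {
    gp_validation_error("spectrum contains NA values")
  }
  d <- diff(wavenumber)
  if (all(d < 0)) {               # descending axis: canonicalize
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
    d <- -rev(d)
  }
  if (any(d <= 0)) {
    gp_validation_error("wavenumber axis is not strictly monotone")
  }
  if (!is.null(temperature)) assert_temperature(temperature)
  if (!is.null(reference_ph)) assert_scalar_number(reference_ph, "reference_ph")
  structure(
    list(wavenumber = as.double(wavenumber),
         intensity = as.double(intensity),
         temperature = temperature,
         reference_ph = reference_ph,
         label = as.character(label)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s: %d points, %.1f-%.1f cm-1",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (!is.null(x$temperature)) cat(sprintf(", T = %.2f K", x$temperature))
  if (!is.null(x$reference_ph)) cat(sprintf(", ref pH = %.3f", x$reference_ph))
  cat("\n")
  invisible(x)
}

#' Ordered collection of Raman spectra on a shared wavenumber grid
#'
#' @param spectra List of [raman_spectrum()] objects sharing one axis.
#' @param label Experiment label.
#' @param timestamps Optional numeric vector of acquisition times in seconds.
#' @return A `spectrum_series` object.
#' @export
spectrum_series <- function(spectra, label = "", timestamps = NULL) {
  if (length(spectra) == 0L) gp_validation_error("series must be non-empty")
  ok <- vapply(spectra, inherits, logical(1), "raman_spectrum")
  if (!all(ok)) gp_validation_error("all elements must be raman_spectrum objects")
  ref <- spectra[[1L]]$wavenumber
  same <- vapply(spectra, function(s) {
    length(s$wavenumber) == length(ref) && all(s$wavenumber == ref)
  }, logical(1))
  if (!all(same)) gp_validation_error("all spectra must share one wavenumber grid")
  if (!is.null(timestamps) && length(timestamps) != length(spectra)) {
    gp_validation_error("timestamps length must match number of spectra")
  }
  structure(list(spectra = spectra, label = as.character(label),
                 timestamps = timestamps),
            class = "spectrum_series")
}

#' @export
length.spectrum_series <- function(x) length(x$spectra)

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> %s: %d spectra, %d points each\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$spectra), length(x$spectra[[1L]]$wavenumber)))
  invisible(x)
}

#' Read a Raman spectrum from CSV or JCAMP-DX
#'
#' CSV files are two numeric columns (wavenumber, intensity), comma- or
#' tab-separated, with optional `#`-prefixed `key=value` metadata lines and
#' an optional header row. JCAMP-DX files may use either the
#' `XYDATA=(X++(Y..Y))` or the `XYPOINTS=(XY..XY)` dialect (AFFN numerals).
#' Decreasing axes are reversed on read so the returned axis is strictly
#' increasing.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jcamp"`; `"auto"` guesses from the extension.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) gp_io_error(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") read_spectrum_csv(path) else read_spectrum_jcamp(path)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  data_rows <- character(0)
  data_lineno <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      if (grepl("=", kv, fixed = TRUE)) {
        key <- trimws(sub("=.*$", "", kv))
        val <- trimws(sub("^[^=]*=", "", kv))
        meta[[key]] <- val
      }
      next
    }
    data_rows <- c(data_rows, ln)
    data_lineno <- c(data_lineno, i)
  }
  if (length(data_rows) == 0L) gp_parse_error(sprintf("%s: no data rows", path))
  # optional single header row, recognized by a non-numeric FIRST column
  # (a numeric first column with a bad second column is a data error, not
  # a header)
  first_fields <- strsplit(data_rows[[1L]], "[,\t]")[[1L]]
  if (suppressWarnings(is.na(as.numeric(first_fields[1L])))) {
    data_rows <- data_rows[-1L]
    data_lineno <- data_lineno[-1L]
    if (length(data_rows) == 0L) gp_parse_error(sprintf("%s: no data rows", path))
  }
  n <- length(data_rows)
  wn <- numeric(n); it <- numeric(n)
  for (j in seq_len(n)) {
    fields <- strsplit(data_rows[[j]], "[,\t]")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      gp_parse_error(sprintf("%s: cannot parse two numbers on line %d: '%s'",
                             path, data_lineno[[j]], data_rows[[j]]))
    }
    wn[j] <- vals[1L]; it[j] <- vals[2L]
  }
  temp <- if (!is.null(meta[["temperature_K"]])) as.numeric(meta[["temperature_K"]]) else NULL
  refp <- if (!is.null(meta[["reference_ph"]])) as.numeric(meta[["reference_ph"]]) else NULL
  lab <- if (!is.null(meta[["label"]])) meta[["label"]] else ""
  raman_spectrum(wn, it, temperature = temp, reference_ph = refp, label = lab)
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^##", name, "="), "", lines[[hit[1L]]]))
  }
  num_ldr <- function(name) {
    v <- ldr(name)
    if (is.null(v)) NULL else suppressWarnings(as.numeric(v))
  }
  title <- ldr("TITLE")
  temp <- num_ldr("\\$TEMPERATUREKELVIN")
  refp <- num_ldr("\\$REFERENCEPH")

  xy_start <- grep("^##XYPOINTS=", lines)
  xd_start <- grep("^##XYDATA=", lines)
  end_idx <- grep("^##END", lines)
  end_for <- function(start) {
    after <- c(grep("^##", lines)[grep("^##", lines) > start], length(lines) + 1L)
    min(after) - 1L
  }
  parse_nums <- function(txt) {
    toks <- unlist(strsplit(txt, "[,;[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) gp_parse_error(sprintf("%s: non-numeric token in data block", path))
    vals
  }
  if (length(xy_start) > 0L) {
    block <- lines[(xy_start[1L] + 1L):end_for(xy_start[1L])]
    vals <- parse_nums(paste(block, collapse = " "))
    if (length(vals) %% 2L != 0L) {
      gp_parse_error(sprintf("%s: odd number of values in XYPOINTS", path))
    }
    wn <- vals[seq(1L, length(vals), by = 2L)]
    it <- vals[seq(2L, length(vals), by = 2L)]
  } else if (length(xd_start) > 0L) {
    xfac <- num_ldr("XFACTOR"); if (is.null(xfac) || is.na(xfac)) xfac <- 1
    yfac <- num_ldr("YFACTOR"); if (is.null(yfac) || is.na(yfac)) yfac <- 1
    block <- lines[(xd_start[1L] + 1L):end_for(xd_start[1L])]
    wn <- numeric(0); it <- numeric(0)
    for (ln in block) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      vals <- parse_nums(ln)
      if (length(vals) < 2L) {
        gp_parse_error(sprintf("%s: XYDATA line with fewer than 2 values", path))
      }
      x0 <- vals[1L] * xfac
      ys <- vals[-1L] * yfac
      # abscissa of each y inferred from the declared increment; fall back to
      # evenly spacing toward the next line is unnecessary for AFFN X++(Y..Y)
      dx <- num_ldr("DELTAX")
      if (is.null(dx) || is.na(dx)) {
        first <- num_ldr("FIRSTX"); last <- num_ldr("LASTX"); np <- num_ldr("NPOINTS")
        if (!is.null(first) && !is.null(last) && !is.null(np) && np > 1) {
          dx <- (last - first) / (np - 1)
        } else {
          gp_parse_error(sprintf("%s: XYDATA without DELTAX or FIRSTX/LASTX/NPOINTS", path))
        }
      }
      wn <- c(wn, x0 + dx * (seq_along(ys) - 1L))
      it <- c(it, ys)
    }
  } else {
    gp_parse_error(sprintf("%s: no XYPOINTS or XYDATA block found", path))
  }
  raman_spectrum(wn, it, temperature = temp, reference_ph = refp,
                 label = if (is.null(title)) "" else title)
}

#' Write a Raman spectrum to CSV or JCAMP-DX
#'
#' Values are written with full double precision (17 significant digits) so
#' that a read/write round trip reproduces the arrays to better than 1e-9
#' relative error. Temperature and reference-pH metadata survive the round
#' trip in both formats.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output path.
#' @param format `"csv"` or `"jcamp"`.
#' @export
write_spectrum <- function(spectrum, path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (!inherits(spectrum, "raman_spectrum")) {
    gp_validation_error("spectrum must be a raman_spectrum")
  }
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  lines <- character(0)
  if (format == "csv") {
    if (nzchar(spectrum$label)) lines <- c(lines, paste0("# label=", spectrum$label))
    if (!is.null(spectrum$temperature)) {
      lines <- c(lines, paste0("# temperature_K=", fmt(spectrum$temperature)))
    }
    if (!is.null(spectrum$reference_ph)) {
      lines <- c(lines, paste0("# reference_ph=", fmt(spectrum$reference_ph)))
    }
    lines <- c(lines, "wavenumber_cm-1,intensity",
               paste0(fmt(spectrum$wavenumber), ",", fmt(spectrum$intensity)))
  } else {
    lines <- c(
      paste0("##TITLE=", if (nzchar(spectrum$label)) spectrum$label else "spectrum"),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=RAMAN SPECTRUM",
      "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
      if (!is.null(spectrum$temperature)) {
        paste0("##$TEMPERATUREKELVIN=", fmt(spectrum$temperature))
      },
      if (!is.null(spectrum$reference_ph)) {
        paste0("##$REFERENCEPH=", fmt(spectrum$reference_ph))
      },
      paste0("##NPOINTS=", length(spectrum$wavenumber)),
      paste0("##FIRSTX=", fmt(spectrum$wavenumber[1L])),
      paste0("##LASTX=", fmt(spectrum$wavenumber[length(spectrum$wavenumber)])),
      "##XYPOINTS=(XY..XY)",
      paste0(fmt(spectrum$wavenumber), ", ", fmt(spectrum$intensity)),
      "##END=")
    lines <- lines[!vapply(lines, is.null, logical(1))]
  }
  ok <- tryCatch({ writeLines(unlist(lines), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) gp_io_error(sprintf("cannot write to %s", path))
  invisible(NULL)
}

#' Crop a spectrum to a closed wavenumber interval
#'
#' Keeps exactly the samples with `lo <= wavenumber <= hi`. The standard
#' evaluation window for the MOPS pH model is 2700-3100 cm^-1.
#'
#' @param spectrum A [raman_spectrum()].
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return The cropped [raman_spectrum()].
#' @export
crop <- function(spectrum, lo, hi) {
  if (!inherits(spectrum, "raman_spectrum")) {
    gp_validation_error("spectrum must be a raman_spectrum")
  }
  assert_scalar_number(lo, "lo"); assert_scalar_number(hi, "hi")
  if (lo >= hi) gp_validation_error("crop requires lo < hi")
  keep <- spectrum$wavenumber >= lo & spectrum$wavenumber <= hi
  if (sum(keep) < 2L) {
    gp_validation_error(sprintf(
      "crop window [%g, %g] overlaps the axis [%g, %g] in fewer than 2 points",
      lo, hi, min(spectrum$wavenumber), max(spectrum$wavenumber)))
  }
  raman_spectrum(spectrum$wavenumber[keep], spectrum$intensity[keep],
                 temperature = spectrum$temperature,
                 reference_ph = spectrum$reference_ph,
                 label = spectrum$label)
}
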