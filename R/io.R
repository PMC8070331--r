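#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files are two numeric columns (wavenumber, ordinate), comma-separated
#' with "." decimal and an optional single header line. JCAMP-DX files are
#' accepted with AFFN-encoded `XYDATA=(X++(Y..Y))` or `XYPOINTS=(XY..XY)`
#' tables; `XFACTOR`/`YFACTOR` are honoured. Compressed (SQZ/DIF/DUP) JCAMP
#' encodings are not supported.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jcamp"`.
#' @param mode Ordinate mode (see [ordinate_modes]). For CSV, may be omitted
#'   when the header names a known mode (as files written by
#'   [write_spectrum()] do); for JCAMP, may be omitted when `##YUNITS=` is
#'   parseable (TRANSMITTANCE, REFLECTANCE, ABSORBANCE, KUBELKA-MUNK). An
#'   explicit argument always wins.
#' @return An [ir_spectrum] with wavenumbers sorted ascending.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("csv", "jcamp"), mode = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "csv") read_spectrum_csv(path, mode) else read_spectrum_jcamp(path, mode)
}

num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

read_spectrum_csv <- function(path, mode) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file", call. = FALSE)
  fields1 <- trimws(strsplit(lines[[1]], ",", fixed = TRUE)[[1]])
  has_header <- !all(grepl(num_re, fields1))
  if (has_header) {
    if (is.null(mode)) {
      hit <- fields1[fields1 %in% ordinate_modes]
      if (length(hit) == 1L) mode <- hit
      else stop("`mode` not given and not named in the CSV header", call. = FALSE)
    }
    lines <- lines[-1L]
  }
  if (is.null(mode)) {
    stop("`mode` must be given for headerless CSV spectra", call. = FALSE)
  }
  if (length(lines) < 2L) stop("spectrum needs at least 2 data rows", call. = FALSE)
  wn <- numeric(length(lines)); y <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1]])
    if (length(f) != 2L || !all(grepl(num_re, f))) {
      stop(sprintf("non-numeric or malformed CSV row at data line %d: '%s'",
                   i, lines[[i]]), call. = FALSE)
    }
    wn[i] <- as.numeric(f[[1]]); y[i] <- as.numeric(f[[2]])
  }
  if (anyDuplicated(wn)) stop("duplicate wavenumbers in file", call. = FALSE)
  ir_spectrum(wn, y, mode)
}

jcamp_yunits_to_mode <- c(
  "TRANSMITTANCE" = "percent_transmittance",
  "REFLECTANCE"   = "percent_reflectance",
  "ABSORBANCE"    = "absorbance",
  "KUBELKA-MUNK"  = "kubelka_munk",
  "KUBELKA MUNK"  = "kubelka_munk"
)

read_spectrum_jcamp <- function(path, mode) {
  lines <- readLines(path, warn = FALSE)
  ldr_idx <- grep("^\\s*##", lines)
  labels <- character(0); values <- character(0)
  for (i in ldr_idx) {
    m <- regmatches(lines[[i]], regexec("^\\s*##([^=]*)=(.*)$", lines[[i]]))[[1]]
    if (length(m) == 3L) {
      # JCAMP labels compare case-insensitively with spaces/dashes ignored
      labels <- c(labels, toupper(gsub("[ _-]", "", m[[2]])))
      values <- c(values, trimws(m[[3]]))
    }
  }
  ldr <- function(name, default = NA_character_) {
    j <- which(labels == name)
    if (length(j)) values[[j[1]]] else default
  }
  if (is.null(mode)) {
    yu <- toupper(ldr("YUNITS"))
    if (!is.na(yu) && yu %in% names(jcamp_yunits_to_mode)) {
      mode <- unname(jcamp_yunits_to_mode[[yu]])
    } else {
      stop("`mode` not given and ##YUNITS= not parseable", call. = FALSE)
    }
  }
  xfac <- as.numeric(ldr("XFACTOR", "1"))
  yfac <- as.numeric(ldr("YFACTOR", "1"))
  data_start <- grep("^\\s*##\\s*(XYDATA|XYPOINTS|XY\\s*DATA|XY\\s*POINTS)\\s*=",
                     toupper(lines))
  if (!length(data_start)) {
    stop("no ##XYDATA= or ##XYPOINTS= table in JCAMP file", call. = FALSE)
  }
  i0 <- data_start[[1]]
  is_points <- grepl("XYPOINTS", toupper(lines[[i0]]))
  rest <- lines[seq(i0 + 1L, length(lines))]
  stop_at <- grep("^\\s*##", rest)
  if (length(stop_at)) rest <- rest[seq_len(stop_at[[1]] - 1L)]
  rest <- rest[nzchar(trimws(rest))]
  if (!length(rest)) stop("empty JCAMP data table", call. = FALSE)

  tokenize <- function(line, lineno) {
    toks <- strsplit(trimws(line), "[,;[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    bad <- !grepl(num_re, toks)
    if (any(bad)) {
      stop(sprintf("non-AFFN token '%s' in JCAMP data line %d (compressed forms unsupported)",
                   toks[bad][[1]], lineno), call. = FALSE)
    }
    as.numeric(toks)
  }

  if (is_points) {
    vals <- unlist(lapply(seq_along(rest), function(i) tokenize(rest[[i]], i)))
    if (length(vals) %% 2L != 0L) {
      stop("odd token count in XYPOINTS table", call. = FALSE)
    }
    wn <- vals[seq(1L, length(vals), 2L)] * xfac
    y <- vals[seq(2L, length(vals), 2L)] * yfac
  } else {
    firstx <- as.numeric(ldr("FIRSTX"))
    lastx <- as.numeric(ldr("LASTX"))
    npts <- as.numeric(ldr("NPOINTS"))
    if (is.na(firstx) || is.na(lastx) || is.na(npts) || npts < 2) {
      stop("XYDATA table requires ##FIRSTX=, ##LASTX= and ##NPOINTS= >= 2", call. = FALSE)
    }
    dx <- (lastx - firstx) / (npts - 1)
    wn <- numeric(0); y <- numeric(0)
    for (i in seq_along(rest)) {
      toks <- tokenize(rest[[i]], i)
      if (length(toks) < 2L) {
        stop(sprintf("XYDATA line %d has no ordinate values", i), call. = FALSE)
      }
      x0 <- toks[[1]] * xfac
      ys <- toks[-1L] * yfac
      wn <- c(wn, x0 + (seq_along(ys) - 1L) * dx)
      y <- c(y, ys)
    }
  }
  if (anyDuplicated(wn)) stop("duplicate wavenumbers in file", call. = FALSE)
  ir_spectrum(wn, y, mode)
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' The written file reads back with [read_spectrum()] to a spectrum equal to
#' the original (values kept to 12 significant digits). CSV output carries a
#' header line `wavenumber_cm-1,<mode>`; JCAMP output uses an AFFN
#' `XYPOINTS=(XY..XY)` table with unit X/Y factors.
#'
#' @param s An [ir_spectrum].
#' @param path Output path.
#' @param format `"csv"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "ir_spectrum"))
  fmt <- function(x) sprintf("%.12g", x)
  if (format == "csv") {
    lines <- c(paste0("wavenumber_cm-1,", s$mode),
               paste(fmt(s$wavenumbers), fmt(s$ordinate), sep = ","))
  } else {
    yunits <- switch(s$mode,
      percent_transmittance = "TRANSMITTANCE",
      percent_reflectance = "REFLECTANCE",
      absorbance = "ABSORBANCE",
      kubelka_munk = "KUBELKA-MUNK"
    )
    n <- length(s$wavenumbers)
    lines <- c(
      sprintf("##TITLE=%s", if (!is.null(s$meta$sample_id)) s$meta$sample_id else "spectrum"),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      sprintf("##YUNITS=%s", yunits),
      "##XFACTOR=1",
      "##YFACTOR=1",
      sprintf("##FIRSTX=%s", fmt(s$wavenumbers[[1]])),
      sprintf("##LASTX=%s", fmt(s$wavenumbers[[n]])),
      sprintf("##NPOINTS=%d", n),
      "##XYPOINTS=(XY..XY)",
      paste(fmt(s$wavenumbers), fmt(s$ordinate), sep = ", "),
      "##END="
    )
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  invisible(path)
}
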