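## MassBank record format I/O.
##
## The parser reads the minimal field set needed here (ACCESSION,
## AC$MASS_SPECTROMETRY: ION_MODE, MS$FOCUSED_ION: PRECURSOR_M/Z,
## MS$FOCUSED_ION: ION (selected ion m/z fallback), CH$EXACT_MASS,
## COMMENT: COMPOUND_ID, PK$NUM_PEAK, PK$PEAK) and ignores unknown tags,
## for forward compatibility with richer records. Multiple records in one
## file are separated by "//". When the precursor m/z is absent the
## selected-ion mass is used; absence of both is a record-level error.

#' Read a spectral library from a MassBank-format file
#'
#' @param path file containing one or more MassBank records separated by
#'   `"//"`.
#' @param name library name (defaults to the file name).
#' @return a [SpectralLibrary-class] with one [Spectrum-class] per record,
#'   peaks sorted ascending. When both a raw and a relative intensity
#'   column are present, the raw intensity is used.
#' @seealso [writeMassBank()], [readMGF()]
#' @export
readMassBank <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ## split records on "//" terminator lines
  recEnd <- grepl("^//\\s*$", lines)
  recId <- cumsum(c(0L, head(recEnd, -1L)))
  recs <- split(lines[!recEnd], recId[!recEnd])
  entries <- list()
  for (rec in recs) {
    rec <- rec[nzchar(trimws(rec))]
    if (!length(rec)) next
    entries[[length(entries) + 1L]] <- .parseMassBankRecord(rec)
  }
  spectralLibrary(entries, name = name)
}

.mbField <- function(rec, tag) {
  hit <- grep(paste0("^", gsub("\\$", "\\\\$", tag), ":"), rec, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub("^[^:]*:", "", hit[1]))
}

.mbSubtag <- function(rec, tag, sub) {
  pat <- paste0("^", gsub("\\$", "\\\\$", tag), ": ", sub, " ")
  hit <- grep(pat, rec, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(pat, "", hit[1]))
}

.parseMassBankRecord <- function(rec) {
  acc <- .mbField(rec, "ACCESSION")
  if (is.na(acc)) stop("MassBank record without ACCESSION", call. = FALSE)
  mode <- .mbSubtag(rec, "AC$MASS_SPECTROMETRY", "ION_MODE")
  ionMode <- if (!is.na(mode) && toupper(mode) %in% c("NEGATIVE", "N"))
    "negative" else "positive"
  prec <- suppressWarnings(
    as.numeric(.mbSubtag(rec, "MS$FOCUSED_ION", "PRECURSOR_M/Z")))
  if (is.na(prec))
    prec <- suppressWarnings(
      as.numeric(.mbSubtag(rec, "MS$FOCUSED_ION", "ION")))
  if (is.na(prec))
    stop("record ", acc,
         ": neither precursor m/z nor selected-ion mass present",
         call. = FALSE)
  cmpMass <- suppressWarnings(as.numeric(.mbField(rec, "CH$EXACT_MASS")))
  cmpId <- .mbSubtag(rec, "COMMENT", "COMPOUND_ID")
  ## peak table
  hdrIdx <- grep("^PK\\$PEAK:", rec)
  if (!length(hdrIdx))
    stop("record ", acc, ": no PK$PEAK table", call. = FALSE)
  nDecl <- suppressWarnings(as.integer(.mbField(rec, "PK$NUM_PEAK")))
  peakLines <- rec[seq(hdrIdx + 1L, length(rec))]
  peakLines <- peakLines[nzchar(trimws(peakLines))]
  peakLines <- peakLines[!grepl("^[A-Z]{2}\\$", peakLines)]
  mass <- numeric(length(peakLines)); inten <- numeric(length(peakLines))
  for (i in seq_along(peakLines)) {
    fields <- strsplit(trimws(peakLines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop("record ", acc, ": malformed peak line ", i, ": '",
           peakLines[i], "'", call. = FALSE)
    mass[i] <- vals[1]
    inten[i] <- vals[2]  # raw intensity; rel.int. column (3rd) ignored
  }
  if (!is.na(nDecl) && nDecl != length(mass))
    stop("record ", acc, ": PK$NUM_PEAK declares ", nDecl,
         " peaks but ", length(mass), " rows present", call. = FALSE)
  spectrum(acc, prec, mass, inten, ionMode = ionMode,
           compoundMass = cmpMass, compoundId = cmpId)
}

#' Write a spectral library in MassBank record format
#'
#' @param lib a [SpectralLibrary-class].
#' @param path output file; records are separated by `"//"`.
#' @param digits number of decimal places for masses and intensities.
#' @return `path`, invisibly.
#' @export
writeMassBank <- function(lib, path, digits = 6) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in librarySpectra(lib)) {
    writeLines(c(
      paste0("ACCESSION: ", spectrumId(s)),
      paste0("AC$MASS_SPECTROMETRY: ION_MODE ", toupper(ionMode(s))),
      if (!is.na(compoundMass(s)))
        paste0("CH$EXACT_MASS: ", formatC(compoundMass(s), digits = digits,
                                          format = "f")),
      if (!is.na(compoundId(s)))
        paste0("COMMENT: COMPOUND_ID ", compoundId(s)),
      paste0("MS$FOCUSED_ION: PRECURSOR_M/Z ",
             formatC(precursorMz(s), digits = digits, format = "f")),
      paste0("PK$NUM_PEAK: ", nPeaks(s)),
      "PK$PEAK: m/z int. rel.int."
    ), con)
    pk <- peakTable(s)
    base <- if (nrow(pk)) max(pk[, "intensity"]) else 1
    for (i in seq_len(nrow(pk)))
      writeLines(sprintf("  %s %s %d",
                         formatC(pk[i, "mass"], digits = digits,
                                 format = "f"),
                         formatC(pk[i, "intensity"], digits = digits,
                                 format = "f"),
                         max(1L, round(999 * pk[i, "intensity"] / base))),
                 con)
    writeLines("//", con)
  }
  invisible(path)
}
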