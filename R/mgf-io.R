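## Mascot generic format (MGF) I/O: BEGIN IONS / END IONS blocks with
## PEPMASS, CHARGE and TITLE headers. COMPOUNDMASS and COMPOUNDID are
## carried as extra KEY=VALUE headers so benchmark ground truth survives a
## round trip; unknown headers are ignored.

#' Read a spectral library from an MGF file
#'
#' @param path MGF file with `BEGIN IONS`/`END IONS` blocks.
#' @param name library name (defaults to the file name).
#' @return a [SpectralLibrary-class]; a `CHARGE` ending in `-` yields
#'   negative ion mode. A block without `PEPMASS` is an error; an empty
#'   file yields an empty library with a warning.
#' @seealso [writeMGF()], [readMassBank()]
#' @export
readMGF <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  if (!length(begins)) {
    warning("no spectra found in ", path)
    return(spectralLibrary(name = name))
  }
  entries <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[seq(begins[k] + 1L, ends[k] - 1L)]
    block <- block[nzchar(block)]
    isHdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[isHdr]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    getHdr <- function(key) if (key %in% keys) vals[match(key, keys)]
                            else NA_character_
    pep <- getHdr("PEPMASS")
    if (is.na(pep))
      stop("MGF block ", k, " has no PEPMASS", call. = FALSE)
    prec <- as.numeric(strsplit(trimws(pep), "\\s+")[[1]][1])
    charge <- getHdr("CHARGE")
    mode <- if (!is.na(charge) && grepl("-\\s*$", charge)) "negative"
            else "positive"
    id <- getHdr("TITLE")
    if (is.na(id)) id <- sprintf("%s_%d", name, k)
    cmpMass <- suppressWarnings(as.numeric(getHdr("COMPOUNDMASS")))
    cmpId <- getHdr("COMPOUNDID")
    peakLines <- block[!isHdr]
    mass <- numeric(length(peakLines)); inten <- numeric(length(peakLines))
    for (i in seq_along(peakLines)) {
      vals2 <- suppressWarnings(
        as.numeric(strsplit(peakLines[i], "\\s+")[[1]]))
      if (length(vals2) < 2L || any(is.na(vals2[1:2])))
        stop("MGF block ", k, ": malformed peak line '", peakLines[i], "'",
             call. = FALSE)
      mass[i] <- vals2[1]; inten[i] <- vals2[2]
    }
    entries[[k]] <- spectrum(id, prec, mass, inten, ionMode = mode,
                             compoundMass = cmpMass, compoundId = cmpId)
  }
  spectralLibrary(entries, name = name)
}

#' Write a spectral library as MGF
#'
#' @param lib a [SpectralLibrary-class].
#' @param path output file.
#' @param digits number of decimal places for masses and intensities.
#' @return `path`, invisibly.
#' @export
writeMGF <- function(lib, path, digits = 6) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in librarySpectra(lib)) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", spectrumId(s)), con)
    writeLines(paste0("PEPMASS=", formatC(precursorMz(s), digits = digits,
                                          format = "f")), con)
    writeLines(paste0("CHARGE=1", if (ionMode(s) == "negative") "-" else "+"),
               con)
    if (!is.na(compoundMass(s)))
      writeLines(paste0("COMPOUNDMASS=",
                        formatC(compoundMass(s), digits = digits,
                                format = "f")), con)
    if (!is.na(compoundId(s)))
      writeLines(paste0("COMPOUNDID=", compoundId(s)), con)
    pk <- peakTable(s)
    for (i in seq_len(nrow(pk)))
      writeLines(paste(formatC(pk[i, "mass"], digits = digits, format = "f"),
                       formatC(pk[i, "intensity"], digits = digits,
                               format = "f")), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
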