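## Decoy-library builder: one decoy per usable target spectrum, mirroring
## the target library entry-for-entry so that any precursor-mass window
## contains the same number of target and decoy spectra by construction.

#' Build a decoy spectral library
#'
#' @param targets the target [SpectralLibrary-class].
#' @param trees for `method = "tree_based"`: a named list of
#'   [FragmentationTree-class] objects keyed by spectrum identifier.
#'   Targets without a tree are skipped (and should be removed from the
#'   target side as well, to keep target/decoy parity).
#' @param method decoy construction: `"naive"`, `"spectrum_based"` or
#'   `"tree_based"`.
#' @param seed integer seed; a single seeded generator is consumed in
#'   entry order, so builds are bit-reproducible.
#' @param ... passed to the per-spectrum decoy constructor.
#' @return a [DecoyLibrary-class]; its `report` slot records per-spectrum
#'   status (`ok`, `skipped`, `error`) and messages. Decoy identifiers are
#'   the target identifiers prefixed with `DECOY_`.
#' @export
buildDecoyLibrary <- function(targets, trees = NULL,
                              method = c("naive", "spectrum_based",
                                         "tree_based"),
                              seed = 1L, ...) {
  method <- match.arg(method)
  if (method == "tree_based" && is.null(trees))
    stop("tree_based decoys require fragmentation trees", call. = FALSE)
  specs <- librarySpectra(targets)
  ids <- libraryIds(targets)
  status <- character(length(specs)); msg <- character(length(specs))
  entries <- list()
  withSeed(seed, {
    shared <- switch(method,
      naive = .poolMasses(targets),
      spectrum_based = .poolIndex(targets),
      tree_based = NULL)
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      res <- tryCatch({
        d <- switch(method,
          naive = naiveDecoy(s, shared, ...),
          spectrum_based = spectrumBasedDecoy(s, shared, ...),
          tree_based = {
            tr <- trees[[spectrumId(s)]]
            if (is.null(tr)) NULL else treeBasedDecoy(s, tr, ...)
          })
        if (is.null(d)) {
          status[i] <- "skipped"; msg[i] <- "no fragmentation tree"
        } else {
          d@identifier <- paste0("DECOY_", spectrumId(s))
          entries[[length(entries) + 1L]] <- d
          status[i] <- "ok"
          fb <- attr(d, "fallback"); dr <- attr(d, "dropped")
          msg[i] <- paste(c(
            if (!is.null(fb) && fb > 0L) paste0(fb, " naive-fallback peaks"),
            if (!is.null(dr) && dr > 0L) paste0(dr, " nodes dropped")),
            collapse = "; ")
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) { status[i] <- "error"; msg[i] <- res }
    }
  })
  new("DecoyLibrary",
      entries = entries,
      name = paste0(libraryName(targets), "_decoy_", method),
      method = method,
      sourceLibrary = libraryName(targets),
      seed = as.integer(seed),
      report = data.frame(identifier = ids, status = status,
                          message = msg, stringsAsFactors = FALSE))
}

#' Write a decoy-library build report as JSON
#'
#' @param decoys a [DecoyLibrary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDecoyReport <- function(decoys, path) {
  jsonlite::write_json(
    list(method = decoys@method, seed = decoys@seed,
         source_library = decoys@sourceLibrary,
         n_decoys = length(decoys),
         spectra = decoys@report),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
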