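#' A single LC-HRMS injection
#'
#' Container for one injection's scan stream: MS1 spectra plus any
#' data-dependent (DDA) or data-independent (DIA) MS2 spectra, ordered by
#' retention time. Spectra are stored as a tibble with list-columns `mz` and
#' `intensity` (centroided peak lists).
#'
#' @param spectra Tibble with columns `ms_level` (1 or 2), `rt` (seconds),
#'   `polarity` ("positive"/"negative"), `precursor_mz` (Da, `NA` for MS1),
#'   `acquisition_mode` ("none", "DDA" or "DIA"), and list-columns `mz`,
#'   `intensity`.
#' @param path Source file path (or a synthetic label).
#' @param acquired_at Acquisition timestamp (`POSIXct`).
#' @param sample_type `"blank"`, `"sample"` or `"standard"`.
#' @param batch_id Batch label.
#' @return An object of class `qc_run`.
#' @export
qc_run <- function(spectra, path = NA_character_,
                   acquired_at = Sys.time(),
                   sample_type = c("sample", "blank", "standard"),
                   batch_id = NA_character_) {
  sample_type <- match.arg(sample_type)
  needed <- c("ms_level", "rt", "polarity", "precursor_mz",
              "acquisition_mode", "mz", "intensity")
  missing_cols <- setdiff(needed, names(spectra))
  if (length(missing_cols) > 0) {
    abort(paste0("spectra tibble missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.unsorted(spectra$rt)) {
    spectra <- spectra[order(spectra$rt), , drop = FALSE]
  }
  bad_len <- which(lengths(spectra$mz) != lengths(spectra$intensity))
  if (length(bad_len) > 0) {
    abort(paste0("mz/intensity length mismatch in spectra: ",
                 paste(head(bad_len, 3), collapse = ", ")))
  }
  structure(
    list(path = path, acquired_at = acquired_at, sample_type = sample_type,
         batch_id = batch_id, spectra = tibble::as_tibble(spectra)),
    class = "qc_run"
  )
}

#' @export
print.qc_run <- function(x, ...) {
  n1 <- sum(x$spectra$ms_level == 1)
  n2 <- sum(x$spectra$ms_level == 2)
  cat("<qc_run> ", basename(x$path %||% "<in-memory>"),
      " [", x$sample_type, "]\n", sep = "")
  cat("  acquired:", format(x$acquired_at), "\n")
  cat("  spectra: ", n1, " MS1, ", n2, " MS2",
      if (nrow(x$spectra) > 0)
        paste0("; RT ", round(min(x$spectra$rt), 1), "-",
               round(max(x$spectra$rt), 1), " s"),
      "\n", sep = "")
  invisible(x)
}

ms1_spectra <- function(run) {
  run$spectra[run$spectra$ms_level == 1L, , drop = FALSE]
}

run_polarity <- function(run) {
  if (nrow(run$spectra) == 0) return(NA_character_)
  names(sort(table(run$spectra$polarity), decreasing = TRUE))[1]
}

#' Classify a run's sample type from filename tokens
#'
#' The acquisition system does not record whether an injection is a blank;
#' by convention that information lives in the file name. A file whose base
#' name contains a configured token (case-insensitive, default `"blank"` or
#' `"standard"`) is classified accordingly; everything else is a sample.
#'
#' @param path File path or name.
#' @param tokens Named list mapping sample types to tokens, as in
#'   `qc_config()$sample_type_tokens`.
#' @return One of `"blank"`, `"standard"`, `"sample"`.
#' @export
#' @examples
#' classify_sample_type("2024-03-25_blank_01.mzML")
classify_sample_type <- function(path, tokens = qc_config()$sample_type_tokens) {
  base <- tolower(basename(path))
  for (type in names(tokens)) {
    if (grepl(tolower(tokens[[type]]), base, fixed = TRUE)) return(type)
  }
  "sample"
}

#' Has a raw file been untouched long enough to be complete?
#'
#' The acquisition software writes files incrementally; a file is treated as
#' complete once it has not been modified for at least `quiet_period` seconds
#' (boundary inclusive). Files still being written are deferred to the next
#' polling cycle.
#'
#' @param path File path.
#' @param now Reference time (`POSIXct`), default `Sys.time()`.
#' @param quiet_period Seconds without modification required (default 120).
#' @return `TRUE` if ready; `FALSE` if recently modified or vanished.
#' @export
is_file_ready <- function(path, now = Sys.time(), quiet_period = 120) {
  mt <- file.mtime(path)
  if (is.na(mt)) return(FALSE)
  as.numeric(difftime(now, mt, units = "secs")) >= quiet_period
}

#' Find raw files not yet processed
#'
#' Recursively lists mzML/mzXML files under `root` (subfolders included),
#' drops paths already processed, and returns the rest sorted by modification
#' time ascending so runs are handled in acquisition order.
#'
#' @param root Folder to scan.
#' @param processed Character vector of already-processed paths.
#' @return Character vector of file paths.
#' @export
discover_unprocessed <- function(root, processed = character()) {
  if (!dir.exists(root)) abort(paste0("folder not found: ", root))
  files <- list.files(root, pattern = "\\.(mzML|mzXML)$", ignore.case = TRUE,
                      recursive = TRUE, full.names = TRUE)
  files <- setdiff(normalizePath(files, mustWork = FALSE),
                   normalizePath(processed, mustWork = FALSE))
  files[order(file.mtime(files), files)]
}

#' Load an mzML/mzXML file into a `qc_run`
#'
#' Reads all MS1 scans and MS2 scans via the proteowizard-backed `mzR`
#' reader. MS2 scans with a recorded precursor are treated as DDA;
#' precursor-less MS2 scans are kept as DIA (parsed, but ignored by the MS2
#' library check). Profile-mode files are rejected: peak picking is expected
#' upstream. Loading the same file twice yields equal runs.
#'
#' @param path mzML or mzXML file.
#' @param sample_type_rule Named token list for [classify_sample_type()].
#' @param acquired_at Acquisition timestamp; defaults to the file's mtime.
#' @param batch_id Optional batch label.
#' @return A [qc_run()].
#' @export
load_run <- function(path, sample_type_rule = qc_config()$sample_type_tokens,
                     acquired_at = NULL, batch_id = NA_character_) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading raw files requires the 'mzR' package")
  }
  if (!file.exists(path)) abort(paste0("raw file not found: ", path))
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) abort(paste0("cannot open '", path,
                                                      "': ", conditionMessage(e))))
  on.exit(try(mzR::close(handle), silent = TRUE), add = TRUE)
  hdr <- tryCatch(mzR::header(handle),
                  error = function(e) abort(paste0("cannot read header of '",
                                                   path, "': ",
                                                   conditionMessage(e))))
  if (nrow(hdr) == 0) {
    spectra <- tibble::tibble(
      ms_level = integer(), rt = numeric(), polarity = character(),
      precursor_mz = numeric(), acquisition_mode = character(),
      mz = list(), intensity = list()
    )
  } else {
    if ("centroided" %in% names(hdr) &&
        any(!is.na(hdr$centroided) & !hdr$centroided)) {
      abort(paste0("'", path, "' contains profile spectra; centroided data required"))
    }
    pks <- mzR::peaks(handle)
    if (is.matrix(pks)) pks <- list(pks)
    prec <- hdr$precursorMZ
    prec[is.na(prec) | prec <= 0] <- NA_real_
    mode <- ifelse(hdr$msLevel >= 2,
                   ifelse(is.na(prec), "DIA", "DDA"),
                   "none")
    spectra <- tibble::tibble(
      ms_level = as.integer(hdr$msLevel),
      rt = as.numeric(hdr$retentionTime),
      polarity = ifelse(hdr$polarity >= 0 & hdr$polarity != 0,
                        "positive", "negative"),
      precursor_mz = prec,
      acquisition_mode = mode,
      mz = purrr::map(pks, ~ as.numeric(.x[, 1])),
      intensity = purrr::map(pks, ~ as.numeric(.x[, 2]))
    )
  }
  qc_run(
    spectra,
    path = path,
    acquired_at = acquired_at %||% file.mtime(path),
    sample_type = classify_sample_type(path, sample_type_rule),
    batch_id = batch_id
  )
}

#' Write a `qc_run` to mzML
#'
#' Optional export used for end-to-end tests of the file-based pipeline;
#' requires `mzR`.
#'
#' @param run A [qc_run()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("writing mzML requires the 'mzR' package")
  }
  sp <- run$spectra
  n <- nrow(sp)
  if (n == 0) abort("cannot write an empty run to mzML")
  pol <- ifelse(sp$polarity == "positive", 1L, 0L)
  npk <- lengths(sp$mz)
  tic <- vapply(sp$intensity, function(v) sum(v), numeric(1))
  bpi <- vapply(sp$intensity, function(v) if (length(v)) max(v) else 0, numeric(1))
  bpm <- mapply(function(m, i) if (length(i)) m[which.max(i)] else 0,
                sp$mz, sp$intensity)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = sp$ms_level, polarity = pol, peaksCount = as.integer(npk),
    totIonCurrent = tic, retentionTime = sp$rt,
    basePeakMZ = as.numeric(bpm), basePeakIntensity = bpi,
    collisionEnergy = ifelse(sp$ms_level > 1, 35, 0), ionisationEnergy = 0,
    lowMZ = vapply(sp$mz, function(m) if (length(m)) min(m) else 0, numeric(1)),
    highMZ = vapply(sp$mz, function(m) if (length(m)) max(m) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(is.na(sp$precursor_mz), 0, sp$precursor_mz),
    precursorCharge = ifelse(sp$ms_level > 1, 1L, 0L),
    precursorIntensity = ifelse(sp$ms_level > 1, 1, 0),
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is.na(sp$precursor_mz), NA_real_,
                                     sp$precursor_mz),
    isolationWindowLowerOffset = ifelse(sp$ms_level > 1, 0.5, NA_real_),
    isolationWindowUpperOffset = ifelse(sp$ms_level > 1, 0.5, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  pks <- mapply(function(m, i) cbind(mz = m, intensity = i),
                sp$mz, sp$intensity, SIMPLIFY = FALSE)
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}
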