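#' Select the DDA MS2 spectrum for a compound
#'
#' Among data-dependent MS2 spectra whose precursor lies within `eic_ppm` of
#' the compound's theoretical m/z, the one acquired nearest the peak apex
#' (within the +/-9 s quantification window) is returned. DIA spectra are
#' never considered. Returns `NULL` when no spectrum qualifies, in which
#' case the library check is skipped for this run.
#'
#' @param run A [qc_run()].
#' @param compound One row of a [compound_list()].
#' @param apex_rt Apex retention time, seconds.
#' @param cfg A [qc_config()].
#' @return One-row spectra tibble, or `NULL`.
#' @export
select_dda_spectrum <- function(run, compound, apex_rt, cfg = qc_config()) {
  sp <- run$spectra
  tol <- compound$theoretical_mz * cfg$eic_ppm * 1e-6
  cand <- which(sp$ms_level == 2L & sp$acquisition_mode == "DDA" &
                  !is.na(sp$precursor_mz) &
                  abs(sp$precursor_mz - compound$theoretical_mz) <= tol &
                  abs(sp$rt - apex_rt) <= cfg$peak_half_window)
  if (length(cand) == 0) return(NULL)
  sp[cand[which.min(abs(sp$rt[cand] - apex_rt))], , drop = FALSE]
}

#' Bin a fragment spectrum
#'
#' Fragments are assigned to fixed-width m/z bins anchored at 0
#' (`bin = floor(mz / bin_width)`); intensities within a bin are summed.
#'
#' @param mz,intensity Fragment m/z values (Da) and intensities.
#' @param bin_width Bin width in Da (default 0.5).
#' @return Named numeric vector; names are bin indices.
#' @export
#' @examples
#' bin_spectrum(c(100.10, 100.30), c(5, 7)) # one bin, 12
bin_spectrum <- function(mz, intensity, bin_width = 0.5) {
  if (bin_width <= 0) abort("bin_width must be > 0")
  if (length(mz) == 0) return(setNames(numeric(0), character(0)))
  bins <- floor(mz / bin_width)
  v <- tapply(intensity, bins, sum)
  setNames(as.numeric(v), names(v))
}

#' Cosine similarity of two binned spectra
#'
#' Plain dot product of the two non-zero binned vectors over the product of
#' their norms; intensities are used as-is (no square-root weighting). The
#' result lies in `[0, 1]` for non-negative spectra. A zero vector is an
#' error — the caller reports a no-match with reason instead.
#'
#' @param a,b Named numeric vectors from [bin_spectrum()].
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity of a zero vector is undefined")
  keys <- union(names(a), names(b))
  av <- setNames(numeric(length(keys)), keys); av[names(a)] <- a
  bv <- setNames(numeric(length(keys)), keys); bv[names(b)] <- b
  sum(av * bv) / (na * nb)
}

#' Count matching fragments
#'
#' Number of library fragments with at least one acquired fragment within
#' `tol` Da, under greedy nearest one-to-one pairing (an acquired fragment
#' can confirm at most one library fragment and vice versa).
#'
#' @param acquired_mz,library_mz Fragment m/z vectors.
#' @param tol Mass tolerance in Da.
#' @return Integer count, at most `min(length(acquired), length(library))`.
#' @export
count_matching_fragments <- function(acquired_mz, library_mz, tol = 0.01) {
  if (tol <= 0) abort("tol must be > 0")
  if (length(acquired_mz) == 0 || length(library_mz) == 0) return(0L)
  pairs <- expand.grid(a = seq_along(acquired_mz), l = seq_along(library_mz))
  pairs$d <- abs(acquired_mz[pairs$a] - library_mz[pairs$l])
  pairs <- pairs[pairs$d <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_a <- logical(length(acquired_mz))
  used_l <- logical(length(library_mz))
  n <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; l <- pairs$l[r]
    if (!used_a[a] && !used_l[l]) {
      used_a[a] <- TRUE; used_l[l] <- TRUE; n <- n + 1L
    }
  }
  n
}

#' Read and write per-compound MS2 library entries
#'
#' The library is one JSON document per compound; the file stem must equal
#' the compound identifier (entries whose stem mismatches are rejected with
#' a warning, so externally supplied libraries must adhere to the naming
#' template). Fragments are stored sorted by m/z with positive intensities.
#'
#' @param identifier Compound key (= file stem).
#' @param name Display name.
#' @param precursor_mz Precursor m/z, Da.
#' @param polarity `"positive"` or `"negative"`.
#' @param fragment_mz,fragment_intensity Fragment arrays.
#' @param acquired_at Acquisition timestamp of the source standard run.
#' @return A list of class `ms2_library_entry`.
#' @export
ms2_library_entry <- function(identifier, name, precursor_mz, polarity,
                              fragment_mz, fragment_intensity,
                              acquired_at = NA) {
  if (any(fragment_intensity <= 0)) abort("fragment intensities must be > 0")
  ord <- order(fragment_mz)
  fragment_mz <- fragment_mz[ord]
  fragment_intensity <- fragment_intensity[ord]
  if (any(diff(fragment_mz) <= 0)) abort("fragment m/z must be strictly increasing")
  structure(
    list(identifier = identifier, name = name, precursor_mz = precursor_mz,
         polarity = polarity,
         fragments = tibble::tibble(mz = fragment_mz,
                                    intensity = fragment_intensity),
         acquired_at = if (is.na(acquired_at[1])) NA_character_
                       else format(acquired_at, "%Y-%m-%dT%H:%M:%S")),
    class = "ms2_library_entry"
  )
}

#' @rdname ms2_library_entry
#' @param entry An `ms2_library_entry`.
#' @param dir Library directory.
#' @return `write_library_entry()`: the file path, invisibly.
#' @export
write_library_entry <- function(entry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(entry$identifier, ".json"))
  jsonlite::write_json(
    list(identifier = entry$identifier, name = entry$name,
         precursor_mz = entry$precursor_mz, polarity = entry$polarity,
         acquired_at = entry$acquired_at,
         fragments = as.data.frame(entry$fragments)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname ms2_library_entry
#' @param path JSON file path.
#' @return `read_library_entry()`: an `ms2_library_entry`, or `NULL` when the
#'   file stem does not match the stored identifier.
#' @export
read_library_entry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stem <- sub("\\.json$", "", basename(path))
  if (!identical(raw$identifier, stem)) {
    warn(paste0("library entry '", path, "' rejected: identifier '",
                raw$identifier, "' does not match file stem"))
    return(NULL)
  }
  ms2_library_entry(raw$identifier, raw$name, raw$precursor_mz, raw$polarity,
                    raw$fragments$mz, raw$fragments$intensity,
                    acquired_at = NA) |>
    (\(e) { e$acquired_at <- raw$acquired_at %||% NA_character_; e })()
}

#' Build a library entry from a standard run
#'
#' Measures the compound in the standard run, selects the qualifying DDA
#' spectrum at the apex, and writes it as the compound's library entry
#' (overwriting any previous entry; the new acquisition timestamp is
#' recorded).
#'
#' @param run A [qc_run()] of a standard injection.
#' @param compound One row of a [compound_list()].
#' @param dir Library directory.
#' @param cfg A [qc_config()].
#' @param rt_state Current [rt_correction_state()].
#' @return The written `ms2_library_entry`, invisibly.
#' @export
build_library_entry <- function(run, compound, dir, cfg = qc_config(),
                                rt_state = rt_correction_state()) {
  m <- measure_compound(run, compound,
                        compound$expected_rt + rt_state$shift, cfg)
  if (!m$detected) {
    abort(paste0("no acceptable peak for '", compound$identifier,
                 "' in the standard run"))
  }
  sp <- select_dda_spectrum(run, compound, m$apex_rt, cfg)
  if (is.null(sp)) {
    abort(paste0("no DDA MS2 spectrum for '", compound$identifier,
                 "' near the apex"))
  }
  keep <- sp$intensity[[1]] > 0
  entry <- ms2_library_entry(
    compound$identifier, compound$name, compound$theoretical_mz,
    compound$polarity, sp$mz[[1]][keep], sp$intensity[[1]][keep],
    acquired_at = run$acquired_at
  )
  write_library_entry(entry, dir)
  invisible(entry)
}

#' Confirm a target against its MS2 library entry
#'
#' Computes the binned cosine similarity and the matched-fragment count
#' between the acquired DDA spectrum at the apex and the compound's library
#' entry.
#'
#' @param run A [qc_run()].
#' @param compound One row of a [compound_list()].
#' @param apex_rt Apex RT from peak measurement.
#' @param library_dir Library directory with `<identifier>.json` entries.
#' @param cfg A [qc_config()].
#' @return One-row tibble: `compound_id`, `cosine`, `n_matching_fragments`,
#'   `n_acquired_fragments`, `status` (`"ok"`, `"no_dda_spectrum"`,
#'   `"no_library_entry"`, `"zero_vector"`).
#' @export
ms2_match <- function(run, compound, apex_rt, library_dir, cfg = qc_config()) {
  out <- tibble::tibble(
    compound_id = compound$identifier, cosine = NA_real_,
    n_matching_fragments = NA_integer_, n_acquired_fragments = NA_integer_,
    status = "ok"
  )
  key <- if (!is.na(compound$ms2_key)) compound$ms2_key else compound$identifier
  lib_path <- file.path(library_dir, paste0(key, ".json"))
  if (!file.exists(lib_path)) {
    out$status <- "no_library_entry"
    return(out)
  }
  entry <- read_library_entry(lib_path)
  if (is.null(entry)) {
    out$status <- "no_library_entry"
    return(out)
  }
  sp <- select_dda_spectrum(run, compound, apex_rt, cfg)
  if (is.null(sp)) {
    out$status <- "no_dda_spectrum"
    return(out)
  }
  acq_mz <- sp$mz[[1]]; acq_int <- sp$intensity[[1]]
  out$n_acquired_fragments <- length(acq_mz)
  a <- bin_spectrum(acq_mz, acq_int, cfg$ms2_bin_width)
  b <- bin_spectrum(entry$fragments$mz, entry$fragments$intensity,
                    cfg$ms2_bin_width)
  if (sum(a^2) == 0 || sum(b^2) == 0) {
    out$status <- "zero_vector"
    return(out)
  }
  out$cosine <- cosine_similarity(a, b)
  out$n_matching_fragments <- count_matching_fragments(
    acq_mz, entry$fragments$mz, cfg$ms2_fragment_tol)
  out
}
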