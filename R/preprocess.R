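#' Preprocessing parameters
#'
#' @param depth Peak picking depth: maximum peaks kept per 100 Th window
#'   (default 15).
#' @param low_mass_cutoff Low-mass ion removal threshold in Th (default 145,
#'   below the smallest singly charged y1 of interest; excludes the
#'   immonium region).
#' @param precursor_window Half-width in Th of the exclusion window around
#'   each precursor-derived species (default 2).
#' @param normalization_total Target sum of intensities after scaling
#'   (default 100; only ratios matter downstream).
#' @param fragment_tol_ppm Fragment match tolerance in ppm (default 20).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(depth = 15L, low_mass_cutoff = 145,
                              precursor_window = 2,
                              normalization_total = 100,
                              fragment_tol_ppm = 20) {
  stopifnot(depth >= 1, low_mass_cutoff >= 0, precursor_window >= 0,
            normalization_total > 0, fragment_tol_ppm > 0)
  structure(list(depth = as.integer(depth), low_mass_cutoff = low_mass_cutoff,
                 precursor_window = precursor_window,
                 normalization_total = normalization_total,
                 fragment_tol_ppm = fragment_tol_ppm),
            class = "preprocess_params")
}

# m/z positions of precursor-derived species: the precursor at charges
# z, z-1, ..., 1 (same protonated mass, reduced charge) and their -H2O and
# -NH3 neutral-loss satellites.
precursor_derived_mz <- function(precursor_mz, charge) {
  M <- (precursor_mz - PROTON_MASS) * charge  # neutral mass
  zs <- seq_len(charge)
  base <- (M + zs * PROTON_MASS) / zs
  c(base, base - H2O_MASS / zs, base - NH3_MASS / zs)
}

#' Remove unspecific ions from a spectrum
#'
#' Drops low-mass ions (m/z below `low_mass_cutoff`) and all ions derived
#' from the precursor: peaks within `precursor_window` Th of the precursor
#' m/z, of its charge-reduced species down to 1+, and of their -H2O/-NH3
#' neutral-loss satellites.
#'
#' @param s An [spectrum()].
#' @param params A [preprocess_params()].
#' @return The filtered spectrum; if everything is removed, a spectrum with
#'   `empty = TRUE` (searches skip it).
#' @export
remove_unspecific_peaks <- function(s, params = preprocess_params()) {
  pk <- s$peaks
  keep <- pk$mz >= params$low_mass_cutoff
  for (ex in precursor_derived_mz(s$precursor_mz, s$precursor_charge))
    keep <- keep & abs(pk$mz - ex) > params$precursor_window
  s$peaks <- pk[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s$empty <- nrow(s$peaks) == 0L
  s
}

#' Windowed peak picking
#'
#' Within each fixed 100 Th window `[100k, 100(k+1))` only the `m` highest
#' intensity peaks survive; ties are resolved by keeping the lower-m/z
#' peak. Relative order by m/z is preserved.
#'
#' @param s An [spectrum()].
#' @param m Peak picking depth (peaks per 100 Th window).
#' @return The thinned spectrum.
#' @export
pick_peaks <- function(s, m = 15L) {
  pk <- s$peaks
  if (nrow(pk) == 0L) return(s)
  win <- floor(pk$mz / 100)
  keep <- logical(nrow(pk))
  for (w in unique(win)) {
    idx <- which(win == w)
    if (length(idx) <= m) { keep[idx] <- TRUE; next }
    best <- idx[order(-pk$intensity[idx], pk$mz[idx])[seq_len(m)]]
    keep[best] <- TRUE
  }
  s$peaks <- pk[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Scale intensities to a fixed total
#'
#' @param s An [spectrum()] with at least one non-zero intensity.
#' @param total Target intensity sum.
#' @return Spectrum with `sum(intensity) == total` and `normalized = TRUE`;
#'   relative intensities and ranks are unchanged.
#' @export
normalize_intensities <- function(s, total = 100) {
  tot <- sum(s$peaks$intensity)
  if (tot <= 0) stop("cannot normalize spectrum '", s$id, "': all intensities zero")
  s$peaks$intensity <- s$peaks$intensity * (total / tot)
  s$normalized <- TRUE
  s
}

#' Full spectrum preprocessing
#'
#' Composition of [remove_unspecific_peaks()], [pick_peaks()] and
#' [normalize_intensities()] — the identical pipeline is applied to input
#' and library spectra before scoring. The operation is idempotent.
#'
#' @param s An [spectrum()].
#' @param params A [preprocess_params()].
#' @return Preprocessed spectrum (possibly flagged empty).
#' @export
preprocess_spectrum <- function(s, params = preprocess_params()) {
  s <- remove_unspecific_peaks(s, params)
  if (s$empty) return(s)
  s <- pick_peaks(s, params$depth)
  normalize_intensities(s, params$normalization_total)
}
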