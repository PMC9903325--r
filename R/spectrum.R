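#' Construct a peak table
#'
#' Peaks live in a `data.frame` with columns `mz`, `intensity` and the
#' annotation columns `ann_series`, `ann_ordinal`, `ann_charge`, `ann_loss`,
#' `ann_start`, `ann_end` (`NA` when unannotated). `ann_start`/`ann_end`
#' hold the 0-based half-open residue interval of internal fragments.
#'
#' @param mz Numeric vector of m/z values (Th, > 0).
#' @param intensity Numeric vector of intensities (>= 0).
#' @return Peak `data.frame` sorted ascending by m/z.
#' @export
peak_table <- function(mz = numeric(), intensity = numeric()) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && (any(mz <= 0) || any(intensity < 0)))
    stop("peaks require mz > 0 and intensity >= 0")
  df <- data.frame(
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    ann_series = NA_character_, ann_ordinal = NA_integer_,
    ann_charge = NA_integer_, ann_loss = NA_real_,
    ann_start = NA_integer_, ann_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  df[order(df$mz), , drop = FALSE]
}

#' Construct a tandem mass spectrum
#'
#' @param id Spectrum identifier (scan title or running index).
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Precursor charge state (integer >= 1).
#' @param peaks A peak `data.frame` (see [peak_table()]); duplicate m/z
#'   values are kept as separate peaks.
#' @param normalized Whether intensities have been scaled to a fixed total.
#' @return An object of class `ms_spectrum`.
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, peaks,
                     normalized = FALSE) {
  stopifnot(precursor_mz > 0, precursor_charge >= 1)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(id = as.character(id), precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 peaks = peaks, normalized = isTRUE(normalized),
                 empty = nrow(peaks) == 0L),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  %.4f Th %d+  %d peaks%s\n", x$id,
              x$precursor_mz, x$precursor_charge, nrow(x$peaks),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Construct a spectral library entry
#'
#' Binds a peptide to its (optionally annotated) reference spectrum.
#'
#' @param peptide A [peptide()].
#' @param spectrum An [spectrum()]; precursor charge must agree with the
#'   peptide's charge.
#' @param is_decoy Decoy flag.
#' @param origin Free-text provenance of the entry.
#' @return An object of class `lib_entry`.
#' @export
library_entry <- function(peptide, spectrum, is_decoy = FALSE, origin = "") {
  if (peptide$charge != spectrum$precursor_charge)
    stop("peptide and spectrum charge disagree for ", peptide$sequence)
  structure(list(peptide = peptide, spectrum = spectrum,
                 is_decoy = isTRUE(is_decoy), origin = as.character(origin)),
            class = "lib_entry")
}

#' @export
print.lib_entry <- function(x, ...) {
  cat(sprintf("<library entry> %s/%d  %d peaks%s\n", x$peptide$sequence,
              x$peptide$charge, nrow(x$spectrum$peaks),
              if (x$is_decoy) "  [decoy]" else ""))
  invisible(x)
}

# Intensity ranks, 1 = most intense; ties broken by ascending m/z so ranking
# is deterministic.
intensity_ranks <- function(intensity, mz) {
  n <- length(intensity)
  ranks <- integer(n)
  ranks[order(-intensity, mz)] <- seq_len(n)
  ranks
}
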