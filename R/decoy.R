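# Shuffle-and-reposition decoy generation: shuffle the interior of the
# target sequence (termini fixed) until the positional Kendall-Tau drops to
# 0.5 or below, then move every annotated peak by the theoretical mass
# shift its annotation acquires under the decoy sequence.

DECOY_TAU_MAX <- 0.5

#' Positional Kendall-Tau of a permutation
#'
#' Rank correlation between residue positions before and after shuffling:
#' `tau = 1 - 4q / (L(L-1))` where `q` is the inversion count of the
#' permutation.
#'
#' @param permutation Integer vector: a permutation of `0..L-1`, entry `i`
#'   giving the new (0-based) position of original residue `i`.
#' @return tau in `[-1, 1]`.
#' @export
positional_tau <- function(permutation) {
  L <- length(permutation)
  if (L < 2L) stop("need at least 2 positions")
  if (!setequal(permutation, 0:(L - 1L))) stop("not a permutation of 0..L-1")
  q <- count_discordant(seq_len(L), permutation + 1L)$q
  1 - 4 * q / (L * (L - 1))
}

#' Shuffle a peptide into a decoy sequence
#'
#' Keeps the N- and C-terminal residues fixed and uniformly shuffles the
#' interior. Positioned modifications travel with their residue instance;
#' terminal modifications stay put. A shuffle is accepted when the
#' positional Kendall-Tau between original and shuffled residue positions
#' is at most 0.5; otherwise it is redrawn, up to `len(sequence)^2` trials.
#' Duplicate residues are tracked as distinct instances so tau is always
#' defined on a true permutation.
#'
#' @param p A [peptide()] of length >= 4 (shorter interiors cannot reach
#'   the tau threshold).
#' @return List with `decoy_peptide`, `permutation` (original index -> new
#'   index, 0-based), `tau` and `attempts`; or `NULL` if no acceptable
#'   shuffle was found within the trial cap.
#' @export
shuffle_decoy_sequence <- function(p) {
  L <- nchar(p$sequence)
  if (L < 4L) return(NULL)
  residues <- strsplit(p$sequence, "")[[1]]
  interior <- 2:(L - 1L)
  max_trials <- L * L
  for (attempt in seq_len(max_trials)) {
    # permutation[i] = new 0-based position of original residue i
    perm <- 0:(L - 1L)
    shuffled <- sample(interior)
    perm[interior] <- shuffled - 1L
    tau <- positional_tau(perm)
    if (tau <= DECOY_TAU_MAX) {
      new_residues <- character(L)
      new_residues[perm + 1L] <- residues
      mods <- p$modifications
      if (nrow(mods)) {
        interior_mod <- !is.na(mods$position)
        mods$position[interior_mod] <- perm[mods$position[interior_mod] + 1L]
      }
      decoy <- peptide(paste(new_residues, collapse = ""), p$charge, mods)
      return(list(decoy_peptide = decoy, permutation = perm, tau = tau,
                  attempts = attempt))
    }
  }
  NULL
}

#' Build a decoy spectrum by peak repositioning
#'
#' Every annotated peak moves by `delta = mz(annotation | decoy) -
#' mz(annotation | target)` at the annotation's charge, keeping its
#' intensity (and hence the original calibration error). Internal-fragment
#' annotations are recomputed from the same positional interval applied to
#' the decoy sequence. Peaks shifted outside `detectable_range` are
#' discarded; unannotated peaks are copied verbatim.
#'
#' @param entry Annotated target [library_entry()].
#' @param shuffle Result of [shuffle_decoy_sequence()] for the entry's
#'   peptide.
#' @param detectable_range Length-2 m/z range; defaults to the first and
#'   last observed m/z of the target spectrum.
#' @return A decoy [library_entry()] (`is_decoy = TRUE`) with the same
#'   precursor (the interior permutation conserves the neutral mass).
#' @export
build_decoy_spectrum <- function(entry, shuffle, detectable_range = NULL) {
  pk <- entry$spectrum$peaks
  if (is.null(detectable_range))
    detectable_range <- range(pk$mz)
  target <- entry$peptide
  decoy <- shuffle$decoy_peptide
  ann <- !is.na(pk$ann_series)
  new_mz <- pk$mz
  if (any(ann)) {
    mz_t <- annotation_mz(target, pk$ann_series[ann], pk$ann_ordinal[ann],
                          pk$ann_charge[ann], pk$ann_loss[ann],
                          pk$ann_start[ann], pk$ann_end[ann])
    mz_d <- annotation_mz(decoy, pk$ann_series[ann], pk$ann_ordinal[ann],
                          pk$ann_charge[ann], pk$ann_loss[ann],
                          pk$ann_start[ann], pk$ann_end[ann])
    new_mz[ann] <- pk$mz[ann] + (mz_d - mz_t)
  }
  keep <- !ann | (new_mz >= detectable_range[1] & new_mz <= detectable_range[2])
  pk$mz <- new_mz
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk$mz), , drop = FALSE]
  rownames(pk) <- NULL
  sp <- spectrum(paste0("DECOY_", entry$spectrum$id),
                 entry$spectrum$precursor_mz,
                 entry$spectrum$precursor_charge, pk,
                 normalized = entry$spectrum$normalized)
  library_entry(decoy, sp, is_decoy = TRUE, origin = entry$origin)
}

#' Generate a decoy library
#'
#' Annotates any unannotated target entry at `tol_ppm` (the annotation
#' tolerance must match the fragment tolerance used for searching), then
#' emits one decoy per target for which shuffling succeeds. Each entry gets
#' its own RNG stream derived from `(seed, entry index)`, so output is
#' order-stable and reproducible.
#'
#' @param entries List of target [library_entry()] objects.
#' @param tol_ppm Fragment/annotation tolerance in ppm.
#' @param seed Integer seed.
#' @return List of decoy [library_entry()] objects; entries whose shuffle
#'   fails (or whose sequence is too short) are skipped and counted in the
#'   `n_failed` attribute.
#' @export
generate_decoy_library <- function(entries, tol_ppm = 20, seed = 1L) {
  out <- list()
  failed <- 0L
  for (i in seq_along(entries)) {
    ent <- entries[[i]]
    if (all(is.na(ent$spectrum$peaks$ann_series)))
      ent <- annotate_spectrum(ent, tol_ppm)
    entry_seed <- (as.numeric(seed) * 48271 + i) %% 2147483647
    set.seed(as.integer(entry_seed))
    sh <- shuffle_decoy_sequence(ent$peptide)
    if (is.null(sh)) { failed <- failed + 1L; next }
    d <- build_decoy_spectrum(ent, sh)
    attr(d, "tau") <- sh$tau
    attr(d, "attempts") <- sh$attempts
    out[[length(out) + 1L]] <- d
  }
  attr(out, "n_failed") <- failed
  out
}
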