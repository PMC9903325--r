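#' Search parameters
#'
#' Defaults follow the engine's standard HCD configuration: precursor
#' tolerance 10 ppm, fragment tolerance 20 ppm, peak picking depth 15 per
#' 100 Th, and scoring on y-ions, b-ions and the internal fragments derived
#' from them.
#'
#' @param prec_tol_ppm Precursor mass tolerance in ppm.
#' @param frag_tol_ppm Fragment mass tolerance in ppm.
#' @param depth Peak picking depth per 100 Th window.
#' @param scoring_series Ion series entering the quantitative score.
#' @param preprocess [preprocess_params()] used for both input and library
#'   spectra.
#' @return A `search_params` list.
#' @export
search_params <- function(prec_tol_ppm = 10, frag_tol_ppm = 20, depth = 15L,
                          scoring_series = c("y", "b", "internal"),
                          preprocess = preprocess_params(depth = depth,
                                                         fragment_tol_ppm = frag_tol_ppm)) {
  structure(list(prec_tol_ppm = prec_tol_ppm, frag_tol_ppm = frag_tol_ppm,
                 depth = as.integer(depth), scoring_series = scoring_series,
                 preprocess = preprocess),
            class = "search_params")
}

#' Index a library for candidate lookup
#'
#' @param entries List of [library_entry()] objects (targets and decoys).
#' @return Index object for [select_candidates()].
#' @export
library_index <- function(entries) {
  pmz <- vapply(entries, function(e) e$spectrum$precursor_mz, numeric(1))
  chg <- vapply(entries, function(e) e$spectrum$precursor_charge, integer(1))
  ord <- order(chg, pmz)
  structure(list(entries = entries, order = ord, pmz = pmz[ord], charge = chg[ord]),
            class = "library_index")
}

#' Select candidate library entries for a spectrum
#'
#' Entries with the same precursor charge whose precursor m/z lies within
#' the closed interval `± prec_tol_ppm` (relative to the query precursor
#' m/z).
#'
#' @param s Query [spectrum()].
#' @param index A [library_index()].
#' @param prec_tol_ppm Precursor tolerance in ppm.
#' @return Integer indices into the index's entry list.
#' @export
select_candidates <- function(s, index, prec_tol_ppm = 10) {
  # closed interval; tiny relative slack so an entry at exactly +tol ppm is
  # not lost to floating-point rounding
  tol <- prec_tol_ppm * s$precursor_mz * 1e-6 * (1 + 1e-9)
  sel <- which(index$charge == s$precursor_charge &
               index$pmz >= s$precursor_mz - tol &
               index$pmz <= s$precursor_mz + tol)
  index$order[sel]
}

PSM_SERIES <- c("y", "b", "a", "y_loss", "b_loss", "a_loss", "internal")

psm_row <- function(spectrum_id, entry, bd, rank) {
  row <- data.frame(
    spectrum_id = spectrum_id, peptide = entry$peptide$sequence,
    charge = entry$peptide$charge, is_decoy = entry$is_decoy, rank = rank,
    S = bd$S, P = bd$P, Q = bd$Q, p_B = bd$p_B, p_KT = bd$p_KT,
    p_HG = bd$p_HG, n_matched = bd$n, r = bd$r,
    q = ifelse(is.na(bd$q), 0L, bd$q), N_I = bd$N_I, N_L = bd$N_L,
    q_value = NA_real_, stringsAsFactors = FALSE)
  for (s in PSM_SERIES) {
    if (is.null(bd$per_series)) { a <- 0; rel <- 0 }
    else {
      i <- match(s, bd$per_series$series)
      a <- bd$per_series$absolute[i]; rel <- bd$per_series$relative[i]
    }
    row[[paste0(s, "_abs")]] <- a
    row[[paste0(s, "_rel")]] <- rel
  }
  row
}

#' Run a spectral library search
#'
#' Preprocesses every query spectrum and library spectrum once, scores each
#' query against its precursor-matched candidates and returns ranked PSMs.
#' Output order is deterministic: query order, then rank; per-spectrum
#' score ties are broken by larger matched peak count, then lexicographic
#' peptide sequence.
#'
#' @param spectra List of query [spectrum()] objects.
#' @param entries Library entries (targets plus decoys), annotated.
#' @param params A [search_params()].
#' @param top_n PSM ranks kept per spectrum.
#' @return `data.frame` of PSMs with score breakdown columns and per-series
#'   matched intensity columns.
#' @export
search_run <- function(spectra, entries, params = search_params(), top_n = 1L) {
  prepped <- lapply(entries, function(e) {
    e$spectrum <- preprocess_spectrum(e$spectrum, params$preprocess)
    e
  })
  keep <- !vapply(prepped, function(e) e$spectrum$empty, logical(1))
  prepped <- prepped[keep]
  idx <- library_index(prepped)
  rows <- list()
  for (s in spectra) {
    sp <- preprocess_spectrum(s, params$preprocess)
    if (sp$empty) {
      message("spectrum '", s$id, "' empty after preprocessing; skipped")
      next
    }
    cand <- select_candidates(sp, idx, params$prec_tol_ppm)
    if (length(cand) == 0L) next
    bds <- lapply(idx$entries[cand], function(e)
      score_match(sp, e, params$frag_tol_ppm, params$scoring_series))
    ord <- order(-vapply(bds, `[[`, numeric(1), "S"),
                 -vapply(bds, `[[`, numeric(1), "n"),
                 vapply(idx$entries[cand], function(e) e$peptide$sequence,
                        character(1)))
    for (k in seq_len(min(top_n, length(ord)))) {
      j <- ord[k]
      rows[[length(rows) + 1L]] <- psm_row(sp$id, idx$entries[[cand[j]]],
                                           bds[[j]], k)
    }
  }
  if (length(rows) == 0L) {
    cols <- c("spectrum_id", "peptide", "charge", "is_decoy", "rank", "S",
              "P", "Q", "p_B", "p_KT", "p_HG", "n_matched", "r", "q", "N_I",
              "N_L", "q_value", paste0(rep(PSM_SERIES, each = 2),
                                       c("_abs", "_rel")))
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a PSM result table
#'
#' Tab-separated, one row per PSM: identifiers, score breakdown and the
#' absolute and relative matched intensity of every ion series, for use by
#' downstream rescoring tools.
#'
#' @param psms PSM `data.frame` from [search_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Target-decoy FDR at a score threshold
#'
#' `FDR = decoy hits / target hits`, where hits are rank-1 PSMs with
#' `S >= threshold` in the respective search space.
#'
#' @param psms Rank-1 PSM `data.frame` with `S` and `is_decoy`.
#' @param threshold Score threshold (non-strict).
#' @return List with `threshold`, `target_hits`, `decoy_hits`, `fdr` and
#'   `undefined` (`TRUE` when there are no target hits, in which case
#'   `fdr` is reported as 1).
#' @export
compute_fdr <- function(psms, threshold) {
  sel <- psms$rank == 1L & psms$S >= threshold
  target_hits <- sum(sel & !psms$is_decoy)
  decoy_hits <- sum(sel & psms$is_decoy)
  if (target_hits == 0L)
    return(list(threshold = threshold, target_hits = 0L,
                decoy_hits = decoy_hits, fdr = 1, undefined = TRUE))
  list(threshold = threshold, target_hits = target_hits,
       decoy_hits = decoy_hits, fdr = decoy_hits / target_hits,
       undefined = FALSE)
}

#' Assign q-values to rank-1 PSMs
#'
#' Sweeps a threshold over every distinct score (descending), computes the
#' target-decoy FDR at each, and assigns each PSM the minimum FDR over all
#' thresholds that would accept it.
#'
#' @param psms Rank-1 PSM `data.frame`.
#' @return The same `data.frame` with `q_value` filled; q-values are
#'   non-increasing in `S`.
#' @export
qvalues <- function(psms) {
  r1 <- which(psms$rank == 1L)
  if (length(r1) == 0L) return(psms)
  S <- psms$S[r1]; dec <- psms$is_decoy[r1]
  thresholds <- sort(unique(S), decreasing = TRUE)
  fdr <- vapply(thresholds, function(t) compute_fdr(psms[r1, ], t)$fdr, numeric(1))
  qv <- rev(cummin(rev(fdr)))  # min FDR over thresholds <= each score
  psms$q_value[r1] <- qv[match(S, thresholds)]
  psms
}

#' Synthetic-pool FDR
#'
#' On synthetic peptide pool data, a target hit is correct when its
#' stripped sequence equals a pool sequence or is a contiguous substring of
#' one (truncated synthesis products); the synthetic FDR is
#' `incorrect / (incorrect + correct)`.
#'
#' @param psms Accepted target PSM `data.frame` (rank-1, non-decoy).
#' @param pool Character vector of pool peptide sequences.
#' @param ile_equivalent Treat I and L as interchangeable when matching.
#' @return List with `correct_hits`, `incorrect_hits` and `synthetic_fdr`.
#' @export
synthetic_fdr <- function(psms, pool, ile_equivalent = FALSE) {
  stopifnot(length(pool) > 0)
  seqs <- psms$peptide
  if (ile_equivalent) {
    seqs <- gsub("I", "L", seqs, fixed = TRUE)
    pool <- gsub("I", "L", pool, fixed = TRUE)
  }
  correct <- vapply(seqs, function(s)
    any(vapply(pool, function(p) grepl(s, p, fixed = TRUE), logical(1))),
    logical(1), USE.NAMES = FALSE)
  n_ok <- sum(correct); n_bad <- sum(!correct)
  list(correct_hits = n_ok, incorrect_hits = n_bad,
       synthetic_fdr = if (n_ok + n_bad > 0) n_bad / (n_ok + n_bad) else 0)
}
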