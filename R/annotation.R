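# Iterative expert-system annotation of library spectra. A base list of
# b/y ions is matched first; every successful match spawns derived ions
# (neutral losses gated on the residues actually spanned, and internal
# fragments consistent with a second backbone cleavage), which are matched
# against the still-unannotated peaks until a fixpoint is reached.

# Annotation priority, lower = more common fragment type under HCD and the
# winner when two annotations land on one peak.
ann_priority <- function(series, loss) {
  base <- c(y = 1, b = 3, a = 9, internal = 13)[series]
  has_loss <- !is.na(loss) & loss > 0
  # y < b < y-loss < b-loss < a < a-loss < internal
  ifelse(has_loss & series == "y", 5,
  ifelse(has_loss & series == "b", 7,
  ifelse(has_loss & series == "a", 11, base)))
}

# theoretical m/z for annotations under a given peptide (also used to
# reposition decoy peaks); vectorized over annotation fields
annotation_mz <- function(p, series, ordinal, charge, loss,
                          start = NA_integer_, end = NA_integer_) {
  fragment_mz_vec(pep_masses(p), series, ordinal, charge,
                  ifelse(is.na(loss), 0, loss), start, end)
}

ion_key <- function(df) {
  sprintf("%s|%s|%d|%.4f|%s|%s", df$series,
          ifelse(is.na(df$ordinal), "-", df$ordinal), df$charge,
          ifelse(is.na(df$loss), 0, df$loss),
          ifelse(is.na(df$start), "-", df$start),
          ifelse(is.na(df$end), "-", df$end))
}

empty_ion_df <- function() {
  data.frame(series = character(), ordinal = integer(), charge = integer(),
             loss = numeric(), start = integer(), end = integer(),
             mz = numeric(), generation = integer(), priority = numeric(),
             stringsAsFactors = FALSE)
}

#' Theoretical fragment ions of a peptide
#'
#' b/y (and optionally a) ions for ordinals `1..len-1` at charges
#' `1..max_charge`, with modification masses included at their positions.
#'
#' @param p A [peptide()] of length >= 2.
#' @param series Character vector from `c("b", "y", "a")`.
#' @param max_charge Highest fragment charge to generate.
#' @return `data.frame` of ions (series, ordinal, charge, loss, internal
#'   bounds, m/z, generation 0, priority), sorted by m/z.
#' @export
theoretical_fragments <- function(p, series = c("b", "y"), max_charge = 1L) {
  len <- nchar(p$sequence)
  if (len < 2L) stop("peptide too short to fragment: ", p$sequence)
  grid <- expand.grid(series = series, ordinal = seq_len(len - 1L),
                      charge = seq_len(max_charge),
                      stringsAsFactors = FALSE)
  mz <- fragment_mz_vec(pep_masses(p), grid$series, grid$ordinal,
                        grid$charge, 0)
  out <- data.frame(series = grid$series, ordinal = as.integer(grid$ordinal),
                    charge = as.integer(grid$charge), loss = 0,
                    start = NA_integer_, end = NA_integer_, mz = mz,
                    generation = 0L, priority = ann_priority(grid$series, 0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# residue span (1-based inclusive) covered by an ion
ion_span <- function(series, ordinal, start, end, len) {
  switch(series,
         b = c(1L, ordinal), a = c(1L, ordinal),
         y = c(len - ordinal + 1L, len),
         internal = c(start + 1L, end))
}

#' Derive neutral-loss and internal-fragment ions from matched ions
#'
#' For each matched ion, emits -H2O and -NH3 variants when the spanned
#' residues can support the loss (S/T/E/D for water, K/R/N/Q for ammonia),
#' and for matched b/y ions the internal fragments produced by a second
#' backbone cleavage inside their span (length >= 2, singly charged).
#' Duplicates of already-proposed ions are suppressed.
#'
#' @param matched `data.frame` of matched ions (rows of the theoretical
#'   list).
#' @param p The owning [peptide()].
#' @param known_keys Character keys of ions already proposed.
#' @return `data.frame` of new ions with `generation = parent + 1`.
#' @export
derive_ions <- function(matched, p, known_keys = character()) {
  len <- nchar(p$sequence)
  residues <- strsplit(p$sequence, "")[[1]]
  h2o_ok <- residues %in% c("S", "T", "E", "D")
  nh3_ok <- residues %in% c("K", "R", "N", "Q")
  ser <- character(); ord <- integer(); chg <- integer(); loss <- numeric()
  st <- integer(); en <- integer(); gen <- integer()
  emit <- function(series, ordinal, charge, lss, start, end, g) {
    ser <<- c(ser, series); ord <<- c(ord, ordinal); chg <<- c(chg, charge)
    loss <<- c(loss, lss); st <<- c(st, start); en <<- c(en, end)
    gen <<- c(gen, g)
  }
  for (i in seq_len(nrow(matched))) {
    ion <- matched[i, ]
    if (ion$loss != 0) next  # losses and internals derive from loss-free ions
    span <- ion_span(ion$series, ion$ordinal, ion$start, ion$end, len)
    g <- ion$generation + 1L
    if (any(h2o_ok[span[1]:span[2]]))
      emit(ion$series, ion$ordinal, ion$charge, H2O_MASS, ion$start, ion$end, g)
    if (any(nh3_ok[span[1]:span[2]]))
      emit(ion$series, ion$ordinal, ion$charge, NH3_MASS, ion$start, ion$end, g)
    if (ion$series == "b" && ion$ordinal >= 3L) {
      starts <- seq_len(ion$ordinal - 2L)              # 0-based start >= 1
      emit(rep("internal", length(starts)), rep(NA_integer_, length(starts)),
           rep(1L, length(starts)), rep(0, length(starts)),
           as.integer(starts), rep(ion$ordinal, length(starts)),
           rep(g, length(starts)))
    } else if (ion$series == "y") {
      s0 <- len - ion$ordinal                          # 0-based start of y span
      if (s0 >= 1L && s0 + 2L <= len - 1L) {
        ends <- seq.int(s0 + 2L, len - 1L)
        emit(rep("internal", length(ends)), rep(NA_integer_, length(ends)),
             rep(1L, length(ends)), rep(0, length(ends)),
             rep(as.integer(s0), length(ends)), as.integer(ends),
             rep(g, length(ends)))
      }
    }
  }
  if (length(ser) == 0L) return(empty_ion_df())
  out <- data.frame(series = ser, ordinal = ord, charge = chg, loss = loss,
                    start = st, end = en, mz = NA_real_, generation = gen,
                    priority = ann_priority(ser, loss),
                    stringsAsFactors = FALSE)
  out$mz <- fragment_mz_vec(pep_masses(p), out$series, out$ordinal,
                            out$charge, out$loss, out$start, out$end)
  out <- out[!duplicated(ion_key(out)) & !(ion_key(out) %in% known_keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a library spectrum
#'
#' Iterative annotation: the base b/y ion list (charges up to
#' `min(2, precursor charge)`) is matched to unannotated peaks within
#' `tol_ppm`; matched ions spawn derived ions via [derive_ions()]; the loop
#' stops when a pass annotates no new peak. Each peak carries at most one
#' annotation; conflicts go to the lower priority value (more common ion
#' type), ties to the smaller absolute ppm error.
#'
#' @param entry A [library_entry()].
#' @param tol_ppm Match tolerance in ppm.
#' @return The entry with annotation columns filled in its spectrum's peak
#'   table and an `annotation_fraction` attribute (fraction of total peak
#'   intensity annotated).
#' @export
annotate_spectrum <- function(entry, tol_ppm = 20) {
  stopifnot(tol_ppm > 0)
  pep <- entry$peptide
  pk <- entry$spectrum$peaks
  npk <- nrow(pk)
  mz <- pk$mz
  assigned <- rep(NA_integer_, npk)  # index into the ion list, NA = open
  ions <- theoretical_fragments(pep, c("b", "y"),
                                max_charge = min(2L, pep$charge))
  known <- ion_key(ions)
  matched_ever <- logical(nrow(ions))
  repeat {
    unann <- which(is.na(assigned))
    if (length(unann) == 0L) break
    new_hits <- 0L
    for (j in unann) {
      err <- 1e6 * (mz[j] - ions$mz) / ions$mz
      cand <- which(abs(err) <= tol_ppm)
      if (length(cand) == 0L) next
      assigned[j] <- cand[order(ions$priority[cand], abs(err[cand]))][1]
      new_hits <- new_hits + 1L
    }
    if (new_hits == 0L) break
    fresh <- setdiff(unique(assigned[!is.na(assigned)]), which(matched_ever))
    matched_ever[fresh] <- TRUE
    derived <- derive_ions(ions[fresh, , drop = FALSE], pep, known_keys = known)
    if (nrow(derived) > 0L) {
      ions <- rbind(ions, derived)
      known <- c(known, ion_key(derived))
      matched_ever <- c(matched_ever, logical(nrow(derived)))
    }
  }
  hit <- !is.na(assigned)
  sel <- assigned[hit]
  pk$ann_series <- NA_character_; pk$ann_ordinal <- NA_integer_
  pk$ann_charge <- NA_integer_; pk$ann_loss <- NA_real_
  pk$ann_start <- NA_integer_; pk$ann_end <- NA_integer_
  pk$ann_series[hit] <- ions$series[sel]
  pk$ann_ordinal[hit] <- ions$ordinal[sel]
  pk$ann_charge[hit] <- ions$charge[sel]
  pk$ann_loss[hit] <- ions$loss[sel]
  pk$ann_start[hit] <- ions$start[sel]
  pk$ann_end[hit] <- ions$end[sel]
  entry$spectrum$peaks <- pk
  tot <- sum(pk$intensity)
  attr(entry, "annotation_fraction") <-
    if (tot > 0) sum(pk$intensity[!is.na(pk$ann_series)]) / tot else 0
  entry
}

#' Annotation parameter signature
#'
#' Deterministic fingerprint of annotation-relevant parameters, stored in
#' library Comments; a mismatch at search time signals that annotations and
#' decoys must be regenerated for the current tolerance.
#'
#' @param tol_ppm Fragment tolerance in ppm.
#' @param series Base ion series used for annotation.
#' @param depth Peak picking depth.
#' @return A single character fingerprint.
#' @export
annotation_signature <- function(tol_ppm = 20, series = c("b", "y"), depth = 15L) {
  sprintf("tol=%g;series=%s;depth=%d", tol_ppm,
          paste(sort(series), collapse = ","), as.integer(depth))
}
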