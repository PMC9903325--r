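# Monoisotopic mass constants (Da). Proton mass per CODATA; molecular values
# from standard atomic monoisotopic masses.
PROTON_MASS <- 1.00727646688
H2O_MASS <- 18.0105646863
NH3_MASS <- 17.0265491015
CO_MASS <- 27.9949146221

# Monoisotopic residue masses of the 20 standard amino acids.
RESIDUE_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202840, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259309, M = 131.04048491, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

# Built-in modification masses; the only named modifications the engine's
# default searches use. Unknown names are carried as opaque text with an
# explicit mass_delta.
MOD_MASS <- c(
  Carbamidomethyl = 57.02146,
  Oxidation = 15.99491
)

#' Construct a peptide
#'
#' A peptide is a residue sequence (standard 20 one-letter codes), an
#' optional set of positioned modifications and a precursor charge.
#'
#' @param sequence Uppercase residue string.
#' @param charge Precursor charge state (integer >= 1).
#' @param modifications `data.frame` with columns `position` (0-based residue
#'   index, `NA` for terminal modifications), `terminus` (`NA`, `"N"` or
#'   `"C"`), `mass_delta` (Da) and `name`. `NULL` means unmodified.
#' @return An object of class `pep_peptide`.
#' @export
peptide <- function(sequence, charge = 2L, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  residues <- strsplit(sequence, "")[[1]]
  if (!all(residues %in% names(RESIDUE_MASS)))
    stop("sequence contains non-standard residues: ", sequence)
  if (is.null(modifications)) {
    modifications <- data.frame(position = integer(), terminus = character(),
                                mass_delta = numeric(), name = character(),
                                stringsAsFactors = FALSE)
  } else {
    modifications <- as.data.frame(modifications, stringsAsFactors = FALSE)
    if (!all(c("position", "terminus", "mass_delta", "name") %in% names(modifications)))
      stop("modifications must have columns position, terminus, mass_delta, name")
    bad <- !is.na(modifications$position) &
      (modifications$position < 0 | modifications$position >= nchar(sequence))
    if (any(bad)) stop("modification position out of sequence bounds")
  }
  structure(list(sequence = sequence, charge = as.integer(charge),
                 modifications = modifications),
            class = "pep_peptide")
}

#' @export
print.pep_peptide <- function(x, ...) {
  nm <- nrow(x$modifications)
  cat(sprintf("<peptide> %s/%d%s\n", x$sequence, x$charge,
              if (nm) sprintf(" (%d mod%s)", nm, if (nm > 1) "s" else "") else ""))
  invisible(x)
}

# Sum of modification mass deltas attached to residue positions
# pos_lo..pos_hi (0-based, inclusive). Terminal modifications count when the
# span reaches the respective terminus of a sequence of length len.
mod_mass_in_span <- function(peptide, pos_lo, pos_hi, len = nchar(peptide$sequence)) {
  m <- peptide$modifications
  if (nrow(m) == 0L) return(0)
  sel <- (!is.na(m$position) & m$position >= pos_lo & m$position <= pos_hi) |
    (!is.na(m$terminus) & m$terminus == "N" & pos_lo == 0L) |
    (!is.na(m$terminus) & m$terminus == "C" & pos_hi == len - 1L)
  sum(m$mass_delta[sel])
}

#' Neutral monoisotopic peptide mass
#'
#' @param p A [peptide()].
#' @return Neutral monoisotopic mass in Da (residues + H2O + modifications).
#' @export
peptide_mass <- function(p) {
  residues <- strsplit(p$sequence, "")[[1]]
  sum(RESIDUE_MASS[residues]) + H2O_MASS +
    mod_mass_in_span(p, 0L, length(residues) - 1L)
}

#' Precursor m/z of a peptide at its charge
#' @param p A [peptide()].
#' @param charge Charge state; defaults to the peptide's own.
#' @return m/z in Th.
#' @export
precursor_mz <- function(p, charge = p$charge) {
  (peptide_mass(p) + charge * PROTON_MASS) / charge
}

# Precomputed fragment-mass support for a peptide: cumulative residue +
# positional-modification masses plus terminal modification masses. The
# prefix vector has length len + 1 with prefix[1] = 0.
pep_masses <- function(p) {
  residues <- strsplit(p$sequence, "")[[1]]
  len <- length(residues)
  per_res <- unname(RESIDUE_MASS[residues])
  m <- p$modifications
  nterm <- 0; cterm <- 0
  if (nrow(m)) {
    pos <- !is.na(m$position)
    for (i in which(pos)) per_res[m$position[i] + 1L] <-
        per_res[m$position[i] + 1L] + m$mass_delta[i]
    nterm <- sum(m$mass_delta[!pos & m$terminus == "N"], na.rm = TRUE)
    cterm <- sum(m$mass_delta[!pos & m$terminus == "C"], na.rm = TRUE)
  }
  list(prefix = c(0, cumsum(per_res)), nterm = nterm, cterm = cterm, len = len)
}

# Vectorized theoretical m/z for fragment ions given precomputed masses.
# series in {"b", "y", "a", "internal"}; ordinal 1-based from the series
# terminus; internal uses (start, end), a 0-based half-open residue
# interval with b-type (acylium) chemistry and no terminal modifications.
# loss is a neutral-loss mass in Da subtracted from the neutral fragment.
fragment_mz_vec <- function(pm, series, ordinal, charge, loss,
                            start = NA_integer_, end = NA_integer_) {
  len <- pm$len
  loss <- ifelse(is.na(loss), 0, loss)
  is_int <- series == "internal"
  is_by <- series %in% c("b", "a")
  neutral <- numeric(length(series))
  if (any(is_int)) {
    s <- start[is_int]; e <- end[is_int]
    if (any(s < 0 | e > len | s >= e)) stop("invalid internal bounds")
    neutral[is_int] <- pm$prefix[e + 1L] - pm$prefix[s + 1L]
  }
  if (any(is_by)) {
    o <- ordinal[is_by]
    if (any(o < 1L | o > len - 1L)) stop("b/a ordinal out of range")
    neutral[is_by] <- pm$prefix[o + 1L] + pm$nterm -
      ifelse(series[is_by] == "a", CO_MASS, 0)
  }
  is_y <- series == "y"
  if (any(is_y)) {
    o <- ordinal[is_y]
    if (any(o < 1L | o > len - 1L)) stop("y ordinal out of range")
    neutral[is_y] <- pm$prefix[len + 1L] - pm$prefix[len - o + 1L] +
      pm$cterm + ifelse(o == len, pm$nterm, 0) + H2O_MASS
  }
  bad <- !(is_int | is_by | is_y)
  if (any(bad)) stop("unsupported series: ", series[bad][1])
  (neutral - loss + charge * PROTON_MASS) / charge
}

# Scalar convenience wrapper around fragment_mz_vec().
fragment_mz <- function(p, series, ordinal = NA_integer_, charge = 1L,
                        loss = 0, bounds = NULL) {
  fragment_mz_vec(pep_masses(p), series, ordinal, charge, loss,
                  start = if (is.null(bounds)) NA_integer_ else bounds[1],
                  end = if (is.null(bounds)) NA_integer_ else bounds[2])
}
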