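# Synthetic peptides, theoretical spectra with configurable noise, fixture
# libraries and validation runs, emulating a synthetic-peptide-pool
# experiment at desk scale. Everything is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults describe a moderately noisy Orbitrap-like HCD run: 5 ppm
#' fragment mass jitter, 20% fragment dropout, 20 noise peaks per spectrum,
#' and a rank-exponential intensity model: intensity proportional to
#' `exp(-rank/10)` with a peptide-intrinsic rank order (replicate spectra
#' of one peptide share their fragmentation pattern) and about 30%
#' log-normal spectrum-to-spectrum variation — a realistic dynamic range
#' with reproducible ranks.
#'
#' @param n_peptides Number of peptides to generate.
#' @param length_range Min/max sequence length (tryptic pool convention:
#'   at least 7 residues).
#' @param charge_range Min/max precursor charge.
#' @param noise_peaks Uniform-random noise peaks added per spectrum.
#' @param intensity_model `"rank_exponential"` or `"uniform"`.
#' @param jitter_ppm Gaussian fragment m/z error spread in ppm.
#' @param dropout_fraction Fraction of fragment peaks removed.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_peptides = 200L, length_range = c(7L, 20L),
                       charge_range = c(2L, 3L), noise_peaks = 20L,
                       intensity_model = c("rank_exponential", "uniform"),
                       jitter_ppm = 5, dropout_fraction = 0.2, seed = 1L) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(n_peptides >= 0, length_range[1] >= 2, noise_peaks >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1, jitter_ppm >= 0)
  structure(list(n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 charge_range = as.integer(charge_range),
                 noise_peaks = as.integer(noise_peaks),
                 intensity_model = intensity_model, jitter_ppm = jitter_ppm,
                 dropout_fraction = dropout_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate random tryptic-style peptides
#'
#' Sequences end in K or R, contain no internal K/R (fully cleaved), and
#' are unique; reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List of [peptide()] objects with charges drawn from
#'   `charge_range`.
#' @export
generate_peptides <- function(cfg = sim_config()) {
  if (cfg$n_peptides == 0L) return(list())
  set.seed(cfg$seed)
  interior_alphabet <- setdiff(names(RESIDUE_MASS), c("K", "R"))
  seqs <- character(0)
  tries <- 0L
  while (length(seqs) < cfg$n_peptides) {
    tries <- tries + 1L
    if (tries > cfg$n_peptides * 100L)
      stop("cannot generate ", cfg$n_peptides, " unique peptides in length range")
    len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
    s <- paste0(paste(sample(interior_alphabet, len - 1L, replace = TRUE),
                      collapse = ""),
                sample(c("K", "R"), 1L))
    if (!s %in% seqs) seqs <- c(seqs, s)
  }
  charges <- sample(cfg$charge_range[1]:cfg$charge_range[2],
                    cfg$n_peptides, replace = TRUE)
  mapply(peptide, seqs, charges, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Deterministic fragment intensity rank order for a peptide, drawn from a
# stream seeded by the sequence and charge; the ambient RNG state is left
# untouched.
peptide_rank_order <- function(p, nf) {
  h <- (sum(utf8ToInt(p$sequence) * seq_len(nchar(p$sequence))) * 131L +
        p$charge) %% 2147483647L
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(h)
  out <- sample(nf)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  out
}

#' Simulate a fragment spectrum for a peptide
#'
#' b/y fragment peaks (charges 1 to `min(2, precursor charge)`) at
#' theoretical m/z with Gaussian ppm jitter; intensities from the
#' configured model; `dropout_fraction` of fragments removed; noise peaks
#' drawn uniformly over the detectable range with intensities from the
#' lowest quartile of the fragment intensities.
#'
#' @param p A [peptide()].
#' @param cfg A [sim_config()].
#' @param id Spectrum identifier.
#' @return An [spectrum()].
#' @export
simulate_spectrum <- function(p, cfg = sim_config(), id = p$sequence) {
  frags <- theoretical_fragments(p, c("b", "y"),
                                 max_charge = min(2L, p$charge))
  nf <- nrow(frags)
  # fragmentation propensity is a property of the peptide: the rank order
  # is drawn from a peptide-derived stream so replicate spectra of the
  # same peptide share their intensity pattern, as real spectra do
  ranks <- peptide_rank_order(p, nf)
  intensity <- switch(cfg$intensity_model,
    rank_exponential = 1000 * exp(-ranks / 10) *
      exp(stats::rnorm(nf, 0, 0.3)),  # per-spectrum ~30% CV
    uniform = stats::runif(nf, 10, 1000))
  mz <- frags$mz * (1 + stats::rnorm(nf, 0, cfg$jitter_ppm) * 1e-6)
  n_drop <- round(cfg$dropout_fraction * nf)
  if (n_drop > 0) {
    drop <- sample(nf, n_drop)
    mz <- mz[-drop]; intensity <- intensity[-drop]
  }
  if (cfg$noise_peaks > 0L) {
    lo <- 145; hi <- precursor_mz(p) * p$charge
    noise_mz <- stats::runif(cfg$noise_peaks, lo, hi)
    base <- if (length(intensity)) intensity else 1
    noise_int <- stats::runif(cfg$noise_peaks,
                              min(base), stats::quantile(base, 0.25))
    mz <- c(mz, noise_mz); intensity <- c(intensity, noise_int)
  }
  spectrum(id, precursor_mz(p), p$charge, peak_table(mz, intensity))
}

#' Build an annotated fixture library
#'
#' One entry per peptide from a low-noise simulation (1 ppm jitter, no
#' dropout, no noise peaks — consensus-library-like), annotated by
#' [annotate_spectrum()] at `tol_ppm`.
#'
#' @param peptides List of [peptide()] objects.
#' @param cfg A [sim_config()] (its seed controls the simulation).
#' @param tol_ppm Annotation tolerance in ppm.
#' @param path Optional MSP output path.
#' @return List of annotated target [library_entry()] objects.
#' @export
build_fixture_library <- function(peptides, cfg = sim_config(), tol_ppm = 20,
                                  path = NULL) {
  lib_cfg <- cfg
  lib_cfg$jitter_ppm <- 1; lib_cfg$dropout_fraction <- 0; lib_cfg$noise_peaks <- 0L
  set.seed(lib_cfg$seed + 1L)
  entries <- lapply(seq_along(peptides), function(i) {
    p <- peptides[[i]]
    sp <- simulate_spectrum(p, lib_cfg, id = sprintf("LIB_%s/%d", p$sequence, p$charge))
    annotate_spectrum(library_entry(p, sp, origin = "simulated"), tol_ppm)
  })
  if (!is.null(path)) write_msp(entries, path,
                                signature = annotation_signature(tol_ppm))
  entries
}

#' Build a validation run with planted ground truth
#'
#' Emits query spectra simulated from pool peptides (identifiable against a
#' pool-only library) mixed with spectra from off-pool peptides
#' (unidentifiable), plus a truth table mapping every spectrum id to its
#' generating peptide.
#'
#' @param pool,off_pool Disjoint lists of [peptide()] objects.
#' @param cfg A [sim_config()].
#' @param pool_weight Fraction of spectra drawn from the pool.
#' @param mgf_path Optional MGF output path.
#' @return List with `spectra` (list of [spectrum()]) and `truth`
#'   (`data.frame`: spectrum_id, peptide, in_pool).
#' @export
build_validation_run <- function(pool, off_pool, cfg = sim_config(),
                                 pool_weight = 1, mgf_path = NULL) {
  pool_seqs <- vapply(pool, function(p) p$sequence, character(1))
  off_seqs <- vapply(off_pool, function(p) p$sequence, character(1))
  if (length(intersect(pool_seqs, off_seqs)) > 0)
    stop("pool and off-pool peptides must be disjoint")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_peptides
  from_pool <- stats::runif(n) < pool_weight
  src <- ifelse(from_pool,
                sample.int(max(length(pool), 1L), n, replace = TRUE),
                sample.int(max(length(off_pool), 1L), n, replace = TRUE))
  spectra <- vector("list", n)
  truth <- data.frame(spectrum_id = character(n), peptide = character(n),
                      in_pool = logical(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- if (from_pool[i]) pool[[src[i]]] else off_pool[[src[i]]]
    id <- sprintf("scan=%d %s", i, p$sequence)
    spectra[[i]] <- simulate_spectrum(p, cfg, id = id)
    truth$spectrum_id[i] <- id
    truth$peptide[i] <- p$sequence
    truth$in_pool[i] <- from_pool[i]
  }
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  list(spectra = spectra, truth = truth)
}

#' Read a plain-text peptide pool list
#' @param path One uppercase sequence per line.
#' @return Character vector of sequences.
#' @export
read_pool <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a plain-text peptide pool list
#' @param sequences Character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool <- function(sequences, path) {
  writeLines(sequences, path)
  invisible(path)
}
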