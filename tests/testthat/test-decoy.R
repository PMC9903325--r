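test_that("positional_tau matches direct pairwise concordance counting", {
  L <- 6L
  expect_equal(positional_tau(0:(L - 1L)), 1)
  expect_equal(positional_tau((L - 1L):0), -1)
  set.seed(17)
  for (rep in 1:20) {
    perm <- sample(0:(L - 1L))
    # direct pairwise: concordant minus discordant over all pairs
    conc <- 0L; disc <- 0L
    for (i in 1:(L - 1L)) for (j in (i + 1L):L) {
      if (perm[i] < perm[j]) conc <- conc + 1L else disc <- disc + 1L
    }
    expect_equal(positional_tau(perm), (conc - disc) / (L * (L - 1) / 2))
  }
  expect_error(positional_tau(c(0L, 0L, 2L)), "permutation")
})

test_that("shuffled decoys keep termini, residue multiset and tau <= 0.5", {
  set.seed(23)
  for (seq_str in c("PEPTIDEK", "AAAGGGSSSK", "WLDNATERVIK")) {
    p <- peptide(seq_str, 2L)
    sh <- shuffle_decoy_sequence(p)
    expect_false(is.null(sh))
    d <- sh$decoy_peptide$sequence
    expect_equal(substr(d, 1, 1), substr(seq_str, 1, 1))
    expect_equal(substr(d, nchar(d), nchar(d)),
                 substr(seq_str, nchar(seq_str), nchar(seq_str)))
    expect_equal(sort(strsplit(d, "")[[1]]), sort(strsplit(seq_str, "")[[1]]))
    expect_lte(sh$tau, 0.5)
    expect_equal(positional_tau(sh$permutation), sh$tau)
  }
})

test_that("homopolymer interiors are handled on residue instances", {
  # for identical residues tau is computed on tracked instance positions,
  # so acceptance follows the same threshold rule as any other sequence
  set.seed(5)
  p <- peptide("AAAAAAAK", 2L)
  sh <- shuffle_decoy_sequence(p)
  expect_false(is.null(sh))
  expect_equal(sh$decoy_peptide$sequence, "AAAAAAAK")  # sequence unchanged
  expect_lte(sh$tau, 0.5)                              # but positions moved
})

test_that("too-short sequences and unreachable thresholds give no decoy", {
  expect_null(shuffle_decoy_sequence(peptide("ACK", 2L)))
  # length 4: the only interior move gives tau = 2/3 > 0.5, cap exhausts
  set.seed(1)
  expect_null(shuffle_decoy_sequence(peptide("ACDK", 2L)))
})

test_that("interior modifications travel with their residue", {
  mods <- data.frame(position = 3L, terminus = NA_character_,
                     mass_delta = 57.02146, name = "Carbamidomethyl")
  p <- peptide("AAACDEFK", 2L, mods)
  set.seed(31)
  sh <- shuffle_decoy_sequence(p)
  dp <- sh$decoy_peptide
  newpos <- dp$modifications$position
  expect_equal(substr(dp$sequence, newpos + 1, newpos + 1), "C")
  expect_equal(peptide_mass(dp), peptide_mass(p), tolerance = 1e-9)
})

test_that("decoy spectra reposition annotated peaks and copy the rest", {
  e <- clean_entry("SPETKDILNR", 2L)
  # add one unannotated noise peak
  pk <- e$spectrum$peaks
  noise <- pk[1, ]; noise$mz <- 433.3333; noise$intensity <- 5
  noise$ann_series <- NA_character_; noise$ann_ordinal <- NA_integer_
  noise$ann_charge <- NA_integer_; noise$ann_loss <- NA_real_
  e$spectrum$peaks <- rbind(pk, noise)
  e$spectrum$peaks <- e$spectrum$peaks[order(e$spectrum$peaks$mz), ]
  set.seed(41)
  sh <- shuffle_decoy_sequence(e$peptide)
  d <- build_decoy_spectrum(e, sh, detectable_range = c(0, 1e5))
  expect_true(d$is_decoy)
  # same count (nothing out of range), intensities a permutation of target's
  expect_equal(nrow(d$spectrum$peaks), nrow(e$spectrum$peaks))
  expect_equal(sort(d$spectrum$peaks$intensity),
               sort(e$spectrum$peaks$intensity))
  # unannotated peak untouched
  expect_true(433.3333 %in% d$spectrum$peaks$mz)
  # y1 has fixed C-terminal residue: delta = 0
  y1_t <- speclib:::fragment_mz(e$peptide, "y", 1, 1)
  expect_true(any(abs(d$spectrum$peaks$mz - y1_t) < 1e-9))
  # precursor conserved
  expect_equal(d$spectrum$precursor_mz, e$spectrum$precursor_mz)
  # every repositioned peak sits at decoy theoretical mass + original error
  dk <- d$spectrum$peaks
  ann <- !is.na(dk$ann_series)
  theo_d <- annotation_mz(d$peptide, dk$ann_series[ann], dk$ann_ordinal[ann],
                          dk$ann_charge[ann], dk$ann_loss[ann],
                          dk$ann_start[ann], dk$ann_end[ann])
  expect_true(all(abs(dk$mz[ann] - theo_d) < 0.01))
})

test_that("peak bookkeeping: decoy count = target count - out-of-range", {
  e <- clean_entry("SPETKDILNR", 2L)
  set.seed(43)
  sh <- shuffle_decoy_sequence(e$peptide)
  # force discards with a range clipped to the middle of the spectrum
  rng <- quantile(e$spectrum$peaks$mz, c(0.25, 0.75))
  d <- build_decoy_spectrum(e, sh, detectable_range = rng)
  # oracle: recompute shifted positions and count in-range by hand
  pk <- e$spectrum$peaks
  delta <- annotation_mz(sh$decoy_peptide, pk$ann_series, pk$ann_ordinal,
                         pk$ann_charge, pk$ann_loss, pk$ann_start, pk$ann_end) -
    annotation_mz(e$peptide, pk$ann_series, pk$ann_ordinal,
                  pk$ann_charge, pk$ann_loss, pk$ann_start, pk$ann_end)
  shifted <- pk$mz + delta
  expect_equal(nrow(d$spectrum$peaks),
               sum(shifted >= rng[1] & shifted <= rng[2]))
})

test_that("generate_decoy_library is reproducible and conserves invariants", {
  fx <- small_fixture(12)
  dec1 <- generate_decoy_library(fx$library, 20, seed = 99L)
  dec2 <- generate_decoy_library(fx$library, 20, seed = 99L)
  expect_length(dec1, 12L)
  p1 <- withr::local_tempfile(fileext = ".msp")
  p2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(dec1, p1); write_msp(dec2, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical
  for (i in seq_along(dec1)) {
    expect_true(dec1[[i]]$is_decoy)
    expect_equal(dec1[[i]]$spectrum$precursor_mz,
                 fx$library[[i]]$spectrum$precursor_mz)
    expect_equal(sort(strsplit(dec1[[i]]$peptide$sequence, "")[[1]]),
                 sort(strsplit(fx$library[[i]]$peptide$sequence, "")[[1]]))
  }
  dec3 <- generate_decoy_library(fx$library, 20, seed = 100L)
  expect_false(identical(vapply(dec1, function(e) e$peptide$sequence, ""),
                         vapply(dec3, function(e) e$peptide$sequence, "")))
})

test_that("decoys stay realistic: counts, intensity and span near targets", {
  fx <- small_fixture(40)
  dec <- generate_decoy_library(fx$library, 20, seed = 7L)
  stat <- function(entries, f)
    vapply(entries, function(e) f(e$spectrum$peaks), numeric(1))
  for (f in list(function(p) nrow(p), function(p) sum(p$intensity),
                 function(p) diff(range(p$mz)))) {
    t_mean <- mean(stat(fx$library, f)); d_mean <- mean(stat(dec, f))
    expect_lt(abs(d_mean - t_mean) / t_mean, 0.10)
  }
})

test_that("decoys score below targets on matching query spectra", {
  fx <- small_fixture(30)
  dec <- generate_decoy_library(fx$library, 20, seed = 3L)
  run <- build_validation_run(fx$peptides, list(), fx$cfg)
  res <- search_run(run$spectra, c(fx$library, dec), top_n = 5L)
  r1 <- res[res$rank == 1, ]
  expect_lt(mean(r1$is_decoy), 0.05)
  best_decoy <- vapply(split(res, res$spectrum_id), function(df) {
    d <- df$S[df$is_decoy]
    if (length(d)) max(d) else NA_real_
  }, numeric(1))
  expect_lt(median(best_decoy, na.rm = TRUE), median(r1$S[!r1$is_decoy]))
})
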