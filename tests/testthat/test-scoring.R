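test_that("match_peaks pairs identical spectra perfectly", {
  s <- toy_spectrum(c(200, 300, 400), c(1, 2, 3))
  m <- match_peaks(s, s, 20)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$ppm_error == 0))
  expect_equal(m$input_rank, m$library_rank)
})

test_that("match_peaks returns nothing for disjoint m/z sets", {
  a <- toy_spectrum(c(200, 300), c(1, 1))
  b <- toy_spectrum(c(500, 600), c(1, 1))
  expect_equal(nrow(match_peaks(a, b, 20)), 0L)
})

test_that("greedy pairing agrees with exhaustive assignment when unambiguous", {
  set.seed(9)
  for (rep in 1:10) {
    ni <- sample(3:5, 1); nl <- sample(3:5, 1)
    base <- sort(runif(nl, 400, 1200))
    # input peaks near library peaks with distinct small errors
    mzL <- base
    take <- sample(nl, ni, replace = TRUE)
    mzI <- sort(mzL[take] * (1 + runif(ni, -15e-6, 15e-6)))
    sI <- toy_spectrum(mzI, seq_len(ni))
    sL <- toy_spectrum(mzL, seq_len(nl))
    got <- match_peaks(sI, sL, 20)
    err <- outer(sI$peaks$mz, sL$peaks$mz,
                 function(a, b) 1e6 * (a - b) / b)
    oracle <- best_assignment(err, 20)
    expect_equal(nrow(got), oracle$size)
    # when greedy is unambiguous it attains the oracle's minimal total error
    expect_equal(sum(abs(got$ppm_error)), oracle$cost, tolerance = 1e-9)
  }
})

test_that("one-to-one constraint holds", {
  sI <- toy_spectrum(c(500.000, 500.004), c(1, 2))
  sL <- toy_spectrum(c(500.002), c(5))
  m <- match_peaks(sI, sL, 20)
  expect_equal(nrow(m), 1L)
  expect_false(any(duplicated(m$input_index)))
  expect_false(any(duplicated(m$library_index)))
})

test_that("match_probability covers the interval-union definition", {
  # non-overlapping intervals: additive
  sI <- toy_spectrum(c(100, 1100), c(1, 1))         # span 1000
  sL <- toy_spectrum(c(500, 700), c(1, 1))
  p <- match_probability(sI, sL, 20)
  w <- 2 * (500 * 20e-6) + 2 * (700 * 20e-6)
  expect_equal(p, w / 1000, tolerance = 1e-12)
  # library window covering the whole input span clamps just below 1
  sI_narrow <- toy_spectrum(c(500.000, 500.010), c(1, 1))
  sL_cover <- toy_spectrum(500.005, 1)
  expect_equal(match_probability(sI_narrow, sL_cover, 20), 1 - 1e-9)
  # overlapping intervals merge (random oracle)
  set.seed(21)
  for (rep in 1:10) {
    mzL <- sort(runif(30, 200, 210))  # heavy overlap at 20 ppm
    sL2 <- toy_spectrum(mzL, rep(1, 30))
    sI2 <- toy_spectrum(c(150, 250), c(1, 1))
    tol <- mzL * 20e-6
    expect_equal(match_probability(sI2, sL2, 20),
                 interval_union_len(pmax(mzL - tol, 150),
                                    pmin(mzL + tol, 250)) / 100,
                 tolerance = 1e-12)
  }
  # degenerate single-peak input
  expect_warning(p0 <- match_probability(toy_spectrum(500, 1), sL, 20), "span")
  expect_equal(p0, 1e-9)
})

test_that("binomial p-value equals term enumeration on small instances", {
  for (N in c(1, 3, 6, 12)) for (p in c(0.1, 0.3, 0.5, 0.9)) for (n in 0:N) {
    expect_equal(binomial_pvalue(n, N, p), binom_tail_enum(n, N, p),
                 tolerance = 1e-12)
  }
  expect_equal(binomial_pvalue(0, 10, 0.5), 1)
  expect_equal(binomial_pvalue(3, 3, 0.5), 0.125)
  expect_equal(binomial_pvalue(2, 3, 0.5), 0.5)
  expect_error(binomial_pvalue(5, 3, 0.5), "exceed")
})

test_that("hypergeometric p-value equals draw enumeration on small instances", {
  for (N_max in c(4, 8, 12)) for (n in 1:min(6, N_max)) for (r in 0:n) {
    expect_equal(hypergeometric_pvalue(n, r, N_max),
                 hyper_tail_enum(n, r, N_max), tolerance = 1e-12)
  }
  expect_equal(hypergeometric_pvalue(2, 0, 4), 1)
  expect_equal(hypergeometric_pvalue(2, 2, 4), 1 / 6)
  expect_error(hypergeometric_pvalue(5, 2, 4), "exceed")
  expect_error(hypergeometric_pvalue(3, 4, 8), "r must")
})

test_that("Fisher combination is symmetric and matches quadrature", {
  expect_equal(fisher_combine(1, 1, 1)$statistic, 0)
  expect_equal(fisher_combine(1, 1, 1)$p, 1)
  a <- fisher_combine(0.02, 0.5, 0.11)
  b <- fisher_combine(0.11, 0.02, 0.5)
  expect_equal(a$p, b$p)
  X <- -6 * log(0.1)
  quad <- stats::integrate(function(x) stats::dchisq(x, 6), X, Inf,
                           rel.tol = 1e-12)$value
  got <- fisher_combine(0.1, 0.1, 0.1)
  expect_equal(got$statistic, X)
  expect_equal(got$p, quad, tolerance = 1e-10)
  expect_error(fisher_combine(0, 0.5, 0.5), "0, 1")
})

test_that("quantitative score is the matched scoring-ion intensity fraction", {
  e <- clean_entry("PEPTIDESK", 2L)
  e$spectrum <- normalize_intensities(e$spectrum, 100)
  # all peaks matched and y/b annotated -> Q = 1
  m_all <- data.frame(input_index = seq_len(nrow(e$spectrum$peaks)),
                      library_index = seq_len(nrow(e$spectrum$peaks)))
  expect_equal(quantitative_score(m_all, e$spectrum)$Q, 1)
  # no matches -> 0
  m_none <- m_all[0, ]
  expect_equal(quantitative_score(m_none, e$spectrum)$Q, 0)
  # half the intensity matched -> Q = that fraction
  half <- which(cumsum(e$spectrum$peaks$intensity) <= 50)
  m_half <- m_all[half, ]
  expect_equal(quantitative_score(m_half, e$spectrum)$Q,
               sum(e$spectrum$peaks$intensity[half]) / 100)
  # per-series intensities sum to at most the total
  ps <- quantitative_score(m_all, e$spectrum)$per_series
  expect_lte(sum(ps$absolute), 100 + 1e-9)
})

test_that("self-match dominates any cross-match in a fixture library", {
  fx <- small_fixture(8)
  pp <- preprocess_params()
  prepped <- lapply(fx$library, function(e) {
    e$spectrum <- preprocess_spectrum(e$spectrum, pp); e
  })
  for (i in seq_along(prepped)) {
    self <- score_match(prepped[[i]]$spectrum, prepped[[i]])
    expect_equal(self$n, self$N_L)
    expect_equal(self$q, 0L)
    expect_equal(self$r, self$n)
    expect_equal(self$Q, 1, tolerance = 1e-12)
    for (j in seq_along(prepped)[-i]) {
      cross <- score_match(prepped[[i]]$spectrum, prepped[[j]])
      expect_lt(cross$S, self$S)
    }
  }
})

test_that("score breakdown invariants hold on noisy random pairs", {
  fx <- small_fixture(6, jitter_ppm = 8, dropout_fraction = 0.3)
  cfg <- fx$cfg
  pp <- preprocess_params()
  prepped <- lapply(fx$library, function(e) {
    e$spectrum <- preprocess_spectrum(e$spectrum, pp); e
  })
  set.seed(13)
  for (rep in 1:10) {
    i <- sample(length(prepped), 1); j <- sample(length(prepped), 1)
    sp <- preprocess_spectrum(simulate_spectrum(fx$peptides[[i]], cfg), pp)
    bd <- score_match(sp, prepped[[j]])
    expect_true(bd$Q >= 0 && bd$Q <= 1)
    expect_true(all(c(bd$p_B, bd$p_KT, bd$p_HG) > 0))
    expect_true(all(c(bd$p_B, bd$p_KT, bd$p_HG) <= 1))
    expect_equal(bd$N_max, max(bd$N_I, bd$N_L))
    if (bd$n >= 2) expect_true(bd$q >= 0 && bd$q <= bd$q_max)
    expect_lte(bd$L_scoring, bd$L_total + 1e-9)
    # determinism: bit-identical on recompute
    bd2 <- score_match(sp, prepped[[j]])
    expect_identical(bd$S, bd2$S)
  }
})

test_that("zero-match scoring yields the no-evidence result", {
  a <- toy_spectrum(c(200, 300, 400), c(1, 2, 3))
  e <- clean_entry("PEPTIDESK", 2L)
  e$spectrum$peaks$mz <- e$spectrum$peaks$mz + 3  # push out of tolerance
  bd <- score_match(a, e, 20)
  expect_equal(bd$S, 0)
  expect_equal(bd$Q, 0)
  expect_equal(c(bd$p_B, bd$p_KT, bd$p_HG), c(1, 1, 1))
})

test_that("score is monotone in its subscores", {
  # S = (-log10 pF) * Q: increasing Q at fixed p-values raises S;
  # increasing any p-value lowers S.
  S_of <- function(pB, pKT, pHG, Q) -log10(fisher_combine(pB, pKT, pHG)$p) * Q
  grid <- expand.grid(p = c(1e-6, 1e-3, 0.05, 0.5), Q = c(0.2, 0.5, 0.9))
  for (k in seq_len(nrow(grid))) {
    p <- grid$p[k]; Q <- grid$Q[k]
    expect_lt(S_of(p, p, p, Q), S_of(p, p, p, min(1, Q + 0.05)))
    expect_gt(S_of(p, p, p, Q), S_of(min(1, p * 10), p, p, Q))
    expect_gt(S_of(p, p, p, Q), S_of(p, min(1, p * 10), p, Q))
    expect_gt(S_of(p, p, p, Q), S_of(p, p, min(1, p * 10), Q))
  }
})
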