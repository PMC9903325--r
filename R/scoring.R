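# Composite spectrum-to-spectrum score: three match p-values (cumulative
# binomial on peak-mass matches, exact Kendall-Tau on intensity ranks among
# matched peaks, hypergeometric on exact rank coincidences) combined by
# Fisher's method into a probabilistic score P, multiplied by a
# quantitative score Q (fraction of library intensity in matched scoring
# ion series).

P_EPS <- 1e-9      # clamp for p_match
P_FLOOR <- 1e-300  # p-value floor before logs

#' Pair peaks between an input and a library spectrum
#'
#' One-to-one pairing: among all candidate pairs within `tol_ppm` of the
#' library peak, pairs are chosen greedily by ascending absolute ppm error
#' (ties by input then library index).
#'
#' @param s_I,s_L Preprocessed input and library [spectrum()]s.
#' @param tol_ppm Fragment tolerance in ppm.
#' @return `data.frame` with one row per match: `input_index`,
#'   `library_index`, `ppm_error`, and intensity ranks `input_rank`,
#'   `library_rank` within the full preprocessed spectra.
#' @export
match_peaks <- function(s_I, s_L, tol_ppm) {
  mi <- s_I$peaks$mz; ml <- s_L$peaks$mz
  empty <- data.frame(input_index = integer(), library_index = integer(),
                      ppm_error = numeric(), input_rank = integer(),
                      library_rank = integer())
  if (length(mi) == 0L || length(ml) == 0L) return(empty)
  # candidate pairs via sorted-window lookup
  tol <- ml * tol_ppm * 1e-6
  lo <- findInterval(ml - tol, mi) + 1L
  hi <- findInterval(ml + tol, mi)
  cand_i <- integer(); cand_l <- integer()
  for (j in seq_along(ml)) {
    if (lo[j] > hi[j]) next
    idx <- lo[j]:hi[j]
    cand_i <- c(cand_i, idx)
    cand_l <- c(cand_l, rep.int(j, length(idx)))
  }
  if (length(cand_i) == 0L) return(empty)
  err <- 1e6 * (mi[cand_i] - ml[cand_l]) / ml[cand_l]
  ord <- order(abs(err), cand_i, cand_l)
  used_i <- logical(length(mi)); used_l <- logical(length(ml))
  keep <- integer()
  for (k in ord) {
    if (used_i[cand_i[k]] || used_l[cand_l[k]]) next
    used_i[cand_i[k]] <- TRUE; used_l[cand_l[k]] <- TRUE
    keep <- c(keep, k)
  }
  ri <- intensity_ranks(s_I$peaks$intensity, mi)
  rl <- intensity_ranks(s_L$peaks$intensity, ml)
  out <- data.frame(input_index = cand_i[keep], library_index = cand_l[keep],
                    ppm_error = err[keep], input_rank = ri[cand_i[keep]],
                    library_rank = rl[cand_l[keep]])
  out[order(out$input_index), , drop = FALSE]
}

#' Chance probability of matching one peak
#'
#' The fraction of the input spectrum's m/z range (first peak to last peak)
#' covered by the union of `±tol` windows around the library spectrum's
#' peaks, clamped to `[1e-9, 1 - 1e-9]`.
#'
#' @param s_I,s_L Non-empty [spectrum()]s.
#' @param tol_ppm Fragment tolerance in ppm.
#' @return Probability in (0, 1).
#' @export
match_probability <- function(s_I, s_L, tol_ppm) {
  mi <- s_I$peaks$mz; ml <- s_L$peaks$mz
  if (length(mi) == 0L || length(ml) == 0L) stop("empty spectrum")
  span <- c(mi[1], mi[length(mi)])
  W <- span[2] - span[1]
  if (W <= 0) {
    warning("input spectrum span is zero; p_match set to minimum")
    return(P_EPS)
  }
  tol <- ml * tol_ppm * 1e-6
  lo <- pmax(ml - tol, span[1]); hi <- pmin(ml + tol, span[2])
  ok <- hi > lo
  if (!any(ok)) return(P_EPS)
  lo <- lo[ok]; hi <- hi[ok]
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  # merge overlapping intervals, accumulate union length
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (j in seq_along(lo)[-1]) {
    if (lo[j] <= cur_hi) cur_hi <- max(cur_hi, hi[j])
    else { total <- total + (cur_hi - cur_lo); cur_lo <- lo[j]; cur_hi <- hi[j] }
  }
  total <- total + (cur_hi - cur_lo)
  min(max(total / W, P_EPS), 1 - P_EPS)
}

#' Cumulative binomial match p-value
#'
#' Probability of matching `n` or more of the `N_I` input peaks by chance
#' when each matches with probability `p_match`. Peak intensities play no
#' role here.
#'
#' @param n Matched peak count.
#' @param N_I Input peak count after preprocessing.
#' @param p_match Single-peak chance match probability in (0, 1).
#' @return p-value in (0, 1].
#' @export
binomial_pvalue <- function(n, N_I, p_match) {
  if (n > N_I) stop("n cannot exceed N_I")
  stopifnot(p_match > 0, p_match < 1)
  if (n <= 0) return(1)
  stats::pbinom(n - 1, size = N_I, prob = p_match, lower.tail = FALSE)
}

#' Hypergeometric rank-coincidence p-value
#'
#' Probability of `r` or more of the `n` matched peak pairs sharing exactly
#' the same intensity rank in their respective spectra: the upper tail of a
#' hypergeometric with population `N_max = max(N_I, N_L)`, `n` marked
#' items and `n` draws.
#'
#' @param n Matched peak count.
#' @param r Exact rank coincidences among matches.
#' @param N_max `max(N_I, N_L)`.
#' @return p-value in (0, 1].
#' @export
hypergeometric_pvalue <- function(n, r, N_max) {
  if (n > N_max) stop("n cannot exceed N_max")
  if (r > n || r < 0) stop("r must lie in [0, n]")
  if (r <= 0) return(1)
  stats::phyper(r - 1, m = n, n = N_max - n, k = n, lower.tail = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' @param p_B,p_KT,p_HG p-values in (0, 1].
#' @return List with `statistic` `X = -2(ln p_B + ln p_KT + ln p_HG)` and
#'   `p` (upper tail of chi-square with 6 degrees of freedom at `X`).
#' @export
fisher_combine <- function(p_B, p_KT, p_HG) {
  ps <- c(p_B, p_KT, p_HG)
  if (any(ps <= 0) || any(ps > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(ps))
  list(statistic = X, p = stats::pchisq(X, df = 6, lower.tail = FALSE))
}

# does an annotation series count toward the quantitative score?
is_scoring_series <- function(series, loss, scoring_series) {
  core <- !is.na(series) & series %in% setdiff(scoring_series, "internal") &
    (is.na(loss) | loss == 0)
  internal <- !is.na(series) & series == "internal" & "internal" %in% scoring_series
  core | internal
}

#' Quantitative score
#'
#' `Q = L_scoring / L_total`: the fraction of the library spectrum's total
#' peak intensity carried by scoring peaks — peaks that are both matched to
#' an input peak and annotated with a relevant ion series. The default
#' scoring series are y-ions, b-ions and the internal fragments derived
#' from them.
#'
#' @param matches Output of [match_peaks()].
#' @param s_L Annotated, preprocessed library [spectrum()].
#' @param scoring_series Character vector of relevant series.
#' @return List with `Q` and `per_series`, a `data.frame` of absolute and
#'   relative matched intensity per annotated ion series.
#' @export
quantitative_score <- function(matches, s_L,
                               scoring_series = c("y", "b", "internal")) {
  pk <- s_L$peaks
  L_total <- sum(pk$intensity)
  if (L_total <= 0) stop("library spectrum has zero total intensity")
  matched <- logical(nrow(pk))
  matched[matches$library_index] <- TRUE
  scoring <- matched & is_scoring_series(pk$ann_series, pk$ann_loss, scoring_series)
  L_scoring <- sum(pk$intensity[scoring])
  series_label <- ifelse(is.na(pk$ann_series), "unannotated",
    ifelse(!is.na(pk$ann_loss) & pk$ann_loss > 0,
           paste0(pk$ann_series, "_loss"), pk$ann_series))
  all_series <- c("y", "b", "a", "y_loss", "b_loss", "a_loss", "internal")
  abs_int <- vapply(all_series, function(s)
    sum(pk$intensity[matched & series_label == s]), numeric(1))
  per_series <- data.frame(series = all_series, absolute = abs_int,
                           relative = abs_int / L_total)
  list(Q = L_scoring / L_total, per_series = per_series,
       L_scoring = L_scoring, L_total = L_total)
}

#' Score one spectrum-to-library-entry match
#'
#' Computes the full score breakdown for a preprocessed input spectrum
#' against an annotated, preprocessed library spectrum: the composite
#' score `S = P * Q`, where `P = -log10` of the Fisher-combined p-value of
#' the binomial, Kendall-Tau and hypergeometric subscores and `Q` is the
#' matched scoring-ion intensity fraction.
#'
#' For the Kendall subscore, intensity ranks are re-ranked within the
#' matched subset; the hypergeometric subscore uses ranks within the full
#' preprocessed spectra.
#'
#' @param s_I Preprocessed input [spectrum()].
#' @param entry Annotated [library_entry()] whose spectrum is preprocessed.
#' @param tol_ppm Fragment tolerance in ppm.
#' @param scoring_series Relevant series for the quantitative score.
#' @return An object of class `score_breakdown`: S, P, Q, the three
#'   p-values, match counts, rank statistics and per-series intensity
#'   summaries. With no matched peaks, S = 0, p-values 1 and Q = 0.
#' @export
score_match <- function(s_I, entry, tol_ppm = 20,
                        scoring_series = c("y", "b", "internal")) {
  s_L <- entry$spectrum
  N_I <- nrow(s_I$peaks); N_L <- nrow(s_L$peaks)
  matches <- match_peaks(s_I, s_L, tol_ppm)
  n <- nrow(matches)
  if (n == 0L) {
    return(structure(list(S = 0, P = 0, Q = 0, p_B = 1, p_KT = 1, p_HG = 1,
                          n = 0L, p_match = NA_real_, q = NA_integer_,
                          q_max = NA_integer_, r = 0L, N_I = N_I, N_L = N_L,
                          N_max = max(N_I, N_L), L_scoring = 0,
                          L_total = sum(s_L$peaks$intensity),
                          per_series = NULL, matches = matches),
                     class = "score_breakdown"))
  }
  p_match <- match_probability(s_I, s_L, tol_ppm)
  p_B <- binomial_pvalue(n, N_I, p_match)
  if (n >= 2L) {
    sub_rank_i <- intensity_ranks(s_I$peaks$intensity[matches$input_index],
                                  s_I$peaks$mz[matches$input_index])
    sub_rank_l <- intensity_ranks(s_L$peaks$intensity[matches$library_index],
                                  s_L$peaks$mz[matches$library_index])
    dc <- count_discordant(sub_rank_l, sub_rank_i)
    q <- dc$q; q_max <- dc$q_max
    p_KT <- kendall_pvalue(q, n)
  } else {
    q <- 0L; q_max <- 0L; p_KT <- 1
  }
  r <- sum(matches$input_rank == matches$library_rank)
  p_HG <- hypergeometric_pvalue(n, r, max(N_I, N_L))
  fi <- fisher_combine(max(p_B, P_FLOOR), max(p_KT, P_FLOOR), max(p_HG, P_FLOOR))
  qs <- quantitative_score(matches, s_L, scoring_series)
  P <- -log10(max(fi$p, P_FLOOR))
  structure(list(S = P * qs$Q, P = P, Q = qs$Q, p_B = p_B, p_KT = p_KT,
                 p_HG = p_HG, n = n, p_match = p_match, q = q, q_max = q_max,
                 r = as.integer(r), N_I = N_I, N_L = N_L,
                 N_max = max(N_I, N_L), L_scoring = qs$L_scoring,
                 L_total = qs$L_total, per_series = qs$per_series,
                 matches = matches),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score> S=%.3f  P=%.3f  Q=%.3f  n=%d  p_B=%.3g p_KT=%.3g p_HG=%.3g\n",
              x$S, x$P, x$Q, x$n, x$p_B, x$p_KT, x$p_HG))
  invisible(x)
}
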