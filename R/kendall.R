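# Exact Kendall-Tau machinery: frequency distribution of the inversion
# count, discordant-pair counting, and the rank-correlation p-value used in
# the probabilistic score.

KENDALL_EXACT_MAX_N <- 170L

.kendall_cache <- new.env(parent = emptyenv())

#' Exact inversion-count frequency distribution
#'
#' `f(q, n)`: the number of permutations of `n` items with exactly `q`
#' inversions, for `q = 0..n(n-1)/2`, computed by the standard recurrence
#' in exact big-integer arithmetic and cached per `n`. Exact construction
#' is supported up to `n = 170`.
#'
#' @param n Number of ranks (2..170).
#' @param exact If `TRUE`, return the exact counts as decimal strings
#'   (counts exceed exact double range for large `n`).
#' @return Numeric (or character) vector of length `n(n-1)/2 + 1` indexed
#'   by `q = 0, 1, ...`.
#' @export
kendall_frequency <- function(n, exact = FALSE) {
  n <- as.integer(n)
  if (n < 2L || n > KENDALL_EXACT_MAX_N)
    stop("exact frequency distribution requires 2 <= n <= ", KENDALL_EXACT_MAX_N)
  if (exact) return(kendall_freq_exact_cpp(n))
  kendall_freq_table_cpp(n)
}

kendall_cum_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.kendall_cache[[key]]))
    .kendall_cache[[key]] <- kendall_cum_pvalues_cpp(n)
  .kendall_cache[[key]]
}

#' Count discordant pairs between two rank lists
#'
#' The Kendall-Tau distance: the number of discordant pairs, equal to the
#' minimum number of neighbor interchanges needed to transform one rank
#' list into the other.
#'
#' @param library_ranks,input_ranks Equal-length permutations of `1..n`
#'   (ties must be resolved beforehand).
#' @return List with `q` (discordant pairs) and `q_max = n(n-1)/2`.
#' @export
count_discordant <- function(library_ranks, input_ranks) {
  n <- length(library_ranks)
  if (length(input_ranks) != n) stop("rank lists differ in length")
  if (n < 2L) stop("need at least two ranks")
  # order by library ranks; q = inversions among the aligned input ranks
  v <- input_ranks[order(library_ranks)]
  q <- 0L
  for (i in seq_len(n - 1L))
    q <- q + sum(v[(i + 1L):n] < v[i])
  list(q = as.integer(q), q_max = as.integer(n * (n - 1L) / 2L))
}

#' Kendall-Tau rank correlation p-value
#'
#' Probability of observing a rank correlation as good or better by chance:
#' the lower tail `P(Q <= q)` of the exact inversion-count distribution
#' (fewer discordances = better correlation). Exact for `2 <= n <= 170`;
#' for `n < 2` returns 1; beyond 170 a continuity-corrected normal
#' approximation with mean `q_max/2` and variance `n(n-1)(2n+5)/72` is
#' used.
#'
#' @param q Number of discordant pairs, `0 <= q <= n(n-1)/2`.
#' @param n Number of matched ranks.
#' @return p-value in (0, 1].
#' @export
kendall_pvalue <- function(q, n) {
  n <- as.integer(n)
  if (n < 2L) return(1)
  q_max <- n * (n - 1) / 2
  if (q < 0 || q > q_max) stop("q out of range [0, ", q_max, "]")
  if (n <= KENDALL_EXACT_MAX_N)
    return(kendall_cum_cached(n)[q + 1L])
  mu <- q_max / 2
  sigma <- sqrt(n * (n - 1) * (2 * n + 5) / 72)
  stats::pnorm(q + 0.5, mean = mu, sd = sigma)
}
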