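# Brute-force oracles, independent of the implementation paths they check.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# inversion count by direct pair enumeration
inversions_pairwise <- function(v) {
  n <- length(v)
  q <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) if (v[i] > v[j]) q <- q + 1L
  q
}

# bubble-sort swap count
bubble_swaps <- function(v) {
  swaps <- 0L
  repeat {
    done <- TRUE
    for (i in seq_len(length(v) - 1L)) {
      if (v[i] > v[i + 1L]) {
        tmp <- v[i]; v[i] <- v[i + 1L]; v[i + 1L] <- tmp
        swaps <- swaps + 1L
        done <- FALSE
      }
    }
    if (done) return(swaps)
  }
}

# upper-tail binomial by term enumeration
binom_tail_enum <- function(n, N, p) {
  if (n <= 0) return(1)
  sum(vapply(n:N, function(k) choose(N, k) * p^k * (1 - p)^(N - k), numeric(1)))
}

# hypergeometric upper tail by enumerating all draws of n from N_max with
# n marked items (overlap >= r)
hyper_tail_enum <- function(n, r, N_max) {
  if (r <= 0) return(1)
  draws <- utils::combn(N_max, n)
  mean(apply(draws, 2, function(d) sum(d <= n) >= r))
}

# union length of intervals by fine merging
interval_union_len <- function(lo, hi) {
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  total <- 0; cl <- lo[1]; ch <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= ch) ch <- max(ch, hi[i])
    else { total <- total + ch - cl; cl <- lo[i]; ch <- hi[i] }
  }
  total + ch - cl
}

# minimum-total-|ppm error| one-to-one assignment by exhaustive recursion
best_assignment <- function(err_matrix, tol) {
  ni <- nrow(err_matrix); nl <- ncol(err_matrix)
  best <- list(size = -1L, cost = Inf, pairs = NULL)
  recurse <- function(i, used_l, pairs, cost) {
    if (i > ni) {
      size <- nrow(pairs)
      if (size > best$size || (size == best$size && cost < best$cost))
        best <<- list(size = size, cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used_l, pairs, cost)  # leave input peak i unmatched
    for (l in seq_len(nl)) {
      if (!used_l[l] && abs(err_matrix[i, l]) <= tol) {
        u <- used_l; u[l] <- TRUE
        recurse(i + 1L, u, rbind(pairs, c(i, l)), cost + abs(err_matrix[i, l]))
      }
    }
  }
  recurse(1L, logical(nl), matrix(integer(), 0, 2), 0)
  best
}
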