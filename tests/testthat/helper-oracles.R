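# Independent oracles used across the suite.  Each takes a different route to
# the quantity than the package does, so agreement is evidence, not tautology.

# Irwin-Hall CDF by the textbook alternating series, in plain double
# arithmetic.  Catastrophic cancellation limits it to small m (the worst
# cancellation ratio at m = 8 costs ~2 digits), where it is an exact closed
# form -- the natural cross-check for the B-spline/quadrature evaluation.
ih_cdf_series <- function(u, m) {
  vapply(u, function(ui) {
    if (ui <= 0) return(0)
    if (ui >= m) return(1)
    j <- 0:floor(ui)
    sum((-1)^j * choose(m, j) * (ui - j)^m) / factorial(m)
  }, numeric(1))
}

# Irwin-Hall CDF by repeated numerical convolution: F_k(u) is the integral of
# F_{k-1} over [u-1, u] on a uniform grid.  F_k is only piecewise smooth
# (kinks at integers), so each integral is split at the interior integer and
# every smooth run is integrated with Simpson (plus a 3/8 panel when the
# interval count is odd).  Error O(h^4) per smooth run.
ih_cdf_convolution <- function(m, h = 1 / 400) {
  q <- round(1 / h)
  # Newton-Cotes over consecutive grid values within one smooth run
  nc_int <- function(v) {
    n <- length(v) - 1L
    if (n <= 0L) return(0)
    if (n == 1L) return(h * (v[1] + v[2]) / 2)
    if (n == 2L) return(h / 3 * (v[1] + 4 * v[2] + v[3]))
    if (n == 3L) return(3 * h / 8 * (v[1] + 3 * v[2] + 3 * v[3] + v[4]))
    if (n %% 2 == 0L) {
      w <- c(1, rep(c(4, 2), length.out = n - 1), 1) * h / 3
      return(sum(w * v))
    }
    head <- v[seq_len(n - 2L)]            # n - 3 intervals: even
    w <- c(1, rep(c(4, 2), length.out = n - 4L), 1) * h / 3
    sum(w * head) + 3 * h / 8 * (v[n - 2L] + 3 * v[n - 1L] + 3 * v[n] +
                                   v[n + 1L])
  }
  grid <- seq(-1, m, by = h)              # padded left so [u-1, u] stays in range
  is_int <- abs(grid - round(grid)) < h / 4
  f <- pmin(pmax(grid, 0), 1)             # exact F_1
  for (k in seq_len(m - 1)) {
    fk <- numeric(length(grid))
    for (i in seq_along(grid)) {
      lo <- i - q
      if (lo < 1) next
      cut <- which(is_int[(lo + 1L):(i - 1L)])  # interior kink, if any
      fk[i] <- if (length(cut) == 0L) {
        nc_int(f[lo:i])
      } else {
        j <- lo + cut[1]
        nc_int(f[lo:j]) + nc_int(f[j:i])
      }
    }
    f <- fk
  }
  list(grid = grid, cdf = f)
}

# Exact WRS tail probability by full enumeration of all choose(N, m) group
# assignments of the observed midrank multiset (feasible for N <= 12).
enum_exact_p <- function(x, y, alternative = "greater") {
  r <- rank(c(x, y), ties.method = "average")
  m <- length(x)
  W_obs <- sum(r[seq_len(m)])
  sums <- combn(r, m, sum)
  p_greater <- mean(sums >= W_obs - 1e-9)
  p_less <- mean(sums <= W_obs + 1e-9)
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# values 1..N with the gene set occupying the top m ranks (no ties)
extreme_config <- function(m, N) {
  list(set = as.numeric((N - m + 1):N), complement = as.numeric(1:(N - m)))
}

# small expression fixture: g genes x (n1 + n2) samples
make_expr_fixture <- function(g = 20, n1 = 3, n2 = 3, seed = 42) {
  set.seed(seed)
  mat <- matrix(rnorm(g * (n1 + n2), mean = 7), nrow = g)
  tib <- tibble::as_tibble(as.data.frame(mat),
                           .name_repair = ~ sprintf("s%02d", seq_along(.x)))
  tib <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%03d", seq_len(g))),
                          tib)
  list(data = tib, group = rep(c("A", "B"), c(n1, n2)))
}
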