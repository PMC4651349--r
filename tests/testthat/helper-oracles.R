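# Independent enumeration oracles for the exact modes.

enum_signed_rank_p <- function(d) {
  # two-sided exact p by enumerating all 2^n sign assignments to the ranks
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(code) {
    signs <- bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  lower <- mean(vs <= v_obs); upper <- mean(vs >= v_obs)
  min(1, 2 * min(lower, upper))
}

enum_mann_whitney_p <- function(x, y) {
  # two-sided exact p by enumerating all assignments of ranks to group x
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(sort(r)[idx]) - nx * (nx + 1) / 2)
  lower <- mean(us <= u_obs); upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}
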