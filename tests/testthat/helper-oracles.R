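# Independent reference implementations used as oracles. These deliberately
# take the slow, direct route (raw-value scans, recursive flood fill,
# quadrature) so they share no code path with the package.

# Exhaustive Otsu scan over integer thresholds, computing class weights and
# means directly from raw pixel values; plateau midpoint tie-break.
oracle_otsu_integer <- function(v) {
  v <- as.numeric(v)
  cand <- min(v):(max(v) - 1)
  var_b <- vapply(cand, function(t) {
    bg <- v <= t
    w0 <- mean(bg); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(v[bg]) - mean(v[!bg]))^2
  }, 0)
  vmax <- max(var_b)
  plateau <- which(var_b >= vmax - max(abs(vmax), 1) * 1e-10)
  (cand[min(plateau)] + cand[max(plateau)]) / 2
}

# Stack-based flood fill over a binary array with full connectivity
# (8 in 2D, 26 in 3D). Returns list(count, sizes sorted decreasing).
oracle_flood_fill <- function(arr) {
  dims <- dim(arr)
  nd <- length(dims)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  seen <- array(FALSE, dims)
  fg <- arr != 0
  sizes <- integer(0)
  for (start in which(fg & !seen)) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      cc <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1L) || any(nb > dims)) next
        lin <- nb[1L]
        mult <- 1L
        for (d in seq_len(nd - 1L)) {
          mult <- mult * dims[d]
          lin <- lin + (nb[d + 1L] - 1L) * mult
        }
        if (fg[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          stack <- c(stack, lin)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(count = length(sizes), sizes = sort(sizes, decreasing = TRUE))
}

# Two-sided t-tail by numeric quadrature of the t density.
oracle_t_pvalue <- function(tstat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(tstat), Inf,
                       rel.tol = 1e-10)$value
}

# Small random 8-bit test image: mixture of two intensity populations.
random_8bit <- function(n = 32, p_fg = 0.3, mu = c(60, 180), sd = 25) {
  fg <- runif(n * n) < p_fg
  v <- rnorm(n * n, ifelse(fg, mu[2], mu[1]), sd)
  matrix(pmin(pmax(round(v), 0), 255), n, n)
}
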