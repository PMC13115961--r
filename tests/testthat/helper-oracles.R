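# Independent oracles and small fixture builders shared across tests.

# naive double-loop local Moran: I_i = (z_i/m2) * sum_j W_ij z_j with queen
# contiguity, off-mask neighbours dropped, row-standardized weights
brute_local_moran <- function(values, mask) {
  nr <- nrow(values); nc <- ncol(values)
  on <- which(mask)
  xbar <- mean(values[on])
  m2 <- mean((values[on] - xbar)^2)
  I <- matrix(NA_real_, nr, nc)
  lag <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc]) {
          nb <- c(nb, values[rr, cc])
        }
      }
      if (!length(nb)) next
      lag[r, c] <- mean(nb - xbar)
      I[r, c] <- (values[r, c] - xbar) / m2 * lag[r, c]
    }
  }
  list(I = I, lag = lag, xbar = xbar, m2 = m2)
}

# loop-based pseudo p-values replaying the engine's exact permutation
# streams through mirsa:::perm_pool_indices
oracle_pseudo_p <- function(values, mask, n_perm, seed) {
  w <- build_weights(mask)
  on <- w$index
  x <- values[on]
  z <- x - mean(x)
  m2 <- mean(z^2)
  zs <- sort(z)
  n <- length(z)
  p <- matrix(NA_real_, nrow(values), ncol(values))
  bf <- brute_local_moran(values, mask)
  for (i in seq_len(n)) {
    k <- length(w$neighbors[[i]])
    if (k == 0) next
    wt <- w$weights[[i]]
    pos <- which(zs >= z[i])[1]            # first occurrence (lower bound)
    draws <- mirsa:::perm_pool_indices(seed, z[i], k, n - 1L, n_perm)
    Iobs <- bf$I[on[i]]
    count <- 0L
    for (pr in seq_len(n_perm)) {
      pool_idx <- draws[pr, ] + 1L         # 1-based into pool
      zidx <- ifelse(pool_idx < pos, pool_idx, pool_idx + 1L)
      Ip <- z[i] / m2 * sum(wt * zs[zidx])
      if (Iobs >= 0) count <- count + (Ip >= Iobs)
      else count <- count + (Ip <= Iobs)
    }
    p[on[i]] <- (count + 1) / (n_perm + 1)
  }
  p
}

# deterministic toy cube: values = r + 10*c + 100*band/10 pattern plus a
# seeded noise component, float32-representable when asked
toy_cube <- function(nr = 4, nc = 5, nb = 3, wn = NULL, seed = 1,
                     float32 = FALSE) {
  if (is.null(wn)) wn <- seq(1000, by = 4, length.out = nb)
  set.seed(seed)
  arr <- array(rnorm(nr * nc * nb), c(nr, nc, nb))
  if (float32) arr <- round(arr * 1024) / 1024   # exactly representable
  spectral_cube(arr, wn, sample_id = "toy")
}

# two-region label map: left half tissue A, right half tissue B
toy_labels <- function(nr, nc, a = "tumor", b = "stroma") {
  lab <- matrix(2L, nr, nc)
  lab[, seq_len(floor(nc / 2))] <- 1L
  label_map(lab, stats::setNames(c(a, b), c("1", "2")))
}
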