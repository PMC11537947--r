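# Independent straight-line reimplementation of the field model used as a
# dual-implementation oracle: kernels, weight matrix, the eight inputs and
# the leaky-integrator loop are all written out directly, without calling
# the package's drive-matrix path.

oracle_toroidal <- function(x, center, period = 10) {
  d <- abs(x - center) %% period
  min(d, period - d)
}

oracle_kernel <- function(center, pos, amp = 1.05, gam = 0.6) {
  sapply(pos, function(x) {
    d <- oracle_toroidal(x, center)
    amp * exp(-d^2 / (2 * gam^2))
  })
}

oracle_weight_matrix <- function(n = 100, dx = 0.1, sf = 74.7, sigma = 0.85,
                                 m_frac = 0.8) {
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- min(abs(i - j), n - abs(i - j)) * dx
      G[i, j] <- sf * exp(-d^2 / (2 * sigma^2))
    }
  }
  (G - m_frac * max(G)) * dx
}

# external drive of all eight inputs at absolute time t (ms), evaluated
# from the assignment with scalar closed forms
oracle_drive_at <- function(t, asg, pos, target_mm,
                            t_gap = 200, t_tgt = 400) {
  k_t <- oracle_kernel(target_mm, pos)
  k_0 <- oracle_kernel(0, pos)
  k_m <- oracle_kernel(-target_mm, pos)
  mask <- as.numeric(abs(pos) > 1)
  t_int <- t_tgt + asg[["internal_onset"]]

  # 1 visual transient: rise to cap, decay to half-cap plateau
  r <- asg[["vt_ror"]] / 100; M <- asg[["vt_maxval"]]
  s <- max(0, t - (t_tgt + asg[["vt_onset"]]))
  tri <- min(r * s, M, 2 * M - r * s)
  v1 <- max(tri, if (r * s >= M / 2) M / 2 else 0, 0)

  # 2 automated motor: ramp and sustain
  r <- asg[["am_ror"]] / 100; M <- asg[["am_maxval"]]
  v2 <- min(max(0, r * (t - (t_tgt + asg[["am_onset"]]))), M)

  # 3 automated fixation: rise from onset, release from gap onset
  r <- asg[["af_ror"]] / 100; M <- asg[["af_maxval"]]
  v3 <- max(0, min(r * max(0, t - asg[["af_onset"]]), M) -
                 r * max(0, t - t_gap))

  # 4 voluntary motor: uncapped ramp from the internal onset
  v4 <- asg[["vm_ror"]] / 100 * max(0, t - t_int)

  # 5 voluntary fixation: hold from fixation onset, release from the
  # internal onset
  r <- asg[["vf_ror"]] / 100; M <- asg[["vf_maxval"]]
  v5 <- max(0, min(r * max(0, t - asg[["vf_onset"]]), M) -
                 r * max(0, t - t_int))

  # 6 voluntary preparation: both candidate locations, cap in 100 ms,
  # reaching it at target onset
  M <- asg[["vp_maxval"]]
  v6 <- min(M / 100 * max(0, t - (t_gap + 100)), M)

  # 7 inhibitory gate: barrier over the non-central map, windowed release
  r <- asg[["ig_ror"]] / 100; M <- asg[["ig_maxval"]]
  rel7 <- min(r * max(0, t - t_int), M)
  f7 <- pmin(mask * (-M + (k_t / 1.05) * rel7), 0)

  # 8 peripheral inhibition: uniform release over the non-central map
  r <- asg[["pi_ror"]] / 100; M <- asg[["pi_maxval"]]
  f8 <- -mask * max(0, M - r * max(0, t - t_int))

  k_t * (v1 + v2 + v4) + k_0 * (v3 + v5) + (k_t + k_m) * v6 + f7 + f8
}

# full trial: returns the threshold-crossing SRT (ms after target onset)
# or NA, plus the crossing node
oracle_trial <- function(asg, target_mm = 2, timeout = 500) {
  n <- 100
  pos <- -5 + (0:(n - 1)) * 0.1
  W <- oracle_weight_matrix()
  beta <- 0.09
  u <- rep(-30, n)
  a <- 1 / (1 + exp(-beta * u))
  nc <- which(abs(pos) > 1)
  for (t in seq_len(400 + timeout)) {
    cext <- oracle_drive_at(t - 1, asg, pos, target_mm)
    cint <- vapply(seq_len(n), function(i) sum(W[i, ] * a), numeric(1))
    u <- (1 - 1 / 4) * u + (1 / 4) * (cext + cint)
    a <- 1 / (1 + exp(-beta * u))
    if (any(a[nc] >= 0.7)) {
      over <- nc[a[nc] >= 0.7]
      node <- over[order(-a[over], over)][1]
      return(list(srt_ms = t - 400, node = node))
    }
  }
  list(srt_ms = NA_integer_, node = NA_integer_)
}

# brute-force 1-D optimal transport (north-west-corner coupling on sorted
# atoms, optimal on the line) as an independent Wasserstein oracle
oracle_wasserstein <- function(a, b) {
  a <- sort(a); b <- sort(b)
  wa <- rep(1 / length(a), length(a))
  wb <- rep(1 / length(b), length(b))
  i <- 1; j <- 1; cost <- 0
  while (i <= length(a) && j <= length(b)) {
    m <- min(wa[i], wb[j])
    cost <- cost + m * abs(a[i] - b[j])
    wa[i] <- wa[i] - m; wb[j] <- wb[j] - m
    if (wa[i] <= 1e-15) i <- i + 1
    if (j <= length(b) && wb[j] <= 1e-15) j <- j + 1
  }
  cost
}

# the shipped reference assignment
reference_assignment <- function() {
  kv <- read_config(system.file("extdata", "reference_assignment.cfg",
                                package = "sacfield", mustWork = TRUE))
  unlist(kv)
}

# small fixed assignment builder for monotonicity and symmetry tests
base_assignment <- function(...) {
  asg <- c(vt_onset = 20, vt_ror = 15, vt_maxval = 8,
           am_onset = 45, am_ror = 8, am_maxval = 6,
           af_onset = 45, af_ror = 10, af_maxval = 6,
           vm_ror = 10, vf_onset = 0, vf_ror = 10, vf_maxval = 6,
           vp_maxval = 6, ig_ror = 10, ig_maxval = 6,
           pi_ror = 10, pi_maxval = 6, internal_onset = 100)
  over <- c(...)
  asg[names(over)] <- over
  asg
}
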