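# Shared fixtures and independent oracles used across the suite.

# A fully specified model cell without any sampling.
make_cell <- function(pattern = "immediate", v_rest = -65, delta_v = 20,
                      g_in = 33, ap_amplitude = 85, ap_halfwidth = 1.7,
                      ahp_tau = 42, ahp_amplitude = 5, gain_true = 29,
                      f_half = 30, delay_scale = if (pattern == "delayed") 2.5 else 0,
                      accommodation = if (pattern == "delayed") 8 else 0,
                      mmo = FALSE, noise_sd = 0.3, seed = 1) {
  tibble::tibble(
    id = "test_cell", genotype = "WT", pattern = pattern,
    v_rest = v_rest, g_in = g_in,
    v_threshold = v_rest + delta_v,
    v_threshold_render = v_rest + delta_v + accommodation,
    delta_v = delta_v,
    rheobase_true = g_in * delta_v / 1000,
    recruitment_true = g_in * delta_v / 1000,
    ap_amplitude = ap_amplitude, ap_halfwidth = ap_halfwidth,
    ahp_amplitude = ahp_amplitude, ahp_tau = ahp_tau,
    gain_true = gain_true, f_half_second_true = f_half,
    mmo_present = mmo, mmo_amplitude = 2, delay_scale = delay_scale,
    soma_area = 550, tau_m = 20, noise_sd = noise_sd, seed = seed
  )
}

# Flat sweep with optional hand-placed triangular spikes (peak +10 mV).
make_flat_sweep <- function(v_level = -65, n = 5000, dt = 1e-4,
                            spike_at = numeric(0), current = NULL,
                            t_on = NULL) {
  v <- rep(v_level, n)
  for (tp in spike_at) {
    i <- round(tp / dt) + 1L
    w <- 10L
    tri <- c(seq(v_level, 10, length.out = w), seq(10, v_level, length.out = w)[-1])
    v[i:(i + length(tri) - 1L)] <- tri
  }
  if (is.null(current)) current <- rep(0, n)
  meta <- if (!is.null(t_on)) list(t_on = t_on) else list()
  mnphys:::new_sweep(dt, v, current, 1L, "TEST", meta = meta)
}

# --- Mann-Whitney exact two-tailed p by full enumeration of partitions ----
mw_enumerate <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_stat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- u_stat(seq_len(na))
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, u_stat)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# --- Fisher exact two-tailed p by hypergeometric enumeration --------------
# Walks every table with the observed margins and sums the mass of those no
# more probable than the observed one (with a relative tolerance for ties).
fisher_enumerate <- function(k11, k12, k21, k22) {
  r1 <- k11 + k12; r2 <- k21 + k22; c1 <- k11 + k21
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- probs[k11 - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Zero-intercept slope by brute-force grid minimization ----------------
grid_slope <- function(g, i) {
  f <- function(u) sum((i - u * g)^2)
  span <- range(i / g)
  u <- seq(span[1] - 0.05, span[2] + 0.05, length.out = 4001)
  best <- u[which.min(vapply(u, f, numeric(1)))]
  for (k in 1:6) {
    u <- seq(best - 10^(-k), best + 10^(-k), length.out = 401)
    best <- u[which.min(vapply(u, f, numeric(1)))]
  }
  best
}

# --- Brute-force morphometry on a node table ------------------------------
# Independent of compute_metrics: walks every pair explicitly.
brute_metrics <- function(m) {
  n <- nrow(m)
  root <- which(m$parent == -1L)
  parent_of <- function(i) which(m$id == m$parent[i])
  children_of <- function(i) which(m$parent == m$id[i])
  elen <- function(i) {
    j <- parent_of(i)
    sqrt(sum((c(m$x[i], m$y[i], m$z[i]) - c(m$x[j], m$y[j], m$z[j]))^2))
  }
  total <- 0
  for (i in seq_len(n)) if (i != root) total <- total + elen(i)
  tips <- which(vapply(seq_len(n), function(i)
    length(children_of(i)) == 0 && i != root, logical(1)))
  branches <- which(vapply(seq_len(n), function(i)
    length(children_of(i)) >= 2 && i != root, logical(1)))
  paths <- numeric(0); terms <- numeric(0)
  for (tp in tips) {
    d <- 0; dterm <- 0; past <- FALSE
    i <- tp
    while (i != root) {
      d <- d + elen(i)
      if (!past) dterm <- dterm + elen(i)
      j <- parent_of(i)
      if (j %in% branches || j == root) past <- TRUE
      i <- j
    }
    paths <- c(paths, d); terms <- c(terms, dterm)
  }
  list(n_primary = length(children_of(root)),
       n_branch_points = length(branches),
       total_length = total / 1000,
       dendritic_paths = paths,
       terminal_segment_lengths = terms)
}

# Random small tree as a raw morphology table (<= n_max nodes).
random_small_tree <- function(n_max = 20, seed = 1) {
  withr::with_seed(seed, {
    n <- sample(5:n_max, 1)
    parent <- c(-1L, vapply(2:n, function(i) sample(seq_len(i - 1), 1), integer(1)))
    mnphys:::new_morphology(tibble::tibble(
      id = seq_len(n), type = c(1L, rep(3L, n - 1)),
      x = c(0, runif(n - 1, -100, 100)),
      y = c(0, runif(n - 1, -100, 100)),
      z = c(0, runif(n - 1, 0, 40)),
      radius = 1, parent = parent))
  })
}
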