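# Internal numerical utilities shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so seeded calls never perturb a session.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Mean and sd of a normal(mu, sigma) truncated to [lo, hi].
trunc_norm_moments <- function(mu, sigma, lo, hi) {
  if (sigma <= 0) return(c(mean = mu, sd = 0))
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  if (z < 1e-12) {
    mid <- (lo + hi) / 2
    return(c(mean = mid, sd = 0))
  }
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the underlying (mu, sigma) whose truncation to [lo, hi] has the
# requested mean and sd. The printed summary rows are sample statistics of data
# already confined to the printed range, so the generator must invert the
# truncation. Some rows are infeasible (requested sd larger than any
# distribution on [lo, hi] can attain); the weighted objective then pins the
# mean and accepts the closest achievable sd.
trunc_norm_solve <- function(mean, sd, lo, hi) {
  stopifnot(lo <= mean, mean <= hi)
  if (sd <= 0) return(c(mu = mean, sigma = 0))
  scale <- hi - lo
  if (scale <= 0) return(c(mu = mean, sigma = 0))
  obj <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    mo <- trunc_norm_moments(mu, sigma, lo, hi)
    # keep the truncation acceptance probability workable: infeasible rows
    # (printed sd larger than the support allows) must not drive the solver
    # into a remote tail of the underlying normal
    z <- pnorm((hi - mu) / sigma) - pnorm((lo - mu) / sigma)
    pen <- if (z < 0.005) 1e3 * (0.005 - z) / 0.005 else 0
    50 * ((mo["mean"] - mean) / scale)^2 + ((mo["sd"] - sd) / scale)^2 + pen
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = min(exp(fit$par[2]), 5 * scale))
}

.trunc_cache <- new.env(parent = emptyenv())

trunc_norm_params <- function(mean, sd, lo, hi) {
  key <- paste(format(c(mean, sd, lo, hi), digits = 12), collapse = "|")
  if (!is.null(.trunc_cache[[key]])) return(.trunc_cache[[key]])
  out <- trunc_norm_solve(mean, sd, lo, hi)
  .trunc_cache[[key]] <- out
  out
}

# Rejection sampler for the truncated normal (resample cap per draw).
rtrunc_norm <- function(n, mean, sd, lo, hi, match_moments = TRUE,
                        max_tries = 1e5) {
  if (n == 0) return(numeric(0))
  if (sd <= 0 || lo == hi) return(rep(mean, n))
  par <- if (match_moments) trunc_norm_params(mean, sd, lo, hi) else
    c(mu = mean, sigma = sd)
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    if (tries >= max_tries) {
      abort("truncation interval accepts too few draws (empty or near-empty)")
    }
    m <- max(2 * (n - length(out)), 100)
    x <- rnorm(m, par["mu"], par["sigma"])
    out <- c(out, x[x >= lo & x <= hi])
    tries <- tries + 1
  }
  out[seq_len(n)]
}

# Map standard-normal scores to truncated-normal draws (Gaussian copula arm).
qtrunc_norm <- function(z, mean, sd, lo, hi) {
  if (sd <= 0 || lo == hi) return(rep(mean, length(z)))
  par <- trunc_norm_params(mean, sd, lo, hi)
  pa <- pnorm(lo, par["mu"], par["sigma"])
  pb <- pnorm(hi, par["mu"], par["sigma"])
  p <- pa + pnorm(z) * (pb - pa)
  pmin(pmax(qnorm(p, par["mu"], par["sigma"]), lo), hi)
}

# Centered moving-average smoother (odd window, edges padded by replication).
boxcar <- function(x, width) {
  if (width <= 1) return(x)
  w <- as.integer(width)
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}

# Indices of strict local maxima of x with both-sided prominence >= min_prom.
local_maxima <- function(x, min_prom = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (min_prom <= 0 || length(core) == 0) return(core)
  mins <- which(x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  bounds <- c(1L, mins, n)
  keep <- logical(length(core))
  for (i in seq_along(core)) {
    p <- core[i]
    left <- bounds[bounds < p]
    right <- bounds[bounds > p]
    lmin <- if (length(left)) min(x[max(left)]) else x[1]
    rmin <- if (length(right)) min(x[min(right)]) else x[n]
    keep[i] <- (x[p] - max(lmin, rmin)) >= min_prom
  }
  core[keep]
}
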