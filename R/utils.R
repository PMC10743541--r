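# Internal numerical helpers shared across modules.

#' @importFrom stats pnorm qnorm dnorm optim quantile rnorm runif rexp rbinom
#'   plogis qlogis glm binomial coef vcov t.test chisq.test loess predict
#'   complete.cases sd setNames
NULL

# Deterministic sub-stream seed for one variable block. Keeps every derived
# seed inside 32-bit integer range.
derive_seed <- function(master, block) {
  as.integer((abs(as.numeric(master)) * 48271 + block * 1299721) %% 2147483647)
}

# Inverse-CDF truncated-normal sampler; `hi`/`lo` may be vectors (used for
# per-subject diastolic upper bounds).
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# Mean and SD of N(mu, sigma^2) truncated to [lo, hi].
tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- ifelse(is.finite(a), dnorm(a), 0)
  db <- ifelse(is.finite(b), dnorm(b), 0)
  aa <- ifelse(is.finite(a), a * da, 0)
  bb <- ifelse(is.finite(b), b * db, 0)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (aa - bb) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Solve for the untruncated (mu, sigma) whose truncation to [lo, hi] has the
# requested mean and SD, so configured marginals survive range restriction.
tnorm_params <- function(target_mean, target_sd, lo = -Inf, hi = Inf) {
  if (!is.finite(lo) && !is.finite(hi)) {
    return(c(mean = target_mean, sd = target_sd))
  }
  obj <- function(p) {
    m <- tnorm_moments(p[1], exp(p[2]), lo, hi)
    (m[1] - target_mean)^2 / target_sd^2 + (m[2] - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Log-normal parameters matching an arithmetic mean and SD.
lnorm_params <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_cfg <- function(msg) stop(msg, call. = FALSE)
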