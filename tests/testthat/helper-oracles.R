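# Independent oracles and small fixture builders used across test files.

# brute-force ISS: maximize the sum of squared region maxima over all
# region subsets of size <= 3 (AIS 6 convention applied on top)
oracle_iss <- function(iss_region, ais) {
  if (any(ais == 6)) return(75L)
  maxima <- as.integer(tapply(ais, iss_region, max))
  best <- 0L
  for (size in seq_len(min(3L, length(maxima)))) {
    subsets <- utils::combn(length(maxima), size)
    for (q in seq_len(ncol(subsets))) {
      best <- max(best, sum(maxima[subsets[, q]]^2))
    }
  }
  as.integer(best)
}

# independent Holm step-down: sort ascending, scale by (m - i + 1),
# enforce monotonicity, cap at 1, restore input order
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    v <- min((m - i + 1) * p[ord[i]], 1)
    running <- max(running, v)
    adj[ord[i]] <- running
  }
  adj
}

# brute-force Bernoulli-mixture log-likelihood by direct product over items
oracle_loglik <- function(x, prop, rho) {
  x <- as.matrix(x)
  total <- 0
  for (i in seq_len(nrow(x))) {
    li <- 0
    for (k in seq_along(prop)) {
      li <- li + prop[k] *
        prod(rho[, k]^x[i, ] * (1 - rho[, k])^(1 - x[i, ]))
    }
    total <- total + log(li)
  }
  total
}

# one brute-force M-step: responsibility-weighted means, no clipping
oracle_m_step <- function(posterior, x) {
  k <- ncol(posterior)
  j <- ncol(x)
  prop <- colSums(posterior) / nrow(x)
  rho <- matrix(0, j, k)
  for (g in seq_len(k)) {
    for (jj in seq_len(j)) {
      rho[jj, g] <- sum(posterior[, g] * x[, jj]) / sum(posterior[, g])
    }
  }
  list(prop = prop, rho = rho)
}

# match estimated classes to true classes by exhaustive permutation search
# minimizing total absolute difference of item-probability profiles
match_classes <- function(rho_est, rho_true) {
  k <- ncol(rho_est)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_d <- Inf
  for (p in perms(seq_len(k))) {
    d <- sum(abs(rho_est[, p] - rho_true))
    if (d < best_d) {
      best_d <- d
      best <- p
    }
  }
  best
}

# small injury-record tibble builder
make_records <- function(casualty_id, region, nature, ais,
                         open_flag = NA) {
  tibble::tibble(
    casualty_id = casualty_id, region_code = region, nature_code = nature,
    ais = ais, open_fracture_flag = open_flag
  )
}

# random binary data with given marginals
random_binary <- function(n, j, seed) {
  set.seed(seed)
  p <- stats::runif(j, 0.1, 0.9)
  matrix(stats::rbinom(n * j, 1, rep(p, each = n)), n, j)
}
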