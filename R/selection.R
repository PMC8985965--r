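#' Free parameter count of a latent class model
#'
#' A K-class model over J binary items has `K*J` item probabilities and
#' `K-1` free mixing proportions.
#'
#' @param k Number of classes.
#' @param j Number of items.
#' @return Integer parameter count `k*j + (k-1)`.
#' @export
count_parameters <- function(k, j) {
  stopifnot(k >= 1, j >= 1)
  as.integer(k * j + (k - 1))
}

#' Information criteria for a fitted latent class model
#'
#' Computes the four penalized-likelihood criteria used to choose the
#' number of classes, all affine in the log-likelihood with
#' `p = K*J + (K-1)` free parameters:
#' \deqn{BIC = -2\ell + p\ln N,\quad
#'       AIC = -2\ell + 2p,\quad
#'       CAIC = -2\ell + p(\ln N + 1),\quad
#'       SABIC = -2\ell + p\ln\frac{N+2}{24}.}
#' SABIC is the sample-size-adjusted BIC with the `(N+2)/24` adjustment;
#' CAIC adds one unit per parameter on top of BIC.
#'
#' @param log_lik Log-likelihood, or an [fit_lca()] object (in which case
#'   `k`, `j`, `n` are taken from the fit).
#' @param k,j Number of classes and items.
#' @param n Sample size (>= 2).
#' @return One-row tibble: `k`, `log_lik`, `n_parameters`, `bic`, `sabic`,
#'   `aic`, `caic`.
#' @examples
#' information_criteria(-107823.0, k = 7, j = 181, n = 5227)
#' @export
information_criteria <- function(log_lik, k, j, n) {
  if (inherits(log_lik, "lca_fit")) {
    fit <- log_lik
    log_lik <- fit$log_lik
    k <- fit$k
    j <- fit$j
    n <- fit$n
  }
  stopifnot(n >= 2)
  p <- count_parameters(k, j)
  d <- -2 * log_lik
  tibble::tibble(
    k = k,
    log_lik = log_lik,
    n_parameters = p,
    bic = d + p * log(n),
    sabic = d + p * log((n + 2) / 24),
    aic = d + 2 * p,
    caic = d + p * (log(n) + 1)
  )
}

#' Relative entropy of a latent class solution
#'
#' Standardized entropy `1 - sum_i sum_k(-p_ik log p_ik) / (N log K)`,
#' in `[0, 1]`: 1 when every posterior row is one-hot (perfect class
#' separation), 0 when all rows are uniform. Values above 0.80 are
#' conventionally read as good classification. Undefined for K = 1
#' (returned as `NA`).
#'
#' @param posterior Row-stochastic N x K posterior matrix (or an
#'   [fit_lca()] object).
#' @return A single number in `[0, 1]`, or `NA` for K = 1.
#' @export
relative_entropy <- function(posterior) {
  if (inherits(posterior, "lca_fit")) posterior <- posterior$posterior
  p <- as.matrix(posterior)
  k <- ncol(p)
  if (k < 2L) return(NA_real_)
  h <- -p * log(p)
  h[!is.finite(h)] <- 0 # 0 * log(0) := 0
  1 - sum(h) / (nrow(p) * log(k))
}

#' Classification diagnostics of the maximum-probability assignment
#'
#' For each assignment group (row) the mean posterior probability of
#' membership in every class (column). Well-separated solutions show large
#' diagonals (conventionally > 0.70) and small off-diagonals
#' (conventionally <= 0.05); both flags are reported per row. Groups with
#' no assigned casualties yield an `NA` row, flagged `empty`.
#'
#' @param posterior Row-stochastic N x K posterior matrix (or an
#'   [fit_lca()] object, in which case `assignment` is taken from it).
#' @param assignment Integer class assignments from [assign_classes()].
#' @return A tibble with `assigned_class`, `n` (group size), mean posterior
#'   columns `class1..classK`, and flags `diagonal`, `well_separated`
#'   (diagonal >= 0.70 and off-diagonals <= 0.05), `empty`.
#' @export
classification_diagnostics <- function(posterior, assignment = NULL) {
  if (inherits(posterior, "lca_fit")) {
    if (is.null(assignment)) assignment <- posterior$assignment
    posterior <- posterior$posterior
  }
  p <- as.matrix(posterior)
  k <- ncol(p)
  stopifnot(length(assignment) == nrow(p))
  means <- matrix(NA_real_, k, k,
                  dimnames = list(NULL, paste0("class", seq_len(k))))
  sizes <- integer(k)
  for (r in seq_len(k)) {
    at <- which(assignment == r)
    sizes[r] <- length(at)
    if (length(at) > 0) means[r, ] <- colMeans(p[at, , drop = FALSE])
  }
  diagonal <- means[cbind(seq_len(k), seq_len(k))]
  off_ok <- vapply(seq_len(k), function(r) {
    all(means[r, -r] <= 0.05) %in% TRUE
  }, logical(1))
  out <- tibble::as_tibble(as.data.frame(means))
  dplyr::bind_cols(
    tibble::tibble(assigned_class = seq_len(k), n = sizes),
    out,
    tibble::tibble(
      diagonal = diagonal,
      well_separated = !is.na(diagonal) & diagonal >= 0.70 & off_ok,
      empty = sizes == 0L
    )
  )
}

#' Fit latent class models across a range of class counts
#'
#' Fits the model for every K in `k_range`, tabulates the information
#' criteria and relative entropy for each, and selects a working model.
#' The automatic selection is the smallest CAIC; the full table is
#' reported so the parsimony/interpretability judgement — which is a human
#' step — can override it. A failed fit for one K is recorded and the scan
#' continues.
#'
#' @inheritParams fit_lca
#' @param k_range Integer vector of class counts to fit (default `1:10`).
#' @param criterion Criterion minimized by the automatic selection
#'   (`"caic"`, `"bic"`, `"sabic"`, or `"aic"`; default `"caic"`).
#' @return An object of class `lca_scan`: `fits` (named list of
#'   [fit_lca()] objects), `statistics` (tibble with one row per K: the
#'   criteria plus `entropy` and `converged`), `selected_k`, `criterion`,
#'   `errors` (named list of failure messages).
#' @examples
#' coh <- sample_cohort(default_template(3, 12, seed = 1), n = 400)
#' scan <- scan_lca(coh$indicators, k_range = 1:4, n_starts = 3, seed = 1)
#' scan$selected_k
#' @export
scan_lca <- function(data, k_range = 1:10, n_starts = 20, tol = 1e-8,
                     max_iter = 5000, seed = 1L, eps = 1e-6,
                     criterion = c("caic", "bic", "sabic", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(length(k_range) >= 1, all(k_range >= 1))
  fits <- list()
  errors <- list()
  rows <- list()
  for (k in k_range) {
    key <- as.character(k)
    fit <- tryCatch(
      fit_lca(data, k, n_starts = n_starts, tol = tol,
              max_iter = max_iter, seed = child_seed(seed, 10L * k), eps = eps),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errors[[key]] <- conditionMessage(fit)
      rows[[key]] <- tibble::tibble(
        k = k, log_lik = NA_real_, n_parameters = NA_integer_,
        bic = NA_real_, sabic = NA_real_, aic = NA_real_, caic = NA_real_,
        entropy = NA_real_, converged = NA
      )
      next
    }
    fits[[key]] <- fit
    stats_row <- information_criteria(fit)
    stats_row$entropy <- relative_entropy(fit)
    stats_row$converged <- fit$converged
    rows[[key]] <- stats_row
  }
  statistics <- dplyr::bind_rows(rows)
  crit <- statistics[[criterion]]
  selected_k <- if (all(is.na(crit))) NA_integer_ else {
    statistics$k[which.min(crit)]
  }
  structure(
    list(fits = fits, statistics = statistics, selected_k = selected_k,
         criterion = criterion, errors = errors, seed = as.integer(seed)),
    class = "lca_scan"
  )
}

#' @export
print.lca_scan <- function(x, ...) {
  cat(sprintf("<lca_scan> %d models fitted; selected k = %s (smallest %s)\n",
              length(x$fits), format(x$selected_k), toupper(x$criterion)))
  print(format_fit_statistics(x$statistics))
  invisible(x)
}

# Table-1-style formatted fit statistics (smallest value per criterion
# starred; entropy dash for k = 1).
format_fit_statistics <- function(statistics) {
  df <- statistics
  fmt_crit <- function(v) {
    s <- sprintf("%.1f", v)
    best <- which.min(v)
    s[best] <- paste0(s[best], "*")
    s[is.na(v)] <- "-"
    s
  }
  tibble::tibble(
    K = df$k,
    LL = sprintf("%.1f", df$log_lik),
    BIC = fmt_crit(df$bic),
    SABIC = fmt_crit(df$sabic),
    AIC = fmt_crit(df$aic),
    CAIC = fmt_crit(df$caic),
    Entropy = ifelse(is.na(df$entropy), "-", sprintf("%.3f", df$entropy))
  )
}
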