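#' Latent class model log-likelihood
#'
#' Observed-data log-likelihood of a K-class mixture of independent
#' Bernoulli items:
#' \deqn{\ell = \sum_i \log \sum_k \pi_k \prod_j \rho_{jk}^{x_{ij}}
#'   (1-\rho_{jk})^{1-x_{ij}}}
#' computed in log space for numerical stability.
#'
#' @param params List with `prop` (length-K mixing proportions) and `rho`
#'   (J x K item probability matrix), e.g. the `params` of an [fit_lca()]
#'   object.
#' @param data Binary N x J data frame or matrix (a `casualty_id` column is
#'   ignored).
#' @return The log-likelihood (a single non-positive number).
#' @export
lca_log_likelihood <- function(params, data) {
  x <- as_indicator_matrix(data)
  e <- bernoulli_e_step(x, params$prop, params$rho)
  e$log_lik
}

#' EM steps for the Bernoulli-mixture latent class model
#'
#' `lca_e_step()` returns the posterior class-membership probabilities
#' (responsibilities) of each observation: row i, class k proportional to
#' \eqn{\pi_k \prod_j \rho_{jk}^{x_{ij}} (1-\rho_{jk})^{1-x_{ij}}},
#' normalized over k. `lca_m_step()` maximizes the expected complete-data
#' log-likelihood given responsibilities: mixing proportions are mean
#' responsibilities and item probabilities are responsibility-weighted item
#' means, clipped away from 0 and 1.
#'
#' @inheritParams lca_log_likelihood
#' @param posterior Row-stochastic N x K matrix of responsibilities.
#' @param eps Clipping bound for item probabilities (default `1e-6`).
#' @return `lca_e_step()`: N x K posterior matrix. `lca_m_step()`: list
#'   with `prop` and `rho`.
#' @export
lca_e_step <- function(params, data) {
  x <- as_indicator_matrix(data)
  bernoulli_e_step(x, params$prop, params$rho)$posterior
}

#' @rdname lca_e_step
#' @export
lca_m_step <- function(posterior, data, eps = 1e-6) {
  x <- as_indicator_matrix(data)
  posterior <- as.matrix(posterior)
  stopifnot(nrow(posterior) == nrow(x))
  bernoulli_m_step(x, posterior, eps)
}

# log rho and log(1 - rho) collapse to one matmul via the logit trick:
# log f_k(x_i) = x_i %*% (log rho_k - log(1-rho_k)) + sum_j log(1-rho_jk)
bernoulli_e_step <- function(x, prop, rho) {
  rho <- as.matrix(rho)
  stopifnot(ncol(x) == nrow(rho), length(prop) == ncol(rho))
  rho_c <- pmin(pmax(rho, 1e-12), 1 - 1e-12)
  a <- log(rho_c) - log1p(-rho_c)
  base <- colSums(log1p(-rho_c))
  logp <- x %*% a
  logp <- sweep(logp, 2L, base + log(pmax(prop, 1e-300)), "+")
  ll_i <- row_logsumexp(logp)
  list(posterior = exp(logp - ll_i), log_lik = sum(ll_i))
}

bernoulli_m_step <- function(x, posterior, eps = 1e-6) {
  nk <- colSums(posterior)
  if (any(nk < 10 * .Machine$double.eps)) {
    stop("degenerate class: a component lost all responsibility",
         call. = FALSE)
  }
  prop <- nk / nrow(x)
  rho <- sweep(crossprod(x, posterior), 2L, nk, "/")
  rho <- pmin(pmax(rho, eps), 1 - eps)
  list(prop = prop, rho = rho)
}

#' Fit a latent class model to binary injury indicators
#'
#' Fits a K-class mixture of independent Bernoulli items by
#' expectation-maximization with multiple random restarts, keeping the
#' restart with the highest final log-likelihood. Each restart initializes
#' responsibilities from a flat Dirichlet and alternates M- and E-steps
#' until the relative log-likelihood improvement falls below `tol`.
#' Classes are put in canonical order (descending mixing proportion, ties
#' by first-item probability) and casualties are hard-assigned by the
#' maximum-probability rule.
#'
#' @param data Binary N x J data frame or matrix of injury indicators; a
#'   `casualty_id` column is carried through but not modeled.
#' @param k Number of latent classes (>= 1).
#' @param n_starts Number of random restarts (default 20).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 5000).
#' @param seed Seed controlling all restarts (restart r uses a derived
#'   child seed, so the fit is reproducible).
#' @param eps Item-probability clipping bound (default 1e-6).
#' @return An object of class `lca_fit`: `params` (`prop`, `rho`),
#'   `log_lik`, `posterior` (N x K), `assignment` (length N),
#'   `n_iter`, `converged`, `n_starts`, `k`, `n`, `j`, `seed`,
#'   `item_names`, `casualty_id`.
#' @examples
#' coh <- sample_cohort(default_template(3, 12, seed = 1), n = 300)
#' fit <- fit_lca(coh$indicators, k = 3, n_starts = 3, seed = 1)
#' fit$params$prop
#' @export
fit_lca <- function(data, k, n_starts = 20, tol = 1e-8, max_iter = 5000,
                    seed = 1L, eps = 1e-6) {
  stopifnot(k >= 1, n_starts >= 1, max_iter >= 1)
  ids <- if (is.data.frame(data) && "casualty_id" %in% names(data)) {
    data$casualty_id
  } else NULL
  x <- as_indicator_matrix(data)
  if (nrow(x) == 0L) stop("cannot fit a latent class model to an empty cohort",
                          call. = FALSE)

  best <- NULL
  failures <- character(0)
  for (r in seq_len(n_starts)) {
    run <- tryCatch(
      em_single_run(x, k, tol, max_iter, child_seed(seed, 100L + r), eps),
      error = function(e) e
    )
    if (inherits(run, "error")) {
      failures <- c(failures, conditionMessage(run))
      next
    }
    if (is.null(best) || run$log_lik > best$log_lik) best <- run
    if (k == 1L) break # closed form; restarts are identical
  }
  if (is.null(best)) {
    stop("all EM restarts failed: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }

  ord <- canonical_class_order(best$prop, best$rho)
  prop <- best$prop[ord]
  rho <- best$rho[, ord, drop = FALSE]
  e <- bernoulli_e_step(x, prop, rho)
  posterior <- e$posterior
  item_names <- colnames(x)
  if (is.null(item_names)) item_names <- sprintf("item%03d", seq_len(ncol(x)))
  rownames(rho) <- item_names
  colnames(rho) <- NULL

  structure(
    list(
      params = list(prop = prop, rho = rho),
      log_lik = e$log_lik,
      posterior = posterior,
      assignment = assign_classes(posterior),
      n_iter = best$n_iter,
      converged = best$converged,
      n_starts = n_starts,
      k = k, n = nrow(x), j = ncol(x),
      seed = as.integer(seed),
      item_names = item_names,
      casualty_id = ids,
      ll_trace = best$ll_trace
    ),
    class = "lca_fit"
  )
}

em_single_run <- function(x, k, tol, max_iter, run_seed, eps) {
  set.seed(run_seed)
  n <- nrow(x)
  # flat-Dirichlet random responsibilities, then an M-step
  g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  posterior <- g / rowSums(g)
  params <- bernoulli_m_step(x, posterior, eps)

  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- bernoulli_e_step(x, params$prop, params$rho)
    ll_trace <- c(ll_trace, e$log_lik)
    if (is.finite(ll_prev) &&
        (e$log_lik - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- e$log_lik
    if (iter >= max_iter) break
    params <- bernoulli_m_step(x, e$posterior, eps)
  }
  list(prop = params$prop, rho = params$rho, log_lik = e$log_lik,
       n_iter = iter, converged = converged, ll_trace = ll_trace)
}

canonical_class_order <- function(prop, rho) {
  order(-prop, -rho[1, ], seq_along(prop))
}

#' Maximum-probability class assignment
#'
#' Hard-assigns each observation to the class with the highest posterior
#' probability; ties go to the lowest class index.
#'
#' @param posterior Row-stochastic N x K posterior matrix.
#' @return Integer vector of class indices in 1..K.
#' @examples
#' assign_classes(rbind(c(0.9, 0.1), c(0.5, 0.5))) # 1 1
#' @export
assign_classes <- function(posterior) {
  posterior <- as.matrix(posterior)
  max.col(posterior, ties.method = "first")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf(
    "<lca_fit> %d classes, %d casualties, %d items; logLik %.1f (%s, %d iter, %d starts)\n",
    x$k, x$n, x$j, x$log_lik,
    if (x$converged) "converged" else "not converged", x$n_iter, x$n_starts
  ))
  cat(" class shares:",
      paste(sprintf("%.3f", x$params$prop), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.lca_fit <- function(object, ...) {
  structure(object$log_lik,
            df = count_parameters(object$k, object$j),
            nobs = object$n, class = "logLik")
}
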