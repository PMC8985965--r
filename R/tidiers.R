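#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted latent class model
#'
#' `tidy()` returns one row per (item, class) with the estimated
#' conditional item probability and the class mixing proportion.
#' `glance()` returns a one-row model summary with the information
#' criteria and relative entropy. `augment()` returns casualty-level
#' output: the hard class assignment and the posterior membership
#' probabilities.
#'
#' @param x,object An [fit_lca()] object.
#' @param ... Unused.
#' @return A tibble (see above).
#' @name lca_fit-tidiers
NULL

#' @rdname lca_fit-tidiers
#' @method tidy lca_fit
#' @export
tidy.lca_fit <- function(x, ...) {
  k <- x$k
  tibble::tibble(
    item = rep(x$item_names, times = k),
    class = rep(seq_len(k), each = x$j),
    probability = as.numeric(x$params$rho),
    mixing_proportion = rep(x$params$prop, each = x$j)
  )
}

#' @rdname lca_fit-tidiers
#' @method glance lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  out <- information_criteria(x)
  out$entropy <- relative_entropy(x)
  out$n <- x$n
  out$j <- x$j
  out$converged <- x$converged
  out$n_iter <- x$n_iter
  out
}

#' @rdname lca_fit-tidiers
#' @method augment lca_fit
#' @export
augment.lca_fit <- function(x, ...) {
  post <- tibble::as_tibble(as.data.frame(x$posterior))
  names(post) <- paste0(".posterior", seq_len(x$k))
  id <- if (is.null(x$casualty_id)) seq_len(x$n) else x$casualty_id
  dplyr::bind_cols(
    tibble::tibble(casualty_id = id, .class = x$assignment),
    post
  )
}

#' Tidy a class-count scan
#'
#' `tidy()` returns the fit-statistics table (one row per K); `glance()`
#' returns the row of the selected model plus the selection criterion.
#'
#' @param x An [scan_lca()] object.
#' @param ... Unused.
#' @return A tibble.
#' @name lca_scan-tidiers
NULL

#' @rdname lca_scan-tidiers
#' @method tidy lca_scan
#' @export
tidy.lca_scan <- function(x, ...) {
  x$statistics
}

#' @rdname lca_scan-tidiers
#' @method glance lca_scan
#' @export
glance.lca_scan <- function(x, ...) {
  row <- dplyr::filter(x$statistics, .data$k == x$selected_k)
  row$criterion <- x$criterion
  row
}
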