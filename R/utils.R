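#' Round half away from zero
#'
#' Decimal rounding where ties go up (`0.05 -> 0.1`), the convention used in
#' printed epidemiological tables, rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.15, 0.25), 1) # 0.2 0.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic child seed for a pipeline stage, kept inside 32-bit range.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) + 999983 * stage) %% 2147483647)
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Drop an id column (if present) and return a checked binary numeric matrix.
as_indicator_matrix <- function(data, id_col = "casualty_id") {
  if (is.data.frame(data)) {
    if (id_col %in% names(data)) data <- data[setdiff(names(data), id_col)]
    m <- as.matrix(data)
  } else {
    m <- as.matrix(data)
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("indicator data must be binary (0/1) with no missing values",
         call. = FALSE)
  }
  m
}
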