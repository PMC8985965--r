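#' Label latent classes as injury profiles
#'
#' A class's *defining items* are the indicators whose conditional item
#' probability meets the labeling threshold (default 0.30, boundary
#' inclusive), listed in descending probability. Class prevalence is the
#' share of the cohort hard-assigned to the class. Naming the resulting
#' profiles ("open wounds", "burns", ...) is an analyst judgement and is
#' not automated.
#'
#' @param fit An [fit_lca()] object.
#' @param threshold Minimum conditional item probability (default 0.30).
#' @return A tibble with one row per defining item: `class`, `prevalence`,
#'   `item`, `probability`, and (when items are Barell `cell_id`s)
#'   `nature_name`, `region_name`. A class with no defining item keeps a
#'   single row with `NA` item and raises a warning.
#' @examples
#' coh <- sample_cohort(default_template(3, 12, seed = 1), n = 400)
#' fit <- fit_lca(coh$indicators, k = 3, n_starts = 3, seed = 1)
#' label_profiles(fit)
#' @export
label_profiles <- function(fit, threshold = 0.30) {
  stopifnot(inherits(fit, "lca_fit"), threshold > 0, threshold < 1)
  k <- fit$k
  prevalence <- tabulate(fit$assignment, nbins = k) / fit$n
  rho <- fit$params$rho

  per_class <- lapply(seq_len(k), function(g) {
    keep <- which(rho[, g] >= threshold)
    if (length(keep) == 0L) {
      return(tibble::tibble(class = g, prevalence = prevalence[g],
                            item = NA_character_, probability = NA_real_))
    }
    keep <- keep[order(-rho[keep, g], keep)]
    tibble::tibble(class = g, prevalence = prevalence[g],
                   item = fit$item_names[keep],
                   probability = unname(rho[keep, g]))
  })
  out <- dplyr::bind_rows(per_class)

  empty <- unique(out$class[is.na(out$item)])
  if (length(empty) > 0) {
    warning("class(es) with no defining item at threshold ",
            format(threshold), ": ", paste(empty, collapse = ", "),
            call. = FALSE)
  }

  cells <- barell_cells()
  if (any(out$item %in% cells$cell_id)) {
    out <- dplyr::left_join(
      out, cells[c("cell_id", "nature_name", "region_name")],
      by = c(item = "cell_id")
    )
  }
  attr(out, "threshold") <- threshold
  out
}

#' Cross-tabulate a covariate by assigned class
#'
#' Counts of each level of one categorical covariate by assigned class,
#' with within-class column percentages (rounded half-up to one decimal
#' for display) and a cohort-wide total column.
#'
#' @param covariates Data frame of casualty covariates, one row per
#'   casualty in the order of the assignments.
#' @param assignment Integer class assignments.
#' @param variable Name of the covariate column to tabulate.
#' @return A tibble with `variable`, `level`, `class` (`"total"` plus
#'   `"1"`..`"K"`), `n`, `pct`.
#' @export
crosstab_by_class <- function(covariates, assignment, variable) {
  covariates <- tibble::as_tibble(covariates)
  stopifnot(variable %in% names(covariates),
            nrow(covariates) == length(assignment))
  value <- as.character(covariates[[variable]])
  levels_seen <- if (is.factor(covariates[[variable]])) {
    levels(covariates[[variable]])
  } else sort(unique(value))
  k <- max(assignment)

  grid <- tidyr::expand_grid(level = levels_seen,
                             class = c("total", as.character(seq_len(k))))
  tab <- tibble::tibble(level = value,
                        class = as.character(assignment)) |>
    dplyr::count(.data$level, .data$class)
  tot <- tibble::tibble(level = value) |>
    dplyr::count(.data$level) |>
    dplyr::mutate(class = "total")
  counts <- dplyr::bind_rows(tab, tot)
  out <- dplyr::left_join(grid, counts, by = c("level", "class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))

  group_n <- c(total = length(assignment),
               stats::setNames(tabulate(assignment, nbins = k),
                               as.character(seq_len(k))))
  out$pct <- unname(round_half_up(100 * out$n / group_n[out$class], 1))
  out$pct[group_n[out$class] == 0] <- NA_real_
  dplyr::bind_cols(tibble::tibble(variable = variable), out)
}

# level x class count matrix from a crosstab_by_class() tibble
crosstab_matrix <- function(crosstab) {
  wide <- crosstab |>
    dplyr::filter(.data$class != "total") |>
    dplyr::select("level", "class", "n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$level
  m
}

#' Omnibus chi-square test of a class-by-level table
#'
#' Pearson chi-square test of independence (no continuity correction)
#' between covariate level and assigned class. Zero-margin rows and
#' columns are dropped with a warning; a flag reports whether any expected
#' count is below 5.
#'
#' @param counts Level x class count matrix, or a [crosstab_by_class()]
#'   tibble.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `min_expected`,
#'   `expected_below_5`.
#' @export
class_chisq <- function(counts) {
  m <- if (is.data.frame(counts)) crosstab_matrix(counts) else as.matrix(counts)
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns before the chi-square test",
            call. = FALSE)
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("chi-square test needs at least a 2 x 2 table after dropping ",
         "zero margins", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  min_exp <- min(ht$expected)
  if (min_exp < 5) {
    warning("expected count below 5 in the chi-square table", call. = FALSE)
  }
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    min_expected = min_exp,
    expected_below_5 = min_exp < 5
  )
}

#' Holm-adjusted pairwise proportion comparisons across classes
#'
#' For each level of a categorical variable, compares the level's
#' proportion between every pair of classes with a two-proportion Pearson
#' chi-square test (no continuity correction) and adjusts the p-values by
#' the Holm step-down method. The adjustment family is the set of all
#' `choose(K, 2)` pairwise tests of one level (one report row), matching
#' the row-wise significance marks of the standard presentation. Levels in
#' `exclude_levels` (e.g. "unknown" posture) are tabulated elsewhere but
#' not tested.
#'
#' @param counts Level x class count matrix, or a [crosstab_by_class()]
#'   tibble.
#' @param variable Variable name carried into the output.
#' @param alpha Familywise significance level (default 0.05).
#' @param exclude_levels Levels to skip (default `c("unknown")`).
#' @return A tibble with one row per (level, class pair): `variable`,
#'   `level`, `class_a`, `class_b`, `prop_a`, `prop_b`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
pairwise_holm <- function(counts, variable = "", alpha = 0.05,
                          exclude_levels = c("unknown")) {
  stopifnot(alpha > 0, alpha < 1)
  m <- if (is.data.frame(counts)) crosstab_matrix(counts) else as.matrix(counts)
  k <- ncol(m)
  if (k < 2) stop("pairwise comparisons need at least two classes",
                  call. = FALSE)
  class_n <- colSums(m)
  class_names <- colnames(m)
  if (is.null(class_names)) class_names <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)

  res <- list()
  for (lv in setdiff(rownames(m), exclude_levels)) {
    rows <- lapply(seq_len(ncol(pairs)), function(q) {
      a <- pairs[1, q]
      b <- pairs[2, q]
      n_la <- m[lv, a]
      n_lb <- m[lv, b]
      if (n_la + n_lb == 0 || class_n[a] == 0 || class_n[b] == 0) {
        return(NULL) # level absent in both classes: nothing to compare
      }
      t22 <- rbind(c(n_la, class_n[a] - n_la),
                   c(n_lb, class_n[b] - n_lb))
      p <- if (any(colSums(t22) == 0)) 1 else {
        suppressWarnings(stats::chisq.test(t22, correct = FALSE))$p.value
      }
      tibble::tibble(
        variable = variable, level = lv,
        class_a = class_names[a], class_b = class_names[b],
        prop_a = unname(n_la / class_n[a]),
        prop_b = unname(n_lb / class_n[b]),
        p_raw = p
      )
    })
    fam <- dplyr::bind_rows(rows)
    if (nrow(fam) == 0) next
    fam$p_adj <- stats::p.adjust(fam$p_raw, method = "holm")
    fam$significant <- fam$p_adj < alpha
    res[[lv]] <- fam
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      variable = character(), level = character(), class_a = character(),
      class_b = character(), prop_a = numeric(), prop_b = numeric(),
      p_raw = numeric(), p_adj = numeric(), significant = logical()
    )
  }
  attr(out, "alpha") <- alpha
  out
}

#' Superscript-style significance marks per class
#'
#' Condenses [pairwise_holm()] results into, for each (level, class), the
#' letters of the classes it differs from significantly — the superscript
#' convention of characteristics tables (a = class 1, b = class 2, ...).
#'
#' @param pairwise A [pairwise_holm()] result.
#' @return A tibble with `variable`, `level`, `class`, `marks`.
#' @export
significance_marks <- function(pairwise) {
  sig <- dplyr::filter(pairwise, .data$significant)
  both <- dplyr::bind_rows(
    dplyr::select(sig, "variable", "level",
                  class = "class_a", other = "class_b"),
    dplyr::select(sig, "variable", "level",
                  class = "class_b", other = "class_a")
  )
  if (nrow(both) == 0) {
    return(tibble::tibble(variable = character(), level = character(),
                          class = character(), marks = character()))
  }
  both |>
    dplyr::mutate(mark = letters[as.integer(.data$other)]) |>
    dplyr::group_by(.data$variable, .data$level, .data$class) |>
    dplyr::summarise(marks = paste(sort(.data$mark), collapse = ","),
                     .groups = "drop")
}

#' Characteristics report across injury profiles
#'
#' Builds the full characteristics table for a set of covariates: counts
#' and within-class percentages by level and class, the omnibus chi-square
#' p-value per variable, and Holm-adjusted pairwise significance marks.
#'
#' @param covariates Data frame of casualty covariates.
#' @param assignment Integer class assignments.
#' @param variables Covariate columns to report (default: all non-id
#'   columns).
#' @param alpha Familywise significance level (default 0.05).
#' @param exclude_levels Levels excluded from pairwise testing.
#' @return A list with `table` (tibble: crosstabs + `omnibus_p` + `marks`)
#'   and `pairwise` (all pairwise comparison rows).
#' @export
profile_characteristics <- function(covariates, assignment,
                                    variables = NULL, alpha = 0.05,
                                    exclude_levels = c("unknown")) {
  covariates <- tibble::as_tibble(covariates)
  if (is.null(variables)) {
    variables <- setdiff(names(covariates), "casualty_id")
  }
  tables <- list()
  pw_all <- list()
  for (v in variables) {
    ct <- crosstab_by_class(covariates, assignment, v)
    omni <- tryCatch(class_chisq(ct), error = function(e) NULL)
    pw <- tryCatch(
      pairwise_holm(ct, variable = v, alpha = alpha,
                    exclude_levels = exclude_levels),
      error = function(e) NULL
    )
    ct$omnibus_p <- if (is.null(omni)) NA_real_ else omni$p_value
    if (!is.null(pw) && nrow(pw) > 0) {
      marks <- significance_marks(pw)
      ct <- dplyr::left_join(
        ct, marks[c("level", "class", "marks")], by = c("level", "class")
      )
      pw_all[[v]] <- pw
    } else {
      ct$marks <- NA_character_
    }
    tables[[v]] <- ct
  }
  list(table = dplyr::bind_rows(tables),
       pairwise = dplyr::bind_rows(pw_all))
}
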