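#' Build the binary injury indicator matrix
#'
#' Converts classified injury records into an N x J table of binary
#' indicators, one column per Barell cell: a cell's indicator is 1 when the
#' casualty has at least one injury coded to that cell, irrespective of how
#' many. By default only populated cells (columns with at least one positive
#' entry in this cohort) are kept, so J is the number of populated cells;
#' passing `cells` fixes the column set instead, which is what round-trip
#' checks and out-of-sample coding need.
#'
#' @param records Data frame of injury records with `casualty_id`,
#'   `region_code`, `nature_code`, and `open_fracture_flag` columns (or
#'   already-classified records carrying `cell_id`).
#' @param cells Optional character vector of `cell_id`s fixing the columns
#'   (in the given order). Overrides `populated_only`.
#' @param populated_only Drop all-zero columns (default `TRUE`).
#' @param casualty_ids Optional vector of ids defining the rows (so
#'   casualties without any record still appear as all-zero rows).
#' @return A tibble with `casualty_id` plus one 0/1 column per cell, columns
#'   in row-major Barell order (or the order of `cells`). The cell
#'   definitions are attached as the `"cell_index"` attribute.
#' @examples
#' rec <- data.frame(casualty_id = c(1, 1), region_code = "face",
#'                   nature_code = "open wound", ais = 1,
#'                   open_fracture_flag = NA)
#' build_indicator_matrix(rec)
#' @export
build_indicator_matrix <- function(records, cells = NULL,
                                   populated_only = TRUE,
                                   casualty_ids = NULL) {
  records <- tibble::as_tibble(records)
  if (!"cell_id" %in% names(records)) {
    records <- classify_injury(records)
  }
  if (is.null(casualty_ids)) {
    casualty_ids <- unique(records$casualty_id)
  }
  if (is.null(cells)) {
    all_cells <- barell_cells()$cell_id
    present <- all_cells[all_cells %in% unique(records$cell_id)]
    cells <- if (populated_only) present else all_cells
    if (populated_only && length(cells) == 0L) {
      warning("no populated cells: empty indicator matrix", call. = FALSE)
    }
  } else {
    unknown <- setdiff(unique(records$cell_id), cells)
    if (length(unknown) > 0L) {
      stop("records map to cells outside the supplied cell set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  m <- matrix(0, nrow = length(casualty_ids), ncol = length(cells),
              dimnames = list(NULL, cells))
  if (nrow(records) > 0L && length(cells) > 0L) {
    i <- match(records$casualty_id, casualty_ids)
    j <- match(records$cell_id, cells)
    keep <- !is.na(i) & !is.na(j)
    m[cbind(i[keep], j[keep])] <- 1
  }
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(casualty_id = casualty_ids), out)
  idx <- barell_cells()
  attr(out, "cell_index") <- idx[match(cells, idx$cell_id), ]
  out
}

#' Compute the Injury Severity Score
#'
#' ISS is the sum of the squares of the highest AIS severity in each of the
#' three most severely injured of six body regions (head/neck, face, chest,
#' abdomen, extremities including pelvis, external). Any injury with AIS 6
#' sets ISS to 75 by the standard convention. The bridge from Barell rows to
#' ISS regions is the packaged `iss_region` column of [barell_regions()]; an
#' alternative bridge can be supplied.
#'
#' @param records Data frame of injury records with `casualty_id`, `ais`,
#'   and resolvable region/nature codes (or a `cell_id`/`region_row`
#'   column from [classify_injury()]).
#' @param iss_region_map Optional named character vector mapping
#'   `region_row` (as names, "1".."36") to ISS region labels; defaults to
#'   the packaged bridge.
#' @return A tibble with one row per casualty: `casualty_id`, `iss`
#'   (integer 1-75), and `category` (see [categorize_iss()]).
#' @examples
#' rec <- data.frame(
#'   casualty_id = 1,
#'   region_code = c("type_1_tbi", "chest", "lower_leg_ankle"),
#'   nature_code = c("internal_organ", "internal_organ", "open_wound"),
#'   ais = c(4, 3, 2), open_fracture_flag = NA
#' )
#' compute_iss(rec) # 4^2 + 3^2 + 2^2 = 29
#' @export
compute_iss <- function(records, iss_region_map = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot("ais" %in% names(records))
  if (!"region_row" %in% names(records)) {
    records <- classify_injury(records)
  }
  ais <- records$ais
  if (anyNA(ais) || !all(ais %in% 1:6)) {
    stop("AIS severities must be integers in 1..6", call. = FALSE)
  }
  if (is.null(iss_region_map)) {
    regions <- barell_regions()
    iss_region_map <- stats::setNames(regions$iss_region,
                                      regions$region_row)
  }
  records$iss_region <- unname(iss_region_map[as.character(records$region_row)])
  if (anyNA(records$iss_region)) {
    stop("region row(s) missing from the ISS region map", call. = FALSE)
  }

  records |>
    dplyr::group_by(.data$casualty_id) |>
    dplyr::summarise(iss = iss_from_region_ais(.data$iss_region, .data$ais),
                     .groups = "drop") |>
    dplyr::mutate(category = categorize_iss(.data$iss))
}

# top-3 rule on per-region AIS maxima; AIS 6 anywhere -> 75
iss_from_region_ais <- function(iss_region, ais) {
  if (any(ais == 6)) return(75L)
  maxima <- tapply(ais, iss_region, max)
  top <- sort(as.integer(maxima), decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  as.integer(sum(top^2))
}

#' Categorize an Injury Severity Score
#'
#' Boundary-inclusive severity bands: serious 9-15, severe 16-24,
#' critical >= 25; scores below 9 are `below_serious`.
#'
#' @param iss Integer vector of ISS values in 1..75.
#' @return Character vector of categories.
#' @examples
#' categorize_iss(c(8, 9, 16, 24, 25)) # below_serious serious severe severe critical
#' @export
categorize_iss <- function(iss) {
  if (anyNA(iss) || any(iss < 1 | iss > 75)) {
    stop("ISS must be in 1..75", call. = FALSE)
  }
  dplyr::case_when(
    iss >= 25 ~ "critical",
    iss >= 16 ~ "severe",
    iss >= 9 ~ "serious",
    TRUE ~ "below_serious"
  )
}

#' Apply the severity inclusion filter
#'
#' Keeps casualties at or above a minimum ISS (default 9, i.e. serious or
#' greater), preserving input order, and reports how many were excluded.
#'
#' @param iss_results A tibble from [compute_iss()].
#' @param min_iss Minimum ISS for inclusion (default 9).
#' @return The casualty ids meeting the threshold, in input order, with the
#'   excluded count as the `"n_excluded"` attribute.
#' @export
filter_by_iss <- function(iss_results, min_iss = 9) {
  keep <- iss_results$iss >= min_iss
  ids <- iss_results$casualty_id[keep]
  n_excluded <- sum(!keep)
  if (length(ids) == 0L) {
    warning("no casualties meet the ISS threshold", call. = FALSE)
  }
  message(sprintf("ISS filter: %d included, %d excluded (min ISS %s)",
                  length(ids), n_excluded, format(min_iss)))
  attr(ids, "n_excluded") <- n_excluded
  ids
}
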