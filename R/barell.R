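#' The extended Barell Injury Diagnosis Matrix
#'
#' The Barell matrix is the CDC-endorsed two-dimensional injury
#' classification: 36 body-region rows by 12 nature-of-injury columns. This
#' package uses the extended form in which the fracture column is split into
#' open and closed fractures, giving 13 nature columns. Each (region, nature)
#' pair is one *cell*; a casualty's injuries are summarized as binary
#' indicators over the populated cells.
#'
#' `barell_regions()` and `barell_natures()` return the canonical row and
#' column definitions; `barell_cells()` returns all 36 x 13 cells in
#' deterministic row-major order (region 1..36 within nature-major columns
#' 1..13 nested), each with a stable `cell_id` of the form `"r<RR>c<CC>"`.
#'
#' @return A tibble. For `barell_regions()`: `region_row`, `region_name`,
#'   `region_code` (lookup dialect code), `iss_region` (one of the six
#'   standard ISS body regions). For `barell_natures()`: `nature_col`,
#'   `nature_name`, `nature_code`, `open_fracture` (logical; `NA` for
#'   non-fracture natures). For `barell_cells()`: `cell_id`, `region_row`,
#'   `nature_col`, `region_name`, `nature_name`.
#' @examples
#' barell_regions()
#' barell_natures()
#' nrow(barell_cells()) # 468
#' @export
barell_regions <- function() {
  tibble::tibble(
    region_row = 1:36,
    region_name = c(
      "Type 1 TBI", "Type 2 TBI", "Type 3 TBI", "Other head", "Face", "Eye",
      "Neck", "Head, face, and neck unspecified",
      "Cervical SCI", "Thoracic/dorsal SCI", "Lumbar SCI",
      "Sacrum coccyx SCI", "Spine and back unspecified SCI",
      "Cervical VCI", "Thoracic/dorsal VCI", "Lumbar VCI",
      "Sacrum coccyx VCI", "Spine and back unspecified VCI",
      "Chest", "Abdomen", "Pelvis and urogenital", "Trunk",
      "Back and buttock",
      "Shoulder and upper arm", "Forearm and elbow",
      "Wrist, hand, and fingers", "Other and unspecified upper extremity",
      "Hip", "Upper leg and thigh", "Knee", "Lower leg and ankle",
      "Foot and toes", "Other and unspecified lower extremity",
      "Other/multiple", "Unspecified", "System-wide and late effects"
    ),
    region_code = c(
      "type_1_tbi", "type_2_tbi", "type_3_tbi", "other_head", "face", "eye",
      "neck", "head_face_neck_unspecified",
      "cervical_sci", "thoracic_dorsal_sci", "lumbar_sci",
      "sacrum_coccyx_sci", "spine_back_unspecified_sci",
      "cervical_vci", "thoracic_dorsal_vci", "lumbar_vci",
      "sacrum_coccyx_vci", "spine_back_unspecified_vci",
      "chest", "abdomen", "pelvis_urogenital", "trunk", "back_buttock",
      "shoulder_upper_arm", "forearm_elbow", "wrist_hand_fingers",
      "other_upper_extremity", "hip", "upper_leg_thigh", "knee",
      "lower_leg_ankle", "foot_toes", "other_lower_extremity",
      "other_multiple", "unspecified", "system_wide"
    ),
    # Bridge from Barell rows to the six standard ISS body regions. The
    # published matrix does not prescribe this mapping; it is a declared,
    # editable convention (see compute_iss()).
    iss_region = c(
      "head_neck", "head_neck", "head_neck", "head_neck", "face", "face",
      "head_neck", "head_neck",
      "head_neck", "chest", "abdomen", "abdomen", "abdomen",
      "head_neck", "chest", "abdomen", "abdomen", "abdomen",
      "chest", "abdomen", "extremities", "abdomen", "abdomen",
      "extremities", "extremities", "extremities", "extremities",
      "extremities", "extremities", "extremities", "extremities",
      "extremities", "extremities",
      "external", "external", "external"
    )
  )
}

#' @rdname barell_regions
#' @export
barell_natures <- function() {
  tibble::tibble(
    nature_col = 1:13,
    nature_name = c(
      "Fracture (open)", "Fracture (closed)", "Dislocation",
      "Sprains and strains", "Internal organ", "Open wounds", "Amputations",
      "Blood vessels", "Contusion/superficial", "Crush", "Burns", "Nerves",
      "System-wide and other"
    ),
    nature_code = c(
      "fracture", "fracture", "dislocation", "sprains_strains",
      "internal_organ", "open_wound", "amputation", "blood_vessels",
      "contusion_superficial", "crush", "burns", "nerves", "system_wide"
    ),
    open_fracture = c(TRUE, FALSE, rep(NA, 11))
  )
}

#' @rdname barell_regions
#' @export
barell_cells <- function() {
  regions <- barell_regions()
  natures <- barell_natures()
  cells <- tidyr::expand_grid(
    region_row = regions$region_row,
    nature_col = natures$nature_col
  )
  cells <- dplyr::arrange(cells, .data$region_row, .data$nature_col)
  cells$cell_id <- sprintf("r%02dc%02d", cells$region_row, cells$nature_col)
  cells <- dplyr::left_join(cells, regions[c("region_row", "region_name")],
                            by = "region_row")
  cells <- dplyr::left_join(cells,
                            natures[c("nature_col", "nature_name")],
                            by = "nature_col")
  cells[c("cell_id", "region_row", "nature_col", "region_name",
          "nature_name")]
}

# Normalize a free-text region or nature code to the dialect key:
# lower case, punctuation stripped, whitespace collapsed to underscores.
normalize_code <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[,/()]+", " ", x)
  x <- gsub("[^a-z0-9 ]", " ", x)
  x <- gsub("\\s+", "_", trimws(x))
  x
}

# region synonym table: normalized alias -> region_row
region_lookup <- function() {
  regions <- barell_regions()
  base <- stats::setNames(regions$region_row, regions$region_code)
  from_name <- stats::setNames(regions$region_row,
                               normalize_code(regions$region_name))
  extra <- c(
    wrist_hand_and_fingers = 26L, shoulder_and_upper_arm = 24L,
    forearm_and_elbow = 25L, lower_leg_and_ankle = 31L,
    foot_and_toes = 32L, pelvis_and_urogenital = 21L,
    other_and_unspecified_lower_extremity = 33L,
    other_and_unspecified_upper_extremity = 27L,
    head_face_and_neck_unspecified = 8L,
    other_multiple = 34L, system_wide_and_late_effects = 36L
  )
  out <- c(base, from_name, extra)
  out[!duplicated(names(out))]
}

# normalized alias -> nature_code (fracture routing handled separately)
nature_lookup <- function() {
  natures <- barell_natures()
  codes <- unique(natures$nature_code)
  aliases <- c(
    stats::setNames(codes, codes),
    stats::setNames(natures$nature_code, normalize_code(natures$nature_name)),
    open_wounds = "open_wound", open_wound = "open_wound",
    amputations = "amputation", burn = "burns",
    sprains_and_strains = "sprains_strains",
    contusion = "contusion_superficial",
    system_wide_and_other = "system_wide",
    fracture_open = "fracture", fracture_closed = "fracture"
  )
  aliases[!duplicated(names(aliases))]
}

#' Classify injury records into Barell matrix cells
#'
#' Resolves each record's body-region and nature-of-injury codes to a cell of
#' the extended Barell matrix. Fracture records are routed to the open or
#' closed fracture column by `open_fracture_flag`. Classification is a pure
#' function of the codes: the same record always maps to the same cell.
#'
#' @param records A data frame with columns `region_code`, `nature_code`, and
#'   (for fractures) `open_fracture_flag`. Codes may be dialect keys
#'   (`"lower_leg_ankle"`) or human-readable names
#'   (`"lower leg and ankle"`); matching is case- and punctuation-insensitive.
#' @return The input as a tibble with `cell_id`, `region_row`, `nature_col`,
#'   `region_name`, and `nature_name` columns appended.
#' @examples
#' classify_injury(data.frame(
#'   region_code = "lower leg and ankle", nature_code = "fracture",
#'   open_fracture_flag = TRUE
#' ))
#' @export
classify_injury <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("region_code", "nature_code") %in% names(records)))
  if (!"open_fracture_flag" %in% names(records)) {
    records$open_fracture_flag <- NA
  }

  rl <- region_lookup()
  region_row <- unname(rl[normalize_code(records$region_code)])
  if (anyNA(region_row)) {
    bad <- unique(records$region_code[is.na(region_row)])
    stop("unknown body-region code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  nl <- nature_lookup()
  nature_code <- unname(nl[normalize_code(records$nature_code)])
  if (anyNA(nature_code)) {
    bad <- unique(records$nature_code[is.na(nature_code)])
    stop("unknown nature-of-injury code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  is_frac <- nature_code == "fracture"
  # explicit open/closed spellings also set the flag
  norm_nat <- normalize_code(records$nature_code)
  flag <- as.logical(records$open_fracture_flag)
  flag[norm_nat %in% c("fracture_open", "open_fracture")] <- TRUE
  flag[norm_nat %in% c("fracture_closed", "closed_fracture")] <- FALSE
  if (any(is_frac & is.na(flag))) {
    stop("fracture record(s) without an open/closed fracture flag",
         call. = FALSE)
  }

  natures <- barell_natures()
  col_of <- stats::setNames(natures$nature_col, natures$nature_code)
  nature_col <- unname(col_of[nature_code])
  nature_col[is_frac & !flag] <- 2L
  nature_col[is_frac & flag] <- 1L

  out <- records
  out$region_row <- region_row
  out$nature_col <- nature_col
  out$cell_id <- sprintf("r%02dc%02d", region_row, nature_col)
  cells <- barell_cells()
  out <- dplyr::left_join(
    out, cells[c("cell_id", "region_name", "nature_name")], by = "cell_id"
  )
  out
}
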