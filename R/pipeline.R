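#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the input (an injury
#' records CSV plus optional covariates CSV, or a synthetic-cohort
#' generator configuration), the class-count range, EM settings, the
#' labeling threshold, the significance level, and the severity inclusion
#' threshold.
#'
#' @param records_csv Path to an injury records CSV (`casualty_id`,
#'   `region_code`, `nature_code`, `ais`, `open_fracture_flag`). Mutually
#'   exclusive with `generator`.
#' @param covariates_csv Optional path to a covariates CSV
#'   (`casualty_id` + categorical columns).
#' @param generator A [cohort_config()] or the path to a generator YAML
#'   written by [write_generator_config()].
#' @param k_range Class counts to fit (default `1:10`, must lie in 1..50).
#' @param n_starts,tol,max_iter EM settings (see [fit_lca()]).
#' @param threshold Profile labeling threshold in (0,1), default 0.30.
#' @param alpha Significance level in (0,1), default 0.05.
#' @param min_iss Severity inclusion threshold, default 9.
#' @param seed Master seed.
#' @param output_dir Directory for report artifacts.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(records_csv = NULL, covariates_csv = NULL,
                            generator = NULL, k_range = 1:10,
                            n_starts = 20, tol = 1e-8, max_iter = 5000,
                            threshold = 0.30, alpha = 0.05, min_iss = 9,
                            seed = 1L, output_dir = "injuryprofiles-run") {
  if (is.null(records_csv) == is.null(generator)) {
    stop("supply exactly one of records_csv or generator", call. = FALSE)
  }
  stopifnot(all(k_range >= 1), all(k_range <= 50),
            threshold > 0, threshold < 1, alpha > 0, alpha < 1,
            min_iss >= 1)
  if (is.character(generator)) generator <- read_generator_config(generator)
  structure(
    list(records_csv = records_csv, covariates_csv = covariates_csv,
         generator = generator, k_range = k_range, n_starts = n_starts,
         tol = tol, max_iter = max_iter, threshold = threshold,
         alpha = alpha, min_iss = min_iss, seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the injury-profiling pipeline end to end
#'
#' Executes coding, severity filtering, the class-count scan, model
#' selection, profile labeling, and covariate comparisons, writing every
#' report to `config$output_dir`: `fit_statistics.csv` (+ formatted
#' `fit_statistics.txt`), `diagnostics.csv`, `profiles.csv`,
#' `characteristics.csv` (+ `characteristics.txt`), `assignments.csv`,
#' and a `manifest.json` echoing the configuration, the seed, and stage
#' summaries. Runs are deterministic: the same configuration and seed
#' yield identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `scan`, selected `fit`, `profiles`,
#'   `characteristics`, `iss`, and the `manifest`; artifacts on disk as a
#'   side effect. A stage failure writes a `FAILED` marker naming the
#'   stage and rethrows the error.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(config$output_dir, "FAILED"))
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  inputs <- stage("input", {
    if (!is.null(config$records_csv)) {
      if (!file.exists(config$records_csv)) {
        stop("records file not found: ", config$records_csv)
      }
      records <- readr::read_csv(config$records_csv,
                                 show_col_types = FALSE)
      covariates <- if (!is.null(config$covariates_csv)) {
        readr::read_csv(config$covariates_csv, show_col_types = FALSE)
      } else NULL
      list(records = records, covariates = covariates)
    } else {
      coh <- sample_cohort(config$generator, seed = config$seed)
      coh <- sample_injury_records(coh, seed = config$seed)
      list(records = coh$records, covariates = coh$covariates)
    }
  })

  iss <- stage("iss_filter", {
    res <- compute_iss(inputs$records)
    included <- suppressMessages(filter_by_iss(res, config$min_iss))
    list(results = res, included = included,
         n_excluded = attr(included, "n_excluded"))
  })

  indicators <- stage("coding", {
    rec <- dplyr::filter(inputs$records,
                         .data$casualty_id %in% iss$included)
    build_indicator_matrix(rec, populated_only = TRUE,
                           casualty_ids = iss$included)
  })

  scan <- stage("fit_scan", {
    scan_lca(indicators, k_range = config$k_range,
             n_starts = config$n_starts, tol = config$tol,
             max_iter = config$max_iter, seed = config$seed)
  })

  fit <- scan$fits[[as.character(scan$selected_k)]]

  profiles <- stage("labeling", {
    suppressWarnings(label_profiles(fit, threshold = config$threshold))
  })

  characteristics <- stage("comparisons", {
    if (is.null(inputs$covariates)) return(NULL)
    covs <- inputs$covariates[
      match(iss$included, inputs$covariates$casualty_id), , drop = FALSE]
    covs$iss_category <- iss$results$category[
      match(iss$included, iss$results$casualty_id)]
    suppressWarnings(
      profile_characteristics(covs, fit$assignment, alpha = config$alpha)
    )
  })

  stage("reports", {
    out <- config$output_dir
    readr::write_csv(scan$statistics, file.path(out, "fit_statistics.csv"))
    writeLines(format_table_text(format_fit_statistics(scan$statistics)),
               file.path(out, "fit_statistics.txt"))
    readr::write_csv(classification_diagnostics(fit),
                     file.path(out, "diagnostics.csv"))
    readr::write_csv(profiles, file.path(out, "profiles.csv"))
    readr::write_csv(augment(fit), file.path(out, "assignments.csv"))
    if (!is.null(characteristics)) {
      readr::write_csv(characteristics$table,
                       file.path(out, "characteristics.csv"))
      readr::write_csv(characteristics$pairwise,
                       file.path(out, "pairwise_comparisons.csv"))
      writeLines(format_characteristics_text(characteristics$table),
                 file.path(out, "characteristics.txt"))
    }
    invisible(NULL)
  })

  manifest <- list(
    package = "injuryprofiles",
    version = as.character(utils::packageVersion("injuryprofiles")),
    seed = config$seed,
    k_range = config$k_range,
    selected_k = scan$selected_k,
    selection_criterion = scan$criterion,
    threshold = config$threshold,
    alpha = config$alpha,
    min_iss = config$min_iss,
    n_included = length(iss$included),
    n_excluded = iss$n_excluded,
    n_items = ncol(indicators) - 1L,
    input = if (is.null(config$records_csv)) "synthetic" else
      config$records_csv
  )
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(scan = scan, fit = fit, profiles = profiles,
                 characteristics = characteristics, iss = iss,
                 manifest = manifest))
}

# fixed-width text rendering of a small tibble
format_table_text <- function(df) {
  m <- rbind(names(df), as.matrix(dplyr::mutate(df, dplyr::across(
    dplyr::everything(), as.character))))
  m[is.na(m)] <- "-"
  widths <- apply(nchar(m), 2L, max)
  apply(m, 1L, function(r) {
    paste(mapply(function(s, w) sprintf("%-*s", w, s), r, widths),
          collapse = "  ")
  })
}

format_characteristics_text <- function(tab) {
  tab |>
    dplyr::mutate(
      cell = sprintf("%d (%.1f)%s", .data$n, .data$pct,
                     ifelse(is.na(.data$marks), "",
                            paste0(" [", .data$marks, "]"))),
      p = ifelse(is.na(.data$omnibus_p), "-",
                 ifelse(.data$omnibus_p < 0.001, "<0.001",
                        sprintf("%.2f", .data$omnibus_p)))
    ) |>
    dplyr::select("variable", "level", "class", "cell", "p") |>
    tidyr::pivot_wider(names_from = "class", values_from = "cell") |>
    format_table_text()
}

#' Read and write generator configurations as YAML
#'
#' Serializes a [cohort_config()] (including the item template and the
#' covariate model) to a YAML file and back.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a [cohort_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  tmpl <- config$item_probability_template
  lst <- list(
    k = config$k, j = config$j, n = config$n,
    mixing_proportions = config$mixing_proportions,
    background_probability = config$background_probability,
    seed = config$seed,
    items = colnames(tmpl),
    template = lapply(seq_len(nrow(tmpl)), function(r) unname(tmpl[r, ])),
    covariate_model = lapply(config$covariate_model, function(pm) {
      list(levels = rownames(pm),
           probs = lapply(seq_len(nrow(pm)), function(r) unname(pm[r, ])))
    })
  )
  yaml::write_yaml(lst, path, precision = 12L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  lst <- yaml::read_yaml(path)
  tmpl <- do.call(rbind, lst$template)
  colnames(tmpl) <- lst$items
  covm <- lapply(lst$covariate_model, function(cm) {
    pm <- do.call(rbind, cm$probs)
    rownames(pm) <- cm$levels
    pm
  })
  cohort_config(
    k = lst$k, j = lst$j, n = lst$n,
    mixing_proportions = lst$mixing_proportions,
    item_probability_template = tmpl,
    covariate_model = covm,
    background_probability = lst$background_probability,
    seed = lst$seed
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `indicators.csv` (`casualty_id` + one 0/1 column per cell),
#' `covariates.csv`, and, when present, `records.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$indicators, file.path(dir, "indicators.csv"))
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  if (!is.null(cohort$records)) {
    readr::write_csv(cohort$records, file.path(dir, "records.csv"))
  }
  invisible(dir)
}
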