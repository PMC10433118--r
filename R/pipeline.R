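#' Write a sample table to CSV
#'
#' Emits the canonical long-form schema
#' (`site,metal,concentration_mg_per_L,uncertainty_mg_per_L`) understood by
#' [load_samples_csv()] and the command-line pipeline.
#'
#' @param table A `sample_table`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a sample table from CSV
#'
#' Accepts two schemas, auto-detected from the header: the canonical long
#' form (`site,metal,concentration_mg_per_L[,uncertainty_mg_per_L]`) or a
#' wide form (`site` plus one column per metal symbol, optionally
#' `<metal>_uncertainty` columns). Validates the complete-grid and
#' positivity invariants on load; a blank cell is an incomplete-grid error
#' naming the site and metal.
#'
#' @param path CSV file with a header row.
#' @param known_metals Symbols accepted in the metal/metal-column position;
#'   defaults to the ten classified metals of the bundled registry.
#' @return A `sample_table`.
#' @export
load_samples_csv <- function(path, known_metals = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0) stop("input file has no data rows: ", path, call. = FALSE)
  if (is.null(known_metals)) {
    cfg <- bundled_config()
    known_metals <- unique(c(names(cfg$toxicity), cfg$carcinogens,
                             cfg$non_carcinogens))
  }
  long_cols <- c("site", "metal", "concentration_mg_per_L")
  if (all(long_cols %in% names(raw))) {
    df <- raw
    unknown <- setdiff(unique(df$metal), known_metals)
    if (length(unknown)) {
      stop("unknown metal symbol(s): ", paste(unknown, collapse = ", "),
           "; recognized: ", paste(known_metals, collapse = ", "),
           call. = FALSE)
    }
    df$concentration_mg_per_L <-
      parse_numeric_col(df$concentration_mg_per_L, df$site, df$metal,
                        "concentration")
    if (!is.null(df$uncertainty_mg_per_L)) {
      df$uncertainty_mg_per_L <-
        parse_numeric_col(df$uncertainty_mg_per_L, df$site, df$metal,
                          "uncertainty", allow_zero = TRUE)
    }
    return(sample_table(df))
  }
  if (!"site" %in% names(raw)) {
    stop("unrecognized schema: need either long form (site,metal,",
         "concentration_mg_per_L) or wide form (site + one column per ",
         "metal)", call. = FALSE)
  }
  metal_cols <- setdiff(names(raw), c("site", grep("_uncertainty$",
                                                   names(raw), value = TRUE)))
  unknown <- setdiff(metal_cols, known_metals)
  if (length(unknown)) {
    stop("unknown metal column(s): ", paste(unknown, collapse = ", "),
         "; recognized: ", paste(known_metals, collapse = ", "),
         call. = FALSE)
  }
  recs <- do.call(rbind, lapply(metal_cols, function(m) {
    unc_col <- paste0(m, "_uncertainty")
    data.frame(
      site = raw$site, metal = m,
      concentration_mg_per_L =
        parse_numeric_col(raw[[m]], raw$site, m, "concentration"),
      uncertainty_mg_per_L = if (unc_col %in% names(raw)) {
        parse_numeric_col(raw[[unc_col]], raw$site, m, "uncertainty",
                          allow_zero = TRUE)
      } else 0,
      stringsAsFactors = FALSE
    )
  }))
  # restore site-major order to match the long form of the same data
  recs <- recs[order(match(recs$site, unique(raw$site)),
                     match(recs$metal, metal_cols)), ]
  sample_table(recs)
}

parse_numeric_col <- function(x, site, metal, what, allow_zero = FALSE) {
  x <- trimws(x)
  blank <- is.na(x) | x == ""
  if (any(blank)) {
    i <- which(blank)[1L]
    stop("incomplete grid: missing ", what, " for site ", site[i],
         ", metal ", metal[i], call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(x))
  bad <- is.na(val) | (if (allow_zero) val < 0 else val <= 0)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("invalid ", what, " '", x[i], "' at row ", i, " (site ", site[i],
         ", metal ", metal[i], "): must be a ",
         if (allow_zero) "non-negative" else "positive", " number",
         call. = FALSE)
  }
  val
}

#' Build an assessment configuration
#'
#' Bundles everything one pipeline run needs: the input table, the limit
#' authority, the cohorts, an optional reference-registry override and the
#' report precision.
#'
#' @param input Path to a sample CSV, or a `sample_table` directly.
#' @param authority Limit-set label for HEI and exceedance screening
#'   (default `"WHO"`).
#' @param cohorts Cohorts to assess (default adult and child; must be
#'   non-empty).
#' @param reference Optional path to a registry YAML overriding the bundled
#'   one.
#' @param correct_s7_pb Passed to [sosiani_survey()] when `input` is the
#'   literal string `"fixture"`.
#' @param precision Significant figures used in the written report tables
#'   (default 4, matching the published tables).
#' @return A list of class `assessment_config`.
#' @export
assessment_config <- function(input, authority = "WHO",
                              cohorts = c("adult", "child"),
                              reference = NULL, correct_s7_pb = TRUE,
                              precision = 4L) {
  if (length(cohorts) == 0) {
    stop("at least one cohort is required", call. = FALSE)
  }
  if (!is.numeric(precision) || precision < 1) {
    stop("precision must be a positive integer", call. = FALSE)
  }
  structure(list(input = input, authority = authority, cohorts = cohorts,
                 reference = reference, correct_s7_pb = correct_s7_pb,
                 precision = as.integer(precision)),
            class = "assessment_config")
}

#' Run the full assessment pipeline
#'
#' Loads (or takes) the sample table, computes the index table, the per-
#' cohort hazard tables and the cancer-risk table, and screens each metal's
#' mean concentration against every bundled authority's limit. Deterministic
#' given the configuration.
#'
#' @param config An `assessment_config`.
#' @return A list of class `assessment_report` with elements `samples`,
#'   `indices`, `risk` (long), `hazard` (named list of wide per-cohort
#'   tibbles), `ilcr` (wide tibble), `exceedance`, `summary_lines`, and
#'   `config`.
#' @export
#' @examples
#' report <- run_assessment(assessment_config(sosiani_survey(quiet = TRUE)))
#' report$indices
run_assessment <- function(config) {
  if (!inherits(config, "assessment_config")) {
    stop("config must be an assessment_config", call. = FALSE)
  }
  refcfg <- if (is.null(config$reference)) bundled_config() else
    load_reference_config(config$reference)

  table <- stage("load", {
    inp <- config$input
    if (inherits(inp, "sample_table")) inp
    else if (identical(inp, "fixture")) {
      sosiani_survey(correct_s7_pb = config$correct_s7_pb, quiet = TRUE)
    } else load_samples_csv(inp)
  })
  limits <- stage("reference", get_limit_set(config$authority, refcfg))
  indices <- stage("indices", summarize_indices(table, limits))
  risk <- stage("risk", risk_table(table, config$cohorts, refcfg))
  hazard <- lapply(config$cohorts, function(co) hazard_wide(risk, co))
  names(hazard) <- config$cohorts
  ilcr <- ilcr_wide(risk)

  means <- mean_concentrations(table)
  exc <- stage("exceedance", {
    rows <- list()
    for (auth in names(refcfg$limits)) {
      lims <- unlist(refcfg$limits[[auth]])
      for (m in names(means)) {
        if (!m %in% names(lims)) next
        rows[[length(rows) + 1L]] <- data.frame(
          metal = m, authority = auth, mean_mg_per_L = means[[m]],
          limit_mg_per_L = lims[[m]],
          exceeds = means[[m]] > lims[[m]], stringsAsFactors = FALSE)
      }
    }
    tibble::as_tibble(do.call(rbind, rows))
  })

  mean_idx <- indices[indices$site == "Mean", ]
  lines <- c(
    sprintf("mean_mpi: %s", signif(mean_idx$mpi, config$precision)),
    sprintf("mean_mpi_class: %s", mean_idx$mpi_class),
    sprintf("mean_hei: %s", signif(mean_idx$hei, config$precision)),
    sprintf("mean_hei_class: %s", mean_idx$hei_class)
  )
  for (co in config$cohorts) {
    hz <- hazard[[co]]
    mh <- hz[hz$site == "Mean", ]
    lines <- c(lines,
               sprintf("mean_hi_%s: %s", co, signif(mh$hi, config$precision)),
               sprintf("mean_hi_%s_significant: %s", co,
                       tolower(as.character(mh$hi_significant))))
  }
  carc_rows <- risk[!is.na(risk$ilcr) & risk$site == "Mean", ]
  for (i in seq_len(nrow(carc_rows))) {
    r <- carc_rows[i, ]
    cases <- excess_cases_per_million(r$ilcr)
    key <- paste0(r$cohort, "_", r$metal)
    lines <- c(lines,
               sprintf("mean_ilcr_%s: %s", key,
                       signif(r$ilcr, config$precision)),
               sprintf("mean_ilcr_%s_class: %s", key, r$ilcr_class),
               sprintf("excess_cases_per_million_%s: %s", key,
                       signif(cases$cases, config$precision)),
               sprintf("excess_cases_per_million_%s_ceiling: %d", key,
                       as.integer(cases$cases_ceiling)))
  }
  for (i in seq_len(nrow(exc))) {
    lines <- c(lines, sprintf(
      "limit_%s_%s: mean %s vs MAC %s -> %s",
      exc$metal[i], exc$authority[i],
      signif(exc$mean_mg_per_L[i], config$precision),
      exc$limit_mg_per_L[i],
      if (exc$exceeds[i]) "exceeds" else "ok"))
  }

  structure(list(samples = table, indices = indices, risk = risk,
                 hazard = hazard, ilcr = ilcr, exceedance = exc,
                 summary_lines = lines, config = config),
            class = "assessment_report")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Write an assessment report to disk
#'
#' Writes the index table, one hazard CSV per cohort, the cancer-risk CSV
#' and a key-value `summary.txt` (which also carries the exceedance
#' screening and classification lines). Numeric cells are rounded to the
#' configured number of significant figures; re-running into the same
#' directory is idempotent.
#'
#' @param report An `assessment_report`.
#' @param directory Output directory (created if absent).
#' @param quiet Suppress the per-file log messages.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, directory, quiet = FALSE) {
  if (!inherits(report, "assessment_report")) {
    stop("report must be an assessment_report", call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory) || file.access(directory, 2) != 0) {
    stop("output directory is not writable: ", directory, call. = FALSE)
  }
  p <- report$config$precision
  written <- character()
  emit <- function(df, name) {
    path <- file.path(directory, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = p)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE,
                     quote = FALSE)
    if (!quiet) message("wrote ", path)
    written <<- c(written, path)
  }
  emit(report$indices, "indices.csv")
  for (co in names(report$hazard)) {
    emit(report$hazard[[co]], paste0("hazard_", co, ".csv"))
  }
  emit(report$ilcr, "ilcr.csv")
  summary_path <- file.path(directory, "summary.txt")
  writeLines(report$summary_lines, summary_path)
  if (!quiet) message("wrote ", summary_path)
  invisible(c(written, summary_path))
}
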