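#' Chronic daily intake (CDI) via drinking-water ingestion
#'
#' `CDI = Ci * IR * EF * ED / (BW * AT)`, in mg per kg body weight per day.
#' The averaging time AT is selected by endpoint from the profile's two
#' stored values: the cancer AT spans the exposure duration in days, while
#' the non-cancer AT is an independent, shorter averaging period (30 y for
#' the bundled adult, 6 y for the bundled child). Keeping both stored rather
#' than deriving AT from ED is deliberate: it is what reproduces published
#' non-cancer doses computed under that convention.
#'
#' @param concentration Metal concentration in water, mg/L (>= 0).
#' @param profile An `exposure_profile`.
#' @param endpoint `"noncarcinogenic"` (default) or `"carcinogenic"`.
#' @return CDI, mg/kg bw/day. Vectorised over `concentration`.
#' @export
#' @examples
#' compute_cdi(0.105714, get_exposure_profile("adult"))
compute_cdi <- function(concentration, profile,
                        endpoint = c("noncarcinogenic", "carcinogenic")) {
  endpoint <- match.arg(endpoint)
  if (!inherits(profile, "exposure_profile")) {
    stop("profile must be an exposure_profile", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  at <- switch(endpoint,
               noncarcinogenic = profile$averaging_time_noncarcinogenic,
               carcinogenic = profile$averaging_time_carcinogenic)
  concentration * profile$ingestion_rate * profile$exposure_frequency *
    profile$exposure_duration / (profile$body_weight * at)
}

#' Hazard quotient (HQ)
#'
#' `HQ = CDI / RfD`. Values at or above 1 flag a potential non-cancer
#' concern.
#'
#' @param cdi Chronic daily intake, mg/kg bw/day (>= 0).
#' @param reference A `toxicity_reference` carrying an oral reference dose.
#' @return Dimensionless quotient. Vectorised over `cdi`.
#' @export
compute_hq <- function(cdi, reference) {
  if (!inherits(reference, "toxicity_reference")) {
    stop("reference must be a toxicity_reference", call. = FALSE)
  }
  if (is.null(reference$rfd)) {
    stop("no oral reference dose for metal ", reference$metal, call. = FALSE)
  }
  if (any(!is.finite(cdi)) || any(cdi < 0)) {
    stop("cdi must be non-negative", call. = FALSE)
  }
  cdi / reference$rfd
}

#' Hazard index (HI)
#'
#' Sum of the hazard quotients of co-occurring metals. An HI at or above 1
#' implies significant non-cancer risk.
#'
#' @param hq_values Numeric vector of hazard quotients (>= 0, non-empty).
#' @return Numeric of length 1 with attribute `significant` (`TRUE` when
#'   HI >= 1).
#' @export
compute_hi <- function(hq_values) {
  if (length(hq_values) == 0) {
    stop("hazard index requires at least one hazard quotient", call. = FALSE)
  }
  if (any(!is.finite(hq_values)) || any(hq_values < 0)) {
    stop("hazard quotients must be non-negative", call. = FALSE)
  }
  hi <- sum(hq_values)
  structure(hi, significant = hi >= 1)
}

#' Incremental lifetime cancer risk (ILCR)
#'
#' `ILCR = CDI * CSF`, clamped to the probability domain [0, 1]. Defined only
#' for metals flagged carcinogenic: requesting it for a non-carcinogen is an
#' error rather than zero, because "no slope factor" is not evidence of no
#' risk.
#'
#' @param cdi_carc CDI computed under the carcinogenic averaging time,
#'   mg/kg bw/day.
#' @param reference A `toxicity_reference` for a carcinogen.
#' @return Dimensionless lifetime probability. Vectorised over `cdi_carc`.
#' @export
compute_ilcr <- function(cdi_carc, reference) {
  if (!inherits(reference, "toxicity_reference")) {
    stop("reference must be a toxicity_reference", call. = FALSE)
  }
  if (!isTRUE(reference$carcinogenic) || is.null(reference$csf)) {
    stop("ILCR undefined for non-carcinogen ", reference$metal, call. = FALSE)
  }
  if (any(!is.finite(cdi_carc)) || any(cdi_carc < 0)) {
    stop("cdi must be non-negative", call. = FALSE)
  }
  pmin(cdi_carc * reference$csf, 1)
}

#' Classify a cancer-risk value
#'
#' Below 1e-6 the excess risk is negligible; between 1e-6 and 1e-4
#' (inclusive) it is low; above 1e-4 it is likely a high health risk.
#'
#' @param ilcr Lifetime risk in [0, 1].
#' @return `"negligible"`, `"low"` or `"high"`.
#' @export
classify_ilcr <- function(ilcr) {
  if (!is.finite(ilcr) || ilcr < 0 || ilcr > 1) {
    stop("ilcr must lie in [0, 1]", call. = FALSE)
  }
  if (ilcr < 1e-6) "negligible" else if (ilcr <= 1e-4) "low" else "high"
}

#' Excess cancer cases per million people
#'
#' Scales a lifetime risk to a population of one million. Both the exact
#' real value and its ceiling are returned: the ceiling is the conservative
#' integer convention (never understating the expected case count), and
#' reporting the exact value alongside avoids committing to any single
#' rounding rule.
#'
#' @param ilcr Lifetime risk in [0, 1].
#' @return List with `cases` (ilcr x 1e6) and `cases_ceiling`.
#' @export
excess_cases_per_million <- function(ilcr) {
  if (!is.finite(ilcr) || ilcr < 0 || ilcr > 1) {
    stop("ilcr must lie in [0, 1]", call. = FALSE)
  }
  cases <- ilcr * 1e6
  list(cases = cases, cases_ceiling = ceiling(cases))
}

#' Full site-by-cohort risk table
#'
#' Runs the ingestion chain (CDI, HQ, HI; and CDI/ILCR under the cancer
#' averaging time for carcinogens) for every site and cohort, and appends a
#' `Mean` row per cohort evaluated at the per-metal mean concentrations.
#' Because every quantity in the chain is linear in concentration, the Mean
#' row equals the mean of the per-site values on a complete grid.
#'
#' @param table A `sample_table`.
#' @param cohorts Character vector of cohort labels (default adult and
#'   child); must be non-empty.
#' @param config A `reference_config`; `NULL` uses the bundled registry.
#' @return Long tibble with one row per (site, cohort, metal): columns
#'   `site`, `cohort`, `metal`, `cdi_noncarc`, `hq`, `hi` (repeated within a
#'   site-cohort group), `hi_significant`, `cdi_carc`, `ilcr`, `ilcr_class`
#'   (NA for non-carcinogens).
#' @export
#' @examples
#' risk_table(sosiani_survey(quiet = TRUE))
risk_table <- function(table, cohorts = c("adult", "child"), config = NULL) {
  if (length(cohorts) == 0) {
    stop("at least one cohort is required", call. = FALSE)
  }
  config <- resolve_config(config)
  metals <- table_metals(table)
  refs <- lapply(metals, get_toxicity_reference, config = config)
  names(refs) <- metals
  site_conc <- c(
    lapply(table_sites(table),
           function(s) site_concentrations(table, s)[metals]),
    list(mean_concentrations(table))
  )
  names(site_conc) <- c(table_sites(table), "Mean")

  out <- list()
  for (cohort in cohorts) {
    profile <- get_exposure_profile(cohort, config)
    for (s in names(site_conc)) {
      conc <- site_conc[[s]]
      cdi_nc <- compute_cdi(conc, profile, "noncarcinogenic")
      hq <- vapply(metals, function(m) compute_hq(cdi_nc[[m]], refs[[m]]),
                   numeric(1))
      hi <- compute_hi(hq)
      hi_sig <- isTRUE(attr(hi, "significant"))
      cdi_c <- compute_cdi(conc, profile, "carcinogenic")
      ilcr <- vapply(metals, function(m) {
        if (refs[[m]]$carcinogenic) compute_ilcr(cdi_c[[m]], refs[[m]])
        else NA_real_
      }, numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        site = s, cohort = cohort, metal = metals,
        concentration_mg_per_L = unname(conc),
        cdi_noncarc = unname(cdi_nc),
        hq = unname(hq),
        hi = as.numeric(hi),
        hi_significant = hi_sig,
        cdi_carc = ifelse(is.na(ilcr), NA_real_, unname(cdi_c)),
        ilcr = unname(ilcr),
        ilcr_class = ifelse(is.na(ilcr), NA_character_,
                            vapply(ifelse(is.na(ilcr), 0, ilcr),
                                   classify_ilcr, character(1)))
      )
    }
  }
  do.call(rbind, out)
}

#' Wide hazard table for one cohort
#'
#' Pivots [risk_table()] output into the report layout: one row per site
#' with per-metal HQ columns and the HI.
#'
#' @param risk Output of [risk_table()].
#' @param cohort Cohort label present in `risk`.
#' @return Tibble with columns `site`, `hq_<metal>`..., `hi`,
#'   `hi_significant`.
#' @export
hazard_wide <- function(risk, cohort) {
  rows <- risk[risk$cohort == cohort, ]
  if (nrow(rows) == 0) stop("no rows for cohort '", cohort, "'", call. = FALSE)
  metals <- unique(rows$metal)
  sites <- unique(rows$site)
  out <- lapply(sites, function(s) {
    sub <- rows[rows$site == s, ]
    vals <- stats::setNames(as.list(sub$hq[match(metals, sub$metal)]),
                            paste0("hq_", metals))
    c(list(site = s), vals,
      list(hi = sub$hi[1L], hi_significant = sub$hi_significant[1L]))
  })
  tibble::as_tibble(do.call(rbind, lapply(out, as.data.frame)))
}

#' Wide cancer-risk table
#'
#' One row per site with the ILCR of every carcinogenic metal for every
#' requested cohort.
#'
#' @param risk Output of [risk_table()].
#' @return Tibble with columns `site`, then `ilcr_<cohort>_<metal>` for each
#'   cohort and carcinogen.
#' @export
ilcr_wide <- function(risk) {
  rows <- risk[!is.na(risk$ilcr), ]
  if (nrow(rows) == 0) {
    return(tibble::tibble(site = unique(risk$site)))
  }
  sites <- unique(risk$site)
  combos <- unique(rows[, c("cohort", "metal")])
  out <- lapply(sites, function(s) {
    vals <- lapply(seq_len(nrow(combos)), function(i) {
      v <- rows$ilcr[rows$site == s & rows$cohort == combos$cohort[i] &
                       rows$metal == combos$metal[i]]
      if (length(v)) v[1L] else NA_real_
    })
    names(vals) <- paste0("ilcr_", combos$cohort, "_", combos$metal)
    c(list(site = s), vals)
  })
  tibble::as_tibble(do.call(rbind, lapply(out, as.data.frame)))
}
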