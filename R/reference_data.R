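#' Path of the bundled reference registry
#'
#' The registry is a YAML file with sections `toxicity` (oral reference doses
#' and cancer slope factors), `carcinogens` / `non_carcinogens` (the
#' IARC-style classification gating cancer-risk computation), `limits`
#' (drinking-water maximum allowable concentrations per authority) and
#' `exposure_profiles` (ingestion parameters per cohort).
#'
#' @return Path to the YAML file shipped with the package.
#' @export
default_reference_path <- function() {
  system.file("extdata", "reference_data.yaml", package = "aquarisk",
              mustWork = TRUE)
}

#' Load a reference registry
#'
#' Reads and validates a registry file. Every numeric entry must be strictly
#' positive; a cancer slope factor must be present if and only if the metal is
#' flagged carcinogenic; every exposure profile must carry both averaging
#' times explicitly (they are never derived from the exposure duration,
#' because non-cancer and cancer assessments average over different periods).
#'
#' @param path Registry file; `NULL` uses the bundled one.
#' @return A validated list of class `reference_config`.
#' @export
load_reference_config <- function(path = NULL) {
  if (is.null(path)) path <- default_reference_path()
  if (!file.exists(path)) {
    stop("reference config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  validate_reference_config(cfg)
}

#' Write a reference registry to a YAML file
#'
#' Round-trips with [load_reference_config()]: reloading the written file
#' reproduces the registry exactly.
#'
#' @param config A `reference_config` list.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_reference_config <- function(config, path) {
  config <- validate_reference_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

validate_reference_config <- function(cfg) {
  for (section in c("toxicity", "limits", "exposure_profiles")) {
    if (is.null(cfg[[section]])) {
      stop("reference config is missing its '", section, "' section",
           call. = FALSE)
    }
  }
  carc <- as.character(cfg$carcinogens %||% character())
  for (metal in names(cfg$toxicity)) {
    entry <- cfg$toxicity[[metal]]
    flag <- isTRUE(entry$carcinogenic) || metal %in% carc
    tox <- toxicity_reference(metal = metal, rfd = entry$rfd,
                              csf = entry$csf, carcinogenic = flag)
    cfg$toxicity[[metal]]$carcinogenic <- tox$carcinogenic
  }
  for (auth in names(cfg$limits)) {
    lims <- unlist(cfg$limits[[auth]])
    if (length(lims) == 0 || any(!is.finite(lims)) || any(lims <= 0)) {
      stop("limit set '", auth, "' must contain strictly positive MACs",
           call. = FALSE)
    }
  }
  for (cohort in names(cfg$exposure_profiles)) {
    p <- cfg$exposure_profiles[[cohort]]
    do.call(exposure_profile, c(list(cohort = cohort), p))
  }
  structure(cfg, class = "reference_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a toxicity reference record
#'
#' @param metal Element symbol (e.g. `"Pb"`).
#' @param rfd Oral reference dose, mg per kg body weight per day; must be
#'   strictly positive when supplied.
#' @param csf Cancer slope factor, risk per (mg/kg bw/day); required for
#'   carcinogens, forbidden for non-carcinogens.
#' @param carcinogenic Logical carcinogenicity flag.
#' @return A list of class `toxicity_reference`.
#' @export
toxicity_reference <- function(metal, rfd = NULL, csf = NULL,
                               carcinogenic = FALSE) {
  stopifnot(is.character(metal), length(metal) == 1L, nzchar(metal))
  carcinogenic <- isTRUE(carcinogenic)
  if (!is.null(rfd) && (!is.finite(rfd) || rfd <= 0)) {
    stop("rfd for ", metal, " must be strictly positive", call. = FALSE)
  }
  if (carcinogenic && is.null(csf)) {
    stop("carcinogenic metal ", metal, " must carry a cancer slope factor",
         call. = FALSE)
  }
  if (!carcinogenic && !is.null(csf)) {
    stop("non-carcinogenic metal ", metal,
         " must not carry a cancer slope factor", call. = FALSE)
  }
  if (!is.null(csf) && (!is.finite(csf) || csf <= 0)) {
    stop("csf for ", metal, " must be strictly positive", call. = FALSE)
  }
  structure(list(metal = metal, rfd = rfd, csf = csf,
                 carcinogenic = carcinogenic),
            class = "toxicity_reference")
}

#' Look up the toxicity reference for a metal
#'
#' Bundled values: RfD (mg/kg/day) Zn 0.3, Cu 0.04, Pb 0.0035; CSF Pb 0.0085.
#' The bundled carcinogen classification flags Cd, Cr, Pb and As as
#' carcinogenic and Cu, Zn, Fe, Ni, Mn and Co as non-carcinogenic.
#'
#' @param metal Element symbol.
#' @param config A `reference_config`; `NULL` uses the bundled registry.
#' @return A `toxicity_reference`.
#' @export
#' @examples
#' get_toxicity_reference("Pb")$csf
get_toxicity_reference <- function(metal, config = NULL) {
  config <- resolve_config(config)
  entry <- config$toxicity[[metal]]
  if (is.null(entry)) {
    stop("no toxicity reference for metal '", metal, "'", call. = FALSE)
  }
  toxicity_reference(metal = metal, rfd = entry$rfd, csf = entry$csf,
                     carcinogenic = isTRUE(entry$carcinogenic))
}

#' Is a metal classified as carcinogenic?
#'
#' Uses the registry's toxicity entry when present, otherwise the bundled
#' IARC-style classification lists.
#'
#' @inheritParams get_toxicity_reference
#' @return `TRUE`, `FALSE`, or an error for an unclassified metal.
#' @export
is_carcinogenic <- function(metal, config = NULL) {
  config <- resolve_config(config)
  entry <- config$toxicity[[metal]]
  if (!is.null(entry)) return(isTRUE(entry$carcinogenic))
  if (metal %in% config$carcinogens) return(TRUE)
  if (metal %in% config$non_carcinogens) return(FALSE)
  stop("metal '", metal, "' has no carcinogenicity classification",
       call. = FALSE)
}

#' Look up an authority's drinking-water limit set
#'
#' Bundled MACs (mg/L): WHO Cu 2.0 / Zn 5.0 / Pb 0.01; FEPA and FAO
#' Cu 1 / Zn 3 / Pb 0.01; USEPA Cu 1.3 / Zn 5 / Pb 0.015.
#'
#' @param authority Label, e.g. `"WHO"`.
#' @param config A `reference_config`; `NULL` uses the bundled registry.
#' @return A list of class `standard_limit_set` with fields `authority` and
#'   `limits` (named numeric vector of MACs, mg/L).
#' @export
get_limit_set <- function(authority, config = NULL) {
  config <- resolve_config(config)
  lims <- config$limits[[authority]]
  if (is.null(lims)) {
    stop("unknown authority '", authority, "'; available: ",
         paste(names(config$limits), collapse = ", "), call. = FALSE)
  }
  structure(list(authority = authority, limits = unlist(lims)),
            class = "standard_limit_set")
}

#' Construct an exposure profile
#'
#' All parameters must be strictly positive. Both averaging times are stored
#' as independent fields: the non-cancer averaging time is not the exposure
#' duration in days (the bundled adult profile averages non-cancer intake
#' over 30 years while its exposure duration is 70 years).
#'
#' @param cohort Label (`"adult"`, `"child"`, or a custom name).
#' @param ingestion_rate Water ingested, L/day (IR).
#' @param exposure_frequency Days of exposure per year (EF).
#' @param exposure_duration Years of exposure (ED).
#' @param body_weight Body weight, kg (BW).
#' @param averaging_time_noncarcinogenic Averaging time for non-cancer
#'   endpoints, days.
#' @param averaging_time_carcinogenic Averaging time for cancer endpoints,
#'   days.
#' @return A list of class `exposure_profile`.
#' @export
exposure_profile <- function(cohort, ingestion_rate, exposure_frequency,
                             exposure_duration, body_weight,
                             averaging_time_noncarcinogenic,
                             averaging_time_carcinogenic) {
  vals <- c(ingestion_rate = ingestion_rate,
            exposure_frequency = exposure_frequency,
            exposure_duration = exposure_duration,
            body_weight = body_weight,
            averaging_time_noncarcinogenic = averaging_time_noncarcinogenic,
            averaging_time_carcinogenic = averaging_time_carcinogenic)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    stop("exposure profile '", cohort, "' has non-positive field(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  structure(c(list(cohort = cohort), as.list(vals)),
            class = "exposure_profile")
}

#' Look up a cohort's exposure profile
#'
#' Bundled cohorts: adult (IR 1.5 L/day, EF 350 d/y, ED 70 y, BW 70 kg,
#' AT 30x365 d non-cancer / 70x365 d cancer) and child (IR 0.7, EF 350,
#' ED 15 y, BW 15 kg, AT 6x365 / 15x365 d).
#'
#' @param cohort Cohort label.
#' @param config A `reference_config`; `NULL` uses the bundled registry.
#' @return An `exposure_profile`.
#' @export
get_exposure_profile <- function(cohort, config = NULL) {
  config <- resolve_config(config)
  p <- config$exposure_profiles[[cohort]]
  if (is.null(p)) {
    stop("unknown cohort '", cohort, "'; available: ",
         paste(names(config$exposure_profiles), collapse = ", "),
         call. = FALSE)
  }
  do.call(exposure_profile, c(list(cohort = cohort), p))
}

resolve_config <- function(config) {
  if (is.null(config)) return(bundled_config())
  if (!inherits(config, "reference_config")) {
    config <- validate_reference_config(config)
  }
  config
}

the <- new.env(parent = emptyenv())

bundled_config <- function() {
  if (is.null(the$bundled)) the$bundled <- load_reference_config()
  the$bundled
}
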