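#' Construct a site-by-metal sample table
#'
#' The canonical container for measured concentrations: a long-form tibble
#' with one row per (site, metal) cell. The grid must be complete (every site
#' measured for every metal), concentrations strictly positive and reported
#' uncertainties non-negative. Uncertainties are carried through I/O as
#' descriptive annotations; they never enter the indices or the risk chain,
#' which are point-estimate computations.
#'
#' @param records Data frame with columns `site`, `metal`,
#'   `concentration_mg_per_L` and optionally `uncertainty_mg_per_L`
#'   (defaults to 0).
#' @return A tibble of class `sample_table` with attributes `sites` and
#'   `metals` (first-appearance order).
#' @export
sample_table <- function(records) {
  records <- as.data.frame(records)
  needed <- c("site", "metal", "concentration_mg_per_L")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(records$uncertainty_mg_per_L)) {
    records$uncertainty_mg_per_L <- 0
  }
  records <- records[, c(needed, "uncertainty_mg_per_L")]
  records$site <- as.character(records$site)
  records$metal <- as.character(records$metal)
  conc <- records$concentration_mg_per_L
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    bad <- which(!is.finite(conc) | conc <= 0)[1L]
    stop("concentration must be strictly positive (row ", bad, ": site ",
         records$site[bad], ", metal ", records$metal[bad], ")",
         call. = FALSE)
  }
  unc <- records$uncertainty_mg_per_L
  if (any(!is.finite(unc)) || any(unc < 0)) {
    stop("uncertainty must be non-negative", call. = FALSE)
  }
  key <- paste(records$site, records$metal)
  if (anyDuplicated(key)) {
    stop("duplicate (site, metal) cell: ", key[duplicated(key)][1L],
         call. = FALSE)
  }
  sites <- unique(records$site)
  metals <- unique(records$metal)
  expected <- as.vector(outer(sites, metals, paste))
  absent <- setdiff(expected, key)
  if (length(absent)) {
    stop("incomplete grid: missing cell for (site, metal) = ",
         absent[1L], call. = FALSE)
  }
  # canonical ordering: sites major, metals minor
  records <- records[order(match(records$site, sites),
                           match(records$metal, metals)), , drop = FALSE]
  rownames(records) <- NULL
  structure(tibble::as_tibble(records), sites = sites, metals = metals,
            class = c("sample_table", class(tibble::tibble())))
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", length(attr(x, "sites")), " sites x ",
      length(attr(x, "metals")), " metals\n", sep = "")
  NextMethod()
}

#' Sites and metals of a sample table
#' @param table A `sample_table`.
#' @return Character vector in table order.
#' @export
table_sites <- function(table) attr(table, "sites")

#' @rdname table_sites
#' @export
table_metals <- function(table) attr(table, "metals")

#' Concentrations of one site as a named vector
#' @param table A `sample_table`.
#' @param site Site identifier.
#' @return Named numeric vector (metal -> mg/L).
#' @export
site_concentrations <- function(table, site) {
  rows <- table[table$site == site, ]
  if (nrow(rows) == 0) stop("unknown site '", site, "'", call. = FALSE)
  stats::setNames(rows$concentration_mg_per_L, rows$metal)
}

#' Per-metal mean concentrations
#' @param table A `sample_table`.
#' @return Named numeric vector (metal -> mean mg/L), in table metal order.
#' @export
mean_concentrations <- function(table) {
  metals <- table_metals(table)
  means <- tapply(table$concentration_mg_per_L, table$metal, mean)
  stats::setNames(as.numeric(means[metals]), metals)
}

# Printed cells of the seven-station Sosiani River survey (Zn, Cu, Pb; mg/L,
# value +/- reported uncertainty). S7's Pb cell is transcribed 0.12 in the
# published table, but every downstream published figure for S7 (MPI 0.1978,
# HEI 11.17, adult HQ_Pb 1.507, adult ILCR 1.921e-5) and the published mean
# Pb (0.105714 = 0.74/7) requires 0.11.
sosiani_cells <- function() {
  data.frame(
    site = rep(paste0("S", 1:7), each = 3L),
    metal = rep(c("Zn", "Cu", "Pb"), times = 7L),
    concentration_mg_per_L = c(
      0.43, 0.32, 0.10,
      0.48, 0.28, 0.23,
      0.46, 0.35, 0.08,
      0.42, 0.30, 0.06,
      0.35, 0.27, 0.07,
      0.39, 0.30, 0.09,
      0.32, 0.22, 0.12),
    uncertainty_mg_per_L = c(
      0.06, 0.04, 0.01,
      0.03, 0.03, 0.02,
      0.02, 0.03, 0.02,
      0.02, 0.01, 0.01,
      0.02, 0.02, 0.01,
      0.02, 0.05, 0.03,
      0.02, 0.02, 0.01),
    stringsAsFactors = FALSE
  )
}

#' The bundled Sosiani River survey
#'
#' Seven stations along the Sosiani River (Eldoret, Kenya) measured for Zn,
#' Cu and Pb in mg/L, with the reported plus/minus uncertainty per cell.
#'
#' The survey's published S7 Pb cell (0.12 mg/L) is internally inconsistent:
#' five independent published results for that station (its MPI, HEI, adult
#' hazard quotient for Pb, adult cancer risk, and the column mean) all imply
#' 0.11 mg/L. With the default `correct_s7_pb = TRUE` the reconciled value
#' is returned and a message notes the correction; `FALSE` returns the
#' literal transcribed cells.
#'
#' @param correct_s7_pb Use the reconciled S7 Pb value (default `TRUE`).
#' @param quiet Suppress the correction message.
#' @return A `sample_table` with 21 records.
#' @export
#' @examples
#' s <- sosiani_survey(quiet = TRUE)
#' mean_concentrations(s)
sosiani_survey <- function(correct_s7_pb = TRUE, quiet = FALSE) {
  cells <- sosiani_cells()
  if (isTRUE(correct_s7_pb)) {
    i <- cells$site == "S7" & cells$metal == "Pb"
    cells$concentration_mg_per_L[i] <- 0.11
    if (!quiet) {
      message("sosiani_survey: using reconciled S7 Pb = 0.11 mg/L ",
              "(transcribed 0.12 contradicts the station's published ",
              "indices and risks); pass correct_s7_pb = FALSE for the ",
              "literal cells")
    }
  }
  sample_table(cells)
}

#' Generate a synthetic site-by-metal table
#'
#' Draws each (site, metal) concentration independently from a lognormal
#' distribution parameterised so that the arithmetic mean equals
#' `metal_means[m]` and the coefficient of variation equals `cv[m]`
#' (`sigma^2 = log(1 + cv^2)`, `mu = log(mean) - sigma^2 / 2`). Lognormal
#' sampling guarantees the strict positivity the downstream analysis assumes.
#' `cv = 0` degenerates to every site sitting exactly at the metal mean.
#' Reported uncertainties are set to a fixed fraction of each draw.
#'
#' @param n_sites Number of sites (>= 1).
#' @param metal_means Named numeric vector, metal -> arithmetic mean (mg/L),
#'   all strictly positive.
#' @param cv Coefficient(s) of variation, either one value recycled over
#'   metals or a named vector matching `metal_means`; all >= 0.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param uncertainty_fraction Reported uncertainty as a fraction of each
#'   drawn concentration (default 0.1).
#' @return A `sample_table` with `n_sites * length(metal_means)` records.
#' @export
#' @examples
#' generate_samples(3, c(Zn = 0.4, Pb = 0.1), cv = 0.3, seed = 1)
generate_samples <- function(n_sites, metal_means, cv, seed,
                             uncertainty_fraction = 0.1) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1) {
    stop("n_sites must be a positive integer", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  if (length(metal_means) == 0 || is.null(names(metal_means)) ||
      any(!nzchar(names(metal_means)))) {
    stop("metal_means must be a named vector of per-metal means",
         call. = FALSE)
  }
  if (any(!is.finite(metal_means)) || any(metal_means <= 0)) {
    stop("metal means must be strictly positive", call. = FALSE)
  }
  metals <- names(metal_means)
  if (length(cv) == 1L && is.null(names(cv))) {
    cv <- stats::setNames(rep(cv, length(metals)), metals)
  }
  if (!all(metals %in% names(cv))) {
    stop("cv must be a single value or named per metal", call. = FALSE)
  }
  cv <- cv[metals]
  if (any(!is.finite(cv)) || any(cv < 0)) {
    stop("cv must be non-negative", call. = FALSE)
  }
  if (uncertainty_fraction < 0) {
    stop("uncertainty_fraction must be non-negative", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  draws <- lapply(metals, function(m) {
    if (cv[[m]] == 0) return(rep(metal_means[[m]], n_sites))
    sigma2 <- log(1 + cv[[m]]^2)
    mu <- log(metal_means[[m]]) - sigma2 / 2
    stats::rlnorm(n_sites, meanlog = mu, sdlog = sqrt(sigma2))
  })
  conc <- as.vector(t(matrix(unlist(draws), nrow = n_sites)))
  records <- data.frame(
    site = rep(paste0("S", seq_len(n_sites)), each = length(metals)),
    metal = rep(metals, times = n_sites),
    concentration_mg_per_L = conc,
    uncertainty_mg_per_L = uncertainty_fraction * conc,
    stringsAsFactors = FALSE
  )
  sample_table(records)
}
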