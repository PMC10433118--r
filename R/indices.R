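#' Metal pollution index (MPI)
#'
#' Geometric mean of the supplied concentrations: the n-th root of the
#' product of the n metal concentrations (for Zn, Cu, Pb this is
#' `(C_Zn * C_Cu * C_Pb)^(1/3)`). Computed in the log domain for numerical
#' stability. The geometric mean is undefined at zero, so non-positive
#' concentrations are a domain error rather than silently collapsing the
#' index to zero.
#'
#' @param concentrations Named numeric vector, metal -> mg/L.
#' @return Dimensionless index (same scale as the concentrations).
#' @export
#' @examples
#' compute_mpi(c(Zn = 0.43, Cu = 0.32, Pb = 0.1))
compute_mpi <- function(concentrations) {
  if (length(concentrations) == 0) {
    stop("at least one concentration is required", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("MPI requires strictly positive concentrations", call. = FALSE)
  }
  exp(mean(log(concentrations)))
}

#' Heavy-metal evaluation index (HEI)
#'
#' Sum over metals of concentration divided by the authority's maximum
#' allowable concentration: `HEI = sum_i C_i / MAC_i`. Every supplied metal
#' must have a limit; a missing limit is an error, never a silent skip.
#'
#' @param concentrations Named numeric vector, metal -> mg/L.
#' @param limits A `standard_limit_set` (see [get_limit_set()]) or a named
#'   numeric vector of MACs; defaults to the bundled WHO set.
#' @return Dimensionless index.
#' @export
#' @examples
#' compute_hei(c(Zn = 0.43, Cu = 0.32, Pb = 0.1))
compute_hei <- function(concentrations, limits = get_limit_set("WHO")) {
  if (length(concentrations) == 0) {
    stop("at least one concentration is required", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("HEI requires non-negative concentrations", call. = FALSE)
  }
  mac <- if (inherits(limits, "standard_limit_set")) limits$limits else limits
  absent <- setdiff(names(concentrations), names(mac))
  if (length(absent)) {
    stop("no maximum allowable concentration for metal(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  mac <- mac[names(concentrations)]
  if (any(!is.finite(mac)) || any(mac <= 0)) {
    stop("limits must be strictly positive", call. = FALSE)
  }
  sum(concentrations / mac)
}

#' Default MPI classification bands
#'
#' The published scheme states one band explicitly: 0.3 to 1 is "pure
#' water". Below that the water is cleaner than the pure-water band; above 1
#' it is polluted. Bands are closed on the left and open on the right.
#'
#' @return Data frame with columns `lower`, `upper`, `label`.
#' @export
mpi_bands <- function() {
  data.frame(lower = c(0, 0.3, 1), upper = c(0.3, 1, Inf),
             label = c("below pure-water band", "pure water", "polluted"),
             stringsAsFactors = FALSE)
}

#' Default HEI classification bands
#'
#' Only the top rule of the scheme is encoded: an HEI above 10 marks very
#' highly polluted water.
#'
#' @return Data frame with columns `lower`, `upper`, `label`.
#' @export
hei_bands <- function() {
  data.frame(lower = c(0, 10), upper = c(10, Inf),
             label = c("not very highly polluted", "very highly polluted"),
             stringsAsFactors = FALSE)
}

band_lookup <- function(x, bands, closed_left = TRUE) {
  if (!is.finite(x) || x < 0) {
    stop("index value must be a non-negative number", call. = FALSE)
  }
  for (i in seq_len(nrow(bands))) {
    inside <- if (closed_left) {
      x >= bands$lower[i] && x < bands$upper[i]
    } else {
      x > bands$lower[i] && x <= bands$upper[i]
    }
    if (inside || (!closed_left && i == 1L && x == bands$lower[1L])) {
      return(bands$label[i])
    }
  }
  bands$label[nrow(bands)]
}

#' Classify an MPI value
#'
#' @param mpi Non-negative index value.
#' @param bands Band table (`lower`, `upper`, `label`); intervals are closed
#'   on the left, open on the right. Defaults to [mpi_bands()].
#' @return Band label.
#' @export
classify_mpi <- function(mpi, bands = mpi_bands()) {
  band_lookup(mpi, bands, closed_left = TRUE)
}

#' Classify an HEI value
#'
#' The published rule is "greater than 10", so the upper band is open on the
#' left: exactly 10 is not "very highly polluted".
#'
#' @param hei Non-negative index value.
#' @param bands Band table; defaults to [hei_bands()].
#' @return Band label.
#' @export
classify_hei <- function(hei, bands = hei_bands()) {
  band_lookup(hei, bands, closed_left = FALSE)
}

#' Per-site indices with a summary row
#'
#' Computes MPI and HEI for every site and appends a `Mean` row. By default
#' the summary row evaluates each index at the per-metal mean concentrations
#' (index of means); `mean_method = "mean_of_indices"` averages the per-site
#' index values instead. For the linear HEI the two coincide on a complete
#' grid; for the geometric-mean MPI they differ.
#'
#' @param table A `sample_table`.
#' @param limits Limit set for HEI (default bundled WHO).
#' @param mean_method `"index_of_means"` (default) or `"mean_of_indices"`.
#' @return Tibble with columns `site`, one concentration column per metal,
#'   `mpi`, `hei`, `mpi_class`, `hei_class`; last row is `Mean`.
#' @export
#' @examples
#' summarize_indices(sosiani_survey(quiet = TRUE))
summarize_indices <- function(table, limits = get_limit_set("WHO"),
                              mean_method = c("index_of_means",
                                              "mean_of_indices")) {
  mean_method <- match.arg(mean_method)
  sites <- table_sites(table)
  metals <- table_metals(table)
  rows <- lapply(sites, function(s) {
    conc <- site_concentrations(table, s)[metals]
    c(list(site = s), as.list(conc),
      list(mpi = compute_mpi(conc), hei = compute_hei(conc, limits)))
  })
  means <- mean_concentrations(table)
  if (mean_method == "index_of_means") {
    mean_mpi <- compute_mpi(means)
    mean_hei <- compute_hei(means, limits)
  } else {
    mean_mpi <- mean(vapply(rows, `[[`, numeric(1), "mpi"))
    mean_hei <- mean(vapply(rows, `[[`, numeric(1), "hei"))
  }
  rows <- c(rows, list(c(list(site = "Mean"), as.list(means),
                         list(mpi = mean_mpi, hei = mean_hei))))
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out$mpi_class <- vapply(out$mpi, classify_mpi, character(1))
  out$hei_class <- vapply(out$hei, classify_hei, character(1))
  tibble::as_tibble(out)
}
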