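who <- get_limit_set("WHO")

test_that("MPI is the geometric mean of the concentrations", {
  expect_printed(compute_mpi(c(Zn = 0.43, Cu = 0.32, Pb = 0.1)), "0.2396")
  expect_equal(compute_mpi(c(Zn = 1, Cu = 1, Pb = 1)), 1)
  # independently hand-computed cube root (site S2 of the survey)
  expect_equal(compute_mpi(c(Zn = 0.48, Cu = 0.28, Pb = 0.23)),
               (0.48 * 0.28 * 0.23)^(1 / 3))
  # generalizes beyond three metals
  expect_equal(compute_mpi(c(a = 2, b = 8)), 4)
  expect_error(compute_mpi(c(Zn = 0)), "strictly positive")
  expect_error(compute_mpi(c(Zn = -1, Cu = 2)), "strictly positive")
  expect_error(compute_mpi(numeric()), "at least one")
})

test_that("HEI sums concentration-to-MAC ratios against WHO by default", {
  expect_printed(compute_hei(c(Zn = 0.43, Cu = 0.32, Pb = 0.1), who),
                 "10.25")
  # hand sum for site S4: 0.084 + 0.15 + 6.0
  expect_equal(compute_hei(c(Zn = 0.42, Cu = 0.30, Pb = 0.06), who),
               0.084 + 0.15 + 6.0)
  # all metals at their MAC -> one each
  at_mac <- who$limits
  expect_equal(compute_hei(at_mac, who), length(at_mac))
  # default limit set is WHO
  expect_equal(compute_hei(c(Pb = 0.02)), 2)
  expect_error(compute_hei(c(Hg = 0.1), who), "Hg")
})

test_that("index classification follows the stated band boundaries", {
  expect_equal(classify_mpi(0.5), "pure water")
  expect_equal(classify_mpi(0), "below pure-water band")
  # 0.2323 sits below the stated 0.3 lower bound of the pure-water band
  expect_equal(classify_mpi(0.2323), "below pure-water band")
  expect_equal(classify_mpi(0.3), "pure water")  # closed on the left
  expect_equal(classify_mpi(1), "polluted")      # open on the right
  expect_error(classify_mpi(-0.1), "non-negative")

  expect_equal(classify_hei(10.80), "very highly polluted")
  expect_equal(classify_hei(0), "not very highly polluted")
  expect_equal(classify_hei(9.228), "not very highly polluted")
  expect_equal(classify_hei(10), "not very highly polluted")  # strictly > 10
  expect_error(classify_hei(-1), "non-negative")
})

test_that("summary row uses index-of-means and reproduces the survey table", {
  s <- sosiani_survey(quiet = TRUE)
  idx <- summarize_indices(s)
  expect_equal(idx$site, c(paste0("S", 1:7), "Mean"))
  expect_printed(idx$mpi[1:7], published$mpi, label = "MPI")
  expect_printed(idx$hei[1:7], published$hei, label = "HEI")
  expect_printed(idx$mpi[8], published$mean_mpi, label = "mean MPI")
  expect_printed(idx$hei[8], published$mean_hei, label = "mean HEI")

  # the two summary conventions differ for the geometric-mean index
  idx2 <- summarize_indices(s, mean_method = "mean_of_indices")
  expect_equal(idx2$mpi[8], mean(idx2$mpi[1:7]))
  expect_gt(abs(idx2$mpi[8] - idx$mpi[8]), 1e-3)

  # single-site table: summary row equals the site row
  one <- sample_table(data.frame(site = "A", metal = c("Zn", "Pb"),
                                 concentration_mg_per_L = c(0.4, 0.02)))
  idx1 <- summarize_indices(one)
  expect_equal(idx1$mpi[2], idx1$mpi[1])
  expect_equal(idx1$hei[2], idx1$hei[1])
})

test_that("indices obey scale-equivariance, linearity and oracle parity", {
  set.seed(101)
  for (i in 1:20) {
    conc <- stats::setNames(stats::runif(3, 0.001, 5), c("Zn", "Cu", "Pb"))
    k <- stats::runif(1, 0.1, 10)
    expect_equal(compute_mpi(k * conc), k * compute_mpi(conc))
    expect_equal(compute_hei(k * conc, who), k * compute_hei(conc, who))
    conc2 <- stats::setNames(stats::runif(3, 0.001, 5), names(conc))
    expect_equal(compute_hei(conc + conc2, who),
                 compute_hei(conc, who) + compute_hei(conc2, who))
    # agreement with the independent oracles to 12 significant digits
    expect_equal(compute_mpi(conc), mpi_oracle(conc), tolerance = 1e-12)
    expect_equal(compute_hei(conc, who), hei_oracle(conc, who$limits),
                 tolerance = 1e-12)
  }
})

test_that("HEI mean-commutation holds on complete grids", {
  tab <- generate_samples(30, c(Zn = 0.4, Cu = 0.3, Pb = 0.1), cv = 0.6,
                          seed = 3)
  idx <- summarize_indices(tab)
  expect_equal(idx$hei[idx$site == "Mean"],
               mean(idx$hei[idx$site != "Mean"]))
  # the published S7 row breaks this identity only under the literal cells
  lit <- summarize_indices(sosiani_survey(correct_s7_pb = FALSE,
                                          quiet = TRUE))
  expect_gt(abs(lit$hei[8] - as.numeric(published$mean_hei)), 0.1)
})
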