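adult <- get_exposure_profile("adult")
child <- get_exposure_profile("child")
pb_ref <- get_toxicity_reference("Pb")
zn_ref <- get_toxicity_reference("Zn")

test_that("CDI implements the ingestion equation with the right AT", {
  expect_printed(compute_cdi(0.105714, adult, "noncarcinogenic"),
                 "0.005068")
  expect_equal(compute_cdi(0, adult), 0)
  # independent term-by-term oracle, child carcinogenic endpoint
  expect_equal(compute_cdi(0.105714, child, "carcinogenic"),
               cdi_oracle(0.105714, 0.7, 350, 15, 15, 15 * 365))
  # endpoint selects the stored averaging time (not derived from ED)
  expect_equal(compute_cdi(1, adult, "noncarcinogenic") /
                 compute_cdi(1, adult, "carcinogenic"),
               (70 * 365) / (30 * 365))
  expect_error(compute_cdi(-1, adult), "non-negative")
  expect_error(compute_cdi(1, list()), "exposure_profile")
})

test_that("HQ divides CDI by the oral reference dose", {
  # site S2 adult, Pb
  expect_printed(compute_hq(compute_cdi(0.23, adult), pb_ref), "3.151")
  # site S1 child, Zn, against the independent dose oracle
  expect_printed(
    compute_hq(cdi_oracle(0.43, 0.7, 350, 15, 15, 6 * 365), zn_ref),
    "0.160")
  expect_equal(compute_hq(0, pb_ref), 0)
  no_rfd <- structure(list(metal = "X", rfd = NULL, csf = NULL,
                           carcinogenic = FALSE),
                      class = "toxicity_reference")
  expect_error(compute_hq(1, no_rfd), "no oral reference dose")
})

test_that("HI sums quotients and flags significance at one", {
  hi <- compute_hi(c(0.0687, 0.384, 1.370))
  expect_equal(as.numeric(hi), 1.8227)
  expect_true(attr(hi, "significant"))
  expect_false(attr(compute_hi(c(0.2, 0.3)), "significant"))
  expect_true(attr(compute_hi(1), "significant"))  # boundary: HI >= 1
  expect_equal(as.numeric(compute_hi(0.5)), 0.5)
  # published child Mean row: 0.152 + 0.815 + 3.379
  expect_printed(as.numeric(compute_hi(c(0.152, 0.815, 3.379))), "4.346")
  expect_error(compute_hi(numeric()), "at least one")
  expect_error(compute_hi(c(0.1, -0.2)), "non-negative")
})

test_that("ILCR multiplies carcinogenic CDI by the slope factor", {
  mean_adult <- compute_ilcr(compute_cdi(0.105714, adult, "carcinogenic"),
                             pb_ref)
  expect_printed(mean_adult, "1.846", scale = 1e-5)
  # site S2 child against the independent chain
  expect_printed(
    compute_ilcr(cdi_oracle(0.23, 0.7, 350, 15, 15, 15 * 365), pb_ref),
    "8.748", scale = 1e-5)
  expect_equal(compute_ilcr(0, pb_ref), 0)
  expect_error(compute_ilcr(0.1, zn_ref), "ILCR undefined for non-carcinogen")
  # clamped to the probability domain
  big <- toxicity_reference("Pb", rfd = 0.0035, csf = 1e6,
                            carcinogenic = TRUE)
  expect_equal(compute_ilcr(10, big), 1)
})

test_that("cancer-risk bands and excess cases follow the stated rules", {
  expect_equal(classify_ilcr(1.846e-5), "low")
  expect_equal(classify_ilcr(0), "negligible")
  expect_equal(classify_ilcr(1e-6), "low")    # band closed at 1e-6
  expect_equal(classify_ilcr(1e-4), "low")    # and at 1e-4
  expect_equal(classify_ilcr(2e-4), "high")
  expect_error(classify_ilcr(1.5), "\\[0, 1\\]")

  ec <- excess_cases_per_million(1.846e-5)
  expect_equal(ec$cases, 18.46)
  expect_equal(ec$cases_ceiling, 19)
  expect_equal(excess_cases_per_million(0)$cases, 0)
  expect_equal(excess_cases_per_million(1e-6)$cases, 1)
  expect_equal(excess_cases_per_million(1e-6)$cases_ceiling, 1)
})

test_that("risk_table reproduces the published hazard and cancer tables", {
  s <- sosiani_survey(quiet = TRUE)
  r <- risk_table(s)
  ha <- hazard_wide(r, "adult")
  hc <- hazard_wide(r, "child")
  expect_equal(ha$site, c(paste0("S", 1:7), "Mean"))
  for (i in 1:8) {
    expect_printed(c(ha$hq_Zn[i], ha$hq_Cu[i], ha$hq_Pb[i], ha$hi[i]),
                   published$hq_adult[i, ], label = paste("adult row", i))
    expect_printed(c(hc$hq_Zn[i], hc$hq_Cu[i], hc$hq_Pb[i], hc$hi[i]),
                   published$hq_child[i, ], label = paste("child row", i))
  }
  expect_true(all(ha$hi_significant))
  # mean CDIs per cohort and metal
  mean_rows <- r[r$site == "Mean", ]
  expect_printed(mean_rows$cdi_noncarc[mean_rows$cohort == "adult"],
                 published$mean_cdi_adult, label = "adult mean CDI")
  expect_printed(mean_rows$cdi_noncarc[mean_rows$cohort == "child"],
                 published$mean_cdi_child, label = "child mean CDI")
  # cancer table: Pb only, both cohorts
  iw <- ilcr_wide(r)
  expect_printed(iw$ilcr_adult_Pb, published$ilcr_adult, scale = 1e-5,
                 label = "adult ILCR")
  expect_printed(iw$ilcr_child_Pb, published$ilcr_child, scale = 1e-5,
                 label = "child ILCR")
  expect_true(all(is.na(r$ilcr[r$metal %in% c("Zn", "Cu")])))
  expect_error(risk_table(s, cohorts = character()), "at least one cohort")
})

test_that("risk chain is linear and commutes with the mean", {
  tab <- generate_samples(12, c(Zn = 0.5, Cu = 0.2, Pb = 0.08), cv = 0.5,
                          seed = 11)
  r1 <- risk_table(tab)
  doubled <- as.data.frame(tab)
  doubled$concentration_mg_per_L <- 2 * doubled$concentration_mg_per_L
  r2 <- risk_table(sample_table(doubled))
  expect_equal(r2$hi, 2 * r1$hi)
  expect_equal(r2$hq, 2 * r1$hq)
  expect_equal(r2$ilcr, 2 * r1$ilcr)
  # Mean row equals the mean of per-site values (linearity)
  for (co in c("adult", "child")) {
    sub <- r1[r1$cohort == co & r1$metal == "Pb", ]
    expect_equal(sub$hi[sub$site == "Mean"],
                 mean(sub$hi[sub$site != "Mean"]))
    expect_equal(sub$ilcr[sub$site == "Mean"],
                 mean(sub$ilcr[sub$site != "Mean"]))
  }
})

test_that("bundled cohort dose ratios are the fixed profile constants", {
  ratio_nc <- compute_cdi(1, child, "noncarcinogenic") /
    compute_cdi(1, adult, "noncarcinogenic")
  expect_equal(ratio_nc, (0.7 * 350 * 15 / (15 * 2190)) /
                 (1.5 * 350 * 70 / (70 * 10950)))
  expect_equal(ratio_nc, 7 / 3)
  ratio_c <- compute_cdi(1, child, "carcinogenic") /
    compute_cdi(1, adult, "carcinogenic")
  expect_equal(ratio_c, (0.7 / 15 * 350 / 365) / (1.5 / 70 * 350 / 365))
  expect_equal(ratio_c, 98 / 45)
})
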