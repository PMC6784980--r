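# Boundary timelines, seasonal modulation and the scenario catalogue.

test_that("timeline interpolation reproduces the tabulated breakpoints", {
  expect_equal(boundary_value("O2", 1860), 0.180)
  expect_equal(boundary_value("O2", 1875), 0.090, tolerance = 1e-4)
  expect_equal(boundary_value("O2", 2000), 0.1)
  expect_equal(boundary_value("OM1", 2030, "M"), 350)
  expect_equal(boundary_value("OM1", 2040, "M"), 350)   # held after 2030
  expect_equal(boundary_value("OM1", 1950), 623)        # "from 1950" step
  expect_equal(boundary_value("sed_rate", 1950), 0.33)
  expect_error(boundary_value("XX", 2000), "unknown boundary")
})

test_that("timelines are continuous between breakpoints", {
  # piecewise linearity: halving the sampling step halves the largest jump
  for (v in c("O2", "NH4", "CH4", "OM1", "Db0", "sed_rate")) {
    coarse <- max(abs(diff(boundary_value(v, seq(1851, 2049, by = 0.5)))))
    fine <- max(abs(diff(boundary_value(v, seq(1851, 2049, by = 0.25)))))
    expect_true(all(is.finite(boundary_value(v, seq(1851, 2049, 0.25)))))
    expect_lte(fine, coarse / 2 + 1e-12)
  }
})

test_that("seasonal cosines hit the printed extremes with unit annual mean", {
  expect_equal(seasonal_factor("O2", 0), 1.9)
  expect_equal(seasonal_factor("O2", 0.5), 0.1)
  expect_equal(seasonal_factor("OM1", 0.5), 1.5)
  expect_equal(seasonal_factor("reduced", 0.5), 1.75)
  # annual mean of every group is exactly 1 (numerical quadrature)
  tt <- seq(0, 1, length.out = 20001)[-1]
  for (grp in c("O2", "NO3", "SO4", "reduced", "solids"))
    expect_equal(mean(seasonal_factor(grp, tt)), 1, tolerance = 1e-6)
  expect_error(seasonal_factor("XX", 0), "unknown seasonal group")
  # seasonally modulated boundary values stay non-negative
  vals <- boundary_value("O2", seq(2000, 2002, by = 0.01), seasonal = TRUE)
  expect_true(all(vals >= 0))
})

test_that("the four scenarios share their history and diverge after 2018", {
  cat_ <- scenario_catalog()
  expect_setequal(names(cat_), c("SQ", "M", "O", "NoAa"))
  for (v in c("O2", "NH4", "OM1", "sed_rate"))
    for (sc in names(cat_))
      expect_equal(boundary_value(v, 2017, sc), boundary_value(v, 2017, "SQ"))
  # scenario-defining values
  expect_equal(boundary_value("O2", 2025, "NoAa"), 1e-5)  # anoxic from 2020
  expect_equal(boundary_value("O2", 2030, "M"), 0.15)
  expect_equal(boundary_value("O2", 2030, "O"), 0.2)
  expect_equal(boundary_value("OM1", 2050, "O"), 210)
  expect_equal(boundary_value("Db0", 2030, "NoAa"), 0)
  expect_equal(boundary_value("CH4", 2030, "NoAa"), 0.1)  # 100 umol/L
  # ramped species move monotonically through the transition
  yrs <- seq(2018, 2030, by = 1)
  expect_true(all(diff(boundary_value("OM1", yrs, "M")) <= 0))
  expect_true(all(diff(boundary_value("O2", yrs, "O")) >= 0))
})

test_that("scenario TOC loadings match the narrative carbon fluxes", {
  expect_equal(carbon_flux_gC(boundary_value("OM1", 2015),
                              boundary_value("OM2", 2015)), 107,
               tolerance = 0.01)
  expect_equal(carbon_flux_gC(boundary_value("OM1", 2035, "M"),
                              boundary_value("OM2", 2035, "M")), 60,
               tolerance = 0.01)
  expect_equal(carbon_flux_gC(boundary_value("OM1", 2035, "O"),
                              boundary_value("OM2", 2035, "O")), 36,
               tolerance = 0.01)
})
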