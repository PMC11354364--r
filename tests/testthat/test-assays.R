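test_that("viability follows the dual-wavelength formula exactly", {
  expect_equal(viabilityPercent(0.8, 0.1, 0.8, 0.1), 100)
  expect_equal(viabilityPercent(0.45, 0.1, 0.8, 0.1), 50)   # the GI50 case
  expect_equal(viabilityPercent(0.1, 0.1, 0.8, 0.1), 0)
  expect_error(viabilityPercent(0.5, 0.1, 0.2, 0.3), "control signal")
  expect_error(viabilityPercent(Inf, 0, 1, 0), "finite")
})

test_that("viability is invariant to a common absorbance offset", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(4); x[3] <- x[3] + x[4] + 0.1  # ensure C > Cc
    d <- runif(1, -1, 1)
    expect_equal(viabilityPercent(x[1], x[2], x[3], x[4]),
                 viabilityPercent(x[1] + d, x[2] + d, x[3] + d, x[4] + d),
                 tolerance = 1e-9)
  }
})

test_that("GI levels interpolate log-linearly and hit nodes exactly", {
  curve <- data.frame(concentration = c(1, 10, 100),
                      viability_pct = c(100, 50, 0))
  expect_identical(giLevel(curve, 50)$concentration, 10)
  two <- data.frame(concentration = c(1, 100), viability_pct = c(100, 0))
  expect_equal(giLevel(two, 50)$concentration, 10)  # 10^((0+2)/2)
})

test_that("GI statuses distinguish range and monotonicity failures", {
  high <- data.frame(concentration = c(1, 10, 100),
                     viability_pct = c(100, 95, 80))
  expect_identical(giLevel(high, 50)$status, "above_range")
  low <- data.frame(concentration = c(1, 10, 100),
                    viability_pct = c(40, 30, 20))
  expect_identical(giLevel(low, 50)$status, "below_range")
  rising <- data.frame(concentration = c(1, 10, 100),
                       viability_pct = c(20, 40, 70))
  expect_identical(giLevel(rising, 50)$status, "non_monotone_ambiguous")
  expect_error(giLevel(data.frame(concentration = 1, viability_pct = 50), 50),
               "at least 2")
})

test_that("GI level concentrations are ordered on decreasing curves", {
  for (gi50 in c(5, 25, 100)) {
    # ten 2-fold dilutions so the GI10 of the steepest curve stays in range
    plate <- simulatePlate(gi50True = gi50, dilutions = 200 / 2^(0:9),
                           noiseSd = 0, seed = 1)
    curve <- doseResponseCurve(plate)
    g50 <- giLevel(curve, 50)$concentration
    g25 <- giLevel(curve, 25)$concentration
    g10 <- giLevel(curve, 10)$concentration
    expect_true(g10 <= g25 && g25 <= g50)
  }
})

test_that("GI50 interpolation error shrinks as the dilution step refines", {
  errAt <- function(step) {
    dil <- 200 / step^(0:ceiling(log(200 / 1, step)))
    plate <- simulatePlate(gi50True = 18, dilutions = dil, noiseSd = 0,
                           seed = 1)
    abs(giLevel(doseResponseCurve(plate), 50)$concentration - 18)
  }
  expect_lt(errAt(1.3), errAt(4))
})

test_that("fluorescence ratios follow the stain conventions", {
  expect_equal(fluorescenceRatio(80, 80, "AO_PI")$value, 1)
  expect_equal(fluorescenceRatio(50, 100, "JC1")$value, 2)
  expect_equal(fluorescenceRatio(137.5, 12, "NAO")$value, 137.5)
  z <- fluorescenceRatio(100, 0, "AO_PI")
  expect_identical(z$status, "undefined_ratio")
  expect_true(is.na(z$value))
  expect_error(fluorescenceRatio(-1, 2, "JC1"), ">= 0")
})

test_that("delta-delta-Cq inverts known tables", {
  flat <- data.frame(gene = rep(c("T", "HPRT1"), each = 2),
                     sample = rep(c("treated", "control"), 2),
                     cq = c(24, 24, 20, 20))
  expect_equal(ddcqFoldChange(flat, "T"), 1)
  gain <- data.frame(gene = rep(c("T", "HPRT1"), each = 2),
                     sample = rep(c("treated", "control"), 2),
                     cq = c(23, 24, 20, 20))  # ddCq = -1
  expect_equal(ddcqFoldChange(gain, "T"), 2)
  forced <- data.frame(gene = rep(c("T", "HPRT1"), each = 2),
                       sample = rep(c("treated", "control"), 2),
                       cq = c(25, 24, 20, 20))  # ddCq = +1
  expect_equal(ddcqFoldChange(forced, "T"), 0.5)
})

test_that("replicates average arithmetically and missing cells are named", {
  tab <- data.frame(
    gene = c("T", "T", "T", "T", "HPRT1", "HPRT1"),
    sample = c("treated", "treated", "control", "control", "treated", "control"),
    cq = c(24, 26, 24, 24, 20, 20))  # treated mean 25 vs control 24
  expect_equal(ddcqFoldChange(tab, "T"), 0.5)
  expect_error(ddcqFoldChange(tab, "MISSING"), "gene 'MISSING'")
  expect_error(ddcqFoldChange(tab[tab$sample != "control" |
                                  tab$gene != "HPRT1", ], "T"),
               "gene 'HPRT1', sample 'control'")
})

test_that("a control compared with itself has fold change 1", {
  set.seed(8)
  for (i in 1:5) {
    cqs <- runif(2, 15, 30)
    tab <- data.frame(gene = rep(c("T", "HPRT1"), each = 2),
                      sample = rep(c("treated", "control"), 2),
                      cq = rep(cqs, each = 2))
    expect_equal(ddcqFoldChange(tab, "T"), 1)
  }
})
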