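mkMask <- function(px) new("WoundMask", pixels = px, nComponentsKept = 1L,
                           overridden = FALSE)
bandMask <- function(h, w, cols) {
  px <- matrix(FALSE, h, w)
  if (length(cols)) px[, cols] <- TRUE
  mkMask(px)
}

test_that("open percentage is defined relative to the T0 wound", {
  s <- scratchSeries("w1", c(0, 24, 48),
                     list(bandMask(10, 20, 1:10), bandMask(10, 20, 1:5),
                          bandMask(10, 20, 1:1)))
  res <- openWoundPercent(s)
  expect_identical(res@openPct[1], 100)
  expect_equal(res@openPct, c(100, 50, 10))
  expect_equal(res@closurePct + res@openPct, rep(100, 3))
  expect_identical(res@flags, rep("", 3))
})

test_that("identical masks across timepoints give 100 throughout", {
  m <- bandMask(8, 12, 3:6)
  res <- openWoundPercent(scratchSeries("w", c(0, 24), list(m, m)))
  expect_equal(res@openPct, c(100, 100))
})

test_that("an expanding wound is reported uncapped and flagged", {
  res <- openWoundPercent(scratchSeries("w", c(0, 24),
                                        list(bandMask(10, 20, 1:4),
                                             bandMask(10, 20, 1:5))))
  expect_equal(res@openPct[2], 125)
  expect_identical(res@flags[2], "EXPANDED")
})

test_that("a zero T0 wound is an error suggesting manual override", {
  s <- scratchSeries("w", c(0, 24),
                     list(bandMask(5, 5, integer(0)), bandMask(5, 5, 1)))
  expect_error(openWoundPercent(s), "no initial wound.*override")
})

test_that("series validity enforces time ordering and frame agreement", {
  expect_error(scratchSeries("w", c(24, 0), list(bandMask(5, 5, 1),
                                                 bandMask(5, 5, 1))),
               "strictly increasing")
  expect_error(scratchSeries("w", c(0, 24), list(bandMask(5, 5, 1),
                                                 bandMask(6, 5, 1))),
               "identical frame dimensions")
})

test_that("open percentage is invariant to uniform integer resampling", {
  sim <- simulateScratchSeries(width = 300, height = 60, woundFrac = 0.4,
                               closureFracs = c(1, 0.5, 0.2),
                               times = c(0, 24, 48), seed = 3)
  masks <- lapply(sim$truthSeries@masks, identity)
  res1 <- openWoundPercent(scratchSeries("w", c(0, 24, 48), masks))
  up <- lapply(masks, function(m)
    mkMask(pixels(m)[rep(1:60, each = 2), rep(1:300, each = 2)]))
  res2 <- openWoundPercent(scratchSeries("w", c(0, 24, 48), up))
  expect_true(all(abs(res1@openPct - res2@openPct) < 1))
})

test_that("condition summaries report mean, sd and n per timepoint", {
  r1 <- openWoundPercent(scratchSeries("a", c(0, 24),
                                       list(bandMask(10, 20, 1:10),
                                            bandMask(10, 20, 1:6))))
  tab1 <- compareConditions(list(r1), "treated")
  expect_equal(tab1$sd_open_pct, c(0, 0))
  expect_equal(tab1$n, c(1L, 1L))
  tab2 <- compareConditions(list(r1, r1), c("treated", "treated"))
  expect_equal(tab2$sd_open_pct, c(0, 0))
  expect_equal(tab2$mean_open_pct, c(100, 60))
  expect_error(compareConditions(list(), character(0)), "no results")
})

test_that("replicate truth series recover the programmed closure fractions", {
  results <- lapply(1:5, function(seed) {
    sim <- simulateScratchSeries(width = 400, height = 80, woundFrac = 0.35,
                                 closureFracs = c(1, 0.6, 0.1),
                                 times = c(0, 24, 48), seed = seed)
    openWoundPercent(sim$truthSeries)
  })
  tab <- compareConditions(results, rep("sim", 5))
  expect_true(all(abs(tab$mean_open_pct - c(100, 60, 10)) <= 2))
  expect_equal(tab$n, rep(5L, 3))
})
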