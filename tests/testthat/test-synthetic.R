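test_that("cohort generation respects dispersion and reproducibility", {
  co <- simulateCohort(6, dispersion = 0.2, seed = 21)
  expect_length(co$subjects, 6)
  amps <- sapply(co$subjects, function(s) s$amp["rr"])
  expect_gt(length(unique(amps)), 1)          # distinct under dispersion
  co0 <- simulateCohort(2, dispersion = 0, seed = 21)
  expect_identical(co0$subjects[[1]]$amp, co0$subjects[[2]]$amp)
  expect_identical(co0$subjects[[1]]$baseline, co0$subjects[[2]]$baseline)
  coA <- simulateCohort(4, dispersion = 0.3, seed = 5)
  coB <- simulateCohort(4, dispersion = 0.3, seed = 5)
  expect_identical(coA$subjects, coB$subjects)
})

test_that("ground-truth response is sub-threshold at the weak corner and monotone", {
  s <- simulateCohort(1, dispersion = 0, seed = 1)$subjects[[1]]
  weak <- c(cur = 0.2, npulses = 2, pw = 0.05, ipp = 35, del = 86)
  strong <- c(cur = 1, npulses = 2, pw = 0.2, ipp = 35, del = 86)
  expect_lt(abs(trueEffect(s, weak, "rr")), 2)
  expect_gt(trueEffect(s, strong, "rr"), trueEffect(s, weak, "rr"))
  # magnitude monotone in cur and pw for every marker
  for (m in c("rr", "pr", "dpdt")) {
    e1 <- abs(trueEffect(s, weak, m))
    e2 <- abs(trueEffect(s, strong, m))
    expect_gte(e2, e1)
  }
  expect_error(trueEffect(s, weak, "qt"), "arg")
})

test_that("noiseless simulation chains reproduce the injected effect exactly", {
  s <- simulateCohort(1, dispersion = 0, seed = 1)$subjects[[1]]
  # null configuration: far below recruitment => effect ~ 0, and with the
  # residual terms zeroed the chain is exactly null
  s0 <- s
  s0$amp <- c(rr = 0, pr = 0, dpdt = 0)
  s0$ippCoef <- 0
  s0$delCoef <- 0
  cfg <- c(cur = 0.6, npulses = 2, pw = 0.1, ipp = 35, del = 86)
  sq0 <- simulateSequence(s0, cfg, noiseSd = 0, seed = 2)
  expect_equal(relativeEffect(sq0$off, sq0$on, "rr"), 0)
  # deterministic +20% RR chain: force the response via the amplitude with a
  # saturating configuration
  s20 <- s0
  s20$amp <- c(rr = 20, pr = 0, dpdt = 0)
  s20$thr <- -10                       # always fully recruited
  cfg4 <- c(cur = 1, npulses = 4, pw = 0.2, ipp = 35, del = 86)
  sq20 <- simulateSequence(s20, cfg4, noiseSd = 0, seed = 3)
  expect_equal(relativeEffect(sq20$off, sq20$on, "rr"), 20, tolerance = 1e-12)
})

test_that("strong bradycardia raises the flag at the 1100 ms pacing threshold", {
  s <- simulateCohort(1, dispersion = 0, seed = 1)$subjects[[1]]
  s$baseline["rr"] <- 900
  s$amp["rr"] <- 30                    # 900 * 1.3 = 1170 ms > 1100 ms
  s$thr <- -10
  cfg <- c(cur = 1, npulses = 4, pw = 0.2, ipp = 35, del = 86)
  sq <- simulateSequence(s, cfg, noiseSd = 0, seed = 4)
  expect_true(sq$bradycardia)
  expect_gt(max(sq$on$rr), 1100)
})

test_that("sequences have window-compatible beat counts and reproducible noise", {
  s <- simulateCohort(1, dispersion = 0, seed = 1)$subjects[[1]]
  cfg <- c(cur = 0.9, npulses = 4, pw = 0.18, ipp = 35, del = 86)
  sq <- simulateSequence(s, cfg, noiseSd = 3, seed = 5)
  expect_gte(nrow(sq$off), 10)
  expect_gte(nrow(sq$on), 23)
  sq2 <- simulateSequence(s, cfg, noiseSd = 3, seed = 5)
  expect_identical(sq$on, sq2$on)
})

test_that("the residual interpulse/delay terms are near-null by construction", {
  s <- simulateCohort(1, dispersion = 0, seed = 1)$subjects[[1]]
  grid <- expand.grid(cur = seq(0.2, 1, length.out = 5),
                      npulses = 1:4,
                      pw = seq(0.05, 0.2, length.out = 5),
                      ipp = seq(24.4, 47, length.out = 5),
                      del = seq(16, 156, length.out = 5))
  y <- trueEffect(s, grid, "rr")
  # variance attributable to ipp/del alone (linear in both): compare against
  # total variance over the grid
  vIpp <- var(ave(y, grid$ipp)) + var(ave(y, grid$del))
  expect_lt(vIpp / var(y), 0.02)
})

test_that("beat-table export matches the documented long schema", {
  co <- simulateCohort(2, dispersion = 0, seed = 9)
  cfg <- rescaleDesign(generateLHS(3, 5, seed = 9, nRestarts = 2))
  seqs <- simulateExperiment(co, cfg, noiseSd = 1, seed = 10)
  expect_length(seqs, 6)
  tab <- sequencesToBeatTable(seqs)
  expect_named(tab, c("subject", "config_id", "phase", "beat_index",
                      "rr_ms", "pr_ms", "dpdtmax"))
  expect_setequal(unique(tab$phase), c("off", "on"))
  expect_true(all(tab$rr_ms > 0))
})
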