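test_that("lattice geometry covers the TSS window", {
  lat <- chromLattice()
  pos <- positionsKbp(lat)
  expect_equal(length(pos), 200L)
  expect_equal(min(pos), -10)
  expect_equal(max(pos), 9.9)
  expect_equal(pos[lat@tssIndex], 0)
  expect_error(chromLattice(nSites = 7), "even")
})

test_that("Gaussian profile evaluation matches the closed form", {
  lat <- chromLattice()
  ## wild-type p300 peak: value at the site nearest i0 is within one lattice
  ## step of the analytic peak height psiM + psiB
  pk <- gaussianPeak(0.1196, 0.1666, -0.5438, 5.1875)
  v <- evaluateGaussianProfile(pk, lat)
  iNear <- which.min(abs(positionsKbp(lat) - pk@i0))
  expect_lt(abs(v[iNear] - (0.1666 + 0.1196)), 0.1666 *
              (1 - exp(-(0.05)^2 / (2 * 5.1875^2))) + 1e-6)
  expect_equal(v[iNear], 0.2862, tolerance = 1e-4)
  ## direct evaluation one sigma off-centre
  v2 <- evaluateGaussianProfile(gaussianPeak(0.1, 1, 0, 1), lat)
  i1 <- which(positionsKbp(lat) == 1)
  expect_equal(v2[i1], 0.1 + exp(-0.5), tolerance = 1e-12)
  ## degenerate peak is the background
  expect_equal(evaluateGaussianProfile(gaussianPeak(0.3, 0, 0, 1), lat),
               rep(0.3, 200))
  ## symmetry about i0 up to lattice discretization
  sym <- evaluateGaussianProfile(gaussianPeak(0, 1, 0, 2), lat)
  tss <- lat@tssIndex
  for (k in c(1, 10, 50))
    expect_equal(sym[tss + k], sym[tss - k], tolerance = 1e-12)
  expect_error(gaussianPeak(0.1, 1, 0, 0), "sigma0")
})

test_that("preset profiles scale peaks, not backgrounds", {
  lat <- chromLattice()
  expect_error(makePresetProfile("nope"), "valid presets")
  ## zero scaling leaves the backgrounds
  p0 <- makePresetProfile("pcg_target", recruitmentScales(0, 0), lat)
  expect_true(all(abs(psiSuz12(p0) - min(psiSuz12(p0))) < 1e-12))
  expect_equal(min(psiP300(p0)), 0.1196, tolerance = 1e-12)
  ## SUZ12 peak-above-background is exactly linear in the PRC2 scale
  p1 <- makePresetProfile("pcg_target", recruitmentScales(1, 1), lat)
  p2 <- makePresetProfile("pcg_target", recruitmentScales(2, 1), lat)
  above1 <- psiSuz12(p1) - min(psiSuz12(p1))
  above2 <- psiSuz12(p2) - min(psiSuz12(p2))
  expect_equal(above2, 2 * above1, tolerance = 1e-12)
  ## the PcG-target preset at its default scales carries the wild-type p300
  ## Gaussian (beta = 0.3 times the active-gene amplitude)
  wt <- makePresetProfile("pcg_target")
  expect_equal(psiP300(wt),
               evaluateGaussianProfile(
                 gaussianPeak(0.1196, 0.1666, -0.5438, 5.1875), lat),
               tolerance = 1e-12)
})

test_that("quantile-capped normalization excludes outlier bins", {
  ## brute-force check: 1999 bins at <= 50, one extreme outlier
  set.seed(1)
  v <- c(runif(1999, 0, 50), 1e6)
  ## several bins exactly at the in-range maximum, so the upper-quantile
  ## threshold sits at 50 and only the extreme outlier is excluded
  v[1:5] <- 50
  out <- normalizeTrack(v)
  qs <- quantile(v, c(0.001, 0.999), names = FALSE)
  M <- max(v[v >= qs[1] & v <= qs[2]])
  expect_equal(M, 50)
  expect_equal(out, v / 50)
  expect_equal(max(out[-2000]), 1.0, tolerance = 1e-12)
  ## outlier retained (not clipped) unless asked
  expect_gt(out[2000], 1)
  expect_equal(max(normalizeTrack(v, clip = TRUE)), 1)
  ## constant vector maps to all ones; normalization is idempotent
  expect_equal(normalizeTrack(rep(3, 10)), rep(1, 10))
  w <- normalizeTrack(v)
  expect_equal(normalizeTrack(w), w)
  expect_error(normalizeTrack(rep(0, 5)), "all-zero")
})

test_that("moving-average smoothing has the stated kernel and edges", {
  expect_equal(smoothProfile(rep(2, 50)), rep(2, 50))
  imp <- rep(0, 21); imp[11] <- 1
  sm <- smoothProfile(imp, 300, 100)
  expect_equal(sm[10:12], rep(1 / 3, 3))
  expect_equal(sum(sm), 1)  # interior impulse: mass conserved
  expect_equal(smoothProfile(imp, 100, 100), imp)  # 1-bin window = identity
  expect_error(smoothProfile(imp, 2500, 100), "larger")
  expect_error(smoothProfile(imp, 150, 100), "multiple")
})

test_that("profile IO round-trips and resamples by bin overlap", {
  lat <- chromLattice()
  v <- evaluateGaussianProfile(gaussianPeak(0.1, 0.5, 0, 2), lat)
  tc <- tempfile(fileext = ".tsv"); bg <- tempfile(fileext = ".bedgraph")
  writeProfileTrack(v, tc, "twocolumn", lat)
  expect_identical(readProfileTrack(tc, "twocolumn", lat), v)
  writeProfileTrack(v, bg, "bedgraph", lat)
  ## overlap-averaging arithmetic may differ in the last ulp
  expect_equal(readProfileTrack(bg, "bedgraph", lat), v, tolerance = 1e-14)
  ## 200-bp bedGraph bins: each lattice site takes its covering bin's value
  lat6 <- chromLattice(nSites = 6, bpPerSite = 100)
  f <- tempfile()
  writeLines(c("w\t0\t200\t1.5", "w\t200\t400\t2.5", "w\t400\t600\t4"), f)
  expect_equal(readProfileTrack(f, "bedgraph", lat6),
               c(1.5, 1.5, 2.5, 2.5, 4, 4))
  ## partial overlap averages proportionally
  writeLines(c("w\t0\t150\t1", "w\t150\t300\t3"), f)
  expect_warning(got <- readProfileTrack(f, "bedgraph", lat6), "coverage")
  expect_equal(got[1:3], c(1, 0.5 * 1 + 0.5 * 3, 3))
  ## error paths
  writeLines(character(0), f)
  expect_error(readProfileTrack(f, "bedgraph", lat6))
  writeLines(c("w\t0\t200\t1", "w\t100\t300\t2"), f)
  expect_error(readProfileTrack(f, "bedgraph", lat6), "overlap")
  writeLines(c("0.0\t-1", "0.1\t2"), f)
  expect_warning(
    expect_warning(neg <- readProfileTrack(f, "twocolumn", lat6), "coverage"),
    "negative")
  expect_true(all(neg >= 0))
})
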