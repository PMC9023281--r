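test_that("two well-separated peaks are both detected at their centers", {
  x <- 1:60
  prof <- 100 * exp(-(x - 20)^2 / (2 * 1.3^2)) +
    100 * exp(-(x - 30)^2 / (2 * 1.3^2))
  set.seed(2)
  prof <- prof + rnorm(60, 0, 2)
  fo <- detect_foci(prof)
  expect_equal(nrow(fo), 2)
  expect_equal(fo$position_px, c(20, 30), tolerance = 0.5 / 20)
})

test_that("false-positive rate on pure noise is below 1% at z = 5", {
  set.seed(14)
  hits <- replicate(1000, nrow(detect_foci(rnorm(100), z_threshold = 5)))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("planted foci are recovered with precision and recall >= 0.95", {
  set.seed(15)
  kern <- kymoclear:::gaussian_kernel(1.3)
  stats <- replicate(60, {
    k <- sample(2:5, 1)
    pos <- sort(sample(seq(10, 110, by = 7), k))  # separation > 6 px
    line <- numeric(120)
    line[pos] <- 90
    # realistic single-focus brightness: blurred peak ~10x the noise SD
    prof <- kymoclear:::conv_same(line, kern) * 6 + rnorm(120, 0, 16)
    fo <- detect_foci(prof, min_separation_px = 3, z_threshold = 5)
    tp <- sum(sapply(pos, function(p) any(abs(fo$position_px - p) <= 2)))
    c(recall = tp / k,
      precision = if (nrow(fo)) tp / nrow(fo) else 1)
  })
  expect_gte(mean(stats["recall", ]), 0.95)
  expect_gte(mean(stats["precision", ]), 0.95)
})

test_that("ties break toward the lower column index", {
  prof <- c(rep(0, 10), 50, 50, rep(0, 10)) + 0  # plateau of two equal maxima
  fo <- detect_foci(prof, z_threshold = 1)
  expect_equal(fo$position_px[1], 11)
})

test_that("foci density is count per unit length", {
  roi <- molecule_roi(1, 123, 8)
  foci <- data.frame(position_px = c(10, 30, 50, 80), intensity = 1)
  d <- foci_per_unit_length(foci, roi)     # 4 foci on 13 um
  expect_equal(as.numeric(d), 4 / 13, tolerance = 1e-6)
  expect_equal(as.numeric(foci_per_unit_length(foci[0, ], roi)), 0)
  expect_error(foci_per_unit_length(foci, molecule_roi(5, 6, 8)), NA)
  roi0 <- molecule_roi(5, 6, 8); roi0$anchor_px <- 5L
  expect_error(foci_per_unit_length(foci, roi0), "zero-length")
})

test_that("planted Poisson focus density is recovered within 2 SE", {
  set.seed(16)
  lambda_per_px <- 1 / 30
  kern <- kymoclear:::gaussian_kernel(1.3)
  roi <- molecule_roi(1, 150, 8)
  counts <- replicate(50, {
    k <- rpois(1, lambda_per_px * 150)
    line <- numeric(150)
    if (k > 0) {
      pos <- sort(sample(10:140, min(k, 40)))
      pos <- pos[c(TRUE, diff(pos) > 6)]   # enforce resolvability
      line[pos] <- 100
    }
    prof <- kymoclear:::conv_same(line, kern) * 3 + rnorm(150, 0, 10)
    c(planted = sum(line > 0), found = nrow(detect_foci(prof)))
  })
  expect_lt(abs(mean(counts["found", ]) - mean(counts["planted", ])),
            2 * sd(counts["planted", ]) / sqrt(50) * 2 + 0.3)
})

test_that("bleach-only intensity trace decays as exp(-b t) and starts at 1", {
  b <- 0.01
  cfg <- sim_config(n_frames = 25, span_px = 60, molecule_length_knt = 12,
                    bleach_rate_per_frame = b)
  stk <- render_kymograph(NULL, cfg, noise = FALSE)
  tr <- intensity_trace(stk, channel = "green")
  expect_equal(tr$normalized[1], 1)
  expect_equal(tr$normalized, exp(-b * (tr$frame - 1)), tolerance = 1e-6)
})

test_that("normalization is idempotent and SEM is across molecules", {
  cfg <- sim_config(n_frames = 10, span_px = 40, molecule_length_knt = 8)
  traces <- lapply(1:4, function(s) {
    stk <- render_kymograph(NULL, cfg, seed = s)
    intensity_trace(stk, channel = "green")
  })
  tr <- traces[[1]]
  renorm <- tr$normalized / tr$normalized[1]
  expect_equal(renorm, tr$normalized)
  agg <- aggregate_intensity(traces)
  expect_equal(agg$n, rep(4, 10))
  expect_equal(agg$sem[1], 0)              # all equal 1 at the reference
})

test_that("terminal green loss mirrors magenta gain in coverage units", {
  cfg <- sim_config(n_frames = 30, span_px = 80, molecule_length_knt = 16.4,
                    bleach_rate_per_frame = 0)
  mot <- canonical_motor()
  stk <- render_kymograph(mot, cfg, noise = FALSE)
  g <- intensity_trace(stk, channel = "green")
  m <- intensity_trace(stk, channel = "magenta", reference = 30)
  cleared_frac <- 1 - g$normalized[30]
  expected <- mot$processivity_knt * 1000 /
    (cfg$molecule_length_knt * 1000)
  expect_equal(cleared_frac, expected, tolerance = 0.05)
  # green loss equals magenta gain: the magenta trace rises to its own
  # terminal value along the same coverage bookkeeping
  expect_equal(m$intensity_per_px[30] / g$intensity_per_px[1],
               expected, tolerance = 0.05)
})

test_that("molecules with nonpositive reference intensity are dropped", {
  cfg <- sim_config(n_frames = 6, span_px = 40, molecule_length_knt = 8,
                    background = 0, read_noise_sd = 0)
  stk <- render_kymograph(NULL, cfg, noise = FALSE)
  expect_error(intensity_trace(stk, channel = "magenta"), "dropped")
})

test_that("3x3 focus intensity: uniform, spike and border cases", {
  img <- matrix(10, 9, 9)
  expect_equal(focus_intensity_3x3(img, c(5, 5), background = 10), 0)
  img[5, 5] <- 100
  expect_equal(focus_intensity_3x3(img, c(5, 5), background = 10),
               (100 + 8 * 10) / 9 - 10)
  expect_error(focus_intensity_3x3(img, c(1, 5)), "border")
})

test_that("tether survival: trivial and exponential-breakage cases", {
  state <- matrix(TRUE, 10, 20)
  s <- tether_lifetime(state, challenge_frame = 5)
  expect_true(all(s$fraction_surviving == 1))

  state2 <- matrix(TRUE, 10, 20)
  state2[, 5:20] <- FALSE                  # all break at the challenge
  s2 <- tether_lifetime(state2, challenge_frame = 5)
  expect_equal(min(s2$fraction_surviving), 0)
  expect_equal(s2$time_s[which(s2$fraction_surviving == 0)[1]], 0)

  set.seed(17)
  r <- 0.05                                # per-frame breakage hazard
  nmol <- 400; nf <- 200
  state3 <- matrix(TRUE, nmol, nf)
  brk <- 10 + rgeom(nmol, r)
  for (i in seq_len(nmol))
    if (brk[i] <= nf) state3[i, brk[i]:nf] <- FALSE
  s3 <- tether_lifetime(state3, challenge_frame = 10, frame_interval_s = 5)
  half <- s3$time_s[which(s3$fraction_surviving <= 0.5)[1]]
  expect_equal(half, log(2) / r * 5, tolerance = 0.15)
})
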