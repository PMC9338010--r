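# Stimulus generation: noise fields, equalisation, grids, targets, rendering.

test_that("noise field has requested extent, range and spectral slope", {
  f <- generate_noise_field(c(200, 120), exponent = 2, seed = 1, gen_px = 256)
  expect_equal(dim(f$values), c(120, 200))
  expect_gte(min(f$values), 0)
  expect_lte(max(f$values), 1)
  expect_error(generate_noise_field(c(2000, 768)), "generation dimension")
  expect_error(generate_noise_field(c(0, 10)), "positive")

  # exponent 0 -> white noise: negligible lag-1 autocorrelation
  w <- generate_noise_field(c(1024, 768), exponent = 0, seed = 2)
  r <- cor(as.vector(w$values[, -1]), as.vector(w$values[, -1024]))
  expect_lt(abs(r), 0.05)

  # periodogram oracle: radially averaged log-power slope of the exponent-2
  # field is steeper by ~ 2 * 2 than the exponent-0 field
  slope_of <- function(field) {
    n <- 256
    v <- field$values - mean(field$values)
    P <- Mod(stats::fft(v))^2
    fr <- c(0:(n / 2), seq.int(n / 2 - 1, 1)) / n
    f <- sqrt(outer(fr^2, fr^2, `+`))
    keep <- f > 0.01 & f < 0.4
    bins <- cut(log(f[keep]), 24)
    lp <- tapply(log(P[keep]), bins, mean)
    lf <- tapply(log(f[keep]), bins, mean)
    unname(stats::coef(stats::lm(lp ~ lf))[2])
  }
  s2 <- slope_of(generate_noise_field(c(256, 256), exponent = 2, seed = 3, gen_px = 256))
  s0 <- slope_of(generate_noise_field(c(256, 256), exponent = 0, seed = 3, gen_px = 256))
  expect_equal(s2 - s0, -4, tolerance = 0.15)
})

test_that("parabolic equalisation matches the closed-form reference", {
  # median pixel maps to 0.5 (odd pixel count makes the median rank exact)
  m <- difficulty_map(matrix(runif(11 * 11), 11))
  e <- equalize_to_parabola(m)
  expect_equal(sort(as.vector(e$values))[61], 0.5)

  # tail mass: integrating f over [0,.25] u [.75,1] gives
  # F(.25) + 1 - F(.75) = 0.4375 + 0.4375 = 0.875
  m <- difficulty_map(matrix(runif(300 * 200), 200))
  e <- equalize_to_parabola(m)
  tails <- mean(e$values <= 0.25 | e$values >= 0.75)
  expect_equal(tails, 0.875, tolerance = 0.005)
  expect_equal(min(e$values), 0, tolerance = 0.01)
  expect_equal(max(e$values), 1, tolerance = 0.01)

  # rank transform is equivariant under strictly monotone input transforms
  m2 <- difficulty_map(exp(3 * m$values))
  expect_equal(equalize_to_parabola(m2)$values, e$values)

  expect_error(equalize_to_parabola(difficulty_map(matrix(NaN, 2, 2))), "finite")
})

test_that("cell difficulties are block means of the map", {
  g <- grid_spec(4, 3, cell_px = 8, screen_px = c(32, 24))
  m <- difficulty_map(matrix(0.37, 24, 32))
  expect_equal(cell_difficulties(m, g), matrix(0.37, 3, 4))

  g2 <- grid_spec(2, 2, cell_px = 4, screen_px = c(8, 8))
  v <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  expect_equal(cell_difficulties(difficulty_map(v), g2),
               cbind(c(0, 0), c(1, 1)))

  set.seed(5)
  v <- matrix(runif(24 * 32), 24, 32)
  got <- cell_difficulties(difficulty_map(v), g)
  oracle <- matrix(NA_real_, 3, 4)
  for (r in 1:3) for (c in 1:4) {
    oracle[r, c] <- mean(v[(r - 1) * 8 + 1:8, (c - 1) * 8 + 1:8])
  }
  expect_equal(got, oracle)
  expect_error(cell_difficulties(difficulty_map(v[, 1:16]), g), "extent")
})

test_that("difficulty-to-range mapping is the stated linear interpolation", {
  m <- orientation_range_mapping()
  expect_equal(range_from_difficulty(0, m), pi / 6)
  expect_equal(range_from_difficulty(1, m), 2 * pi / 3)
  expect_equal(range_from_difficulty(0.5, m), 5 * pi / 12)
  expect_error(range_from_difficulty(1.2, m), "\\[0, 1\\]")
  d <- seq(0, 1, by = 0.05)
  r <- range_from_difficulty(d, m)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= m$range_min & r <= m$range_max))
})

test_that("orientation sampling is centred perpendicular to the target", {
  set.seed(7)
  n <- 100
  ranges <- matrix(pi / 6, n, n)
  ori <- sample_orientation_grid(ranges)   # theta = pi/4, centre 3*pi/4
  se <- (pi / 6) / sqrt(12) / n
  expect_lt(abs(mean(ori) - 3 * pi / 4), 3 * se)

  tiny <- sample_orientation_grid(matrix(1e-12, 5, 5))
  expect_equal(tiny, matrix(3 * pi / 4, 5, 5), tolerance = 1e-9)

  tgt <- target_spec(TRUE, cell = c(2, 3), orientation = pi / 4)
  ori <- sample_orientation_grid(matrix(pi / 2, 6, 6), tgt)
  expect_identical(ori[4, 3], pi / 4)
})

test_that("split-half arrays assign halves and place targets correctly", {
  s <- make_split_half(axis = "horizontal", hard_side = "up", seed = 1)
  expect_true(all(s$cell_difficulty[1:8, ] == 1))
  expect_true(all(s$cell_difficulty[9:16, ] == 0))
  expect_equal(sum(s$cell_difficulty == 1), 22 * 16 / 2)

  expect_error(make_split_half(axis = "horizontal", hard_side = "left"),
               "inconsistent")

  # target on the requested half, never on the forbidden cells
  for (sd in 1:20) {
    s <- make_split_half(hard_side = "down", target_half = "hard", seed = sd)
    tc <- s$target$cell
    expect_gte(tc[2], 8)
    expect_true(tc[1] > 0 && tc[1] < 21 && tc[2] < 15)
  }

  # absent targets really are absent: no cell equals theta by construction
  hits <- vapply(1:100, function(sd) {
    s <- make_split_half(target_half = "absent", seed = sd)
    sum(s$orientations == pi / 4)
  }, numeric(1))
  expect_identical(sum(hits), 0)

  expect_equal(make_split_half(seed = 42), make_split_half(seed = 42))
})

test_that("jumbled arrays compose the full generation pipeline", {
  j1 <- make_jumbled(seed = 3)
  expect_equal(dim(j1$cell_difficulty), c(24, 32))
  expect_equal(j1, make_jumbled(seed = 3))

  # pooled cell difficulties are U-shaped (parabolic reference): outer
  # quartiles hold more cells than the inner ones (simulation scaled to 30
  # arrays; plenty at 768 cells each)
  pooled <- unlist(lapply(1:30, function(sd) make_jumbled(seed = sd)$cell_difficulty))
  outer_q <- mean(pooled <= 0.25 | pooled >= 0.75)
  expect_gt(outer_q, 0.5)
})

test_that("all generated orientations lie inside their cell's interval (mod pi)", {
  stims <- list(make_split_half(seed = 11, target_half = "hard"),
                make_jumbled(seed = 12, target_present = TRUE),
                make_uniform_array(condition = "hard", seed = 13))
  for (s in stims) {
    ranges <- range_from_difficulty(s$cell_difficulty, s$mapping)
    centre <- s$target$orientation + pi / 2
    ok <- ori_in_range(s$orientations, centre, ranges)
    if (s$target$present) ok[s$target$cell[2] + 1, s$target$cell[1] + 1] <- TRUE
    expect_true(all(ok))
  }
})

test_that("target placement excludes the edge ring and central cells", {
  g <- exp2_grid()
  cells <- eligible_target_cells(g)
  # brute-force oracle
  oracle <- 0
  for (col in 0:31) for (row in 0:23) {
    edge <- col %in% c(0, 31) || row %in% c(0, 23)
    central <- col %in% c(15, 16) && row %in% c(11, 12)
    if (!edge && !central) oracle <- oracle + 1
  }
  expect_equal(nrow(cells), oracle)
  expect_equal(oracle, 656)

  expect_error(place_target(grid_spec(3, 3)), "eligible")

  # uniformity over eligible cells (chi-square GOF at alpha = 0.01)
  set.seed(9)
  g4 <- grid_spec(6, 5, cell_px = 8, screen_px = c(48, 40))
  elig <- eligible_target_cells(g4)
  draws <- replicate(10000, {
    t <- place_target(g4)
    paste(t$cell, collapse = ",")
  })
  counts <- table(factor(draws, levels = paste(elig$col, elig$row, sep = ",")))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("rendering writes deterministic PNGs of the screen extent", {
  s <- make_split_half(seed = 21)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_stimulus(s, f1)
  render_stimulus(s, f2)
  b <- readBin(f1, "raw", 33)
  expect_identical(b[2:4], as.raw(c(0x50, 0x4E, 0x47)))       # "PNG"
  dims <- c(sum(as.integer(b[17:20]) * 256^(3:0)),            # IHDR width
            sum(as.integer(b[21:24]) * 256^(3:0)))            # IHDR height
  expect_equal(dims, c(1024, 768))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # metadata export round-trips the defining fields
  jf <- tempfile(fileext = ".json")
  write_stimulus_json(s, jf)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(meta$condition, "split_half")
  expect_equal(meta$grid$n_cols, 22)
  expect_equal(matrix(meta$orientations, 16, 22), s$orientations,
               tolerance = 1e-12)
})
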