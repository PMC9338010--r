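# Stimulus generation: oriented line-segment search arrays.
#
# Coordinate conventions used throughout the package:
#   * pixel origin at the top-left of the screen, x rightward, y downward;
#   * cell indices 0-based, addressed as (col, row);
#   * orientations in radians, counter-clockwise from horizontal-rightward,
#     stored modulo pi (line segments are unoriented).

#' Grid geometry of a search array
#'
#' Describes the rectangular grid of cells making up a search array: its cell
#' counts, the pixel size of each (square) cell, the screen it is shown on and
#' the pixel offset of the array's top-left corner. By default the array is
#' centred on the screen.
#'
#' @param n_cols,n_rows number of cell columns / rows (each at least 2).
#' @param cell_px side length of one square cell, in pixels.
#' @param screen_px screen extent `c(width, height)` in pixels.
#' @param origin_px pixel offset `c(x, y)` of the array's top-left corner;
#'   `NULL` (default) centres the array on the screen.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(22, 16)                       # 22 x 16 array on a 1024 x 768 screen
#' grid_spec(32, 24, screen_px = c(1280, 1024))
#' @export
grid_spec <- function(n_cols, n_rows, cell_px = 32,
                      screen_px = c(1024, 768), origin_px = NULL) {
  stop_if_not_scalar(n_cols, "n_cols", lower = 2)
  stop_if_not_scalar(n_rows, "n_rows", lower = 2)
  stop_if_not_scalar(cell_px, "cell_px", lower = 1)
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  extent <- c(n_cols, n_rows) * cell_px
  if (is.null(origin_px)) origin_px <- (screen_px - extent) / 2
  structure(
    list(n_cols = n_cols, n_rows = n_rows, cell_px = cell_px,
         screen_px = as.numeric(screen_px), origin_px = as.numeric(origin_px)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g px, array %g x %g px at (%g, %g) on %g x %g screen\n",
              x$n_cols, x$n_rows, x$cell_px,
              x$n_cols * x$cell_px, x$n_rows * x$cell_px,
              x$origin_px[1], x$origin_px[2], x$screen_px[1], x$screen_px[2]))
  invisible(x)
}

# Array extent c(width, height) in pixels.
grid_extent_px <- function(grid) c(grid$n_cols, grid$n_rows) * grid$cell_px

# Pixel centre of cell (col, row), 0-based; vectorised.
cell_center_px <- function(grid, col, row) {
  cbind(x = grid$origin_px[1] + (col + 0.5) * grid$cell_px,
        y = grid$origin_px[2] + (row + 0.5) * grid$cell_px)
}

# Cell containing pixel (x, y) under the half-open convention; coordinates
# outside the array give NA. Returns cbind(col, row), 0-based.
px_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_px[1]) / grid$cell_px)
  row <- floor((y - grid$origin_px[2]) / grid$cell_px)
  bad <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  col[bad] <- NA_real_; row[bad] <- NA_real_
  cbind(col = col, row = row)
}

#' Mapping from local difficulty to distractor orientation range
#'
#' Local difficulty `d` in \[0, 1\] is mapped linearly to the full width of the
#' uniform distribution from which distractor orientations are drawn: `d = 0`
#' gives `range_min` (homogeneous, target visible peripherally) and `d = 1`
#' gives `range_max` (heterogeneous, target needs central vision).
#'
#' @param range_min,range_max orientation ranges (radians) at difficulty 0 and
#'   1. Defaults pi/6 and 2*pi/3.
#' @return An object of class `orientation_range_mapping`.
#' @export
orientation_range_mapping <- function(range_min = pi / 6, range_max = 2 * pi / 3) {
  stop_if_not_scalar(range_min, "range_min", lower = 1e-12, upper = pi)
  stop_if_not_scalar(range_max, "range_max", lower = 1e-12, upper = pi)
  if (!(range_min < range_max)) stop("`range_min` must be < `range_max`", call. = FALSE)
  structure(list(range_min = range_min, range_max = range_max),
            class = "orientation_range_mapping")
}

#' Linear difficulty-to-range interpolation
#'
#' @param d difficulty value(s) in \[0, 1\].
#' @param mapping an [orientation_range_mapping()].
#' @return Orientation range(s) in radians, same shape as `d`.
#' @export
range_from_difficulty <- function(d, mapping = orientation_range_mapping()) {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    stop("difficulty values must lie in [0, 1]", call. = FALSE)
  }
  mapping$range_min + d * (mapping$range_max - mapping$range_min)
}

#' Generate a 1/f^exponent noise field
#'
#' Builds a random spatial field by inverse Fourier transform of an amplitude
#' spectrum proportional to `1/f^exponent` with independent uniform random
#' phases (obtained by normalising the spectrum of Gaussian white noise to
#' unit amplitude, which keeps the spectrum Hermitian so the inverse transform
#' is real). The field is generated on a `gen_px` x `gen_px` square (a power
#' of two, friendly to the FFT), cropped to `size_px`, and min-max scaled to
#' \[0, 1\]. The DC amplitude is set to zero (the overall mean carries no
#' spatial information and is removed by the scaling anyway).
#'
#' @param size_px requested field extent `c(width, height)` in pixels; both
#'   must be positive and no larger than `gen_px`.
#' @param exponent spectral exponent; 2 (the default) gives 1/f^2 noise, 0
#'   gives white noise.
#' @param seed optional integer seed; the same seed reproduces the field
#'   bit-exactly. `NULL` uses the current RNG stream.
#' @param gen_px generation dimension (default 1024).
#' @return An object of class `difficulty_map`: a list with `values` (a
#'   `height x width` matrix, `values[y, x]`), `width_px` and `height_px`.
#' @export
generate_noise_field <- function(size_px = c(1024, 768), exponent = 2,
                                 seed = NULL, gen_px = 1024) {
  width <- size_px[1]; height <- size_px[2]
  if (width <= 0 || height <= 0) stop("field dimensions must be positive", call. = FALSE)
  if (width > gen_px || height > gen_px) {
    stop(sprintf("requested size exceeds the %d px generation dimension", gen_px),
         call. = FALSE)
  }
  values <- with_seed_opt(seed, {
    white <- matrix(stats::rnorm(gen_px * gen_px), gen_px, gen_px)
    spec <- stats::fft(white)
    mod <- Mod(spec)
    mod[mod == 0] <- 1               # guard; probability-zero event
    phase <- spec / mod              # unit amplitude, uniform phases, Hermitian
    fr <- c(0:(gen_px / 2), seq.int(gen_px / 2 - 1, 1)) / gen_px
    f2 <- outer(fr^2, fr^2, `+`)
    amp <- 1 / sqrt(f2)^exponent
    amp[1, 1] <- 0
    field <- Re(stats::fft(phase * amp, inverse = TRUE)) / (gen_px^2)
    field[seq_len(height), seq_len(width), drop = FALSE]
  })
  rng <- range(values)
  values <- if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1]) else values * 0 + 0.5
  difficulty_map(values)
}

#' @rdname generate_noise_field
#' @param values a numeric matrix of per-pixel difficulties, `values[y, x]`.
#' @export
difficulty_map <- function(values) {
  if (!is.matrix(values) || length(values) == 0L) {
    stop("`values` must be a non-empty matrix", call. = FALSE)
  }
  structure(list(values = values, width_px = ncol(values), height_px = nrow(values)),
            class = "difficulty_map")
}

#' Histogram-equalise a field to the U-shaped parabolic reference
#'
#' Rank-transforms the pixels of a difficulty field to fractional ranks
#' `u = (rank - 0.5) / n` (ties broken by stable ordering on pixel index,
#' column-major) and pushes them through the inverse CDF of the U-shaped
#' parabolic density `f(x) = 3 (2x - 1)^2` on \[0, 1\], whose CDF is
#' `F(x) = ((2x - 1)^3 + 1) / 2`. The result has (up to rank discreteness) the
#' parabolic distribution regardless of the input distribution, concentrating
#' pixels near 0 and 1 so that distinctly homogeneous and heterogeneous
#' regions emerge.
#'
#' @param map a `difficulty_map`.
#' @return A `difficulty_map` of the same extent with equalised values.
#' @export
equalize_to_parabola <- function(map) {
  stopifnot(inherits(map, "difficulty_map"))
  x <- as.vector(map$values)
  if (any(!is.finite(x))) stop("map values must be finite", call. = FALSE)
  n <- length(x)
  u <- (rank(x, ties.method = "first") - 0.5) / n
  out <- parabola_quantile(u)
  difficulty_map(matrix(out, nrow = map$height_px, ncol = map$width_px))
}

#' @rdname equalize_to_parabola
#' @param q probabilities / quantile arguments in \[0, 1\].
#' @details `parabola_cdf()` and `parabola_quantile()` expose the reference
#'   CDF `F` and its inverse for testing and plotting.
#' @export
parabola_cdf <- function(q) ((2 * q - 1)^3 + 1) / 2

#' @rdname equalize_to_parabola
#' @export
parabola_quantile <- function(q) {
  s <- 2 * q - 1
  (1 + sign(s) * abs(s)^(1 / 3)) / 2
}

#' Per-cell difficulty from a per-pixel map
#'
#' Aggregates a pixel-level difficulty field to the cell grid by averaging the
#' map over each cell's `cell_px` x `cell_px` block.
#'
#' @param map a `difficulty_map` whose extent equals the grid's pixel extent.
#' @param grid a [grid_spec()].
#' @return An `n_rows x n_cols` matrix of cell difficulties in \[0, 1\].
#' @export
cell_difficulties <- function(map, grid) {
  stopifnot(inherits(map, "difficulty_map"), inherits(grid, "grid_spec"))
  extent <- grid_extent_px(grid)
  if (map$width_px != extent[1] || map$height_px != extent[2]) {
    stop(sprintf("map extent %d x %d does not match grid extent %g x %g",
                 map$width_px, map$height_px, extent[1], extent[2]), call. = FALSE)
  }
  a <- array(map$values, dim = c(grid$cell_px, grid$n_rows, grid$cell_px, grid$n_cols))
  apply(a, c(2, 4), mean)
}

#' Target specification
#'
#' @param present logical; is a target in the array?
#' @param cell 0-based `c(col, row)` of the target cell, or `NULL` when absent.
#' @param orientation target orientation theta in radians (default pi/4,
#'   i.e. 45 degrees to the right).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(present = FALSE, cell = NULL, orientation = pi / 4) {
  if (present) {
    stopifnot(is.numeric(cell), length(cell) == 2L)
    cell <- as.integer(cell)
  } else {
    cell <- NULL
  }
  structure(list(present = isTRUE(present), cell = cell,
                 orientation = orientation %% pi),
            class = "target_spec")
}

#' Cells where a target may be placed
#'
#' A target may not sit on the outermost ring of cells nor on the central
#' cells of the array (the four centre cells for even-by-even grids). An
#' optional logical mask restricts eligibility further (e.g. to one half of a
#' split-half array).
#'
#' @param grid a [grid_spec()].
#' @param restrict optional `n_rows x n_cols` logical matrix; only `TRUE`
#'   cells remain eligible.
#' @return A data frame with 0-based columns `col` and `row`, one row per
#'   eligible cell, in column-major cell order.
#' @export
eligible_target_cells <- function(grid, restrict = NULL) {
  nc <- grid$n_cols; nr <- grid$n_rows
  col <- rep(0:(nc - 1), each = nr)
  row <- rep(0:(nr - 1), times = nc)
  edge <- col == 0 | col == nc - 1 | row == 0 | row == nr - 1
  c_cols <- unique(c(floor((nc - 1) / 2), ceiling((nc - 1) / 2)))
  c_rows <- unique(c(floor((nr - 1) / 2), ceiling((nr - 1) / 2)))
  central <- col %in% c_cols & row %in% c_rows
  ok <- !edge & !central
  if (!is.null(restrict)) {
    stopifnot(is.logical(restrict), nrow(restrict) == nr, ncol(restrict) == nc)
    ok <- ok & restrict[cbind(row + 1L, col + 1L)]
  }
  data.frame(col = col[ok], row = row[ok])
}

#' Place a target uniformly over eligible cells
#'
#' @inheritParams eligible_target_cells
#' @param orientation target orientation theta (radians).
#' @return A [target_spec()] with `present = TRUE`.
#' @export
place_target <- function(grid, restrict = NULL, orientation = pi / 4) {
  cells <- eligible_target_cells(grid, restrict)
  if (nrow(cells) == 0L) {
    stop("no eligible target cell: grid too small or restriction too tight",
         call. = FALSE)
  }
  i <- sample.int(nrow(cells), 1L)
  target_spec(TRUE, cell = c(cells$col[i], cells$row[i]), orientation = orientation)
}

#' Sample distractor orientations for a grid of ranges
#'
#' Each non-target cell gets an orientation drawn from a uniform distribution
#' of full width equal to its cell's range, centred on `theta + pi/2`
#' (perpendicular to the target); the target cell, if present, is set to
#' `theta` exactly. Orientations are reduced modulo pi.
#'
#' @param cell_ranges `n_rows x n_cols` matrix of orientation ranges (radians).
#' @param target a [target_spec()].
#' @return An `n_rows x n_cols` matrix of orientations in \[0, pi).
#' @export
sample_orientation_grid <- function(cell_ranges, target = target_spec()) {
  stopifnot(is.matrix(cell_ranges))
  centre <- target$orientation + pi / 2
  n <- length(cell_ranges)
  ori <- (centre + (stats::runif(n) - 0.5) * as.vector(cell_ranges)) %% pi
  ori <- matrix(ori, nrow = nrow(cell_ranges), ncol = ncol(cell_ranges))
  if (target$present) {
    ori[target$cell[2] + 1L, target$cell[1] + 1L] <- target$orientation %% pi
  }
  ori
}

new_stimulus_array <- function(grid, cell_difficulty, condition, configuration,
                               target, mapping, seed) {
  structure(
    list(grid = grid,
         cell_difficulty = cell_difficulty,
         orientations = NULL,           # filled by caller
         condition = condition,
         configuration = configuration,
         target = target,
         mapping = mapping,
         seed = seed),
    class = "stimulus_array")
}

finish_stimulus <- function(stim) {
  ranges <- range_from_difficulty(stim$cell_difficulty, stim$mapping)
  stim$orientations <- sample_orientation_grid(ranges, stim$target)
  stim
}

#' @export
print.stimulus_array <- function(x, ...) {
  tgt <- if (x$target$present) {
    sprintf("target at cell (%d, %d)", x$target$cell[1], x$target$cell[2])
  } else "target absent"
  cat(sprintf("<stimulus_array> condition '%s' (%s), %d x %d cells, %s\n",
              x$condition, x$configuration %||% "none",
              x$grid$n_cols, x$grid$n_rows, tgt))
  invisible(x)
}

# Logical mask (n_rows x n_cols) of one half of the grid.
half_mask <- function(grid, axis, which_side) {
  nc <- grid$n_cols; nr <- grid$n_rows
  m <- matrix(FALSE, nr, nc)
  if (axis == "horizontal") {
    rows <- if (which_side == "up") seq_len(nr / 2) else (nr / 2 + 1):nr
    m[rows, ] <- TRUE
  } else {
    cols <- if (which_side == "left") seq_len(nc / 2) else (nc / 2 + 1):nc
    m[, cols] <- TRUE
  }
  m
}

#' Generate a split-half search array
#'
#' One half of the array (split along the requested axis) is heterogeneous --
#' every cell at difficulty 1 (orientation range `range_max`) -- and the other
#' homogeneous (difficulty 0, range `range_min`). A target, if requested, is
#' placed uniformly at random within the requested half, excluding the edge
#' ring and the central cells.
#'
#' @param grid a [grid_spec()]; the cell count along the split axis must be
#'   even. Default: the 22 x 16 array.
#' @param axis `"horizontal"` (upper/lower halves) or `"vertical"`
#'   (left/right halves).
#' @param hard_side which side is heterogeneous: `"up"`/`"down"` for the
#'   horizontal axis, `"left"`/`"right"` for the vertical axis.
#' @param target_half `"absent"`, `"easy"` (homogeneous half) or `"hard"`.
#' @param mapping an [orientation_range_mapping()].
#' @param theta target orientation (radians).
#' @param seed optional integer seed for bit-exact reproducibility.
#' @return A `stimulus_array` with condition `"split_half"` and configuration
#'   `"hard_<side>"`.
#' @export
make_split_half <- function(grid = grid_spec(22, 16),
                            axis = c("horizontal", "vertical"),
                            hard_side = NULL,
                            target_half = c("absent", "easy", "hard"),
                            mapping = orientation_range_mapping(),
                            theta = pi / 4, seed = NULL) {
  axis <- match.arg(axis)
  target_half <- match.arg(target_half)
  sides <- if (axis == "horizontal") c("up", "down") else c("left", "right")
  hard_side <- hard_side %||% sides[1]
  if (!hard_side %in% sides) {
    stop(sprintf("hard_side '%s' inconsistent with axis '%s'", hard_side, axis),
         call. = FALSE)
  }
  n_axis <- if (axis == "horizontal") grid$n_rows else grid$n_cols
  if (n_axis %% 2 != 0) stop("cell count along the split axis must be even", call. = FALSE)
  with_seed_opt(seed, {
    hard <- half_mask(grid, axis, hard_side)
    diffc <- matrix(0, grid$n_rows, grid$n_cols)
    diffc[hard] <- 1
    target <- if (target_half == "absent") {
      target_spec(FALSE, orientation = theta)
    } else {
      place_target(grid, restrict = if (target_half == "hard") hard else !hard,
                   orientation = theta)
    }
    stim <- new_stimulus_array(grid, diffc, "split_half",
                               paste0("hard_", hard_side), target, mapping, seed)
    finish_stimulus(stim)
  })
}

#' Generate a uniformly easy or hard search array
#'
#' All cells share difficulty 0 (`"easy"`) or 1 (`"hard"`).
#'
#' @inheritParams make_split_half
#' @param condition `"easy"` or `"hard"`.
#' @param target_present logical.
#' @export
make_uniform_array <- function(grid = grid_spec(32, 24, screen_px = c(1280, 1024)),
                               condition = c("easy", "hard"),
                               target_present = FALSE,
                               mapping = orientation_range_mapping(),
                               theta = pi / 4, seed = NULL) {
  condition <- match.arg(condition)
  with_seed_opt(seed, {
    d <- if (condition == "hard") 1 else 0
    diffc <- matrix(d, grid$n_rows, grid$n_cols)
    target <- if (target_present) place_target(grid, orientation = theta)
              else target_spec(FALSE, orientation = theta)
    finish_stimulus(new_stimulus_array(grid, diffc, condition, NULL, target,
                                       mapping, seed))
  })
}

#' Generate a jumbled search array from a 1/f^2 difficulty map
#'
#' Composes the full jumbled-stimulus pipeline: a 1/f^2 random-phase noise
#' field is generated at 1024 x 1024, cropped to the array extent, histogram
#' equalised to the parabolic reference, averaged per cell, mapped linearly to
#' orientation ranges, and sampled into an orientation grid. A target, if
#' requested, avoids the edge ring and the central cells.
#'
#' @inheritParams make_uniform_array
#' @param exponent spectral exponent of the noise field (default 2).
#' @return A `stimulus_array` with condition `"jumbled"`.
#' @export
make_jumbled <- function(grid = grid_spec(32, 24, screen_px = c(1280, 1024)),
                         mapping = orientation_range_mapping(),
                         target_present = FALSE, exponent = 2,
                         theta = pi / 4, seed = NULL) {
  with_seed_opt(seed, {
    field <- generate_noise_field(grid_extent_px(grid), exponent = exponent)
    field <- equalize_to_parabola(field)
    diffc <- cell_difficulties(field, grid)
    target <- if (target_present) place_target(grid, orientation = theta)
              else target_spec(FALSE, orientation = theta)
    finish_stimulus(new_stimulus_array(grid, diffc, "jumbled", NULL, target,
                                       mapping, seed))
  })
}

#' Render a stimulus to a PNG image
#'
#' Draws the array centred in the screen extent: one black line segment
#' through each cell centre at the cell's orientation, on a uniform grey
#' background. With fixed style the output file is byte-reproducible.
#'
#' @param stim a `stimulus_array`.
#' @param path output PNG path.
#' @param line_len segment length in pixels (default 0.7 cell).
#' @param line_lwd line width.
#' @param bg background colour.
#' @return `path`, invisibly.
#' @export
render_stimulus <- function(stim, path, line_len = 0.7 * stim$grid$cell_px,
                            line_lwd = 2, bg = "grey60") {
  grid <- stim$grid
  grDevices::png(path, width = grid$screen_px[1], height = grid$screen_px[2],
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i", bg = bg)
  graphics::plot.new()
  # screen coordinates: y axis points downward
  graphics::plot.window(xlim = c(0, grid$screen_px[1]), ylim = c(grid$screen_px[2], 0))
  col <- rep(0:(grid$n_cols - 1), each = grid$n_rows)
  row <- rep(0:(grid$n_rows - 1), times = grid$n_cols)
  ctr <- cell_center_px(grid, col, row)
  a <- as.vector(stim$orientations)           # column-major matches (row, col) pairing
  ori <- a[(col * grid$n_rows) + row + 1L]
  dx <- cos(ori) * line_len / 2
  dy <- -sin(ori) * line_len / 2               # minus: CCW orientation, y-down screen
  graphics::segments(ctr[, "x"] - dx, ctr[, "y"] - dy,
                     ctr[, "x"] + dx, ctr[, "y"] + dy,
                     lwd = line_lwd, col = "black", lend = "butt")
  invisible(path)
}

#' Export stimulus metadata as JSON
#'
#' Writes the grid specification, seed, condition, configuration, target cell
#' and the per-cell difficulty and orientation arrays in a machine-readable
#' form that fully determines the stimulus.
#'
#' @param stim a `stimulus_array`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_stimulus_json <- function(stim, path) {
  meta <- list(
    grid = stim$grid[c("n_cols", "n_rows", "cell_px", "screen_px", "origin_px")],
    condition = stim$condition,
    configuration = stim$configuration,
    seed = stim$seed,
    target = list(present = stim$target$present,
                  cell = stim$target$cell,
                  orientation = stim$target$orientation),
    cell_difficulty = stim$cell_difficulty,
    orientations = stim$orientations)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stimulus_json
#' @details `read_stimulus_json()` restores a `stimulus_array` written by
#'   `write_stimulus_json()` (round trip up to numeric serialisation).
#' @export
read_stimulus_json <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- meta$grid
  grid <- grid_spec(g$n_cols, g$n_rows, cell_px = g$cell_px,
                    screen_px = g$screen_px, origin_px = g$origin_px)
  target <- target_spec(isTRUE(meta$target$present),
                        cell = meta$target$cell,
                        orientation = meta$target$orientation %||% pi / 4)
  stim <- new_stimulus_array(
    grid,
    matrix(meta$cell_difficulty, g$n_rows, g$n_cols),
    meta$condition,
    meta$configuration,
    target,
    orientation_range_mapping(),
    meta$seed)
  stim$orientations <- matrix(meta$orientations, g$n_rows, g$n_cols)
  stim
}
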