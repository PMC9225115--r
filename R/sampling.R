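#' Acquisition protocol
#'
#' Spin-lock times and sampling geometry of a multi-contrast T1rho
#' acquisition.
#'
#' @param tsl numeric vector of spin-lock times in ms; non-negative,
#'   strictly increasing, with at least one positive entry. One contrast is
#'   acquired per spin-lock time.
#' @param matrix_size image side in pixels (even).
#' @param scheme `"radial"` or `"cartesian"`.
#' @param af nominal acceleration factor (full data points / used data
#'   points), `>= 1`.
#' @return an object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(tsl, matrix_size, scheme = c("radial", "cartesian"),
                                 af = 1) {
  scheme <- match.arg(scheme)
  tsl <- as.numeric(tsl)
  matrix_size <- as.integer(matrix_size)
  stopifnot(length(tsl) >= 1L, all(tsl >= 0), !is.unsorted(tsl, strictly = TRUE),
            any(tsl > 0), matrix_size >= 2L, matrix_size %% 2L == 0L, af >= 1)
  structure(list(tsl = tsl, n_contrasts = length(tsl),
                 matrix_size = matrix_size, scheme = scheme, af = af),
            class = "acquisition_protocol")
}

#' Golden-angle increment (radians)
#'
#' The azimuthal increment between successive radial spokes,
#' `pi * (sqrt(5) - 1) / 2` (about 111.246 degrees), which gives
#' near-uniform angular coverage for any contiguous run of spokes.
#' @export
golden_angle <- function() pi * (sqrt(5) - 1) / 2

#' Full golden-angle radial sampling schedule
#'
#' Spoke `k` (0-based) has azimuth `k * golden_angle() mod pi`; each spoke is
#' a diametral line through the k-space origin sampled at `n_readout`
#' equispaced radii spanning `[-0.5, 0.5)` cycles/pixel. For a matrix of side
#' `n`, `round(n * pi / 2)` spokes meet the Nyquist criterion at the k-space
#' edge (302 spokes for a 192 matrix).
#'
#' @param n_spokes number of spokes (>= 1).
#' @param n_readout readout samples per spoke (>= 2).
#' @return an object of class `sampling_schedule` with `scheme = "radial"`,
#'   holding the spoke angles and, per contrast, the spoke indices in use
#'   (initially all spokes for every contrast) and trajectory coordinates.
#' @export
golden_angle_schedule <- function(n_spokes, n_readout) {
  n_spokes <- as.integer(n_spokes)
  n_readout <- as.integer(n_readout)
  stopifnot(n_spokes >= 1L, n_readout >= 2L)
  angles <- ((seq_len(n_spokes) - 1L) * golden_angle()) %% pi
  radii <- ((0:(n_readout - 1L)) - n_readout / 2) / n_readout   # cycles/pixel
  structure(list(scheme = "radial", n_spokes = n_spokes, n_readout = n_readout,
                 angles = angles, radii = radii,
                 spokes = list(seq_len(n_spokes))),   # one contrast: all spokes
            class = "sampling_schedule")
}

#' Nyquist spoke count for a radial acquisition
#'
#' @param matrix_size image side in pixels.
#' @return `round(matrix_size * pi / 2)`, the number of equispaced spokes
#'   whose outermost sample spacing meets the Nyquist criterion.
#' @export
nyquist_spokes <- function(matrix_size) as.integer(round(matrix_size * pi / 2))

#' Complementary radial subsampling across contrasts
#'
#' Splits a golden-angle spoke sequence into consecutive per-contrast
#' blocks: contrast `c` (1-based) receives spokes
#' `((c-1) * k + 1) : (c * k)` with `k = round(n_spokes / af)`, so no spoke
#' is reused across contrasts when `af > 1` (complementary sampling). When
#' the blocks run past the base schedule the golden-angle sequence is
#' simply continued (every spoke is a fresh angle, so complementarity is
#' preserved). With `af = 1` every contrast uses the full spoke set.
#'
#' @param schedule a radial [golden_angle_schedule()].
#' @param af acceleration factor (>= 1).
#' @param n_contrasts number of contrasts.
#' @return a `sampling_schedule` whose `spokes` field is a list of
#'   per-contrast spoke index vectors.
#' @export
radial_subsample <- function(schedule, af, n_contrasts) {
  stopifnot(inherits(schedule, "sampling_schedule"), schedule$scheme == "radial",
            af >= 1, n_contrasts >= 1)
  n_total <- schedule$n_spokes
  if (af == 1) {
    schedule$spokes <- rep(list(seq_len(n_total)), n_contrasts)
    schedule$af <- 1
    return(schedule)
  }
  per <- as.integer(round(n_total / af))
  if (per < 1L)
    stop("acceleration factor too high: fewer than one spoke per contrast")
  needed <- per * as.integer(n_contrasts)
  if (needed > n_total) {
    ## continue the golden-angle sequence beyond the base schedule
    extra <- ((n_total:(needed - 1L)) * golden_angle()) %% pi
    schedule$angles <- c(schedule$angles, extra)
    schedule$n_spokes <- needed
  }
  schedule$spokes <- lapply(seq_len(n_contrasts) - 1L,
                            function(c) c * per + seq_len(per))
  schedule$af <- af
  schedule
}

#' Complementary cartesian row sampling
#'
#' Row-wise cartesian undersampling: every contrast keeps a centred
#' contiguous block of `round(rows_per_contrast / 4)` rows containing the
#' zero-frequency row (0-based row `matrix_size / 2`), and the remaining
#' rows are split evenly between the top and bottom halves, drawn in random
#' order without replacement across contrasts so each outer row is used once
#' before any is reused.
#'
#' @param matrix_size image side in pixels (even).
#' @param af acceleration factor; `rows_per_contrast = round(matrix_size/af)`.
#' @param n_contrasts number of contrasts.
#' @param seed integer seed for the randomized outer-row draw.
#' @return a `sampling_schedule` with `scheme = "cartesian"` and a `rows`
#'   field: list of per-contrast sorted 0-based row indices.
#' @export
cartesian_schedule <- function(matrix_size, af, n_contrasts, seed = 1L) {
  matrix_size <- as.integer(matrix_size)
  stopifnot(matrix_size >= 4L, matrix_size %% 2L == 0L, af >= 1, n_contrasts >= 1)
  per <- as.integer(round(matrix_size / af))
  if (per < 2L) stop("acceleration factor too high: fewer than two rows per contrast")
  per <- min(per, matrix_size)

  zf <- matrix_size %/% 2L                       # 0-based zero-frequency row
  n_centre <- max(1L, as.integer(round(per / 4)))
  n_centre <- min(n_centre, per)
  start <- zf - (n_centre - 1L) %/% 2L
  centre <- start + 0:(n_centre - 1L)
  stopifnot(zf %in% centre, all(centre >= 0), all(centre < matrix_size))

  n_rest <- per - n_centre
  top_pool <- setdiff(0:(start - 1L), centre)
  bot_pool <- setdiff((start + n_centre):(matrix_size - 1L), centre)
  n_top <- n_rest %/% 2L
  n_bot <- n_rest - n_top
  if (n_top != n_bot && length(top_pool) >= length(bot_pool)) {
    n_top <- n_rest - n_rest %/% 2L    # odd remainder goes to the larger half
    n_bot <- n_rest - n_top
  }
  ## near full sampling one half may be smaller than its quota: spill over
  if (n_top > length(top_pool)) {
    n_bot <- n_bot + n_top - length(top_pool); n_top <- length(top_pool)
  }
  if (n_bot > length(bot_pool)) {
    n_top <- n_top + n_bot - length(bot_pool); n_bot <- length(bot_pool)
  }
  stopifnot(n_top <= length(top_pool), n_bot <= length(bot_pool))

  shuf <- function(v) if (length(v) > 1L) sample(v) else v
  rows <- with_seed(seed, {
    draw <- function(pool, k, state) {
      ## draw k values without replacement from a shuffled pool, reshuffling
      ## when exhausted so every row is used once before any repeats; rows
      ## already drawn for the current contrast go to the back of a reshuffle
      out <- integer(0)
      while (k > 0L) {
        if (length(state$order) == 0L) {
          state$order <- c(shuf(setdiff(pool, out)),
                           shuf(intersect(pool, out)))
        }
        take <- min(k, length(state$order))
        out <- c(out, state$order[seq_len(take)])
        state$order <- state$order[-seq_len(take)]
        k <- k - take
      }
      out
    }
    top_state <- new.env(); top_state$order <- integer(0)
    bot_state <- new.env(); bot_state$order <- integer(0)
    lapply(seq_len(n_contrasts), function(c)
      sort(c(centre, draw(top_pool, n_top, top_state),
             draw(bot_pool, n_bot, bot_state))))
  })
  structure(list(scheme = "cartesian", matrix_size = matrix_size, af = af,
                 rows = rows, centre_rows = centre, seed = as.integer(seed),
                 rows_per_contrast = per, n_centre = n_centre),
            class = "sampling_schedule")
}
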