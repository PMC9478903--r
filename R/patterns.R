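#' Synthesize one Fourier basis pattern
#'
#' Builds the sinusoidal structured-detection pattern
#' \deqn{P_\phi(x,y;u,v) = 1/2 + 1/2\,\cos(2\pi u x/M + 2\pi v y/N + \phi)}
#' on an M x N pixel grid. Pixel coordinates are 0-based: x indexes rows
#' (0..M-1), y indexes columns (0..N-1), matching the DFT kernel used at
#' reconstruction.
#'
#' @param u,v Integer frequency coordinates, `0 <= u < M`, `0 <= v < N`
#'   (cycles across the rows / columns of the grid).
#' @param phase Initial phase in radians; must be one of [phase_steps()].
#' @param shape Integer vector `c(M, N)` giving the grid size in pixels.
#' @return An M x N numeric matrix with values in `[0, 1]`.
#' @examples
#' p <- fourier_pattern(1, 0, 0, c(8, 8))
#' range(p)
#' @export
fourier_pattern <- function(u, v, phase, shape) {
  shape <- check_shape(shape)
  check_freq(u, v, shape)
  if (!any(abs(phase - .phase_steps) < 1e-12)) {
    stop("'phase' must be one of 0, 2*pi/3, 4*pi/3 radians")
  }
  M <- shape[1]; N <- shape[2]
  x <- 0:(M - 1); y <- 0:(N - 1)
  0.5 + 0.5 * cos(outer(2 * pi * u * x / M, 2 * pi * v * y / N, "+") + phase)
}

#' Binarize a grayscale pattern by Floyd-Steinberg dithering
#'
#' Error-diffusion binarization for display on a binary spatial light
#' modulator (DMD). Uses the classic 7/16, 3/16, 5/16, 1/16 kernel in a
#' serpentine scan (left-to-right on even rows, right-to-left on odd rows,
#' 0-based), with the kernel mirrored along the scan direction and diffusion
#' error dropped at the grid borders. A pixel quantizes to 1 when its
#' accumulated value is `>= 0.5`. The procedure is deterministic and
#' idempotent on binary inputs, and preserves the pattern mean up to a
#' border-leakage term of order `(M + N) / (M * N)`.
#'
#' @param gray Numeric matrix with all values in `[0, 1]`.
#' @return A numeric matrix of the same shape with values in `{0, 1}`.
#' @examples
#' b <- dither(fourier_pattern(2, 3, 0, c(16, 16)))
#' sort(unique(as.vector(b)))
#' @export
dither <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray)) stop("'gray' must be a numeric matrix")
  if (anyNA(gray) || any(gray < 0 | gray > 1)) {
    stop("dither input must lie in [0, 1]")
  }
  cpp_dither_fs(gray)
}

# wrap-around ("centered") radial frequency
freq_radius <- function(u, v, shape) {
  sqrt(pmin(u, shape[1] - u)^2 + pmin(v, shape[2] - v)^2)
}

#' Conjugate coordinate of a frequency
#'
#' For a real scene the spectrum is Hermitian: the coefficient at
#' `(M - u mod M, N - v mod N)` is the complex conjugate of the one at
#' `(u, v)`, so only one member of each pair needs to be measured.
#'
#' @inheritParams fourier_pattern
#' @return Integer vector `c(u', v')` of the conjugate coordinate.
#' @export
conjugate_coord <- function(u, v, shape) {
  shape <- check_shape(shape)
  c((shape[1] - u) %% shape[1], (shape[2] - v) %% shape[2])
}

# TRUE when (u,v) is the canonical representative of its conjugate pair:
# keep the coordinate whose column index lies in the lower half-plane; on the
# self-mirrored columns (v == N-v mod N) fall back to u <= M-u mod M.
is_canonical <- function(u, v, shape) {
  M <- shape[1]; N <- shape[2]
  vc <- (N - v) %% N
  uc <- (M - u) %% M
  ifelse(v < vc, TRUE, ifelse(v > vc, FALSE, u <= uc))
}

#' Circular (low-frequency-first) Fourier sampling plan
#'
#' Selects Fourier coefficients in order of increasing centered radial
#' frequency `r(u,v) = sqrt(min(u, M-u)^2 + min(v, N-v)^2)` until the
#' requested fraction of the M*N spectrum is covered, keeping one canonical
#' representative per conjugate pair. By default coverage counts each
#' non-self-conjugate selection twice (itself plus the Hermitian-implied
#' conjugate), which is the convention under which a ratio of 1 covers the
#' full spectrum; set `count_conjugates = FALSE` to count only the displayed
#' coefficients. Ties in radius break by `(u, v)` lexicographic order, so
#' plans at smaller ratios are exact prefixes of plans at larger ratios.
#'
#' @param shape Integer `c(M, N)` grid size.
#' @param ratio Target sampling ratio in `(0, 1]`.
#' @param count_conjugates Logical; count Hermitian-implied conjugates toward
#'   coverage (default `TRUE`).
#' @return An object of class `fsi_plan`: a data frame with columns `index`,
#'   `u`, `v`, `radius`, `self_conjugate`, and attributes `shape`, `ratio`
#'   (achieved coverage), `target_ratio` and `strategy`.
#' @examples
#' plan <- circular_sampling_plan(c(96, 128), 0.14)
#' nrow(plan)
#' @export
circular_sampling_plan <- function(shape, ratio, count_conjugates = TRUE) {
  shape <- check_shape(shape)
  if (!is.numeric(ratio) || length(ratio) != 1 || is.na(ratio) ||
      ratio <= 0 || ratio > 1) {
    stop("'ratio' must be a single number in (0, 1]")
  }
  M <- shape[1]; N <- shape[2]
  g <- expand.grid(u = 0:(M - 1), v = 0:(N - 1))
  keep <- is_canonical(g$u, g$v, shape)
  g <- g[keep, , drop = FALSE]
  g$radius <- freq_radius(g$u, g$v, shape)
  self <- g$u == (M - g$u) %% M & g$v == (N - g$v) %% N
  g$self_conjugate <- as.integer(self)
  ord <- order(g$radius, g$u, g$v)
  g <- g[ord, , drop = FALSE]
  weight <- if (count_conjugates) ifelse(g$self_conjugate == 1, 1, 2) else rep(1, nrow(g))
  total <- if (count_conjugates) M * N else nrow(g)
  covered <- cumsum(weight)
  k <- which(covered >= ratio * total)[1]
  if (is.na(k)) k <- nrow(g)
  g <- g[seq_len(k), , drop = FALSE]
  g <- data.frame(index = seq_len(k) - 1L, u = g$u, v = g$v,
                  radius = g$radius, self_conjugate = g$self_conjugate)
  rownames(g) <- NULL
  structure(g,
            shape = shape,
            ratio = covered[k] / total,
            target_ratio = ratio,
            count_conjugates = count_conjugates,
            strategy = "circular",
            class = c("fsi_plan", "data.frame"))
}

#' @export
print.fsi_plan <- function(x, ...) {
  sh <- attr(x, "shape")
  cat(sprintf("<fsi_plan> %s strategy, %d coefficients on %dx%d grid (coverage %.4f)\n",
              attr(x, "strategy"), nrow(x), sh[1], sh[2], attr(x, "ratio")))
  invisible(x)
}

#' Three-step phase triplet of patterns for one coefficient
#'
#' Returns the three phase-shifted basis patterns (phases 0, 2*pi/3,
#' 4*pi/3) for the Fourier coefficient at `(u, v)`, both as grayscale
#' sinusoids and as Floyd-Steinberg binarized versions; one coefficient
#' therefore costs three displayed patterns, so a plan of K coefficients
#' yields 3K patterns.
#'
#' @inheritParams fourier_pattern
#' @return An object of class `fsi_triplet`: a list with `freq`, `shape`,
#'   `grayscale` (list of 3 matrices) and `binary` (list of 3 matrices).
#' @export
triplet_for <- function(u, v, shape) {
  shape <- check_shape(shape)
  check_freq(u, v, shape)
  gs <- lapply(.phase_steps, function(ph) fourier_pattern(u, v, ph, shape))
  structure(list(freq = c(u = u, v = v), shape = shape,
                 grayscale = gs, binary = lapply(gs, dither)),
            class = "fsi_triplet")
}

#' @export
print.fsi_triplet <- function(x, ...) {
  cat(sprintf("<fsi_triplet> (u=%d, v=%d) on %dx%d grid: 3 grayscale + 3 binary patterns\n",
              x$freq[["u"]], x$freq[["v"]], x$shape[1], x$shape[2]))
  invisible(x)
}

#' Write / read a sampling plan as CSV
#'
#' The CSV holds columns `index`, `u`, `v`, `radius`, `self_conjugate`; grid
#' shape, strategy and coverage travel in a JSON sidecar named
#' `<path>.meta.json`.
#'
#' @param plan An `fsi_plan`.
#' @param path Output CSV path.
#' @return `write_plan_csv` returns `path` invisibly; `read_plan_csv`
#'   returns the restored `fsi_plan`.
#' @export
write_plan_csv <- function(plan, path) {
  stopifnot(inherits(plan, "fsi_plan"))
  write.csv(as.data.frame(plan), path, row.names = FALSE)
  meta <- list(shape = attr(plan, "shape"), ratio = attr(plan, "ratio"),
               target_ratio = attr(plan, "target_ratio"),
               count_conjugates = attr(plan, "count_conjugates"),
               strategy = attr(plan, "strategy"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_csv
#' @export
read_plan_csv <- function(path) {
  g <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(g, shape = as.integer(meta$shape), ratio = meta$ratio,
            target_ratio = meta$target_ratio,
            count_conjugates = isTRUE(meta$count_conjugates),
            strategy = meta$strategy,
            class = c("fsi_plan", "data.frame"))
}

#' Export a pattern as an 8-bit PNG or plain PGM image
#'
#' Grayscale values are scaled by 255 and rounded; binary patterns map to
#' \{0, 255\}. Format follows the file extension (`.png` or `.pgm`).
#'
#' @param pattern Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_pattern_image <- function(pattern, path) {
  stopifnot(is.matrix(pattern), all(pattern >= 0 & pattern <= 1))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pattern, path)
  } else if (ext == "pgm") {
    write_pgm(round(pattern * 255), path, maxval = 255)
  } else {
    stop("unsupported pattern image format: ", ext)
  }
  invisible(path)
}

# validation helpers shared across modules -----------------------------------

check_shape <- function(shape) {
  if (length(shape) != 2 || anyNA(shape) || any(shape < 1) ||
      any(shape != round(shape))) {
    stop("'shape' must be two positive integers c(M, N)")
  }
  as.integer(shape)
}

check_freq <- function(u, v, shape) {
  if (length(u) != 1 || length(v) != 1 || anyNA(c(u, v)) ||
      u != round(u) || v != round(v) ||
      u < 0 || u >= shape[1] || v < 0 || v >= shape[2]) {
    stop(sprintf("frequency coordinate (u=%s, v=%s) out of range for %dx%d grid",
                 format(u), format(v), shape[1], shape[2]))
  }
  invisible(NULL)
}

# plain-text (P2) PGM writer; pixel rows of the matrix become image rows
write_pgm <- function(img, path, maxval = 255) {
  img <- round(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(img, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(toks[1] == "P2")
  vals <- as.numeric(toks[-1])
  w <- vals[1]; h <- vals[2]
  matrix(vals[-(1:3)], nrow = h, ncol = w, byrow = TRUE)
}
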