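#' Construct a scene (nonnegative intensity raster)
#'
#' A scene is the object image seen by the structured-detection system: a
#' nonnegative intensity raster with a physical pixel pitch and a modality
#' tag. Rows index the x (vertical) axis, columns the y (horizontal) axis.
#'
#' @param intensity Nonnegative, finite numeric matrix.
#' @param pitch Pixel pitch in object space, mm per pixel (default 0.52).
#' @param modality `"xray"` or `"fluorescence"`.
#' @return An `fsi_scene`: the matrix with `pitch` and `modality` attributes.
#' @export
fsi_scene <- function(intensity, pitch = 0.52, modality = c("xray", "fluorescence")) {
  modality <- match.arg(modality)
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("'intensity' must be a numeric matrix")
  }
  if (anyNA(intensity) || any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("scene intensities must be finite and nonnegative")
  }
  stopifnot(pitch > 0)
  structure(intensity, pitch = pitch, modality = modality,
            class = c("fsi_scene", "matrix", "array"))
}

#' @export
print.fsi_scene <- function(x, ...) {
  cat(sprintf("<fsi_scene> %s, %dx%d px @ %.3g mm/px, intensity [%.4g, %.4g]\n",
              attr(x, "modality"), nrow(x), ncol(x), attr(x, "pitch"),
              min(x), max(x)))
  invisible(x)
}

#' Detector noise model
#'
#' The bucket-detector response carries a single additive noise term; this
#' model splits it into the components relevant to three-step phase
#' shifting: an ambient offset that is constant across the three phase
#' measurements of a triplet (and which the triplet combination cancels
#' exactly), zero-mean Gaussian read noise independent per measurement, and
#' optional Poisson shot noise on the signal itself.
#'
#' @param gaussian_sigma Standard deviation of per-measurement Gaussian
#'   noise, detector units (default 0).
#' @param ambient_offset Constant offset added to every response, detector
#'   units (default 0).
#' @param poisson Logical; replace each noiseless response D by a Poisson
#'   draw with mean D before adding the other terms (default `FALSE`).
#' @param seed Optional integer; when given, acquisition is reproducible.
#' @return An object of class `fsi_noise`.
#' @export
noise_model <- function(gaussian_sigma = 0, ambient_offset = 0,
                        poisson = FALSE, seed = NULL) {
  stopifnot(gaussian_sigma >= 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 ambient_offset = ambient_offset,
                 poisson = isTRUE(poisson), seed = seed),
            class = "fsi_noise")
}

# phantom configurations ------------------------------------------------------

#' Phantom configurations
#'
#' Configuration constructors for the three built-in phantoms: an absorbing
#' wire on a bright field (x-ray transmission), a serial-dilution well row
#' (fluorescence sensitivity), and a tube at depth in a scattering medium
#' (fluorescence imaging depth).
#'
#' @param diameter Wire or tube diameter in mm.
#' @param orientation Wire axis angle in degrees from the horizontal (column)
#'   axis.
#' @param optical_depth Attenuation coefficient times the center-chord path
#'   length (dimensionless); transmission through the wire center is
#'   `exp(-optical_depth)`.
#' @param background Background transmission level (fraction of incident).
#' @param offset Perpendicular offset of the wire axis from the field
#'   center, mm (default 0).
#' @return A config list of the corresponding class.
#' @export
wire_phantom <- function(diameter = 0.4, orientation = 0,
                         optical_depth = 4.6, background = 1, offset = 0) {
  stopifnot(diameter > 0, background >= 0, optical_depth >= 0)
  structure(list(diameter = diameter, orientation = orientation,
                 optical_depth = optical_depth, background = background,
                 offset = offset),
            class = "fsi_wire_config")
}

#' @rdname wire_phantom
#' @param concentrations Fluorophore concentrations in nmol/ml, one per well
#'   (0 = blank). Default: the serial 2x dilution 11.86, 5.93, 2.97, 1.48,
#'   0.74 nmol/ml plus pure water.
#' @param centers Optional 2-column matrix of well centers in pixels
#'   (row, col); defaults to an evenly spaced row across the field middle.
#' @param radius Well radius in pixels.
#' @param gain Emitted intensity per unit concentration (detector units per
#'   nmol/ml).
#' @param ascending Logical; place wells left to right in ascending
#'   concentration (blank leftmost), the layout used for sensitivity tests.
#' @export
dilution_phantom <- function(concentrations = c(11.86, 5.93, 2.97, 1.48, 0.74, 0),
                             centers = NULL, radius = 6, gain = 1,
                             ascending = TRUE) {
  stopifnot(all(concentrations >= 0), radius > 0, gain >= 0)
  structure(list(concentrations = concentrations, centers = centers,
                 radius = radius, gain = gain, ascending = isTRUE(ascending)),
            class = "fsi_dilution_config")
}

#' @rdname wire_phantom
#' @param depth Tube depth below the medium surface, mm.
#' @param mu_a Absorption coefficient of the medium, cm^-1.
#' @param mu_s_prime Reduced scattering coefficient, cm^-1.
#' @param emission Tube emission strength at zero depth (detector units).
#' @param blur Logical; apply the depth-proportional lateral Gaussian spread
#'   (sigma = 0.5 * depth mm) that emulates diffusive broadening.
#' @export
depth_phantom <- function(diameter = 1, depth = 0, mu_a = 0.03,
                          mu_s_prime = 12.3, emission = 1, blur = TRUE) {
  stopifnot(diameter > 0, depth >= 0, mu_a > 0, mu_s_prime >= 0, emission >= 0)
  structure(list(diameter = diameter, depth = depth, mu_a = mu_a,
                 mu_s_prime = mu_s_prime, emission = emission,
                 blur = isTRUE(blur)),
            class = "fsi_depth_config")
}

#' Effective attenuation coefficient of a diffusive medium
#'
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s_prime))`, the exponential decay
#' rate of diffuse light in the diffusion regime.
#'
#' @inheritParams depth_phantom
#' @return Effective attenuation coefficient in cm^-1.
#' @examples
#' effective_attenuation(0.03, 12.3)  # 1 wt% intralipid
#' @export
effective_attenuation <- function(mu_a, mu_s_prime) {
  stopifnot(mu_a > 0, mu_s_prime >= 0)
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Transmission profile across an absorbing cylindrical wire
#'
#' For a ray at perpendicular distance `rho` from the wire axis, the path
#' length through the circular cross-section is the chord
#' `2 sqrt((d/2)^2 - rho^2)`, so the optical depth scales as
#' `sqrt(1 - (2 rho / d)^2)` of its center-chord value.
#'
#' @param rho Perpendicular distance(s) from the wire axis, mm.
#' @inheritParams wire_phantom
#' @return Transmission value(s) in `[0, background]`.
#' @export
wire_transmission <- function(rho, diameter = 0.4, optical_depth = 4.6,
                              background = 1) {
  frac <- 1 - (2 * rho / diameter)^2
  chord <- sqrt(pmax(frac, 0))
  background * exp(-optical_depth * chord)
}

# 4x4 tensor Gauss-Legendre nodes/weights on [-1/2, 1/2], used for per-pixel
# antialiasing quadrature of the wire rendering
.gl4 <- local({
  nodes <- c(-0.8611363115940526, -0.3399810435848563,
             0.3399810435848563, 0.8611363115940526) / 2
  wts <- c(0.3478548451374538, 0.6521451548625461,
           0.6521451548625461, 0.3478548451374538) / 2
  list(n = nodes, w = wts)
})

#' Render the wire phantom (x-ray transmission scene)
#'
#' A straight absorbing wire crosses the field center at the configured
#' orientation on a uniform bright background. Transmission follows
#' Beer-Lambert through the circular cross-section chord
#' (see [wire_transmission()]); each pixel value is the transmission
#' averaged over the pixel footprint by 4x4 Gauss-Legendre quadrature, which
#' gives the sub-pixel accuracy resolution tests need.
#'
#' @param cfg A [wire_phantom()] config.
#' @param shape Grid `c(M, N)` in pixels.
#' @param pitch Pixel pitch, mm.
#' @return An `fsi_scene` with modality `"xray"`.
#' @export
make_wire_scene <- function(cfg = wire_phantom(), shape = c(96, 128),
                            pitch = 0.52) {
  stopifnot(inherits(cfg, "fsi_wire_config"))
  shape <- check_shape(shape)
  M <- shape[1]; N <- shape[2]
  th <- cfg$orientation * pi / 180
  # physical coordinates of pixel centers, field center at origin
  px <- ((0:(M - 1)) + 0.5 - M / 2) * pitch
  py <- ((0:(N - 1)) + 0.5 - N / 2) * pitch
  nx <- cos(th); ny <- -sin(th)  # unit normal to the wire axis
  rho_centers <- abs(outer(px * nx, py * ny, "+") - cfg$offset)
  if (min(rho_centers) > cfg$diameter / 2 + pitch) {
    warning("wire lies outside the field of view; returning uniform background")
    return(fsi_scene(matrix(cfg$background, M, N), pitch, "xray"))
  }
  img <- matrix(0, M, N)
  for (i in seq_along(.gl4$n)) {
    for (j in seq_along(.gl4$n)) {
      dx <- .gl4$n[i] * pitch; dy <- .gl4$n[j] * pitch
      rho <- abs(outer((px + dx) * nx, (py + dy) * ny, "+") - cfg$offset)
      img <- img + .gl4$w[i] * .gl4$w[j] *
        wire_transmission(rho, cfg$diameter, cfg$optical_depth, cfg$background)
    }
  }
  fsi_scene(img, pitch, "xray")
}

#' Render the serial-dilution well phantom (fluorescence scene)
#'
#' Circular wells on a dark background, each filled at
#' `gain * concentration`; the blank (pure water) well is 0. Well edges are
#' antialiased by linear coverage. With `ascending = TRUE` the blank sits
#' leftmost and concentration increases to the right.
#'
#' @param cfg A [dilution_phantom()] config.
#' @inheritParams make_wire_scene
#' @return An `fsi_scene` with modality `"fluorescence"`, carrying the
#'   left-to-right well layout in attributes `well_centers` (pixel rows/cols)
#'   and `well_concentrations`.
#' @export
make_dilution_scene <- function(cfg = dilution_phantom(), shape = c(96, 128),
                                pitch = 0.52) {
  stopifnot(inherits(cfg, "fsi_dilution_config"))
  shape <- check_shape(shape)
  M <- shape[1]; N <- shape[2]
  conc <- cfg$concentrations
  if (cfg$ascending) conc <- sort(conc) else conc <- sort(conc, decreasing = TRUE)
  n <- length(conc)
  centers <- cfg$centers
  if (is.null(centers)) {
    centers <- cbind(rep(M / 2, n), ((seq_len(n)) - 0.5) / n * N)
  }
  stopifnot(nrow(centers) == n)
  if (any(centers[, 1] - cfg$radius < 0 | centers[, 1] + cfg$radius > M |
          centers[, 2] - cfg$radius < 0 | centers[, 2] + cfg$radius > N)) {
    stop("wells do not fit inside the field")
  }
  if (n > 1) {
    dmat <- as.matrix(stats::dist(centers))
    if (min(dmat[upper.tri(dmat)]) < 2 * cfg$radius) {
      stop("overlapping wells in dilution phantom config")
    }
  }
  xs <- (0:(M - 1)) + 0.5; ys <- (0:(N - 1)) + 0.5
  img <- matrix(0, M, N)
  for (k in seq_len(n)) {
    d <- sqrt(outer((xs - centers[k, 1])^2, (ys - centers[k, 2])^2, "+"))
    cover <- pmin(pmax(cfg$radius + 0.5 - d, 0), 1)
    img <- img + cfg$gain * conc[k] * cover
  }
  sc <- fsi_scene(img, pitch, "fluorescence")
  attr(sc, "well_centers") <- centers
  attr(sc, "well_concentrations") <- conc
  sc
}

# 1-D Gaussian blur down the rows of a matrix (zero padding)
gaussian_blur_rows <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  h <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-h:h)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  M <- nrow(img)
  pad <- rbind(matrix(0, h, ncol(img)), img, matrix(0, h, ncol(img)))
  out <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
  out[(h + 1):(h + M), , drop = FALSE]
}

#' Render the depth phantom (tube at depth in a scattering medium)
#'
#' A horizontal emissive stripe of width `diameter / pitch` pixels across
#' the field middle, scaled by the diffusion-regime attenuation
#' `exp(-mu_eff * d)` with `mu_eff = sqrt(3 mu_a (mu_a + mu_s_prime))`
#' (depth converted to cm). When `blur` is on, a lateral Gaussian spread of
#' sigma `0.5 * depth` mm emulates the scattering broadening of the tube
#' image with depth.
#'
#' @param cfg A [depth_phantom()] config.
#' @inheritParams make_wire_scene
#' @return An `fsi_scene` with modality `"fluorescence"`; attribute
#'   `tube_rows` gives the pixel rows covered by the (unblurred) tube and
#'   `attenuation` the applied depth attenuation factor.
#' @export
make_depth_scene <- function(cfg = depth_phantom(), shape = c(96, 128),
                             pitch = 0.52) {
  stopifnot(inherits(cfg, "fsi_depth_config"))
  shape <- check_shape(shape)
  M <- shape[1]; N <- shape[2]
  mu_eff <- effective_attenuation(cfg$mu_a, cfg$mu_s_prime)
  atten <- exp(-mu_eff * cfg$depth / 10)  # depth mm -> cm
  w_px <- cfg$diameter / pitch
  xs <- (0:(M - 1)) + 0.5
  xc <- M / 2
  # fractional coverage of each pixel row by the stripe |x - xc| <= w/2
  lo <- pmax(xs - 0.5, xc - w_px / 2)
  hi <- pmin(xs + 0.5, xc + w_px / 2)
  cover <- pmax(hi - lo, 0)
  profile <- cfg$emission * atten * cover
  img <- matrix(profile, M, N)
  if (cfg$blur && cfg$depth > 0) {
    img <- gaussian_blur_rows(img, 0.5 * cfg$depth / pitch)
  }
  sc <- fsi_scene(img, pitch, "fluorescence")
  attr(sc, "tube_rows") <- which(cover > 0.5)
  attr(sc, "attenuation") <- atten
  sc
}

# forward measurement ---------------------------------------------------------

#' Single bucket-detector measurement
#'
#' The structured-detection response to one pattern:
#' `D = sum_x sum_y I(x,y) P(x,y) + n`, with the noise term n drawn from the
#' given model (ambient offset plus Gaussian read noise; optional Poisson
#' shot noise on the signal).
#'
#' @param scene An `fsi_scene` (or plain matrix).
#' @param pattern Numeric matrix of the same shape.
#' @param noise An [noise_model()]; `NULL` for a noiseless reading.
#' @return A single numeric response.
#' @export
measure <- function(scene, pattern, noise = NULL) {
  if (!all(dim(scene) == dim(pattern))) {
    stop("scene and pattern shapes do not match")
  }
  d <- sum(unclass(scene) * pattern)
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "fsi_noise"))
    d <- apply_noise(matrix(d, 1, 1), noise)[1, 1]
  }
  d
}

apply_noise <- function(D, noise) {
  if (noise$poisson) {
    D[] <- rpois(length(D), pmax(D, 0))
  }
  if (noise$gaussian_sigma > 0) {
    D <- D + rnorm(length(D), 0, noise$gaussian_sigma)
  }
  D + noise$ambient_offset
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Acquire a full measurement set through a sampling plan
#'
#' Simulates the acquisition the real instrument performs: for every
#' coefficient in the plan the three phase-shifted basis patterns are
#' displayed (grayscale, or Floyd-Steinberg binarized when `use_binary`)
#' and the bucket detector integrates the modulated scene, yielding 3K
#' responses for a K-coefficient plan. Noise is applied per the model; the
#' ambient offset is constant across the three responses of a triplet.
#' With a seeded noise model the result is bit-reproducible.
#'
#' @param scene An `fsi_scene`.
#' @param plan An `fsi_plan` with the same grid shape.
#' @param use_binary Display dithered binary patterns (`TRUE`, the fast-FSI
#'   mode) or ideal grayscale sinusoids.
#' @param noise An [noise_model()].
#' @return An `fsi_measurements`: data frame with columns `index`, `u`, `v`,
#'   `phase_index` (0/1/2) and `D`, carrying acquisition metadata
#'   (shape, pitch, plan coverage, strategy, seed, binary flag) in
#'   `attr(, "meta")`.
#' @export
acquire <- function(scene, plan, use_binary = TRUE, noise = noise_model()) {
  stopifnot(inherits(plan, "fsi_plan"))
  shape <- attr(plan, "shape")
  if (!all(dim(scene) == shape)) stop("plan shape does not match scene")
  D0 <- cpp_acquire_noiseless(unclass(scene), as.integer(plan$u),
                              as.integer(plan$v), isTRUE(use_binary))
  D <- with_seed(noise$seed, apply_noise(D0, noise))
  K <- nrow(plan)
  ms <- data.frame(index = rep(plan$index, each = 3),
                   u = rep(plan$u, each = 3),
                   v = rep(plan$v, each = 3),
                   phase_index = rep(0:2, times = K),
                   D = as.vector(t(D)))
  structure(ms,
            meta = list(shape = shape,
                        pitch = attr(scene, "pitch"),
                        ratio = attr(plan, "ratio"),
                        strategy = attr(plan, "strategy"),
                        seed = noise$seed,
                        use_binary = isTRUE(use_binary),
                        noise = unclass(noise)[c("gaussian_sigma",
                                                 "ambient_offset", "poisson")]),
            class = c("fsi_measurements", "data.frame"))
}

#' @export
print.fsi_measurements <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<fsi_measurements> %d responses (%d triplets) on %dx%d grid, %s patterns\n",
              nrow(x), nrow(x) / 3, m$shape[1], m$shape[2],
              if (isTRUE(m$use_binary)) "binary" else "grayscale"))
  invisible(x)
}

#' Write / read a measurement set as CSV plus metadata sidecar
#'
#' Responses go to `<path>` with columns `index, u, v, phase_index, D`;
#' shape, pitch, coverage, strategy, seed and the binary flag go to
#' `<path>.meta.json`.
#'
#' @param ms An `fsi_measurements`.
#' @param path Output CSV path.
#' @return `write_measurements_csv` returns `path` invisibly;
#'   `read_measurements_csv` returns the restored `fsi_measurements`.
#' @export
write_measurements_csv <- function(ms, path) {
  stopifnot(inherits(ms, "fsi_measurements"))
  write.csv(as.data.frame(ms), path, row.names = FALSE)
  jsonlite::write_json(attr(ms, "meta"), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path)
  need <- c("index", "u", "v", "phase_index", "D")
  if (!all(need %in% names(df))) {
    stop("measurement CSV must have columns: ", paste(need, collapse = ", "))
  }
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  meta$shape <- as.integer(meta$shape)
  structure(df, meta = meta,
            class = c("fsi_measurements", "data.frame"))
}

#' Write / read a scene image
#'
#' Scenes persist as 16-bit grayscale TIFF (`.tif`/`.tiff`) or plain-text
#' PGM (`.pgm`); intensities are scaled to the full integer range and the
#' scale, pitch and modality are recorded in a `<path>.meta.json` sidecar so
#' the round trip restores physical units.
#'
#' @param scene An `fsi_scene`.
#' @param path Output path.
#' @return `write_scene` returns `path` invisibly; `read_scene` the restored
#'   `fsi_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "fsi_scene"))
  ext <- tolower(tools::file_ext(path))
  peak <- max(scene)
  scale <- if (peak > 0) peak else 1
  norm <- unclass(scene) / scale
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16)
  } else if (ext == "pgm") {
    write_pgm(round(norm * 65535), path, maxval = 65535)
  } else {
    stop("unsupported scene format: ", ext)
  }
  jsonlite::write_json(list(pitch = attr(scene, "pitch"),
                            modality = attr(scene, "modality"),
                            scale = scale, depth = 16L),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    norm <- tiff::readTIFF(path)
  } else if (ext == "pgm") {
    norm <- read_pgm(path) / 65535
  } else {
    stop("unsupported scene format: ", ext)
  }
  fsi_scene(norm * meta$scale, pitch = meta$pitch, modality = meta$modality)
}
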