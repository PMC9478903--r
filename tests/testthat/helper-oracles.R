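# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Scalar serpentine Floyd-Steinberg error diffusion, pixel by pixel.
reference_dither <- function(gray) {
  M <- nrow(gray); N <- ncol(gray)
  buf <- gray
  out <- matrix(0, M, N)
  for (i in 1:M) {
    cols <- if (i %% 2 == 1) 1:N else N:1   # row 1 is scan row 0 (even)
    dir <- if (i %% 2 == 1) 1L else -1L
    for (j in cols) {
      old <- buf[i, j]
      bit <- if (old >= 0.5) 1 else 0
      out[i, j] <- bit
      err <- old - bit
      jf <- j + dir; jb <- j - dir
      if (jf >= 1 && jf <= N) buf[i, jf] <- buf[i, jf] + err * 7 / 16
      if (i + 1 <= M) {
        if (jb >= 1 && jb <= N) buf[i + 1, jb] <- buf[i + 1, jb] + err * 3 / 16
        buf[i + 1, j] <- buf[i + 1, j] + err * 5 / 16
        if (jf >= 1 && jf <= N) buf[i + 1, jf] <- buf[i + 1, jf] + err * 1 / 16
      }
    }
  }
  out
}

# Direct double-loop unnormalized forward DFT (kernel exp(-2 pi i (ux/M + vy/N))).
reference_dft <- function(img) {
  M <- nrow(img); N <- ncol(img)
  F <- matrix(complex(real = 0, imaginary = 0), M, N)
  for (u in 0:(M - 1)) {
    for (v in 0:(N - 1)) {
      acc <- 0 + 0i
      for (x in 0:(M - 1)) {
        for (y in 0:(N - 1)) {
          acc <- acc + img[x + 1, y + 1] *
            exp(-2i * pi * (u * x / M + v * y / N))
        }
      }
      F[u + 1, v + 1] <- acc
    }
  }
  F
}

# Brute-force circular-plan length: sweep every coordinate in order of
# wrap-around radius (ties by u then v), skip coordinates whose conjugate was
# already taken, accumulate coverage (self-conjugate 1, else 2) to the target.
reference_plan_length <- function(shape, ratio) {
  M <- shape[1]; N <- shape[2]
  g <- expand.grid(u = 0:(M - 1), v = 0:(N - 1))
  g$r <- sqrt(pmin(g$u, M - g$u)^2 + pmin(g$v, N - g$v)^2)
  g <- g[order(g$r, g$u, g$v), ]
  taken <- matrix(FALSE, M, N)
  covered <- 0
  count <- 0
  for (i in seq_len(nrow(g))) {
    u <- g$u[i]; v <- g$v[i]
    uc <- (M - u) %% M; vc <- (N - v) %% N
    if (taken[uc + 1, vc + 1] || taken[u + 1, v + 1]) next
    taken[u + 1, v + 1] <- TRUE
    covered <- covered + if (u == uc && v == vc) 1 else 2
    count <- count + 1
    if (covered >= ratio * M * N) break
  }
  count
}

# Truncate a measurement set to the first k plan coefficients, keeping metadata.
truncate_measurements <- function(ms, k) {
  sub <- ms[ms$index < k, , drop = FALSE]
  attr(sub, "meta") <- attr(ms, "meta")
  class(sub) <- class(ms)
  sub
}

random_scene <- function(shape, seed, pitch = 0.52) {
  set.seed(seed)
  fsi_scene(matrix(runif(prod(shape)), shape[1], shape[2]), pitch = pitch)
}
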