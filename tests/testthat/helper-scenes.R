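# Shared fixtures, all built in code at test time.

# Small synthetic scene for fast unit tests of the tracking pipeline:
# same ingredients as the package's default verification scene (hollow
# dark pillar tips on a bright background, tissue band, speckle, optical
# blur) at about a fifth of the linear scale.
tiny_scene <- function(scene_seed = 7L) {
  h <- 70L
  w <- 160L
  withr::with_seed(as.integer(scene_seed), {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    frame <- 0.75 + 0.02 * sin(xx / 17) +
      gaussian_blur_ref(matrix(runif(h * w, -0.5, 0.5), h, w), 1.2) * 0.04
    cy <- 35
    centers <- list(left = c(40, cy), right = c(120, cy))
    labels <- matrix(1L, h, w)
    capsule <- function(cx, hw = 9, hh = 14, rnd = 7) {
      dx <- abs(xx - 1 - cx)
      dy <- abs(yy - 1 - cy)
      qx <- pmax(dx - (hw - rnd), 0)
      qy <- pmax(dy - (hh - rnd), 0)
      sqrt(qx^2 + qy^2) - rnd
    }
    in_pillar <- matrix(FALSE, h, w)
    for (s in c("left", "right")) {
      d <- capsule(centers[[s]][1])
      frame <- frame - 0.6 / (1 + exp(d / 0.6))
      frame <- frame + 0.5 / (1 + exp((d + 4) / 0.6))
      labels[d <= 0] <- 3L
      in_pillar <- in_pillar | d <= 2
    }
    band <- xx - 1 >= 52 & xx - 1 <= 108 & abs(yy - 1 - cy) <= 10
    frame[band] <- frame[band] - 0.25
    labels[band & labels == 1L] <- 4L
    tex <- gaussian_blur_ref(matrix(runif(h * w, -0.5, 0.5), h, w), 0.7)
    sel <- band | in_pillar
    frame[sel] <- frame[sel] + tex[sel] * 0.16
    frame <- gaussian_blur_ref(frame, 0.5)
    sprite_of <- function(cx) {
      x0 <- as.integer(cx - 24)
      y0 <- 10L
      list(patch = frame[(y0 + 1):(y0 + 50), (x0 + 1):(x0 + 49)],
           rest = c(x0, y0))
    }
    list(background = frame,
         sprites = list(left = sprite_of(centers$left[1]),
                        right = sprite_of(centers$right[1])),
         pillar_centers = centers,
         mask = label_mask(labels))
  })
}

# independent separable Gaussian blur (edge replication), used only to
# build fixtures
gaussian_blur_ref <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_rows <- function(m) {
    n <- ncol(m)
    out <- matrix(0, nrow(m), n)
    for (d in seq_along(k)) {
      out <- out + k[d] * m[, pmin(pmax(seq_len(n) + d - r - 1L, 1L), n)]
    }
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

tiny_simulation <- function(noise_frac = 0, seed = 1L, n_frames = 40L,
                            amplitude_px = 1.5, frequency_hz = 2, ...) {
  sc <- tiny_scene()
  spec <- simulation_spec(sc$background, sc$sprites, sc$pillar_centers,
                          amplitude_px = amplitude_px,
                          frequency_hz = frequency_hz,
                          n_frames = n_frames, noise_frac = noise_frac,
                          seed = seed, ...)
  attr(spec, "mask") <- sc$mask
  generate_video(spec)
}

# textured patch for matching tests: band-limited random texture
textured_patch <- function(nr = 40, nc = 40, seed = 11L, sigma = 0.8) {
  withr::with_seed(as.integer(seed), {
    gaussian_blur_ref(matrix(runif(nr * nc), nr, nc), sigma)
  })
}

# brute-force sliding-window Pearson oracle for the NCC accumulator
pearson_oracle <- function(template, frame, region) {
  patch <- template$patch
  h <- nrow(patch)
  w <- ncol(patch)
  sub <- frame[(region$y0 + 1):(region$y1 + 1),
               (region$x0 + 1):(region$x1 + 1), drop = FALSE]
  ny <- nrow(sub) - h + 1L
  nx <- ncol(sub) - w + 1L
  out <- matrix(NA_real_, ny, nx)
  tv <- as.vector(patch)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      win <- as.vector(sub[j:(j + h - 1L), i:(i + w - 1L)])
      out[j, i] <- if (sd(win) == 0 || sd(tv) == 0) 0 else
        stats::cor(tv, win)
    }
  }
  out
}
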