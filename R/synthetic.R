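#' Specify a synthetic worm
#'
#' A serpenoid body model: signed centerline curvature
#' `kappa(s, t) = kappa0 * sin(2*pi*s/wavelength - 2*pi*freq*t + phase)`,
#' which makes arclength, curvature at any body fraction, and stroke counts
#' available in closed form — the analytic oracle against which the imaging
#' pipeline is validated. Adult C. elegans defaults: 1 mm long, 80 um wide,
#' body wavelength about one body length.
#'
#' @param length_um Body length (um).
#' @param width_um Body width (um); must be < length.
#' @param drift 2-D drift velocity of the body midpoint (um/s).
#' @param freq Undulation frequency (Hz, >= 0); curvature at a fixed body
#'   point crosses zero `2 * freq` times per second.
#' @param kappa0 Curvature amplitude (1/um). Default 4/length: a moderate
#'   crawl bend (radius of a quarter body length at peak).
#' @param wavelength Body wavelength (um).
#' @param position Initial midpoint position (um, scene coordinates, y down).
#' @param heading Initial heading at the midpoint (radians).
#' @param phase Undulation phase offset (radians).
#' @param curl_frames 0-based frame indices during which the worm is posed
#'   as a closed loop (self-collision).
#' @return A `worm_spec`.
#' @export
worm_spec <- function(length_um = 1000, width_um = 80, drift = c(0, 0),
                      freq = 0, kappa0 = 4 / length_um,
                      wavelength = length_um, position = c(0, 0),
                      heading = 0, phase = 0, curl_frames = integer(0)) {
  stopifnot(length_um > width_um, width_um > 0, freq >= 0, wavelength > 0)
  structure(list(length_um = length_um, width_um = width_um, drift = drift,
                 freq = freq, kappa0 = kappa0, wavelength = wavelength,
                 position = position, heading = heading, phase = phase,
                 curl_frames = as.integer(curl_frames)),
            class = "worm_spec")
}

#' Specify a synthetic scene
#'
#' Dark worms on a light background with additive Gaussian noise. With the
#' seed fixed the rendered output is identical across runs. Defaults mirror
#' the two standard assays: crawling on plates recorded at 7.5 fps and
#' thrashing in liquid at 14 fps.
#'
#' @param worms List of `worm_spec`.
#' @param width_px,height_px Frame dimensions.
#' @param ucf Micrometers per pixel.
#' @param frame_rate Frames/second.
#' @param n_frames Frame count (>= 2).
#' @param background Background intensity in `[0, 1]` (light).
#' @param worm_intensity Worm body intensity (dark).
#' @param noise Gaussian noise standard deviation (intensity units).
#' @param seed Random seed for the noise.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(worms, width_px = 320, height_px = 240, ucf = 10,
                       frame_rate = 7.5, n_frames = 30, background = 0.85,
                       worm_intensity = 0.2, noise = 0.02, seed = 1L) {
  stopifnot(length(worms) >= 1L, n_frames >= 2L)
  structure(list(worms = worms, width_px = width_px, height_px = height_px,
                 ucf = ucf, frame_rate = frame_rate, n_frames = n_frames,
                 background = background, worm_intensity = worm_intensity,
                 noise = noise, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Analytic centerline of a worm at time t
#'
#' Integrates the serpenoid curvature law into a unit-speed curve of exact
#' length `length_um`, anchored so that the body midpoint (arclength L/2)
#' sits at `position + drift * t` with the specified heading. This is the
#' ground-truth oracle: positions, tangents and signed curvature at any
#' arclength fraction, in closed form up to quadrature of the heading.
#'
#' @param spec A `worm_spec`.
#' @param t Time in seconds (>= 0).
#' @param n Number of arclength samples of the returned polyline.
#' @param curled If `TRUE`, pose as a closed loop (constant curvature
#'   `2*pi/length`) instead of the serpenoid.
#' @return List with `xy` (`n x 2`, um), `s` (arclength, um),
#'   `curvature(frac)` (function: signed curvature at arclength fractions),
#'   and `arclength` (= `length_um`).
#' @export
centerline <- function(spec, t, n = 400L, curled = FALSE) {
  stopifnot(inherits(spec, "worm_spec"), t >= 0)
  L <- spec$length_um
  s <- seq(0, L, length.out = n)
  if (curled) {
    # close the rendered tube (which spans arclength [w/2, L - w/2]) into a
    # ring with about one body width of end overlap
    k0 <- 2 * pi / (L - 2 * spec$width_um)
    curv <- function(frac) rep(k0, length(frac))
    theta <- spec$heading + k0 * s
  } else {
    om <- 2 * pi * spec$freq
    ph <- function(ss) 2 * pi * ss / spec$wavelength - om * t + spec$phase
    curv <- function(frac) spec$kappa0 * sin(ph(frac * L))
    # closed-form heading: integral of kappa0 * sin(2 pi s / lambda - ...)
    lam <- spec$wavelength
    theta <- spec$heading -
      spec$kappa0 * lam / (2 * pi) * (cos(ph(s)) - cos(ph(0)))
  }
  # unit-speed integration (trapezoid) of the heading
  dx <- cos(theta); dy <- sin(theta)
  ds <- diff(s)
  x <- c(0, cumsum((dx[-n] + dx[-1]) / 2 * ds))
  y <- c(0, cumsum((dy[-n] + dy[-1]) / 2 * ds))
  # anchor the midpoint at position + drift * t
  mid <- c(stats::approx(s, x, L / 2)$y, stats::approx(s, y, L / 2)$y)
  anchor <- spec$position + spec$drift * t
  xy <- cbind(x - mid[1] + anchor[1], y - mid[2] + anchor[2])
  list(xy = xy, s = s, curvature = curv, arclength = L)
}

#' Render a scene to frames plus a ground-truth sidecar
#'
#' Rasterizes each worm as a tube of its width around the analytic
#' centerline (dark on light), adds Gaussian noise, and records per frame
#' and per worm: the rendered mask pixel count, the midpoint position (px),
#' curl/border/collision flags, and the analytic signed curvature at the 7
#' tracking-point arclength fractions (1/um). Collision flags are measured,
#' not scheduled: a frame is flagged when two worms' rendered masks actually
#' intersect.
#'
#' @param scene A `scene_spec`.
#' @return List with `seq` (a `frame_sequence`), `truth` (tibble sidecar)
#'   and `masks` (list over frames of per-worm logical masks).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  W <- scene$width_px; H <- scene$height_px
  diag_um <- sqrt(W^2 + H^2) * scene$ucf
  for (w in scene$worms) {
    if (w$length_um > diag_um) {
      stop("worm of length ", w$length_um, " um cannot fit a ",
           W, "x", H, " px frame at ", scene$ucf, " um/px")
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(scene$seed)

  frames <- vector("list", scene$n_frames)
  masks <- vector("list", scene$n_frames)
  truth <- list()
  fracs <- (0:6) / 6
  for (i in seq_len(scene$n_frames)) {
    t <- (i - 1) / scene$frame_rate
    frame <- matrix(scene$background, H, W)
    wmasks <- vector("list", length(scene$worms))
    for (wi in seq_along(scene$worms)) {
      w <- scene$worms[[wi]]
      curled <- (i - 1L) %in% w$curl_frames
      cl <- centerline(w, t, curled = curled)
      # stamp the tube over arclength [w/2, L - w/2]: with the rounded caps
      # the rendered body then spans exactly length_um head to tail
      core <- cl$s >= w$width_um / 2 & cl$s <= w$length_um - w$width_um / 2
      m <- stamp_tube(cl$xy[core, , drop = FALSE] / scene$ucf,
                      w$width_um / 2 / scene$ucf, H, W)
      wmasks[[wi]] <- m
      mid_um <- cl$xy[which.min(abs(cl$s - cl$arclength / 2)), ]
      truth[[length(truth) + 1L]] <- c(
        frame = i - 1L, worm = wi, mask_px = sum(m),
        mid_x = mid_um[1] / scene$ucf, mid_y = mid_um[2] / scene$ucf,
        curl = as.integer(curled),
        border = as.integer(any(m[1, ]) || any(m[H, ]) ||
                              any(m[, 1]) || any(m[, W])),
        setNames(cl$curvature(fracs), paste0("curv_", 0:6)),
        arclength_um = cl$arclength)
    }
    # measured worm-worm collision flags
    coll <- rep(FALSE, length(scene$worms))
    if (length(scene$worms) > 1L) {
      for (a in seq_len(length(scene$worms) - 1L)) {
        for (b in (a + 1L):length(scene$worms)) {
          if (any(wmasks[[a]] & wmasks[[b]])) coll[c(a, b)] <- TRUE
        }
      }
    }
    n_w <- length(scene$worms)
    for (wi in seq_len(n_w)) {
      rec <- truth[[length(truth) - n_w + wi]]
      rec["collision"] <- as.integer(coll[wi])
      truth[[length(truth) - n_w + wi]] <- rec
    }
    all_mask <- Reduce(`|`, wmasks)
    frame[all_mask] <- scene$worm_intensity
    if (scene$noise > 0) {
      frame <- frame + matrix(stats::rnorm(H * W, 0, scene$noise), H, W)
    }
    # 8-bit quantization, as a camera would deliver
    frames[[i]] <- round(pmin(pmax(frame, 0), 1) * 255) / 255
    masks[[i]] <- wmasks
  }
  truth <- tibble::as_tibble(do.call(rbind, truth))
  list(seq = frame_sequence(frames, scene$frame_rate), truth = truth,
       masks = masks)
}

# Mark all pixels within radius r (px) of the polyline (n x 2, px coords,
# 0-based continuous) in an H x W logical matrix.
stamp_tube <- function(xy, r, H, W) {
  m <- matrix(FALSE, H, W)
  rr <- ceiling(r)
  offs <- expand.grid(dy = -rr:rr, dx = -rr:rr)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  cx <- round(rep(xy[, 1], each = nrow(offs)) + offs$dx)
  cy <- round(rep(xy[, 2], each = nrow(offs)) + offs$dy)
  ok <- cx >= 0 & cx < W & cy >= 0 & cy < H
  m[unique(cx[ok] * H + cy[ok] + 1L)] <- TRUE
  m
}

#' Write a rendered scene to disk as a loadable recording
#'
#' Frames go to `dir` as numbered PNGs with an `fps.txt` sidecar (the format
#' [load_video()] reads) and the ground-truth sidecar to
#' `ground_truth.csv`.
#'
#' @param rendered Output of [render_scene()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(rendered$seq$frames)) {
    png::writePNG(rendered$seq$frames[[i]],
                  file.path(dir, sprintf("frame_%05d.png", i - 1L)))
  }
  writeLines(format(rendered$seq$frame_rate), file.path(dir, "fps.txt"))
  write.csv(rendered$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
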