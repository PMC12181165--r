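#' Named fixture scenes
#'
#' Standard synthetic scenes mirroring the two assay conditions — crawling
#' on a plate at 7.5 fps and thrashing in liquid at 14 fps — plus scripted
#' collision and curl scenarios. Worm counts are kept small (1-3) so scenes
#' render and analyse quickly; kinematics use adult-worm scales (0.7-1 mm
#' body, 50-130 um/s crawl, 0.5-2 Hz thrash).
#'
#' Scenes are designed so the temporal-median background stays clean: every
#' worm either drifts through its own body length over the scene or
#' undulates strongly enough that no pixel is worm-covered in half the
#' frames.
#'
#' @param name One of `"crawl"` (three crawling worms, 7.5 fps),
#'   `"thrash"` (one thrashing worm, 14 fps, 30 s), `"swim"` (thrashing
#'   with a 50 um/s drift), `"collision"` (two straight worms crossing
#'   head-on), `"curl"` (one worm posing as a closed loop on frames 30-40).
#' @param seed Random seed for the rendering noise.
#' @param freq Undulation frequency in Hz (thrash/swim scenes).
#' @param n_frames Frame count override.
#' @return A `scene_spec`.
#' @export
scene_preset <- function(name = c("crawl", "thrash", "swim", "collision",
                                  "curl"),
                         seed = 1L, freq = 1, n_frames = NULL) {
  name <- match.arg(name)
  switch(name,
    crawl = {
      worms <- list(
        worm_spec(length_um = 800, width_um = 60, freq = 0.3, kappa0 = 0.003,
                  wavelength = 800, drift = c(110, 5), position = c(600, 400)),
        worm_spec(length_um = 900, width_um = 70, freq = 0.25, kappa0 = 0.0025,
                  wavelength = 900, drift = c(95, -5), position = c(700, 1250),
                  phase = 1.1),
        worm_spec(length_um = 700, width_um = 55, freq = 0.35, kappa0 = 0.0035,
                  wavelength = 700, drift = c(130, 5), position = c(500, 2000),
                  phase = 2.3))
      scene_spec(worms, frame_rate = 7.5,
                 n_frames = if (is.null(n_frames)) 100L else n_frames,
                 seed = seed)
    },
    thrash = {
      w <- worm_spec(length_um = 800, width_um = 60, freq = freq,
                     kappa0 = 0.005, wavelength = 800, drift = c(40, 15),
                     position = c(1300, 1100), phase = 0.7)
      scene_spec(list(w), frame_rate = 14,
                 n_frames = if (is.null(n_frames)) 420L else n_frames,
                 seed = seed)
    },
    swim = {
      w <- worm_spec(length_um = 800, width_um = 60, freq = freq,
                     kappa0 = 0.005, wavelength = 800, drift = c(50, 0),
                     position = c(900, 1100), phase = 0.4)
      scene_spec(list(w), frame_rate = 14,
                 n_frames = if (is.null(n_frames)) 420L else n_frames,
                 seed = seed)
    },
    collision = {
      worms <- list(
        worm_spec(length_um = 700, width_um = 60, kappa0 = 0,
                  drift = c(450, 0), position = c(500, 1200)),
        worm_spec(length_um = 700, width_um = 60, kappa0 = 0,
                  drift = c(-450, 0), position = c(2700, 1200)))
      scene_spec(worms, frame_rate = 7.5,
                 n_frames = if (is.null(n_frames)) 60L else n_frames,
                 seed = seed)
    },
    curl = {
      w <- worm_spec(length_um = 700, width_um = 60, freq = 1,
                     kappa0 = 0.005, wavelength = 700, drift = c(150, 60),
                     position = c(900, 900), curl_frames = 30:40)
      scene_spec(list(w), frame_rate = 14,
                 n_frames = if (is.null(n_frames)) 120L else n_frames,
                 seed = seed)
    })
}
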