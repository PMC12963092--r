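# Parameter blocks for every stage. Each constructor validates its
# arguments; load_config() merges a YAML document onto these defaults
# and rejects unknown keys (fail fast).

#' Fragment specification for the scene simulator
#'
#' Describes one detachment event: at `split_frame` a connected
#' subregion of the stone holding `area_fraction` of its current area
#' breaks off and translates by `velocity` each frame.
#'
#' @param split_frame 0-based frame of detachment (must satisfy
#'   `0 < split_frame < n_frames`).
#' @param area_fraction fraction of the current stone area carried by
#'   the fragment, in (0, 0.5].
#' @param velocity numeric `c(vx, vy)` in px/frame. Fragments faster
#'   than the tracker's search radius are a documented failure mode.
#' @param lifetime frames the fragment stays in view after detaching.
#' @return A list of class `fragment_spec`.
#' @export
fragment_spec <- function(split_frame, area_fraction = 0.2,
                          velocity = c(2.5, 1.0), lifetime = 60) {
  if (length(split_frame) != 1 || split_frame != floor(split_frame) ||
      split_frame < 1) {
    ft_config_error("split_frame must be an integer >= 1")
  }
  if (length(area_fraction) != 1 || area_fraction <= 0 || area_fraction > 0.5) {
    ft_config_error("area_fraction must lie in (0, 0.5]")
  }
  if (length(velocity) != 2 || !is.numeric(velocity)) {
    ft_config_error("velocity must be c(vx, vy)")
  }
  if (length(lifetime) != 1 || lifetime < 1) {
    ft_config_error("lifetime must be >= 1 frame")
  }
  structure(list(split_frame = as.integer(split_frame),
                 area_fraction = as.numeric(area_fraction),
                 velocity = as.numeric(velocity),
                 lifetime = as.numeric(lifetime)),
            class = "fragment_spec")
}

#' Scene configuration for the synthetic simulator
#'
#' The simulator emulates the structure of a dusting scene: one bright
#' textured stone on a darker noisy background, scope-motion jitter,
#' detaching fragments, and transient sub-threshold dust particles.
#' Physical sizes map to pixels through `microns_per_pixel` (default
#' 50): dust (<= 250 um) is capped at 5 px radius and fragments
#' (> 1000 um across) get at least a 20 px diameter.
#'
#' @param width,height frame size in px.
#' @param n_frames number of frames T.
#' @param frame_rate frames per second.
#' @param background background intensity in \[0, 1\].
#' @param contrast stone intensity above background.
#' @param stone_center `c(x, y)` stone center at frame 0 (0-based px).
#' @param stone_radius `c(rx, ry)` ellipse semi-axes in px.
#' @param texture_amplitude amplitude of the surface texture pattern.
#' @param drift `c(dx, dy)` rigid stone drift in px/frame.
#' @param jitter_sd per-frame camera translation standard deviation (px).
#' @param blur_prob probability a frame is defocus-blurred.
#' @param events list of [fragment_spec()] objects.
#' @param dust_rate expected new dust particles per frame (Poisson).
#' @param dust_radius_range `c(min, max)` dust radius in px; the upper
#'   end may not exceed the dust size limit implied by
#'   `microns_per_pixel`.
#' @param dust_intensity intensity of dust particles.
#' @param noise_sd additive Gaussian intensity noise.
#' @param event_duration labeled ground-truth event length in frames
#'   (events can be as brief as 3 frames at 30 fps).
#' @param microns_per_pixel physical calibration of the scene.
#' @param n_track_points points sampled for the ground-truth track set.
#' @param seed integer seed; the scene is bit-reproducible given it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 256, height = 256, n_frames = 150,
                         frame_rate = 30, background = 0.25,
                         contrast = 0.35, stone_center = NULL,
                         stone_radius = c(50, 42),
                         texture_amplitude = 0.08, drift = c(0, 0),
                         jitter_sd = 0.4, blur_prob = 0.05,
                         events = list(), dust_rate = 1.0,
                         dust_radius_range = c(1.5, 5),
                         dust_intensity = 0.5, noise_sd = 0.02,
                         event_duration = 15, microns_per_pixel = 50,
                         n_track_points = 40, seed = 1) {
  if (width < 16 || height < 16) ft_config_error("frame size too small")
  if (n_frames < 1) ft_config_error("n_frames must be >= 1")
  if (frame_rate <= 0) ft_config_error("frame_rate must be > 0")
  if (is.null(stone_center)) stone_center <- c(width / 2, height / 2)
  if (length(stone_radius) == 1) stone_radius <- rep(stone_radius, 2)
  if (any(stone_radius <= 0)) ft_config_error("stone radii must be > 0")
  margin <- 2
  if (stone_center[1] - stone_radius[1] < margin ||
      stone_center[1] + stone_radius[1] > width - 1 - margin ||
      stone_center[2] - stone_radius[2] < margin ||
      stone_center[2] + stone_radius[2] > height - 1 - margin) {
    ft_config_error("stone must fit in the frame with a margin")
  }
  if (blur_prob < 0 || blur_prob > 1) ft_config_error("blur_prob must be in [0, 1]")
  if (jitter_sd < 0) ft_config_error("jitter_sd must be >= 0")
  if (dust_rate < 0) ft_config_error("dust_rate must be >= 0")
  if (microns_per_pixel <= 0) ft_config_error("microns_per_pixel must be > 0")
  dust_px_limit <- 250 / microns_per_pixel
  if (length(dust_radius_range) != 2 || any(dust_radius_range <= 0) ||
      dust_radius_range[1] > dust_radius_range[2]) {
    ft_config_error("dust_radius_range must be increasing and > 0")
  }
  if (dust_radius_range[2] > dust_px_limit + 1e-9) {
    ft_config_error("dust radius %.3g px exceeds the dust size limit %.3g px",
                    dust_radius_range[2], dust_px_limit)
  }
  if (noise_sd < 0) ft_config_error("noise_sd must be >= 0")
  if (event_duration < 1) ft_config_error("event_duration must be >= 1 frame")
  if (n_track_points < 1) ft_config_error("n_track_points must be >= 1")
  events <- lapply(events, function(e) {
    if (!inherits(e, "fragment_spec")) e <- do.call(fragment_spec, e)
    if (e$split_frame >= n_frames) {
      ft_config_error("split_frame %d must be < n_frames", e$split_frame)
    }
    e
  })
  if (length(events) > 1) {
    sf <- vapply(events, `[[`, integer(1), "split_frame")
    events <- events[order(sf)]
    if (anyDuplicated(sf)) ft_config_error("split frames must be distinct")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_frames = as.integer(n_frames), frame_rate = frame_rate,
    background = background, contrast = contrast,
    stone_center = as.numeric(stone_center),
    stone_radius = as.numeric(stone_radius),
    texture_amplitude = texture_amplitude, drift = as.numeric(drift),
    jitter_sd = jitter_sd, blur_prob = blur_prob, events = events,
    dust_rate = dust_rate, dust_radius_range = as.numeric(dust_radius_range),
    dust_intensity = dust_intensity, noise_sd = noise_sd,
    event_duration = as.integer(event_duration),
    microns_per_pixel = microns_per_pixel,
    n_track_points = as.integer(n_track_points),
    seed = as.integer(seed)), class = "scene_config")
}

#' Segmentation configuration
#'
#' Reference segmenter: intensity threshold, morphological opening then
#' closing, then a connected-component area filter that discards
#' dust-sized specks.
#'
#' @param threshold intensity cut in (0, 1), or `"otsu"` to derive it
#'   per frame from the intensity histogram.
#' @param morph_radius structuring-element (disc) radius in px for
#'   opening-then-closing; 0 disables morphology.
#' @param min_area minimum connected-component area (px) retained.
#' @param backend `"reference"` or `"external"` (precomputed masks).
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(threshold = "otsu", morph_radius = 2,
                           min_area = 120, backend = "reference") {
  if (!identical(threshold, "otsu")) {
    if (!is.numeric(threshold) || length(threshold) != 1 ||
        threshold <= 0 || threshold >= 1) {
      ft_config_error("threshold must be 'otsu' or a number in (0, 1)")
    }
  }
  if (morph_radius < 0) ft_config_error("morph_radius must be >= 0")
  if (min_area < 1) ft_config_error("min_area must be >= 1")
  if (!backend %in% c("reference", "external")) {
    ft_config_error("segment backend must be 'reference' or 'external'")
  }
  structure(list(threshold = threshold,
                 morph_radius = as.integer(morph_radius),
                 min_area = as.integer(min_area), backend = backend),
            class = "segment_config")
}

#' Tracker configuration
#'
#' Reference point tracker: per-frame normalized cross-correlation
#' patch search with parabolic sub-pixel refinement. Query points are a
#' regular grid over the (eroded) stone mask.
#'
#' @param patch_size odd template edge length in px (>= 3).
#' @param search_radius maximum displacement searched per frame (px);
#'   fragments moving faster than this are lost, the pipeline's
#'   documented failure mode.
#' @param min_correlation visibility cut in (0, 1\]: a point whose best
#'   match falls below it is marked lost.
#' @param grid_stride px between query points.
#' @param mask_erosion px eroded from the mask before sampling, keeping
#'   query points off the stone boundary.
#' @param backend `"reference"` or `"external"` (precomputed tracks).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(patch_size = 11, search_radius = 8,
                           min_correlation = 0.5, grid_stride = 8,
                           mask_erosion = 2, backend = "reference") {
  if (patch_size < 3 || patch_size %% 2 != 1) {
    ft_config_error("patch_size must be odd and >= 3")
  }
  if (search_radius < 1) ft_config_error("search_radius must be >= 1")
  if (min_correlation <= 0 || min_correlation > 1) {
    ft_config_error("min_correlation must be in (0, 1]")
  }
  if (grid_stride < 1) ft_config_error("grid_stride must be >= 1")
  if (mask_erosion < 0) ft_config_error("mask_erosion must be >= 0")
  if (!backend %in% c("reference", "external")) {
    ft_config_error("track backend must be 'reference' or 'external'")
  }
  structure(list(patch_size = as.integer(patch_size),
                 search_radius = as.integer(search_radius),
                 min_correlation = min_correlation,
                 grid_stride = as.integer(grid_stride),
                 mask_erosion = as.integer(mask_erosion),
                 backend = backend),
            class = "tracker_config")
}

#' Clustering configuration
#'
#' Parameters of the hierarchical density-based clusterer applied to
#' the visible point positions of each frame (Euclidean metric on
#' `(x, y)`; positions only, never velocities).
#'
#' @param min_cluster_size smallest group accepted as a cluster (>= 2).
#' @param min_samples neighborhood size for core distances (the point
#'   itself counts); defaults to `min_cluster_size`.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(min_cluster_size = 5, min_samples = NULL) {
  if (length(min_cluster_size) != 1 || min_cluster_size < 2 ||
      min_cluster_size != floor(min_cluster_size)) {
    ft_config_error("min_cluster_size must be an integer >= 2")
  }
  if (is.null(min_samples)) min_samples <- min_cluster_size
  if (length(min_samples) != 1 || min_samples < 1 ||
      min_samples != floor(min_samples)) {
    ft_config_error("min_samples must be an integer >= 1")
  }
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples)),
            class = "cluster_config")
}

#' Detector configuration
#'
#' The decision stage: a fragmentation flag fires when the per-frame
#' cluster count exceeds the baseline measured at the last point
#' (re)initialization for `persistence` consecutive frames.
#'
#' @param persistence consecutive frames a raised count must persist
#'   before an event fires (>= 1; 1 reproduces the literal
#'   fire-on-any-increase rule).
#' @param reinit_interval frames between scheduled point
#'   re-initializations.
#' @param min_visible_fraction visible-point fraction below which an
#'   immediate re-initialization is triggered, in (0, 1].
#' @param min_cluster_size,min_samples forwarded to [cluster_config()].
#' @return A list of class `detector_config` holding a `cluster`
#'   sub-config.
#' @export
detector_config <- function(persistence = 3, reinit_interval = 60,
                            min_visible_fraction = 0.3,
                            min_cluster_size = 5, min_samples = NULL) {
  if (persistence < 1 || persistence != floor(persistence)) {
    ft_config_error("persistence must be an integer >= 1")
  }
  if (reinit_interval < persistence) {
    ft_config_error("reinit_interval must be >= persistence")
  }
  if (min_visible_fraction <= 0 || min_visible_fraction > 1) {
    ft_config_error("min_visible_fraction must be in (0, 1]")
  }
  structure(list(persistence = as.integer(persistence),
                 reinit_interval = as.integer(reinit_interval),
                 min_visible_fraction = min_visible_fraction,
                 cluster = cluster_config(min_cluster_size, min_samples)),
            class = "detector_config")
}

#' Evaluation configuration
#'
#' @param tolerance_frames frame-matching tolerance (default 30, i.e.
#'   +/- 1 s at 30 fps).
#' @param segment_len segment length in frames (default 90, i.e. 3 s).
#' @param frame_rate frames per second, for reporting only.
#' @param segment_tp_unit `"event"` (default; segment-level TP counts
#'   matched ground-truth events, so TP+FN equals the number of labeled
#'   events) or `"segment"` (one TP per segment holding a matched
#'   prediction).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(tolerance_frames = 30, segment_len = 90,
                        frame_rate = 30, segment_tp_unit = "event") {
  if (tolerance_frames < 0) ft_config_error("tolerance_frames must be >= 0")
  if (segment_len < 1) ft_config_error("segment_len must be >= 1")
  if (!segment_tp_unit %in% c("event", "segment")) {
    ft_config_error("segment_tp_unit must be 'event' or 'segment'")
  }
  structure(list(tolerance_frames = as.integer(tolerance_frames),
                 segment_len = as.integer(segment_len),
                 frame_rate = frame_rate,
                 segment_tp_unit = segment_tp_unit),
            class = "eval_config")
}

#' Assemble a full run configuration
#'
#' @param seed integer seed applied to every stochastic stage.
#' @param synth,segment,track,detect,eval stage configurations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, synth = scene_config(seed = seed),
                       segment = segment_config(),
                       track = tracker_config(),
                       detect = detector_config(),
                       eval = eval_config()) {
  structure(list(seed = as.integer(seed), synth = synth, segment = segment,
                 track = track, detect = detect, eval = eval),
            class = "run_config")
}

# constructor lookup for load_config()
.block_builders <- list(
  synth = scene_config, segment = segment_config, track = tracker_config,
  detect = detector_config, eval = eval_config
)

#' Load a run configuration from YAML
#'
#' Absent keys take their documented defaults; unknown keys anywhere in
#' the document are rejected. The effective configuration is echoed to
#' the log when verbose logging is on.
#'
#' @param path YAML (or JSON, a YAML subset) file with optional blocks
#'   `synth`, `segment`, `track`, `detect`, `eval` and a top-level
#'   `seed`.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) ft_input_error("config file not found: %s", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) ft_config_error("config document must be a mapping")
  known <- c("seed", names(.block_builders))
  bad <- setdiff(names(doc), known)
  if (length(bad)) ft_config_error("unknown config key(s): %s",
                                   paste(bad, collapse = ", "))
  seed <- if (!is.null(doc$seed)) {
    if (!is.numeric(doc$seed) || doc$seed != floor(doc$seed)) {
      ft_config_error("seed must be an integer")
    }
    as.integer(doc$seed)
  } else 1L
  blocks <- lapply(names(.block_builders), function(nm) {
    builder <- .block_builders[[nm]]
    given <- doc[[nm]]
    if (is.null(given)) given <- list()
    if (!is.list(given)) ft_config_error("config block '%s' must be a mapping", nm)
    ok <- names(formals(builder))
    bad <- setdiff(names(given), ok)
    if (length(bad)) {
      ft_config_error("unknown key(s) in '%s': %s", nm, paste(bad, collapse = ", "))
    }
    if (nm == "synth" && is.null(given$seed)) given$seed <- seed
    do.call(builder, given)
  })
  names(blocks) <- names(.block_builders)
  cfg <- run_config(seed = seed, synth = blocks$synth,
                    segment = blocks$segment, track = blocks$track,
                    detect = blocks$detect, eval = blocks$eval)
  ft_log("effective config: %s",
         jsonlite::toJSON(config_as_list(cfg), auto_unbox = TRUE))
  cfg
}

# plain nested list view (for the manifest / log echo)
config_as_list <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, "fragment_spec")) return(unclass(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(cfg)
}
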