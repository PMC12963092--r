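# Shared scene fixtures. Unit tests use small, fast scenes; the
# acceptance suite builds full-size scenes with its own parameters.

# small quiet scene (no dust/jitter/noise unless overridden)
quiet_scene <- function(n_frames = 30, seed = 1, jitter_sd = 0,
                        blur_prob = 0, dust_rate = 0, noise_sd = 0,
                        stone_center = c(64, 64), stone_radius = c(30, 26),
                        ...) {
  scene_config(width = 128, height = 128, n_frames = n_frames,
               stone_center = stone_center, stone_radius = stone_radius,
               jitter_sd = jitter_sd, blur_prob = blur_prob,
               dust_rate = dust_rate, noise_sd = noise_sd,
               seed = seed, ...)
}

# canonical "one large slow fragment" scene: direction and timing vary
# with the index, speed stays well below the tracker search radius
event_scene_config <- function(i, seed_base = 100) {
  ang <- 2 * pi * (i %% 8) / 8 + 0.3
  speed <- 2 + 0.5 * (i %% 4)
  split <- 30 + ((i * 7) %% 41)   # split frames spread over 30..70
  scene_config(
    n_frames = 120,
    events = list(fragment_spec(split_frame = split, area_fraction = 0.25,
                                velocity = speed * c(cos(ang), sin(ang)),
                                lifetime = 60)),
    seed = seed_base + i)
}

null_scene_config <- function(i, seed_base = 500) {
  scene_config(n_frames = 90, events = list(), seed = seed_base + i)
}
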