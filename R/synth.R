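# Synthetic ureteroscopy-like scene simulator. Surgical video of
# dusting procedures is withheld (PHI), so every downstream stage is
# exercised against generated scenes with complete ground truth: one
# bright textured stone on a darker noisy background, scope-motion
# jitter, detaching fragments with known split frames, and transient
# sub-threshold dust particles.
#
# Geometry is analytic throughout: the stone is an ellipse intersected
# with an accumulating set of half-plane cuts; a fragment is the
# complementary side of its cut, frozen at detachment and translated
# rigidly. This makes the split an exact pixel partition and keeps
# every ground-truth trajectory closed-form.
#
# All randomness draws from one stream seeded by config$seed, in a
# fixed order: (1) texture parameters, (2) jitter increments and blur
# flags, (3) dust particles in frame order, (4) ground-truth track
# point sampling, (5) per-frame pixel noise during rendering.

.scene_grids <- function(W, H) {
  list(X = matrix(0:(W - 1), H, W, byrow = TRUE),
       Y = matrix(0:(H - 1), H, W))
}

# Evaluate an object's pixel set at 0-based frame t. Objects live in
# stone-local coordinates q; a pixel p belongs to the object when
# q = p - origin_t lies in the ellipse and on the kept side of every
# active half-plane cut.
.eval_shape <- function(obj, t, grids) {
  i <- t + 1L
  XL <- grids$X - obj$origins[i, 1]
  YL <- grids$Y - obj$origins[i, 2]
  inside <- (XL / obj$radius[1])^2 + (YL / obj$radius[2])^2 <= 1
  for (cons in obj$cons) {
    if (cons$from > t) next
    v <- cons$n[1] * XL + cons$n[2] * YL
    inside <- inside & if (cons$keep_ge) v >= cons$d else v < cons$d
  }
  inside
}

# Aperiodic surface texture: a smoothed Gaussian random field, frozen
# in stone-local coordinates and sampled bilinearly so it translates
# (sub-pixel) rigidly with the object. Periodic patterns would give
# the correlation tracker false lock-on points one wavelength away;
# granular aperiodic texture is also what stone surfaces look like.
.make_texture_field <- function(radius, amp) {
  span <- 2L * ceiling(2.2 * max(radius)) + 1L
  span <- min(span, 512L)
  f <- matrix(rnorm(span * span), span, span)
  g <- EBImage::makeBrush(9, shape = "gaussian", sigma = 1.5)
  f <- EBImage::filter2(f, g)
  f <- f / stats::sd(f) * amp
  list(field = f, center = (span + 1) / 2, span = span)
}

.local_texture <- function(XL, YL, tex) {
  # bilinear lookup at 1-based continuous field coordinates
  u <- XL + tex$center
  v <- YL + tex$center
  L <- tex$span
  j0 <- pmin(pmax(floor(u), 1), L - 1)
  i0 <- pmin(pmax(floor(v), 1), L - 1)
  fu <- pmin(pmax(u - j0, 0), 1)
  fv <- pmin(pmax(v - i0, 0), 1)
  F <- tex$field
  idx <- cbind(as.vector(i0), as.vector(j0))
  val <- (1 - fv) * (1 - fu) * F[idx] +
    (1 - fv) * fu * F[idx + matrix(c(0L, 1L), nrow(idx), 2, byrow = TRUE)] +
    fv * (1 - fu) * F[idx + matrix(c(1L, 0L), nrow(idx), 2, byrow = TRUE)] +
    fv * fu * F[idx + matrix(c(1L, 1L), nrow(idx), 2, byrow = TRUE)]
  matrix(val, nrow(XL), ncol(XL))
}

# membership test in stone-local coordinates (vector q of length 2)
.in_shape_local <- function(obj, q, t) {
  if ((q[1] / obj$radius[1])^2 + (q[2] / obj$radius[2])^2 > 1) return(FALSE)
  for (cons in obj$cons) {
    if (cons$from > t) next
    v <- cons$n[1] * q[1] + cons$n[2] * q[2]
    ok <- if (cons$keep_ge) v >= cons$d else v < cons$d
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic dusting scene
#'
#' Renders frames, ground-truth masks (union and per-object), labeled
#' fragmentation intervals, and a ground-truth track set, all
#' bit-reproducible from `config$seed`.
#'
#' Each [fragment_spec()] detaches a connected subregion of the current
#' stone — the intersection of the stone with a half-plane
#' perpendicular to the fragment's velocity, sized to the requested
#' area fraction — which then translates by its velocity every frame
#' until its lifetime expires or it leaves the frame. The labeled
#' ground-truth interval spans `[split_frame, split_frame +
#' event_duration - 1]`. Dust particles are transient discs below the
#' fragment-size threshold; they appear in the rendered frames but
#' never in the masks or the event labels.
#'
#' @param config a [scene_config()].
#' @return An object of class `synthetic_scene` with elements `frames`
#'   ([frame_sequence()]), `masks` ([mask_sequence()], union of stone
#'   and fragments), `object_masks` (per-frame named list of per-object
#'   masks), `gt_events` ([event_intervals()]), `gt_tracks`
#'   ([track_set()]), and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    ft_config_error("generate_scene() needs a scene_config")
  }
  withr::with_seed(config$seed, .generate_scene_impl(config))
}

.generate_scene_impl <- function(cfg) {
  W <- cfg$width; H <- cfg$height; T <- cfg$n_frames
  grids <- .scene_grids(W, H)

  # phase 1: surface texture, shared by stone and fragments (fragments
  # keep the stone's surface pattern because q-coordinates are frozen)
  tex <- .make_texture_field(cfg$stone_radius, cfg$texture_amplitude)

  # phase 2: camera jitter random walk and per-frame blur flags
  jit <- matrix(0, T, 2)
  if (T > 1 && cfg$jitter_sd > 0) {
    steps <- matrix(rnorm(2 * (T - 1), 0, cfg$jitter_sd), T - 1, 2)
    jit[2:T, ] <- apply(steps, 2, cumsum)
  } else if (T > 1) {
    invisible(rnorm(2 * (T - 1), 0, 1))  # keep stream layout fixed
  }
  blur <- runif(T) < cfg$blur_prob

  # phase 3: dust particles, spawned per frame
  dust <- list()
  for (t in 0:(T - 1)) {
    n_new <- rpois(1, cfg$dust_rate)
    if (n_new > 0) {
      for (k in seq_len(n_new)) {
        dust[[length(dust) + 1]] <- list(
          spawn = t,
          pos = c(runif(1, 0, W - 1), runif(1, 0, H - 1)),
          radius = runif(1, cfg$dust_radius_range[1], cfg$dust_radius_range[2]),
          vel = runif(2, -2.5, 2.5),
          life = sample(4:12, 1))
      }
    }
  }

  # scene offset = rigid drift + camera jitter (frame 0 at rest)
  off <- cbind(cfg$drift[1] * (0:(T - 1)), cfg$drift[2] * (0:(T - 1))) + jit

  # build objects: the stone, then one fragment per split
  stone <- list(id = "stone", birth = 0L, death = T,
                radius = cfg$stone_radius,
                origins = sweep(off, 2, cfg$stone_center, `+`),
                cons = list())
  objects <- list(stone = stone)
  frag_px_floor <- pi * (1000 / cfg$microns_per_pixel / 2)^2

  for (ev in cfg$events) {
    s <- ev$split_frame
    stone <- objects$stone
    cur <- .eval_shape(stone, s, grids)
    idx <- which(cur)
    if (length(idx) == 0) ft_config_error("stone vanished before split at %d", s)
    # half-plane cut perpendicular to the fragment velocity; the
    # leading side (in the motion direction) detaches
    speed <- sqrt(sum(ev$velocity^2))
    n <- if (speed > 0) ev$velocity / speed else c(1, 0)
    rows <- ((idx - 1L) %% H)
    cols <- ((idx - 1L) %/% H)
    qx <- cols - stone$origins[s + 1L, 1]
    qy <- rows - stone$origins[s + 1L, 2]
    proj <- n[1] * qx + n[2] * qy
    k <- round(ev$area_fraction * length(proj))
    if (k < 1) {
      ft_config_error("fragment at frame %d would be below 1 px", s)
    }
    sorted <- sort(proj, decreasing = TRUE)
    d <- if (k < length(sorted)) (sorted[k] + sorted[k + 1]) / 2 else
      sorted[length(sorted)] - 1e-9
    if (k < frag_px_floor) {
      ft_log("fragment at frame %d (%d px) is below the %d px fragment-size floor",
             s, k, round(frag_px_floor))
    }
    frag_id <- sprintf("fragment_%03d", s)
    frag_origins <- matrix(NA_real_, T, 2)
    tt <- s:(T - 1)
    base <- stone$origins[s + 1L, ]
    frag_origins[tt + 1L, 1] <- base[1] + ev$velocity[1] * (tt - s) +
      (jit[tt + 1L, 1] - jit[s + 1L, 1])
    frag_origins[tt + 1L, 2] <- base[2] + ev$velocity[2] * (tt - s) +
      (jit[tt + 1L, 2] - jit[s + 1L, 2])
    frag <- list(id = frag_id, birth = s,
                 death = min(s + ev$lifetime, T),
                 radius = stone$radius, origins = frag_origins,
                 cons = c(stone$cons,
                          list(list(n = n, d = d, keep_ge = TRUE, from = s))))
    objects$stone$cons <- c(objects$stone$cons,
                            list(list(n = n, d = d, keep_ge = FALSE, from = s)))
    objects[[frag_id]] <- frag
  }

  # per-object masks; a fragment whose pixel set empties (left the
  # frame) is dead from that frame on
  object_masks <- vector("list", T)
  for (t in 0:(T - 1)) object_masks[[t + 1L]] <- list()
  for (oi in seq_along(objects)) {
    obj <- objects[[oi]]
    for (t in obj$birth:(obj$death - 1L)) {
      m <- .eval_shape(obj, t, grids)
      if (!any(m)) { objects[[oi]]$death <- t; break }
      object_masks[[t + 1L]][[obj$id]] <- m
    }
  }

  masks <- lapply(object_masks, function(ml) {
    m <- matrix(FALSE, H, W)
    for (om in ml) m <- m | om
    m
  })

  # ground-truth events: one per fragment spec, starting at the split
  surv <- vapply(objects[-1], function(o) o$death > o$birth, logical(1))
  ev_start <- vapply(objects[-1], function(o) o$birth, integer(1))[surv]
  gt_events <- event_intervals(
    start_frame = ev_start,
    end_frame = pmin(ev_start + cfg$event_duration - 1L, T - 1L))

  geometry <- list(grids = grids, objects = objects, jitter = jit,
                   offsets = off, tex = tex, dust = dust, blur = blur)

  # phase 4: ground-truth material points
  gt_tracks <- .sample_gt_tracks(geometry, masks[[1]], cfg$n_track_points,
                                 W, H, T)

  # phase 5: render frames
  frames <- vector("list", T)
  for (t in 0:(T - 1)) {
    f <- matrix(cfg$background, H, W)
    for (obj in objects) {
      if (t < obj$birth || t >= obj$death) next
      m <- object_masks[[t + 1L]][[obj$id]]
      XL <- grids$X - obj$origins[t + 1L, 1]
      YL <- grids$Y - obj$origins[t + 1L, 2]
      texv <- .local_texture(XL, YL, tex)
      f[m] <- cfg$background + cfg$contrast + texv[m]
    }
    for (p in dust) {
      if (t < p$spawn || t >= p$spawn + p$life) next
      px <- p$pos[1] + p$vel[1] * (t - p$spawn) +
        (jit[t + 1L, 1] - jit[p$spawn + 1L, 1])
      py <- p$pos[2] + p$vel[2] * (t - p$spawn) +
        (jit[t + 1L, 2] - jit[p$spawn + 1L, 2])
      r <- p$radius
      c0 <- max(0, floor(px - r)); c1 <- min(W - 1, ceiling(px + r))
      r0 <- max(0, floor(py - r)); r1 <- min(H - 1, ceiling(py + r))
      if (c0 > c1 || r0 > r1) next
      xs <- c0:c1; ys <- r0:r1
      dd <- outer((ys - py)^2, (xs - px)^2, `+`) <= r^2
      sub <- f[ys + 1L, xs + 1L, drop = FALSE]
      sub[dd] <- cfg$dust_intensity
      f[ys + 1L, xs + 1L] <- sub
    }
    if (cfg$noise_sd > 0) f <- f + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
    if (blur[t + 1L]) f <- .box_blur3(f)
    frames[[t + 1L]] <- pmin(pmax(f, 0), 1)
  }

  structure(list(
    frames = frame_sequence(frames, frame_rate = cfg$frame_rate),
    masks = mask_sequence(masks),
    object_masks = object_masks,
    gt_events = gt_events,
    gt_tracks = gt_tracks,
    config = cfg,
    geometry = geometry), class = "synthetic_scene")
}

.box_blur3 <- function(f) {
  EBImage::filter2(f, matrix(1 / 9, 3, 3))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d frames %dx%d, %d event(s), %d gt points, seed %d\n",
              x$frames$n_frames, nrow(x$frames$frames[[1]]),
              ncol(x$frames$frames[[1]]), nrow(x$gt_events),
              x$gt_tracks$n_points, x$config$seed))
  invisible(x)
}

# Sample material points on the stone at frame 0 and advect them by
# the true object motion. A point's stone-local coordinate q is fixed;
# at a split it transfers to the fragment when q lies on the detaching
# side of the cut. Visibility is sticky-false once the owning object
# dies or the point leaves the frame.
.sample_gt_tracks <- function(geometry, mask0, n_points, W, H, T) {
  idx <- which(mask0)
  if (n_points > length(idx)) {
    ft_config_error("n_points (%d) exceeds stone area (%d px)",
                    n_points, length(idx))
  }
  pick <- sample(idx, n_points)
  rows <- (pick - 1L) %% H
  cols <- (pick - 1L) %/% H
  stone <- geometry$objects$stone
  qx <- cols - stone$origins[1, 1]
  qy <- rows - stone$origins[1, 2]

  frags <- geometry$objects[-1]
  x <- matrix(NA_real_, n_points, T)
  y <- matrix(NA_real_, n_points, T)
  vis <- matrix(FALSE, n_points, T)
  for (k in seq_len(n_points)) {
    q <- c(qx[k], qy[k])
    owner <- stone
    for (fr in frags) {
      if (!identical(owner$id, "stone")) break
      cut <- fr$cons[[length(fr$cons)]]
      if (cut$n[1] * q[1] + cut$n[2] * q[2] >= cut$d &&
          .in_shape_local(stone, q, fr$birth - 1L)) {
        # q is on the detaching side at this split; earlier cuts have
        # already been checked via the stone shape test
        sw <- fr$birth
        x[k, seq_len(sw)] <- q[1] + stone$origins[seq_len(sw), 1]
        y[k, seq_len(sw)] <- q[2] + stone$origins[seq_len(sw), 2]
        owner <- fr
        if (fr$death > sw) {
          tt <- (sw + 1L):min(fr$death, T)
          x[k, tt] <- q[1] + fr$origins[tt, 1]
          y[k, tt] <- q[2] + fr$origins[tt, 2]
        }
        break
      }
    }
    if (identical(owner$id, "stone")) {
      x[k, ] <- q[1] + stone$origins[, 1]
      y[k, ] <- q[2] + stone$origins[, 2]
      alive_to <- T
    } else {
      alive_to <- owner$death
    }
    inb <- !is.na(x[k, ]) & x[k, ] >= 0 & x[k, ] <= W - 1 &
      !is.na(y[k, ]) & y[k, ] >= 0 & y[k, ] <= H - 1
    inb[seq_len(T) > alive_to] <- FALSE
    # sticky invisibility
    dead <- which(!inb)
    if (length(dead)) inb[min(dead):T] <- FALSE
    vis[k, ] <- inb
  }
  x[!vis] <- NA_real_
  y[!vis] <- NA_real_
  # positions must exist at least at frame 0 for the set to be usable
  track_set(x, y, vis, init_frame = 0L)
}

#' Sample ground-truth material point tracks from a scene
#'
#' Points are drawn uniformly from the stone mask at frame 0 and
#' advected by the true object motion; points lying in a region that
#' later detaches follow the fragment from its split frame. Serves as
#' the tracking oracle for tracker and detector tests.
#'
#' @param scene a `synthetic_scene`.
#' @param n_points number of material points (>= 1; must not exceed the
#'   stone area in pixels).
#' @param seed seed for the point draw; defaults to `config$seed + 1`
#'   so it is decoupled from scene generation but still deterministic.
#' @return A [track_set()].
#' @export
ground_truth_points <- function(scene, n_points, seed = NULL) {
  if (!inherits(scene, "synthetic_scene")) {
    ft_input_error("ground_truth_points() needs a synthetic_scene")
  }
  if (n_points < 1) ft_config_error("n_points must be >= 1")
  if (is.null(seed)) seed <- scene$config$seed + 1L
  cfg <- scene$config
  withr::with_seed(seed,
    .sample_gt_tracks(scene$geometry, scene$masks$masks[[1]], n_points,
                      cfg$width, cfg$height, cfg$n_frames))
}
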