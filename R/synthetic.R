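# Synthetic stereo scenes with exact ground truth: a ridged, textured
# surface (spine proxy) viewed by two converging cameras, with landmark
# fiducials, global illumination scaling and additive pixel noise.

#' Default synthetic-scene parameters
#'
#' The rig defaults (400 mm baseline, 1000 px focal length, 1000 mm working
#' distance, 10 degree vergence) are documented plausible stand-ins for a
#' surgical stereo camera head, not measurements of any clinical system.
#' The surface is a central ridge (height 30 mm) with gentle undulation;
#' the procedural texture mixes band-limited speckle, flat-top elliptical
#' blobs sized for the MSER area window, and high-contrast Gaussian
#' landmark fiducials on a locally uniform surround so that landmark image
#' positions are recoverable to sub-pixel precision (the generator's
#' purpose is exact end-to-end validation).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
scene_params <- function(...) {
  p <- list(
    image_size = c(640, 480),     # width, height px
    baseline = 400,               # mm between camera centres
    focal = 1000,                 # px
    vergence_deg = 10,            # total convergence angle
    working_distance = 1000,      # mm from baseline midpoint to the surface
    surface_extent = 140,         # half-extent of the surface domain, mm
    ridge_height = 30,            # mm
    ridge_width = 45,             # Gaussian ridge sigma, mm
    undulation_amp = 5,           # mm, large-scale surface undulation
    n_landmarks = 20,
    landmark_min_sep = 30,        # mm
    base_albedo = 0.32,
    background = 0.02,
    speckle_amp = 0.012,           # RMS albedo contrast of the speckle field
    n_speckle = 40,
    speckle_wavelength = c(18, 60),  # mm
    blob_amp = 0.1,
    n_blobs = 12,
    blob_radius = c(6, 10),       # mm (~px at the default rig)
    dot_amp = c(0.8, 0.9),       # landmark fiducial contrast over surround
    dot_sigma = c(1.1, 2.0),      # mm
    dot_flat_radius = 10,         # px of locally uniform surround
    dot_blend_radius = 13,        # px, end of the surround blend
    illumination = 1.0,
    noise_sigma = 0               # additive Gaussian noise, 8-bit gray levels
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown scene parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p
}

# surface height (mm, positive toward the cameras); vectorized over u, v
scene_height <- function(scene, u, v) {
  p <- scene$params
  h <- p$ridge_height * exp(-u^2 / (2 * p$ridge_width^2))
  for (k in seq_along(scene$und_amp)) {
    h <- h + scene$und_amp[k] *
      cos(2 * pi * (u * scene$und_fx[k] + v * scene$und_fy[k]) + scene$und_ph[k])
  }
  h
}

# procedural albedo at surface coordinates (u, v) in mm
scene_albedo <- function(scene, u, v) {
  p <- scene$params
  a <- rep(p$base_albedo, length(u))
  sc <- p$speckle_amp * sqrt(2 / p$n_speckle)
  for (k in seq_len(p$n_speckle)) {
    a <- a + sc * cos(2 * pi * (u * scene$sp_fx[k] + v * scene$sp_fy[k]) +
                        scene$sp_ph[k])
  }
  for (k in seq_len(p$n_blobs)) {
    d2 <- (u - scene$blob_u[k])^2 + (v - scene$blob_v[k])^2
    a <- a + scene$blob_a[k] / (1 + (d2 / scene$blob_r[k]^2)^4)
  }
  pmin(pmax(a, 0.05), 0.95)
}

# Lambertian shading factor at surface coordinates (numeric normal)
scene_shade <- function(scene, u, v) {
  eps <- 0.5
  gx <- (scene_height(scene, u + eps, v) - scene_height(scene, u - eps, v)) /
    (2 * eps)
  gy <- (scene_height(scene, u, v + eps) - scene_height(scene, u, v - eps)) /
    (2 * eps)
  # surface z = -height; normal points toward the cameras (negative z)
  nx <- -gx; ny <- -gy; nz <- -1
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  l <- c(0.05, 0.04, -1); l <- l / sqrt(sum(l^2))  # toward the light
  ambient <- 0.5
  ambient + (1 - ambient) * pmax((nx * l[1] + ny * l[2] + nz * l[3]) / nn, 0)
}

#' Construct a synthetic stereo scene
#'
#' Draws a deterministic scene from `seed`: surface undulation, texture
#' speckle and blobs, landmark positions (rejection-sampled with a minimum
#' separation, placed on the surface exactly) and per-landmark fiducial
#' contrast/size, plus the converging stereo rig. At least the requested
#' number of landmarks must be visible in both views, otherwise the
#' geometry is infeasible.
#'
#' @param params A [scene_params()] list.
#' @param seed Integer seed; identical seeds give identical scenes.
#' @return An object of class `synthetic_scene` with the rig, landmark
#'   table and all texture parameters.
#' @export
make_scene <- function(params = scene_params(), seed = 1L) {
  p <- params
  if (p$vergence_deg < 0 || p$vergence_deg >= 90)
    stop("infeasible geometry: vergence must lie in [0, 90) degrees")
  w <- p$image_size[1]; h <- p$image_size[2]
  pp <- c((w - 1) / 2, (h - 1) / 2)
  half_v <- p$vergence_deg / 2 * pi / 180
  mk_cam <- function(side) {
    # side -1 = camera 1 (left), +1 = camera 2 (right); yawed inward
    C <- c(side * p$baseline / 2, 0, -p$working_distance)
    zc <- c(-side * sin(half_v), 0, cos(half_v))
    xc <- c(cos(half_v), 0, side * sin(half_v))
    yc <- c(0, 1, 0)
    camera_model(c(p$focal, p$focal), pp, rbind(xc, yc, zc), C)
  }
  rig <- stereo_rig(mk_cam(-1), mk_cam(1))

  scene <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    s <- list(params = p, seed = as.integer(seed), rig = rig)
    s$und_amp <- p$undulation_amp * c(1, 0.6, 0.4)
    wl <- stats::runif(3, 150, 400)
    th <- stats::runif(3, 0, pi)
    s$und_fx <- cos(th) / wl; s$und_fy <- sin(th) / wl
    s$und_ph <- stats::runif(3, 0, 2 * pi)
    wl <- stats::runif(p$n_speckle, p$speckle_wavelength[1],
                       p$speckle_wavelength[2])
    th <- stats::runif(p$n_speckle, 0, pi)
    s$sp_fx <- cos(th) / wl; s$sp_fy <- sin(th) / wl
    s$sp_ph <- stats::runif(p$n_speckle, 0, 2 * pi)
    ext <- p$surface_extent
    s$blob_u <- stats::runif(p$n_blobs, -ext + 15, ext - 15)
    s$blob_v <- stats::runif(p$n_blobs, -ext + 15, ext - 15)
    s$blob_r <- stats::runif(p$n_blobs, p$blob_radius[1], p$blob_radius[2])
    s$blob_a <- p$blob_amp * sample(c(-1, 1), p$n_blobs, replace = TRUE) *
      stats::runif(p$n_blobs, 0.7, 1)
    # landmark fiducials: rejection sampling with minimum separation
    margin <- 25
    lu <- numeric(0); lv <- numeric(0)
    tries <- 0
    while (length(lu) < p$n_landmarks && tries < 20000) {
      tries <- tries + 1
      cu <- stats::runif(1, -ext + margin, ext - margin)
      cv <- stats::runif(1, -ext + margin, ext - margin)
      if (length(lu) == 0 ||
          min((lu - cu)^2 + (lv - cv)^2) >= p$landmark_min_sep^2) {
        lu <- c(lu, cu); lv <- c(lv, cv)
      }
    }
    if (length(lu) < p$n_landmarks)
      stop("could not place ", p$n_landmarks,
           " landmarks at the requested separation")
    s$landmarks <- tibble::tibble(
      u = lu, v = lv,
      amp = stats::runif(p$n_landmarks, p$dot_amp[1], p$dot_amp[2]),
      sigma_mm = stats::runif(p$n_landmarks, p$dot_sigma[1], p$dot_sigma[2]))
    s
  })
  # exact 3D landmark positions on the surface
  lm3 <- cbind(scene$landmarks$u, scene$landmarks$v,
               -scene_height(scene, scene$landmarks$u, scene$landmarks$v))
  proj1 <- tryCatch(project(rig$cam1, lm3),
                    error = function(e) stop("infeasible geometry: ",
                                             conditionMessage(e)))
  proj2 <- tryCatch(project(rig$cam2, lm3),
                    error = function(e) stop("infeasible geometry: ",
                                             conditionMessage(e)))
  vis <- proj1[, 1] >= 0 & proj1[, 1] <= w - 1 &
    proj1[, 2] >= 0 & proj1[, 2] <= h - 1 &
    proj2[, 1] >= 0 & proj2[, 1] <= w - 1 &
    proj2[, 2] >= 0 & proj2[, 2] <= h - 1
  if (!all(vis))
    stop("infeasible geometry: landmarks project outside the views")
  scene$landmarks$X <- lm3[, 1]
  scene$landmarks$Y <- lm3[, 2]
  scene$landmarks$Z <- lm3[, 3]
  scene$landmarks$x1 <- proj1[, 1]; scene$landmarks$y1 <- proj1[, 2]
  scene$landmarks$x2 <- proj2[, 1]; scene$landmarks$y2 <- proj2[, 2]
  class(scene) <- "synthetic_scene"
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene> seed ", x$seed, ", ",
      nrow(x$landmarks), " landmarks, illumination ",
      x$params$illumination, ", noise sigma ", x$params$noise_sigma,
      " gray levels\n", sep = "")
  invisible(x)
}

# render a single camera view of the scene (no noise)
render_one_view <- function(scene, cam) {
  p <- scene$params
  w <- p$image_size[1]; h <- p$image_size[2]
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  d <- backproject_ray(cam, cbind(gx, gy))$direction
  C <- cam$center
  # intersect rays with the heightfield z = -height(u, v) by fixed point
  t <- (0 - C[3]) / d[, 3]
  for (it in 1:8) {
    u <- C[1] + t * d[, 1]
    v <- C[2] + t * d[, 2]
    zs <- -scene_height(scene, u, v)
    t <- (zs - C[3]) / d[, 3]
  }
  u <- C[1] + t * d[, 1]
  v <- C[2] + t * d[, 2]
  inside <- abs(u) <= p$surface_extent & abs(v) <= p$surface_extent
  img_v <- rep(p$background * p$illumination, w * h)
  if (any(inside)) {
    img_v[inside] <- p$illumination *
      scene_albedo(scene, u[inside], v[inside]) *
      scene_shade(scene, u[inside], v[inside])
  }
  img <- matrix(img_v, h, w)

  # landmark fiducials: analytic Gaussian dots on a locally uniform surround
  lm <- scene$landmarks
  proj <- project(cam, cbind(lm$X, lm$Y, lm$Z))
  depth <- sweep(cbind(lm$X, lm$Y, lm$Z), 2, C) %*% cam$rotation[3, ]
  r1 <- p$dot_flat_radius; r2 <- p$dot_blend_radius
  for (i in seq_len(nrow(lm))) {
    px <- proj[i, 1]; py <- proj[i, 2]
    sig <- lm$sigma_mm[i] * cam$focal[1] / depth[i]
    bg <- p$illumination * scene_albedo(scene, lm$u[i], lm$v[i]) *
      scene_shade(scene, lm$u[i], lm$v[i])
    amp <- p$illumination * lm$amp[i] * scene_shade(scene, lm$u[i], lm$v[i])
    # keep the fiducial peak inside the sensor's linear range (no clipping)
    amp <- min(amp, max(0.97 - bg, 0.05))
    c0 <- max(0, floor(px - r2)); c1 <- min(w - 1, ceiling(px + r2))
    rr0 <- max(0, floor(py - r2)); rr1 <- min(h - 1, ceiling(py + r2))
    if (c1 < c0 || rr1 < rr0) next
    xs <- c0:c1; ys <- rr0:rr1
    dx <- matrix(xs - px, length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys - py, length(ys), length(xs))
    dd <- sqrt(dx^2 + dy^2)
    m <- pmin(pmax((r2 - dd) / (r2 - r1), 0), 1)
    m <- m * m * (3 - 2 * m)  # smoothstep
    dot <- bg + amp * exp(-dd^2 / (2 * sig^2))
    sub <- img[ys + 1, xs + 1, drop = FALSE]
    img[ys + 1, xs + 1] <- sub * (1 - m) + dot * m
  }
  pmin(pmax(img, 0), 1)
}

#' Render the two camera views of a scene
#'
#' Perspective rendering of the textured, Lambert-shaded surface in both
#' cameras, scaled by the global illumination factor, with additive
#' Gaussian pixel noise (`noise_sigma`, in 8-bit gray levels) and clipping
#' to `[0, 1]`. Ground-truth landmark projections are computed analytically
#' with [project()], not estimated from the raster.
#'
#' @param scene A [make_scene()] result.
#' @return A list with `img1`, `img2` (matrices in `[0, 1]`) and
#'   `gt` — a tibble `X, Y, Z, x1, y1, x2, y2` of landmark positions (mm)
#'   and exact projections (0-based pixels).
#' @export
render_views <- function(scene) {
  img1 <- render_one_view(scene, scene$rig$cam1)
  img2 <- render_one_view(scene, scene$rig$cam2)
  ns <- scene$params$noise_sigma
  if (ns > 0) {
    imgs <- withr::with_seed(scene$seed + 1L, {
      list(pmin(pmax(img1 + matrix(stats::rnorm(length(img1), 0, ns / 255),
                                   nrow(img1)), 0), 1),
           pmin(pmax(img2 + matrix(stats::rnorm(length(img2), 0, ns / 255),
                                   nrow(img2)), 0), 1))
    })
    img1 <- imgs[[1]]; img2 <- imgs[[2]]
  }
  gt <- scene$landmarks[, c("X", "Y", "Z", "x1", "y1", "x2", "y2")]
  list(img1 = img1, img2 = img2, gt = gt)
}

#' Planted pixel correspondences with known labels
#'
#' Samples surface points, projects them into both views, perturbs the
#' projections with isotropic Gaussian pixel noise, and displaces a fixed
#' fraction of the view-2 points far off their epipolar line in y (at least
#' ten times the default epipolar tolerance), labelling them as outliers.
#'
#' @param scene A [make_scene()] result.
#' @param pixel_noise_sigma Noise on each projected coordinate, pixels.
#' @param outlier_fraction Fraction in `[0, 1)` of planted gross outliers.
#' @param seed Integer seed.
#' @param n_points Number of correspondences.
#' @return A list with `pts1`, `pts2` (n x 2), `labels`
#'   (`"inlier"`/`"outlier"`), and `points3d` (n x 3, mm).
#' @export
planted_correspondence_set <- function(scene, pixel_noise_sigma = 0,
                                       outlier_fraction = 0, seed = 1L,
                                       n_points = 500) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 1)
  p <- scene$params
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    ext <- p$surface_extent - 10
    u <- stats::runif(n_points, -ext, ext)
    v <- stats::runif(n_points, -ext, ext)
    P <- cbind(u, v, -scene_height(scene, u, v))
    p1 <- project(scene$rig$cam1, P)
    p2 <- project(scene$rig$cam2, P)
    if (pixel_noise_sigma > 0) {
      p1 <- p1 + matrix(stats::rnorm(2 * n_points, 0, pixel_noise_sigma),
                        n_points, 2)
      p2 <- p2 + matrix(stats::rnorm(2 * n_points, 0, pixel_noise_sigma),
                        n_points, 2)
    }
    labels <- rep("inlier", n_points)
    n_out <- round(n_points * outlier_fraction)
    if (n_out > 0) {
      which_out <- sample.int(n_points, n_out)
      labels[which_out] <- "outlier"
      p2[which_out, 2] <- p2[which_out, 2] +
        sample(c(-1, 1), n_out, replace = TRUE) *
        (50 + abs(stats::rnorm(n_out, 0, 10)))
    }
    list(pts1 = p1, pts2 = p2, labels = labels, points3d = P)
  })
}

#' Flat textured fixture image for region-detector tests
#'
#' A deterministic 2D image (no stereo geometry): hard-edged elliptical
#' regions of both polarities with areas inside the MSER window, on a
#' mid-gray background carrying only large-scale, sub-quantization shading.
#' Region boundaries are value-separated from the background by a wide
#' empty intensity gap, so the extremal pixel sets are crisp.
#'
#' @param seed Integer seed.
#' @param size Image side length in pixels.
#' @param n_blobs Number of elliptical regions.
#' @param speckle_amp Amplitude of the large-scale background shading.
#' @return A `size x size` matrix in `[0, 1]`.
#' @export
make_textured_fixture <- function(seed = 1L, size = 128, n_blobs = 6,
                                  speckle_amp = 0.0015) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    g <- expand.grid(y = 0:(size - 1), x = 0:(size - 1))
    img <- rep(0.5, nrow(g))
    nsp <- 6
    # large-scale shading below the 8-bit quantization step: the background
    # never forms stable extremal regions of its own
    wl <- stats::runif(nsp, size, 3 * size)
    th <- stats::runif(nsp, 0, pi)
    ph <- stats::runif(nsp, 0, 2 * pi)
    sc <- speckle_amp * sqrt(2 / nsp)
    for (k in seq_len(nsp)) {
      img <- img + sc * cos(2 * pi * (g$x * cos(th[k]) + g$y * sin(th[k])) /
                              wl[k] + ph[k])
    }
    # well-separated hard-edged ellipses, areas pi*ra*rb in [100, 800]
    bu <- numeric(0); bv <- numeric(0)
    tries <- 0
    while (length(bu) < n_blobs) {
      tries <- tries + 1
      sep <- if (tries > 5000) 30 else 38  # relax if the packing is tight
      cu <- stats::runif(1, 20, size - 20)
      cv <- stats::runif(1, 20, size - 20)
      if (length(bu) == 0 || min((bu - cu)^2 + (bv - cv)^2) >= sep^2) {
        bu <- c(bu, cu); bv <- c(bv, cv)
      }
    }
    ra <- stats::runif(n_blobs, 7, 13)
    rb <- pmin(pmax(stats::runif(n_blobs, 0.6, 1.4) * ra, 6), 750 / (pi * ra))
    ang <- stats::runif(n_blobs, 0, pi)
    amp <- sample(c(-1, 1), n_blobs, replace = TRUE) *
      stats::runif(n_blobs, 0.18, 0.26)
    for (k in seq_len(n_blobs)) {
      dx <- g$x - bu[k]; dy <- g$y - bv[k]
      xr <- dx * cos(ang[k]) + dy * sin(ang[k])
      yr <- -dx * sin(ang[k]) + dy * cos(ang[k])
      inside <- (xr / ra[k])^2 + (yr / rb[k])^2 <= 1
      img <- img + amp[k] * inside
    }
    matrix(pmin(pmax(img, 0), 1), size, size)
  })
}
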