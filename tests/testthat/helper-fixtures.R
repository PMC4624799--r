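# Shared fixtures (memoized per session) and brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small fast phantom: coarse voxels, small torso. derive_all ~ a few seconds.
small_spec <- function(...) {
  dots <- list(...)
  args <- list(
    torso_semiaxes = c(120, 95), height = 300, spacing = c(2.5, 2.5, 5),
    subcut_thickness = 24, wall_thickness_mean = 14, wall_thickness_amp = 4,
    wall_period = 125, visceral_semiaxes = c(45, 28),
    label_z_range = c(25, 275),
    hernia = list(center_x = 0, center_z = 150, semiaxes = c(45, 25, 60),
                  depth = 6),
    seed = 7L)
  # assign via list() so an explicit NULL (e.g. hernia = NULL) overrides the
  # default instead of deleting the element (modifyList would drop it)
  for (nm in names(dots)) args[nm] <- list(dots[[nm]])
  do.call(phantom_spec, args)
}

fx_hernia_phantom <- function() fixture("hernia_phantom", function() {
  make_phantom(small_spec())
})

fx_nohernia_phantom <- function() fixture("nohernia_phantom", function() {
  make_phantom(small_spec(hernia = NULL, seed = 11L))
})

# Default clinical-scale geometry at coarse voxels (for envelope checks).
fx_default_coarse <- function() fixture("default_coarse", function() {
  make_phantom(phantom_spec(spacing = c(2.5, 2.5, 5), seed = 3L))
})

# Analytic (non-rasterized) contour sets for an elliptic-cylinder wall:
# skin semi-axes (a, b) centered at (cx, cy), outer wall at depth s,
# inner wall at depth s + t(z), posterior likewise.
analytic_contours <- function(a = 120, b = 95, cx = 160, cy = 150, s = 24,
                              t_fun = function(z) rep(14, length(z)),
                              z_slices = seq(25, 275, by = 50),
                              n_theta = 64, gap_deg = 10) {
  gap <- gap_deg * pi / 180
  th_ant <- seq(gap, pi - gap, length.out = n_theta)
  th_post <- seq(pi + gap, 2 * pi - gap, length.out = n_theta)
  fr <- list(a = a, b = b, cx = cx, cy = cy)
  off_pt <- function(theta, d) {
    nx <- b * cos(theta); ny <- a * sin(theta)
    nn <- sqrt(nx^2 + ny^2)
    cbind(cx + a * cos(theta) - d * nx / nn, cy + b * sin(theta) - d * ny / nn)
  }
  build <- function(th, d_by_z) {
    do.call(rbind, lapply(z_slices, function(z) {
      p <- off_pt(th, d_by_z(z))
      cbind(p, z)
    }))
  }
  outer <- build(th_ant, function(z) s)
  inner <- build(th_ant, function(z) s + t_fun(z))
  post <- build(th_post, function(z) s + t_fun(z))
  info <- function(p) {
    zs <- sort(unique(p[, 3]))
    data.frame(z = zs,
               xmin = vapply(zs, function(z) min(p[p[, 3] == z, 1]), 1),
               xmax = vapply(zs, function(z) max(p[p[, 3] == z, 1]), 1))
  }
  structure(list(outer_anterior = outer, inner_anterior = inner,
                 posterior = post, slices_outer = info(outer),
                 slices_inner = info(inner), slices_posterior = info(post)),
            class = "contour_set")
}

# O(n^2) brute-force distance oracles (kept independent of the package's
# chunked implementation).
msd_brute <- function(A, B) {
  dmin_ab <- vapply(seq_len(nrow(A)), function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), 1)
  dmin_ba <- vapply(seq_len(nrow(B)), function(i)
    min(sqrt(colSums((t(A) - B[i, ])^2))), 1)
  (mean(dmin_ab) + mean(dmin_ba)) / 2
}

hd_brute <- function(A, B) {
  dmin_ab <- vapply(seq_len(nrow(A)), function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), 1)
  dmin_ba <- vapply(seq_len(nrow(B)), function(i)
    min(sqrt(colSums((t(A) - B[i, ])^2))), 1)
  max(max(dmin_ab), max(dmin_ba))
}

# Ground-truth tissue masks for a phantom, from continuous geometry.
phantom_body_mask_gt <- function(ph, spec) {
  vol <- ph$volume
  fr <- herniaquant:::phantom_frame(spec)
  dm <- dim(vol$intensity)
  xs <- vol$origin[1] + (seq_len(dm[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(dm[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(dm[3]) - 1) * vol$spacing[3]
  gx <- array(xs, dm); gy <- array(rep(ys, each = dm[1]), dm)
  gz <- array(rep(zs, each = dm[1] * dm[2]), dm)
  inside <- ((gx - fr$cx) / fr$a)^2 + ((gy - fr$cy) / fr$b)^2 <= 1
  inside | array(herniaquant:::hernia_inside(spec, fr, as.vector(gx),
                                             as.vector(gy), as.vector(gz)), dm)
}
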