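# Shared fixtures (memoised across test files) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Concentric spheres r=20, R=22, 0.5 mm voxels, noise-free: the analytic
# workhorse for thickness / wall-volume checks.
fix_sphere <- function() fixture("sphere", function() {
  make_phantom(phantom_spec("concentric_spheres", endo_radius = 20,
                            wall_thickness = 2, spacing = 0.5,
                            noise_sd = 0, seed = 1))
})

fix_sphere_wall <- function() fixture("sphere_wall", function() {
  ph <- fix_sphere()
  suppressMessages(build_wall_mask(ph$ct, ph$truth$endo, ph$truth$epi))
})

# LA-like phantom, 1 mm voxels, 10 HU noise, with two segment-targeted
# deposits at paper-scale volumes (0.15 mL dense in the LSPV antrum,
# 0.05 mL admixture in the posterior wall).
fix_la <- function() fixture("la", function() {
  ph <- make_phantom(phantom_spec("la_like", spacing = 1.0,
                                  noise_sd = 10, seed = 7))
  ph <- plant_fat(ph, 0.15, "dense", segment = 16)
  plant_fat(ph, 0.05, "admixture", segment = 2)
})

fix_la_run <- function() fixture("la_run", function() {
  ph <- fix_la()
  wall <- suppressMessages(build_wall_mask(ph$ct, ph$truth$endo, ph$truth$epi,
                                           landmarks = ph$truth$landmarks))
  seg <- parcellate(ph$truth$epi, ph$truth$landmarks)
  labels <- label_wall_voxels(seg, wall, ph$ct)
  classes <- classify_fat(ph$ct, wall)
  list(phantom = ph, wall = wall, segments = seg, labels = labels,
       classes = classes,
       metrics = compute_metrics(classes, ph$ct, wall, endo = ph$truth$endo))
})

# Independent point-in-mesh oracle: generalised winding number
# (van Oosterom & Strackee solid-angle formula), pure R, no shared code with
# the scanline voxelizer.
winding_inside <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    a <- t(v[f[, 1], , drop = FALSE]) - p
    b <- t(v[f[, 2], , drop = FALSE]) - p
    c_ <- t(v[f[, 3], , drop = FALSE]) - p
    la <- sqrt(colSums(a^2)); lb <- sqrt(colSums(b^2)); lc <- sqrt(colSums(c_^2))
    num <- a[1, ] * (b[2, ] * c_[3, ] - b[3, ] * c_[2, ]) +
           a[2, ] * (b[3, ] * c_[1, ] - b[1, ] * c_[3, ]) +
           a[3, ] * (b[1, ] * c_[2, ] - b[2, ] * c_[1, ])
    den <- la * lb * lc + colSums(a * b) * lc +
           colSums(a * c_) * lb + colSums(b * c_) * la
    w <- sum(atan2(num, den)) / (2 * pi)
    abs(w) > 0.5
  }, logical(1))
}

# Kruskal-Wallis H from first principles (rank formula, no ties assumed).
kw_rank_oracle <- function(groups_list) {
  x <- unlist(groups_list)
  r <- rank(x)
  n <- length(x)
  sizes <- lengths(groups_list)
  idx <- split(seq_len(n), rep(seq_along(groups_list), sizes))
  rbar <- vapply(idx, function(ii) mean(r[ii]), numeric(1))
  12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
}

# ANCOVA group F from explicit normal equations (reduced vs full model RSS).
ancova_f_oracle <- function(y, g, z) {
  Xf <- cbind(1, as.numeric(g == levels(g)[2]), z)
  Xr <- cbind(1, z)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  df1 <- nlevels(g) - 1
  df2 <- length(y) - ncol(Xf)
  Fv <- ((rss(Xr) - rss(Xf)) / df1) / (rss(Xf) / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

rotation_matrix <- function(ax, angle) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
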