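pv <- l23continuum:::polyval

test_that("an exact quartic is recovered with no pruning", {
  cf <- c(150, -0.12, 6e-5, -8e-9, 4e-13)
  set.seed(21)
  x <- runif(200, 0, 4000)
  cells <- data.frame(x_um = x, y_um = pv(cf, x), anchor_flag = TRUE)
  fit <- fit_pial_surface(cells)
  expect_lt(max(abs((as.numeric(fit) - cf) / cf)), 1e-6)
  expect_equal(attr(fit, "n_anchors_retained"), 200)
})

test_that("deep outliers are pruned and the curve recovered within 5 um", {
  cf <- c(150, -0.12, 6e-5, -8e-9, 4e-13)
  set.seed(22)
  x <- runif(300, 0, 4000)
  y <- pv(cf, x) + rnorm(300, 0, 1)
  xo <- x[1:30]; yo <- pv(cf, xo) + 400   # 10% planted outliers at 400 um
  cells <- data.frame(x_um = c(x, xo), y_um = c(y, yo), anchor_flag = TRUE)
  fit <- fit_pial_surface(cells)
  xs <- seq(0, 4000, by = 10)
  expect_lt(max(abs(pv(as.numeric(fit), xs) - pv(cf, xs))), 5)
  # every outlier pruned
  expect_lte(attr(fit, "n_anchors_retained"), 300)
  expect_error(fit_pial_surface(cells[1:5, ]), ">= 10 anchor")
})

test_that("pial fitting is idempotent on the retained anchors", {
  cf <- c(100, 0.05, 1e-5, 0, 0)
  set.seed(23)
  x <- runif(100, 0, 3000)
  cells <- data.frame(x_um = x, y_um = pv(cf, x) + rnorm(100, 0, 0.5),
                      anchor_flag = TRUE)
  f1 <- fit_pial_surface(cells)
  f2 <- fit_pial_surface(cells)  # same input, same answer
  expect_identical(as.numeric(f1), as.numeric(f2))
})

test_that("coordinates reduce to the obvious answers on flat curves", {
  flat <- structure(c(0, 0, 0, 0, 0), domain = c(0, 4000))
  fr <- assign_cortical_coordinates(
    data.frame(cell_id = c("a", "b"), x_um = c(1234, 100), y_um = c(55, 0)),
    flat)
  expect_equal(fr$depth_um, c(55, 0), tolerance = 1e-9)
  expect_equal(fr$tangent_um, c(1234, 100), tolerance = 1e-9)
  expect_false(any(fr$extrapolated))
  # outside the domain by > 10% of its width
  fr2 <- assign_cortical_coordinates(
    data.frame(cell_id = "c", x_um = 4500, y_um = 10), flat)
  expect_true(fr2$extrapolated)
})

test_that("a cell offset along the normal gets its construction depth", {
  cf <- c(0, 0, 1e-4, 0, 0)
  px <- seq(200, 3800, by = 200)
  nn <- l23continuum:::curve_normal(cf, px)
  pts <- cbind(px, pv(cf, px)) + 100 * nn
  fr <- assign_cortical_coordinates(
    data.frame(cell_id = as.character(seq_along(px)),
               x_um = pts[, 1], y_um = pts[, 2]),
    structure(cf, domain = c(0, 4000)))
  expect_lt(max(abs(fr$depth_um - 100)), 0.5)
})

test_that("coordinates are invariant to rigid translation", {
  cf <- c(150, -0.12, 6e-5, -8e-9, 4e-13)
  set.seed(24)
  x <- runif(150, 0, 4000)
  anch <- data.frame(x_um = x, y_um = pv(cf, x) + rnorm(150, 0, 1),
                     anchor_flag = TRUE)
  qx <- runif(40, 500, 3500)
  cells <- data.frame(cell_id = as.character(1:40), x_um = qx,
                      y_um = pv(cf, qx) + runif(40, 50, 400))
  f0 <- assign_cortical_coordinates(cells, fit_pial_surface(anch))
  sh <- c(500, -200)
  anch2 <- transform(anch, x_um = x_um + sh[1], y_um = y_um + sh[2])
  cells2 <- transform(cells, x_um = x_um + sh[1], y_um = y_um + sh[2])
  f1 <- assign_cortical_coordinates(cells2, fit_pial_surface(anch2))
  expect_equal(f1$depth_um, f0$depth_um, tolerance = 1e-3)
  expect_equal(f1$tangent_um, f0$tangent_um, tolerance = 1e-2)
})

test_that("V1 localization recovers a planted marker interval", {
  set.seed(25)
  n <- 2000
  t <- runif(n, 0, 5000)
  frame <- data.frame(cell_id = as.character(1:n), depth_um = runif(n, 0, 400),
                      tangent_um = t)
  inside <- t >= 1500 & t <= 3500   # planted V1, width 2000 um
  on <- rpois(n, ifelse(inside, 8, 2))   # 4-fold contrast
  off <- rpois(n, ifelse(inside, 2, 8))
  v1 <- locate_v1(frame, on, off, smoothing_um = 100)
  # boundary bias is on the order of the kernel width
  expect_lt(abs(v1[["tm"]] - 1500), 150)
  expect_lt(abs(v1[["tl"]] - 3500), 150)
  expect_gt(diff(v1), 1800)  # ~2 mm wide, the reported V1 scale
  # degenerate: constant profiles qualify everywhere -> full extent
  v1d <- locate_v1(frame, rep(5, n), rep(1, n))
  expect_lt(v1d[["tm"]], min(t) + 30)
  expect_gt(v1d[["tl"]], max(t) - 30)
})

test_that("tangential normalization maps V1 ends to 0 and 1", {
  frame <- data.frame(cell_id = c("a", "b", "c", "d"),
                      depth_um = rep(0, 4),
                      tangent_um = c(1000, 3000, 2000, 500))
  fr <- normalize_tangential(frame, c(tm = 1000, tl = 3000))
  expect_equal(fr$tangent_norm, c(0, 1, 0.5, -0.25))
  expect_error(normalize_tangential(frame, c(5, 5)), "degenerate")
  # scale invariance: microns -> arbitrary units leaves t-tilde unchanged
  fr2 <- normalize_tangential(transform(frame, tangent_um = tangent_um * 3.7),
                              c(tm = 3700, tl = 11100))
  expect_equal(fr2$tangent_norm, fr$tangent_norm)
})

test_that("depth profiles localize a planted gradient and keep empty bins NA", {
  set.seed(26)
  n <- 1200
  depth <- runif(n, 0, 380)  # leave 380-400 empty
  ids <- sprintf("c%04d", 1:n)
  lam <- 5 * exp(-((depth - 200) / 50)^2) + 0.2
  cnt <- cbind(gene1 = rpois(n, lam), gene2 = rpois(n, 2))
  rownames(cnt) <- ids
  nm <- normalized_matrix(log10(cnt + 1), scale(log10(cnt + 1)),
                          provenance = "test")
  frame <- data.frame(cell_id = ids, depth_um = depth,
                      sample = rep(c("s1", "s2"), length.out = n))
  prof <- depth_expression_profile(frame, nm, "gene1", n_bins = 20,
                                   depth_range = c(0, 400))
  expect_true(is.na(prof$mean[20]))
  peak <- prof$bin_mid_um[which.max(prof$mean)]
  expect_lt(abs(peak - 200), 30)
  # spatially uniform gene: flat within sampling error
  prof2 <- depth_expression_profile(frame, nm, "gene2", n_bins = 10,
                                    depth_range = c(0, 380))
  expect_lt(diff(range(prof2$mean)), 0.25)
})
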