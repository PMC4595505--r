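fc_fixture <- function(nt = 60, d = c(6, 6, 6), seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  s <- bold_series(arr, 2)
  masks <- list(
    brain = brain_mask(array(TRUE, d)),
    csf = brain_mask({m <- array(FALSE, d); m[1, 1, 1:2] <- TRUE; m}),
    wm = brain_mask({m <- array(FALSE, d); m[6, 6, 5:6] <- TRUE; m}),
    seed = brain_mask({m <- array(FALSE, d); m[3:4, 3:4, 3] <- TRUE; m}))
  motion <- motion_trace(matrix(rnorm(nt * 3, sd = 0.05), nt, 3),
                         matrix(rnorm(nt * 3, sd = 0.001), nt, 3))
  list(series = s, masks = masks, motion = motion, nt = nt, d = d)
}

test_that("the nuisance set has the documented columns, centered", {
  fx <- fc_fixture()
  nu <- build_nuisance(fx$motion, fx$series, fx$masks$csf, fx$masks$wm,
                       include_global = TRUE, global_mask = fx$masks$brain)
  expect_equal(ncol(nu$regressors), 9)
  expect_equal(colnames(nu$regressors),
               c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                 "csf", "wm", "global"))
  expect_lt(max(abs(colMeans(nu$regressors))), 1e-12)
  nug <- build_nuisance(fx$motion, fx$series, fx$masks$csf, fx$masks$wm,
                        include_global = FALSE)
  expect_equal(ncol(nug$regressors), 8)
  # global column is the voxelwise mean over the brain mask (centered)
  g <- colMeans(matrix(fx$series$data, prod(fx$d), fx$nt))
  expect_equal(nu$regressors[, "global"], g - mean(g), ignore_attr = TRUE)
  # constant columns are dropped with a warning
  still <- motion_trace(matrix(0, fx$nt, 3), fx$motion$rotations)
  expect_warning(nu0 <- build_nuisance(still, fx$series, fx$masks$csf,
                                       fx$masks$wm, FALSE),
                 "trans_x")
  expect_equal(ncol(nu0$regressors), 5)
})

test_that("nuisance regression is an orthogonal projection", {
  fx <- fc_fixture(seed = 5)
  nu <- build_nuisance(fx$motion, fx$series, fx$masks$csf, fx$masks$wm,
                       include_global = TRUE, global_mask = fx$masks$brain)
  # a series equal to a regressor is annihilated
  res <- regress_nuisance(nu$regressors[, "csf"] + 3, nu)
  expect_lt(max(abs(res)), 1e-10)
  # residuals orthogonal to every retained regressor
  y <- rnorm(fx$nt)
  r <- regress_nuisance(y, nu)
  for (j in seq_len(ncol(nu$regressors)))
    expect_lt(abs(sum(r * nu$regressors[, j])),
              1e-8 * sqrt(sum(r^2)) * sqrt(sum(nu$regressors[, j]^2)))
  # hand-computed projection on a 3-regressor toy design
  set.seed(7)
  R <- matrix(rnorm(60), 20, 3)
  toy <- structure(list(regressors = scale(R, scale = FALSE),
                        dropped = character()), class = "nuisance_set")
  yy <- rnorm(20)
  X <- cbind(1, toy$regressors)
  beta <- solve(crossprod(X), crossprod(X, yy))
  expect_equal(regress_nuisance(yy, toy), as.vector(yy - X %*% beta),
               tolerance = 1e-10)
  # a series orthogonal to all regressors only loses its mean
  ortho <- regress_nuisance(yy - X %*% beta + 2, toy)
  expect_equal(ortho, as.vector(yy - X %*% beta), tolerance = 1e-10)
  # collinear columns are dropped with a warning, then the fit proceeds
  dup <- structure(list(regressors = cbind(a = toy$regressors[, 1],
                                           b = toy$regressors[, 1]),
                        dropped = character()), class = "nuisance_set")
  expect_warning(rr <- regress_nuisance(yy, dup), "collinear")
  expect_length(rr, 20)
})

test_that("seed time courses are voxel means over the seed", {
  fx <- fc_fixture(seed = 9)
  one <- brain_mask({m <- array(FALSE, fx$d); m[2, 2, 2] <- TRUE; m})
  expect_equal(seed_timecourse(fx$series, one), fx$series$data[2, 2, 2, ])
  # anticorrelated pair averages to zero
  s2 <- fx$series
  s2$data[1, 2, 3, ] <- 5 * sin(seq_len(fx$nt))
  s2$data[2, 2, 3, ] <- -5 * sin(seq_len(fx$nt))
  pair <- brain_mask({m <- array(FALSE, fx$d); m[1:2, 2, 3] <- TRUE; m})
  expect_lt(max(abs(seed_timecourse(s2, pair))), 1e-12)
})

test_that("FC maps are clamped Fisher transforms of voxel correlations", {
  fx <- fc_fixture(seed = 13)
  s <- bandpass_filter(fx$series, band_spec())
  nu <- build_nuisance(fx$motion, s, fx$masks$csf, fx$masks$wm,
                       include_global = FALSE)
  s <- regress_nuisance(s, nu)
  seed_ts <- s$data[3, 3, 3, ]
  fc <- fc_zmap(s, seed_ts, fx$masks$brain)
  # the seed voxel itself: r clamped, z = atanh(1 - 1e-7)
  expect_equal(fc$r[3, 3, 3], 1 - 1e-7)
  expect_equal(fc$z[3, 3, 3], atanh(1 - 1e-7))
  # an anti-correlated voxel is clamped symmetrically
  s$data[1, 1, 3, ] <- -seed_ts
  fc2 <- fc_zmap(s, seed_ts, fx$masks$brain)
  expect_equal(fc2$r[1, 1, 3], -(1 - 1e-7))
  # z = atanh(r) everywhere in the mask
  expect_equal(fc$z[fx$masks$brain$data], atanh(fc$r[fx$masks$brain$data]))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # provenance is enforced
  expect_error(fc_zmap(fx$series, seed_ts, fx$masks$brain), "bandpass")
  # zero-variance voxels get r = 0 and a QC entry
  s$data[2, 1, 1, ] <- 0
  fc3 <- fc_zmap(s, seed_ts, fx$masks$brain)
  expect_equal(fc3$r[2, 1, 1], 0)
  expect_true(any(fc3$qc$i == 2 & fc3$qc$j == 1 & fc3$qc$k == 1))
})

test_that("group sign maps label coherent regions and flip with the data", {
  d <- c(8, 8, 8)
  mask <- brain_mask(array(TRUE, d))
  region <- array(FALSE, d); region[3:6, 3:6, 3:5] <- TRUE
  set.seed(19)
  make_z <- function(mu) {
    z <- array(rnorm(prod(d), 0, 0.1), d)
    z[region] <- z[region] + mu
    structure(list(r = tanh(z), z = z, seed_label = "seed", mask = mask,
                   qc = NULL), class = "fc_map")
  }
  zmaps <- lapply(1:8, function(i) make_z(0.6))
  null <- monte_carlo_cluster_null(mask, fwhm_mm = 0, n_iterations = 200,
                                   seed = 3)
  sm <- group_sign_map(zmaps, null)
  expect_gte(mean(sm$sign[region] == 1), 0.95)
  expect_lte(mean(sm$sign[!region] != 0), 0.1)
  # sign flip of every input flips the labels
  neg <- lapply(zmaps, function(m) { m$z <- -m$z; m$r <- -m$r; m })
  smn <- group_sign_map(neg, null)
  expect_equal(smn$sign, -sm$sign)
})

test_that("group comparisons are antisymmetric and recover injected couplings", {
  d <- c(8, 8, 8)
  mask <- brain_mask(array(TRUE, d))
  region <- array(FALSE, d); region[2:5, 2:5, 2:4] <- TRUE  # 48 voxels
  null <- monte_carlo_cluster_null(mask, fwhm_mm = 0, n_iterations = 300,
                                   seed = 4)
  set.seed(23)
  make_group <- function(n, mu) lapply(seq_len(n), function(i) {
    z <- array(rnorm(prod(d), 0, 0.15), d)
    z[region] <- z[region] + mu
    structure(list(r = tanh(z), z = z, seed_label = "s", mask = mask,
                   qc = NULL), class = "fc_map")
  })
  a <- make_group(11, 0.6); b <- make_group(13, 0)
  cmp <- fc_group_compare(a, b, mask, null)
  expect_gt(nrow(cmp$clusters), 0)
  expect_gte(sum(cmp$sig & region) / sum(region), 0.9)
  rev <- fc_group_compare(b, a, mask, null)
  expect_equal(rev$stat_map$stat, -cmp$stat_map$stat)
  expect_equal(rev$sig, cmp$sig)
  # identical groups: empty table
  same <- fc_group_compare(a, a, mask, null)
  expect_equal(nrow(same$clusters), 0)
})

test_that("the connectivity-change taxonomy follows the sign/direction rules", {
  expect_equal(classify_change("positive", "positive", "a_greater"),
               "positive_increased")
  expect_equal(classify_change("positive", "positive", "b_greater"),
               "positive_decreased")
  # shared negative sign: magnitude reading (more negative = increased)
  expect_equal(classify_change("negative", "negative", "a_greater"),
               "negative_decreased")
  expect_equal(classify_change("negative", "negative", "b_greater"),
               "negative_increased")
  # differing types: direction of the shift
  expect_equal(classify_change("negative", "positive", "b_greater"),
               "negative_change")
  expect_equal(classify_change("positive", "negative", "a_greater"),
               "positive_change")
  expect_equal(classify_change("none", "positive", "b_greater"),
               "negative_change")
  expect_equal(classify_change("negative", "none", "a_greater"),
               "positive_change")
  expect_error(classify_change("none", "none", "a_greater"), "none")
  expect_error(classify_change("up", "none", "a_greater"), "Signs")
})

test_that("classification is invariant to common positive rescaling of z-maps", {
  d <- c(8, 8, 8)
  mask <- brain_mask(array(TRUE, d))
  region <- array(FALSE, d); region[3:6, 3:6, 3:5] <- TRUE
  null <- monte_carlo_cluster_null(mask, fwhm_mm = 0, n_iterations = 200,
                                   seed = 11)
  set.seed(31)
  mk <- function(n, mu, scale = 1) lapply(seq_len(n), function(i) {
    z <- array(rnorm(prod(d), 0, 0.12), d)
    z[region] <- z[region] + mu
    z <- z * scale
    structure(list(r = tanh(z), z = z, seed_label = "s", mask = mask,
                   qc = NULL), class = "fc_map")
  })
  set.seed(100); a1 <- mk(8, 0.5); set.seed(200); b1 <- mk(8, 0.2)
  set.seed(100); a2 <- mk(8, 0.5, scale = 3); set.seed(200); b2 <- mk(8, 0.2, scale = 3)
  s_a1 <- group_sign_map(a1, null); s_b1 <- group_sign_map(b1, null)
  s_a2 <- group_sign_map(a2, null); s_b2 <- group_sign_map(b2, null)
  c1 <- fc_group_compare(a1, b1, mask, null)
  c2 <- fc_group_compare(a2, b2, mask, null)
  ch1 <- classify_cluster_changes(c1, s_a1, s_b1)
  ch2 <- classify_cluster_changes(c2, s_a2, s_b2)
  expect_equal(ch1$label, ch2$label)
})
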