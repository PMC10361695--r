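# Intensity-threshold WMH segmentation and CSF-adjacent component removal.

gauss_volume <- function(n = 64, mean = 100, sd = 10, seed = 1) {
  v <- array(0, c(n, n, n))
  set.seed(seed)
  v[] <- rnorm(n^3, mean, sd)
  intensity_volume(v, spacing = c(1, 1, 1))
}

test_that("mask statistics are the sample mean and SD over the brain mask", {
  v <- array(0, c(2, 2, 2))
  bm <- array(FALSE, c(2, 2, 2))
  v[1, 1, 1] <- 90; v[2, 1, 1] <- 110
  bm[1, 1, 1] <- TRUE; bm[2, 1, 1] <- TRUE
  vol <- intensity_volume(v, c(1, 1, 1), brain_mask = bm)
  st <- estimate_stats(vol)
  expect_equal(st$mu_I, 100)
  expect_equal(st$sigma_I, 10 * sqrt(2), tolerance = 1e-12)   # ddof = 1
  expect_equal(st$n, 2)

  vol <- gauss_volume(100, 100, 10, seed = 3)
  st <- estimate_stats(vol)
  expect_equal(st$mu_I, 100, tolerance = 0.05)
  expect_equal(st$sigma_I, 10, tolerance = 0.05)

  empty <- intensity_volume(array(1, c(2, 2, 2)), c(1, 1, 1),
                            brain_mask = array(FALSE, c(2, 2, 2)))
  expect_error(estimate_stats(empty), "empty")
})

test_that("constant volumes are rejected at the threshold step", {
  vol <- intensity_volume(array(5, c(3, 3, 3)), c(1, 1, 1))
  st <- estimate_stats(vol)
  expect_equal(st$sigma_I, 0)
  expect_error(threshold_mask(vol, st), "sigma")
})

test_that("background-only false-positive fraction matches the normal tail", {
  vol <- gauss_volume(100, seed = 9)
  st <- estimate_stats(vol, k = 2.5)
  m <- threshold_mask(vol, st)
  n <- sum(vol$brain_mask)
  p_exp <- 1 - pnorm(2.5)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(sum(m$mask) / n - p_exp), 3 * se)
})

test_that("threshold masks nest with k and empty out when nothing exceeds", {
  vol <- gauss_volume(48, seed = 5)
  m25 <- threshold_mask(vol, estimate_stats(vol, k = 2.5))
  m30 <- threshold_mask(vol, estimate_stats(vol, k = 3.0))
  expect_true(all(m25$mask[m30$mask]))
  expect_lt(sum(m30$mask), sum(m25$mask))

  u <- intensity_volume(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  mu <- threshold_mask(u, estimate_stats(u, k = 2.5))
  expect_equal(sum(mu$mask), 0)
})

test_that("connected-component labeling follows 26/6 connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE    # diagonal: 26-connected, not 6-connected
  m[4, 4, 4] <- TRUE
  l26 <- label_components(m, 26)
  expect_equal(l26[1, 1, 1], l26[2, 2, 2])
  expect_false(l26[4, 4, 4] == l26[1, 1, 1])
  l6 <- label_components(m, 6)
  expect_false(l6[1, 1, 1] == l6[2, 2, 2])
  expect_equal(max(l6), 3)
})

test_that("CSF-adjacent component removal uses the strict 50% boundary rule", {
  d <- c(7, 7, 3)
  mask <- array(FALSE, d); csf <- array(FALSE, d)
  # component A: single voxel with 4 of 6 faces CSF-adjacent -> removed
  mask[2, 2, 2] <- TRUE
  csf[1, 2, 2] <- csf[3, 2, 2] <- csf[2, 1, 2] <- csf[2, 3, 2] <- TRUE
  # component B: single voxel with 3 of 6 faces CSF-adjacent -> retained
  mask[5, 5, 2] <- TRUE
  csf[4, 5, 2] <- csf[6, 5, 2] <- csf[5, 4, 2] <- TRUE
  wm <- structure(list(mask = mask, provenance = list(k = 2.5, components_removed = FALSE)),
                  class = "wmh_mask")
  out <- remove_csf_adjacent_components(wm, csf)
  expect_false(out$mask[2, 2, 2])
  expect_true(out$mask[5, 5, 2])

  # fully surrounded by CSF -> removed; zero contact -> retained
  mask2 <- array(FALSE, d); csf2 <- array(FALSE, d)
  mask2[4, 4, 2] <- TRUE
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    csf2[4 + o[1], 4 + o[2], 2 + o[3]] <- TRUE
  mask2[2, 6, 2] <- TRUE
  wm2 <- structure(list(mask = mask2, provenance = list(k = 2.5, components_removed = FALSE)),
                   class = "wmh_mask")
  out2 <- remove_csf_adjacent_components(wm2, csf2)
  expect_false(out2$mask[4, 4, 2])
  expect_true(out2$mask[2, 6, 2])
})

test_that("component removal equals the brute-force face-counting oracle and is idempotent", {
  set.seed(14)
  for (rep in 1:6) {
    d <- c(8, 8, 6)
    mask <- array(runif(prod(d)) < 0.12, d)
    csf <- array(runif(prod(d)) < 0.25, d) & !mask
    wm <- structure(list(mask = mask, provenance = list(k = 2.5, components_removed = FALSE)),
                    class = "wmh_mask")
    out <- remove_csf_adjacent_components(wm, csf)
    expect_identical(out$mask, csf_removal_oracle(mask, csf))
    out2 <- remove_csf_adjacent_components(out, csf)
    expect_identical(out2$mask, out$mask)
  }
})

test_that("planted phantom lesions are recovered with high recall and precision", {
  m <- default_phantom()
  recall <- precision <- numeric(10)
  for (s in 1:10) {
    vol <- synthesize_flair_volume(m, lesion_contrast = 4, seed = 100 + s)
    mask <- segment_wmh(vol, k = 2.5)
    truth <- attr(vol, "wmh_truth")
    tp <- sum(mask$mask & truth)
    recall[s] <- tp / sum(truth)
    precision[s] <- tp / max(sum(mask$mask), 1)
  }
  expect_gte(mean(recall), 0.95)
  expect_gte(mean(precision), 0.9)
})
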