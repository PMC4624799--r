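test_that("MSD and HD satisfy their defining cases", {
  A <- cbind(seq(0, 100, by = 1), 0, 0)
  expect_equal(mean_surface_distance(A, A), 0)
  expect_equal(hausdorff_distance(A, A), 0)
  # parallel line contours 2 mm apart
  B <- cbind(seq(0, 100, by = 1), 2, 0)
  expect_equal(mean_surface_distance(A, B), 2)
  expect_equal(hausdorff_distance(A, B), 2)
  # one 90 mm outlier dominates HD but barely moves MSD
  B2 <- rbind(A, c(50, 90, 0))
  expect_gt(hausdorff_distance(A, B2), 85)
  expect_lt(mean_surface_distance(A, B2), 1)
  expect_error(mean_surface_distance(A[0, ], B), "empty")
  expect_error(hausdorff_distance(A, B[0, ]), "empty")
})

test_that("distance statistics agree with brute-force oracles", {
  set.seed(14)
  for (rep in 1:5) {
    A <- matrix(runif(40 * 3, 0, 100), ncol = 3)
    B <- matrix(runif(55 * 3, 0, 100), ncol = 3)
    expect_equal(mean_surface_distance(A, B), msd_brute(A, B), tolerance = 1e-9)
    expect_equal(hausdorff_distance(A, B), hd_brute(A, B), tolerance = 1e-9)
    # symmetry and MSD <= HD
    expect_equal(mean_surface_distance(A, B), mean_surface_distance(B, A))
    expect_equal(hausdorff_distance(A, B), hausdorff_distance(B, A))
    expect_lte(mean_surface_distance(A, B), hausdorff_distance(A, B))
  }
  # larger sets, exact agreement still required
  A <- matrix(runif(200 * 3, 0, 50), ncol = 3)
  B <- matrix(runif(180 * 3, 0, 50), ncol = 3)
  expect_equal(mean_surface_distance(A, B), msd_brute(A, B), tolerance = 1e-9)
  expect_equal(hausdorff_distance(A, B), hd_brute(A, B), tolerance = 1e-9)
})

test_that("Cohen's kappa matches hand-computed tables", {
  dm <- c(10, 10, 1)
  region <- array(TRUE, dm)
  # constructed 2x2 table a=40, b=10, c=10, d=40 -> p_o=0.8, p_e=0.5, k=0.6
  A <- array(FALSE, dm); B <- array(FALSE, dm)
  A[1:50] <- TRUE                       # A positive on voxels 1..50
  B[c(1:40, 51:60)] <- TRUE             # agree on 40 pos, 40 neg
  expect_equal(cohen_kappa_masks(A, B, region), 0.6)
  # perfect agreement inside a larger region
  expect_equal(cohen_kappa_masks(A, A, region), 1)
  # disjoint equal halves -> kappa = -1
  C <- array(FALSE, dm); D <- array(FALSE, dm)
  C[1:50] <- TRUE; D[51:100] <- TRUE
  expect_equal(cohen_kappa_masks(C, D, region), -1)
  # invariance under simultaneous complementation within the region
  expect_equal(cohen_kappa_masks(!A, !B, region),
               cohen_kappa_masks(A, B, region))
  # degenerate marginals -> NA with warning
  E <- array(TRUE, dm)
  expect_warning(k <- cohen_kappa_masks(E, E, region), "degenerate")
  expect_true(is.na(k))
  expect_error(cohen_kappa_masks(A, B, array(FALSE, dm)), "empty|contain")
})

test_that("landmark representative-point rules dispatch correctly", {
  dm <- c(20, 20, 20)
  reg <- label_registry()
  labels <- array(0L, dm)
  # pubic symphysis blob spanning z: most superior voxel wins
  labels[10, 10, 5:8] <- reg[["pubic_symphysis"]]
  # xiphoid blob of 5 voxels: centroid
  xi <- rbind(c(4, 4, 15), c(5, 4, 15), c(6, 4, 15), c(5, 5, 15), c(5, 4, 16))
  labels[xi] <- reg[["xiphoid"]]
  # ASIS blob with two voxels tied at maximal y: deterministic tie-break
  labels[3, 18, 3] <- reg[["asis_left"]]
  labels[7, 18, 3] <- reg[["asis_left"]]
  labels[5, 17, 3] <- reg[["asis_left"]]
  vol <- labeled_volume(array(0, dm), labels, c(2, 2, 2), c(1, 1, 1))
  ps <- landmark_representative_point(vol, "pubic_symphysis")
  expect_equal(ps[3], 1 + 7 * 2)        # z index 8 (1-based) -> 0-based 7
  xp <- landmark_representative_point(vol, "xiphoid")
  expect_equal(xp, colMeans(voxel_to_mm(vol, xi - 1)), tolerance = 1e-12)
  a1 <- landmark_representative_point(vol, "asis_left")
  expect_identical(a1, landmark_representative_point(vol, "asis_left"))
  # tie at y: most-superior then most-right; both tied voxels share z,
  # so the larger x (voxel x-index 7) is chosen
  expect_equal(a1[1], 1 + 6 * 2)
  expect_error(landmark_representative_point(vol, "umbilicus"), "not labeled")
  expect_error(landmark_representative_point(vol, "nonsense"), "unknown")
})

test_that("self-comparison yields zero distances and kappa 1", {
  ph <- fx_hernia_phantom()
  rep <- reliability_report(ph$volume, ph$volume)
  for (st in rep$wall) {
    expect_equal(st$msd, 0)
    expect_equal(st$hd, 0)
  }
  expect_true(all(rep$landmarks == 0))
  expect_equal(rep$hernia_kappa, 1)
  expect_true(rep$hernia_kappa >= -1 && rep$hernia_kappa <= 1)
})

test_that("batch aggregation reports mean and SD per structure", {
  ph <- fx_hernia_phantom()
  reports <- lapply(1:3, function(i)
    reliability_report(ph$volume,
                       perturb_labels(ph$volume, 1.5, 2, seed = 30L + i)))
  agg <- aggregate_reliability(reports)
  expect_equal(nrow(agg$wall), 5L)
  expect_equal(nrow(agg$landmarks), 7L)
  expect_true(all(agg$wall$msd_mean <= agg$wall$hd_mean))
  expect_true(agg$hernia_kappa$mean > 0.5 && agg$hernia_kappa$mean < 1)
})
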