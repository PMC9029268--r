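test_that("activity-to-SUV conversion follows dose-per-bodyweight normalization", {
  v <- voxel_volume(array(5, c(4, 4, 4)), c(2, 2, 2), "activity")
  a70 <- patient_attributes(70, injected_activity_mbq = 350)
  suv <- to_suv(v, a70)
  expect_equal(unique(as.vector(suv$values)), 1.0)
  expect_equal(suv$unit, "SUV")
  # linear in weight
  a140 <- patient_attributes(140, injected_activity_mbq = 350)
  expect_equal(to_suv(v, a140)$values, 2 * suv$values)
  # zero activity stays zero, already-SUV input is a warning no-op
  v0 <- voxel_volume(array(0, c(2, 2, 2)), c(2, 2, 2), "activity")
  expect_equal(unique(as.vector(to_suv(v0, a70)$values)), 0)
  expect_warning(out <- to_suv(suv, a70), "already")
  expect_identical(out$values, suv$values)
})

test_that("SUL rescaling reproduces the lean-body-mass formulas", {
  attrs <- patient_attributes(80, 180, "male", 300)
  # James LBM, hand-evaluated: 1.10*80 - 128*(80/180)^2 = 62.716 kg
  expect_equal(sul_normalizer(attrs, "lbm_james"), 62.71605, tolerance = 1e-6)
  expect_equal(suv_to_sul(2.0, attrs, "lbm_james"), 2.0 * 62.71605 / 80,
               tolerance = 1e-6, ignore_attr = TRUE)
  # Janmahasatian, hand-evaluated: bmi = 80/1.8^2; 9270*80/(6680+216*bmi)
  bmi <- 80 / 1.8^2
  expect_equal(sul_normalizer(attrs, "lbm_janmahasatian"),
               9270 * 80 / (6680 + 216 * bmi), tolerance = 1e-12)
  # SUL <= SUV whenever the normalizer does not exceed body weight
  for (m in c("lbm_janmahasatian", "lbm_james")) {
    norm <- sul_normalizer(attrs, m)
    expect_lte(norm, attrs$weight_kg)
    expect_lte(as.numeric(suv_to_sul(3, attrs, m)), 3)
  }
  # BSA mass equivalent rescales consistently (it may exceed lean mass)
  expect_equal(as.numeric(suv_to_sul(3, attrs, "bsa")),
               3 * sul_normalizer(attrs, "bsa") / 80)
  # normalizer equal to weight is the identity (reference adult for BSA)
  ref <- patient_attributes(sul_normalizer(attrs, "lbm_james"), 180, "male")
  f <- sul_normalizer(ref, "lbm_james") / ref$weight_kg
  expect_equal(as.numeric(suv_to_sul(1, ref, "lbm_james")), f)
  expect_error(sul_normalizer(patient_attributes(80), "lbm_james"),
               "height")
  expect_error(sul_normalizer(patient_attributes(80, 180), "lbm_james"),
               "sex")
})

test_that("sphere peak equals the value on uniform fields and bounds the max", {
  vals <- array(1, c(20, 20, 20)); vals[6:15, 6:15, 6:15] <- 4
  mask <- array(FALSE, c(20, 20, 20)); mask[6:15, 6:15, 6:15] <- TRUE
  v <- voxel_volume(vals, c(2, 2, 2), "SUV")
  expect_equal(as.numeric(suv_peak(v, mask)), 4)   # uniform interior
  # a 3-voxel hot spike in a cold background averages below its max
  vals2 <- array(0.2, c(20, 20, 20)); vals2[10, 10, 10:12] <- 9
  mask2 <- vals2 > 1
  pk <- as.numeric(suv_peak(voxel_volume(vals2, c(2, 2, 2), "SUV"), mask2))
  expect_lt(pk, 9)
  expect_gt(pk, 0.2)
  expect_error(suv_peak(v, array(FALSE, c(20, 20, 20))), "empty")
  expect_error(suv_peak(v, mask, sphere_diameter_mm = 200), "larger")
})

test_that("sphere peak matches the exhaustive brute-force search", {
  set.seed(4)
  for (trial in 1:4) {
    dims <- c(12, 12, 12)
    vals <- array(runif(prod(dims), 0, 8), dims)
    mask <- array(FALSE, dims)
    mask[sample(prod(dims), 40)] <- TRUE
    sp <- c(2, 2, 2)
    v <- voxel_volume(vals, sp, "SUV")
    expect_equal(as.numeric(suv_peak(v, mask)),
                 oracle_suv_peak(vals, sp, mask), tolerance = 1e-12)
  }
})

test_that("MTV counts delineated voxels and is monotone in the threshold", {
  vals <- array(0.5, c(10, 10, 10))
  vals[3:7, 3:6, 3:7] <- 6              # 5*4*5 = 100 voxels of 2x2x2 mm
  mask <- vals > 1
  v <- voxel_volume(vals, c(2, 2, 2), "SUV")
  res <- mtv(v, mask, relative_pct = 42)
  expect_equal(res$mtv_cm3, 100 * 8 / 1000)
  expect_identical(res$mask, mask)
  # raising the relative threshold never increases MTV
  vals2 <- vals; vals2[3:7, 3:6, 3:7] <- runif(100, 2, 10)
  v2 <- voxel_volume(vals2, c(2, 2, 2), "SUV")
  mtvs <- vapply(seq(10, 95, by = 5),
                 function(p) mtv(v2, mask, relative_pct = p)$mtv_cm3, 0)
  expect_true(all(diff(mtvs) <= 1e-12))
  # nothing above an absolute floor -> zero volume, empty mask
  res0 <- mtv(v, mask, absolute_floor = 100)
  expect_equal(res0$mtv_cm3, 0)
  expect_false(any(res0$mask))
})

test_that("MTV of a 10 mm sphere phantom approximates the analytic volume", {
  dims <- c(30, 30, 30); sp <- c(1, 1, 1)
  ctr <- c(15, 15, 15)
  vals <- array(0.2, dims)
  inside <- sphere_voxels_helper(dims, sp, ctr, 10)
  vals[inside] <- 5
  v <- voxel_volume(vals, sp, "SUV")
  res <- mtv(v, inside, relative_pct = 42)
  expect_equal(res$mtv_cm3, 4 / 3 * pi, tolerance = 0.1)
})

test_that("TLG is the exact product of MTV and SUVmean", {
  expect_equal(tlg(10, 4), 40)
  expect_equal(tlg(0, 7), 0)
  expect_equal(tlg(0.8, 2.5), 2.0)
  expect_error(tlg(-1, 2), ">= 0")
})

test_that("liver reference reports sphere mean and population SD", {
  dims <- c(30, 30, 30); sp <- c(2, 2, 2)
  ctr <- c(30, 30, 30)
  vals <- array(2, dims)
  v_sul <- voxel_volume(vals, sp, "SUL")
  lr <- liver_reference(v_sul, NULL, ctr)
  expect_equal(lr$sulmean, 2.0)
  expect_equal(lr$sul_sd, 0)
  # two-valued sphere {1,3} in equal counts -> mean 2, population SD 1
  inside <- sphere_voxels_helper(dims, sp, ctr, 15)
  vals2 <- array(1, dims)
  alt <- which(inside)
  vals2[alt[seq_along(alt) %% 2 == 0]] <- 3
  n_in <- length(alt)
  if (n_in %% 2 == 1) vals2[alt[1]] <- 2  # keep counts balanced on odd n
  v2 <- voxel_volume(vals2, sp, "SUL")
  lr2 <- liver_reference(v2, NULL, ctr)
  expect_equal(lr2$sulmean, 2.0, tolerance = 0.02)
  expect_equal(lr2$sul_sd, 1.0, tolerance = 0.02)
  # SD is invariant to adding a constant
  v3 <- voxel_volume(vals2 + 5, sp, "SUL")
  expect_equal(liver_reference(v3, NULL, ctr)$sul_sd, lr2$sul_sd)
  expect_error(liver_reference(v_sul, NULL, c(5, 5, 5)), "clipped")
})

test_that("longest diameter matches the all-pairs oracle", {
  m <- array(FALSE, c(10, 10, 10)); m[2, 2, 2] <- TRUE
  expect_equal(longest_diameter(m, c(2, 2, 2)), 0)
  m[7, 2, 2] <- TRUE                    # two voxels, 5 steps of 2 mm apart
  expect_equal(longest_diameter(m, c(2, 2, 2)), 10)
  set.seed(8)
  for (trial in 1:5) {
    mk <- array(FALSE, c(12, 12, 12))
    mk[sample(12^3, 50)] <- TRUE
    sp <- runif(3, 1, 3)
    expect_equal(longest_diameter(mk, sp), oracle_longest_diameter(mk, sp),
                 tolerance = 1e-12)
  }
  # boundary-reduction path for large masks agrees with the oracle
  big <- array(FALSE, c(12, 12, 12)); big[2:11, 2:11, 2:11] <- TRUE
  expect_equal(longest_diameter(big, c(1, 1, 1)),
               oracle_longest_diameter(big, c(1, 1, 1)))
})

test_that("per-lesion invariants hold on quantified phantoms", {
  spec <- phantom_spec(lesions = list(
    list(center_mm = c(25, 25, 70), radius_mm = 8, suv = 6),
    list(center_mm = c(70, 70, 25), radius_mm = 6, suv = 9)))
  pair <- simulate_phantom_pair(spec, changes_pct = c(0, 0),
                                noise_sd_frac = 0.05, seed = 2)
  attrs <- patient_attributes(75, 170, "female", 300)
  q <- quantify_scan(pair$baseline$volume, pair$baseline$labels, attrs)
  expect_equal(nrow(q$lesions), 2)
  expect_true(all(q$lesions$suvpeak <= q$lesions$suvmax + 1e-12))
  expect_true(all(q$lesions$sulpeak <= q$lesions$suvpeak + 1e-12))
  expect_equal(q$lesions$tlg, q$lesions$mtv_cm3 * q$lesions$suvmean)
  expect_true(all(q$lesions$mtv_cm3 > 0))
  expect_s3_class(q$liver, "liver_reference")
  expect_gt(q$liver$suvmean, 1)
})

test_that("NIfTI round trip preserves values and spacing", {
  v <- voxel_volume(array(runif(8 * 8 * 8), c(8, 8, 8)), c(2, 2, 3), "SUV")
  path <- tempfile(fileext = ".nii.gz")
  write_pet_volume(v, path)
  back <- read_pet_volume(path)
  expect_equal(back$values, v$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, v$spacing)
  unlink(path)
})
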