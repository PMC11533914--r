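make_vol <- function(suv, spacing = 4, tracer = "FDG")
  tracer_volume(suv, spacing, tracer)

test_that("liver reference equals the sphere mean (constant and gradient fields)", {
  dims <- c(20, 20, 20)
  v <- make_vol(array(2, dims))
  ctr <- c(38, 38, 38)
  expect_equal(measure_liver_reference(v, ctr), 2)

  # linear gradient along x: value = x-index
  g <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dims)
  vg <- make_vol(g)
  expect_equal(measure_liver_reference(vg, ctr),
               oracle_sphere_mean(g, c(4, 4, 4), ctr, 15))

  # threshold arithmetic: SUVmean 2 -> segmentation threshold 3
  expect_equal(1.5 * measure_liver_reference(v, ctr), 3)

  expect_error(measure_liver_reference(v, c(2, 38, 38)), "outside")
})

test_that("segmentation separates and joins components per connectivity", {
  dims <- c(16, 16, 16)
  a <- array(0, dims)
  a[3:5, 3:5, 3:5] <- 5          # block 1
  a[9:11, 9:11, 9:11] <- 5       # block 2, well separated
  v <- make_vol(a)
  expect_length(segment_vois(v, 2), 2)

  b <- array(0, dims)
  b[3:5, 3:5, 3:5] <- 5
  b[6:8, 6:8, 6:8] <- 5          # touches only at the corner (6,6,6)/(5,5,5)
  vb <- make_vol(b)
  expect_length(segment_vois(vb, 2, connectivity = 26), 1)
  expect_length(segment_vois(vb, 2, connectivity = 6), 2)

  # all-background volume -> no VOI
  expect_length(segment_vois(make_vol(array(1, dims)), 2), 0)

  # supra-threshold voxels recovered exactly for a planted sphere
  sp <- phantom_spec(grid_shape = dims, voxel_spacing = 4,
                     liver_center = c(20, 20, 20), liver_radius = 10,
                     liver_suv = 1,
                     lesions = list(lesion_spec(c(44, 44, 44), radius = 9,
                                                suv_by_tracer = c(FDG = 5))))
  vols <- generate_phantom(sp)
  vois <- segment_vois(vols$FDG, 2)
  expect_length(vois, 1)
  expect_equal(sort(linear_index(vois[[1]]$voxels, dims)),
               which(vols$FDG$suv >= 3))
})

test_that("segmentation matches the flood-fill oracle across connectivities", {
  set.seed(101)
  for (rep in 1:30) {
    dims <- sample(4:12, 3, replace = TRUE)
    conn <- sample(c(6, 18, 26), 1)
    suv <- array(stats::runif(prod(dims)), dims)
    v <- tracer_volume(suv, 4, "FDG")
    vois <- segment_vois(v, 1, threshold_multiplier = 0.7, connectivity = conn)
    mask <- suv >= 0.7
    lab <- oracle_flood_fill(mask, conn)
    expect_equal(length(vois), max(lab))
    if (length(vois)) {
      got <- integer(sum(mask))
      fg <- which(mask)
      for (i in seq_along(vois))
        got[match(linear_index(vois[[i]]$voxels, dims), fg)] <- i
      expect_true(same_partition(got, lab[fg]))
    }
  }
})

test_that("volume filter is strict below 1 cm^3 and keeps the boundary", {
  voi <- function(vol) list(tracer = "FDG", voxels = cbind(1, 1, 1), volume_cm3 = vol)
  vols <- c(0.2, 0.99, 1.00, 1.01, 7)
  out <- filter_small_vois(lapply(vols, voi))
  expect_equal(vapply(out, `[[`, numeric(1), "volume_cm3"), c(1.00, 1.01, 7))
  expect_equal(length(out), sum(vols >= 1))  # direct filter oracle
})

test_that("physiologic exclusion drops VOIs by overlap fraction", {
  dims <- c(10, 10, 10)
  mask <- array(FALSE, dims)
  mask[1:5, , ] <- TRUE
  mkvoi <- function(xs) {
    vox <- as.matrix(expand.grid(xs, 1:2, 1:2))
    list(tracer = "FDG", voxels = vox, volume_cm3 = nrow(vox) * 0.064)
  }
  inside <- mkvoi(1:4)              # fully inside mask
  outside <- mkvoi(7:10)            # fully outside
  partial <- mkvoi(4:8)             # 2/5 = 40% inside
  kept <- exclude_physiologic(list(inside, outside, partial), mask)
  expect_length(kept, 2)
  expect_identical(kept[[1]], outside)
  expect_identical(kept[[2]], partial)
  # empty mask is the identity
  none <- array(FALSE, dims)
  expect_length(exclude_physiologic(list(inside, outside, partial), none), 3)
  expect_error(exclude_physiologic(list(inside), array(FALSE, c(5, 5, 5)),
                                   dims = dims), "grid")
})

test_that("SUVpeak is a sphere max-mean bounded by the voxel extremes", {
  dims <- c(14, 14, 14)
  u <- array(5, dims)
  v <- make_vol(u)
  vox <- as.matrix(expand.grid(5:9, 5:9, 5:9))
  expect_equal(measure_suv_peak(v, vox), 5)

  # single hot voxel in background: averaging pulls the peak below the max
  h <- array(1, dims)
  h[7, 7, 7] <- 10
  vh <- make_vol(h)
  pk <- measure_suv_peak(vh, cbind(7L, 7L, 7L))
  expect_lt(pk, 10)
  expect_gt(pk, 1)

  # gradient lesion: equals the exhaustive sphere-center search
  set.seed(7)
  g <- array(stats::runif(prod(dims), 0, 4), dims)
  vg <- make_vol(g)
  vox <- as.matrix(expand.grid(4:7, 6:9, 5:8))
  expect_equal(measure_suv_peak(vg, vox),
               oracle_suv_peak(g, c(4, 4, 4), vox))

  # bounds: within [min, max] SUV over the search region (union of spheres)
  r <- sphere_radius_mm(1)
  offs <- sphere_offsets(r, c(4, 4, 4))
  region <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    sweep(vox, 2, offs[k, ], "+"))))
  region <- region[in_grid(region, dims), , drop = FALSE]
  vals <- g[linear_index(region, dims)]
  expect_gte(measure_suv_peak(vg, vox), min(vals))
  expect_lte(measure_suv_peak(vg, vox), max(vals))
})

test_that("cross-tracer merging is transitive, idempotent and measures all tracers", {
  dims <- c(16, 16, 16)
  spacing <- 4
  base <- array(0.5, dims)
  fdg <- base; fdg[3:6, 3:6, 3:6] <- 5
  psma <- base; psma[5:9, 3:6, 3:6] <- 5     # overlaps FDG VOI in x 5:6
  vols <- list(FDG = tracer_volume(fdg, spacing, "FDG"),
               PSMA = tracer_volume(psma, spacing, "PSMA"))
  vois <- lapply(vols, segment_vois, liver_suv_mean = 2)
  lesions <- merge_lesions(vois, vols, liver_suv_means = c(FDG = 2, PSMA = 2))
  expect_length(lesions, 1)
  un <- sort(linear_index(lesions[[1]]$voxels, dims))
  expect_equal(un, sort(union(which(fdg >= 3), which(psma >= 3))))
  expect_named(lesions[[1]]$suv_peak_by_tracer, c("FDG", "PSMA"))

  # identical VOI in both tracers -> one lesion, not two
  vols2 <- list(FDG = vols$FDG, PSMA = tracer_volume(fdg, spacing, "PSMA"))
  vois2 <- lapply(vols2, segment_vois, liver_suv_mean = 2)
  expect_length(merge_lesions(vois2, vols2), 1)

  # chain A-B-C with A and C disjoint merges into one lesion (union-find)
  dot <- base; dot[8:11, 3:6, 3:6] <- 5      # overlaps PSMA only
  vols3 <- list(FDG = vols$FDG, PSMA = vols$PSMA,
                DOTATATE = tracer_volume(dot, spacing, "DOTATATE"))
  vois3 <- lapply(vols3, segment_vois, liver_suv_mean = 2)
  expect_length(merge_lesions(vois3, vols3), 1)

  # FDG-only VOI with no PSMA overlap: one lesion, PSMA measured sub-threshold
  far <- base; far[12:15, 12:15, 12:15] <- 5
  vols4 <- list(FDG = tracer_volume(far, spacing, "FDG"),
                PSMA = tracer_volume(base, spacing, "PSMA"))
  vois4 <- lapply(vols4, segment_vois, liver_suv_mean = 2)
  les4 <- merge_lesions(vois4, vols4, liver_suv_means = c(FDG = 2, PSMA = 2))
  expect_length(les4, 1)
  expect_gte(les4[[1]]$ratio_by_tracer[["FDG"]], 1.5)
  expect_lt(les4[[1]]$ratio_by_tracer[["PSMA"]], 1.5)
})

test_that("compartment is assigned by majority vote with deterministic ties", {
  dims <- c(10, 10, 10)
  suv <- array(0.5, dims); suv[2:5, 2:3, 2:3] <- 5
  vols <- list(FDG = tracer_volume(suv, 4, "FDG"))
  cmap <- array("none", dims)
  cmap[2:4, 2:3, 2:3] <- "bones"   # 12 voxels
  cmap[5, 2:3, 2:3] <- "nodes"     # 4 voxels
  vois <- list(FDG = segment_vois(vols$FDG, 2))
  les <- merge_lesions(vois, vols, compartment_map = cmap)
  expect_equal(les[[1]]$compartment, "bones")
})

test_that("lesion capping keeps the 10 hottest per cell and is idempotent", {
  set.seed(3)
  # 12 bone F+/P+ lesions: the 2 coolest are dropped
  tab <- data.frame(
    patient_id = "P1", lesion_id = 1:12, compartment = "bones",
    volume_cm3 = runif(12, 1, 5),
    ratio_fdg = seq(1.6, 3.8, length.out = 12),
    ratio_psma = 1.55, ratio_dotatate = NA_real_)
  capped <- cap_lesions(tab)
  expect_equal(nrow(capped), 10)
  expect_setequal(capped$lesion_id, 3:12)   # lowest hotness = smallest fdg ratio
  expect_identical(cap_lesions(capped), capped)

  # <=10 in every cell is the identity
  small <- tab[1:7, ]
  expect_identical(cap_lesions(small), small)

  # per-cell counts never exceed the cap on random tables
  for (s in 1:5) {
    set.seed(s)
    n <- 300
    rt <- data.frame(
      patient_id = "P1", lesion_id = 1:n,
      compartment = sample(c("nodes", "bones", "liver", "other"), n, TRUE),
      volume_cm3 = runif(n, 1, 9),
      ratio_fdg = runif(n, 0.3, 4), ratio_psma = runif(n, 0.3, 4),
      ratio_dotatate = NA_real_)
    cp <- cap_lesions(rt)
    fp <- paste0(cp$ratio_fdg >= 1.5, cp$ratio_psma >= 1.5, cp$compartment)
    expect_true(all(table(fp) <= 10))
    expect_identical(cap_lesions(cp), cp)
  }
})
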