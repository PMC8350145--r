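mk_mask <- function(assign, dims = c(12, 12, 12)) {
  a <- array(0L, dims)
  for (x in assign) a <- x(a)
  label_mask(a)
}

test_that("pool_ca unions the CA labels and is idempotent", {
  a <- array(0L, c(10, 10, 4))
  a[1:6, 1:5, 2] <- 1L   # CA1: 30
  a[7, 1:5, 2] <- 2L     # CA2: 5
  a[8, 1:5, 2] <- 4L     # CA3: 5
  a[1:4, 7:9, 3] <- 3L   # DG: untouched
  m <- label_mask(a)
  p <- pool_ca(m)
  expect_equal(sum(p$labels == subfield_codes()[["CA"]]), 40)
  expect_equal(sum(p$labels == 3L), 12)
  expect_equal(pool_ca(p)$labels, p$labels)  # idempotent on pooled masks
  # no CA voxels at all: array unchanged, CA count 0
  m2 <- label_mask(array(c(0L, 3L), c(4, 4, 4)))
  p2 <- pool_ca(m2)
  expect_equal(p2$labels, m2$labels)
  expect_error(pool_ca(label_mask(a, label_table = c(CA1 = 1L, CA2 = 2L,
                                                     CA3 = 4L, DG = 3L))),
               "CA")
})

test_that("one-voxel erosion of a cube keeps the 8^3 interior", {
  a <- array(0L, c(12, 12, 12)); a[2:11, 2:11, 2:11] <- 3L
  e <- erode_labels(label_mask(a))
  expect_equal(sum(e$labels == 3L), 512)
  expect_equal(unname(e$erosion_fractions["DG"]), 1 - 512 / 1000)
  expect_true(e$eroded)
})

test_that("a one-voxel-thick sheet is fully removed, with a warning", {
  a <- array(0L, c(10, 10, 5)); a[2:9, 2:9, 3] <- 8L
  expect_warning(e <- erode_labels(label_mask(a)), "fully removed")
  expect_equal(sum(e$labels), 0)
})

test_that("erosion is monotone and per-label independent", {
  set.seed(4)
  m <- gen_subfield_mask(NULL, list(subfield_spec("DG", 900, "blob"),
                                    subfield_spec("EC", 700, "blob")),
                         seed = 4, erosion_band = NULL)
  e1 <- erode_labels(m)
  expect_true(all(m$labels[e1$labels > 0] == e1$labels[e1$labels > 0]))
  e2 <- suppressWarnings(erode_labels(e1))
  expect_true(all(e2$labels[e2$labels > 0] == e1$labels[e2$labels > 0]))
  expect_lte(sum(e2$labels > 0), sum(e1$labels > 0))
  # relabeling EC must not change DG's erosion
  relab <- m$labels
  relab[relab == subfield_codes()[["EC"]]] <- subfield_codes()[["BA36"]]
  e3 <- erode_labels(label_mask(relab))
  expect_equal(e3$labels == 3L, e1$labels == 3L)
})

test_that("adjacent labels erode each other's boundary (other labels count as outside)", {
  a <- array(0L, c(8, 8, 8))
  a[2:7, 2:7, 2:4] <- 3L
  a[2:7, 2:7, 5:7] <- 8L   # SUB slab face-adjacent to DG slab
  e <- erode_labels(label_mask(a))
  # DG survivors: interior in x/y, and z in {3} only (z=2 grid-adjacent
  # background, z=4 touches SUB)
  expect_equal(sum(e$labels == 3L), 4 * 4 * 1)
})

test_that("2-D connectivity erodes in-plane only", {
  a <- array(0L, c(8, 8, 3)); a[2:7, 2:7, 1:3] <- 3L
  e <- erode_labels(label_mask(a), connectivity = "2d")
  expect_equal(sum(e$labels == 3L), 4 * 4 * 3)
})

test_that("extract_subfield_sample collects valid voxels and flags empty overlays", {
  a <- array(0L, c(10, 10, 6)); a[2:7, 2:6, 2:5] <- 3L  # 120 voxels
  mask <- label_mask(a, eroded = TRUE)
  t2 <- array(NA_real_, dim(a)); valid <- array(FALSE, dim(a))
  t2[a == 3L] <- 80; valid[a == 3L] <- TRUE
  tm <- structure(list(t2 = t2, valid = valid, voxel_dims = c(1, 1, 1)),
                  class = "t2_map")
  s <- extract_subfield_sample(tm, mask, "DG", "L", n_before = 200)
  expect_equal(length(s$t2_values), 120)
  expect_equal(s$n_voxels_after_erosion, 120L)
  expect_equal(s$n_invalid, 0L)
  # fully invalid label
  tm$valid[] <- FALSE
  expect_warning(s2 <- extract_subfield_sample(tm, mask, "DG", "L"),
                 "no valid")
  expect_equal(length(s2$t2_values), 0)
  # grid mismatch is a hard error
  tm_small <- structure(list(t2 = t2[1:9, , ], valid = valid[1:9, , ],
                             voxel_dims = c(1, 1, 1)), class = "t2_map")
  expect_error(extract_subfield_sample(tm_small, mask, "DG", "L"), "grid")
})

test_that("subfield_volume is count x voxel volume on the un-eroded mask", {
  a <- array(0L, c(20, 20, 10)); a[1:10, 1:10, 1:10] <- 3L  # 1000 voxels
  m <- label_mask(a, voxel_dims = c(0.34, 0.34, 1.7))
  v <- subfield_volume(m, "DG", icv = 1.4e6)
  expect_equal(v$volume_mm3, 1000 * 0.34 * 0.34 * 1.7)
  expect_equal(v$icv_ratio, v$volume_mm3 / 1.4e6)
  m2 <- label_mask(a, voxel_dims = c(0.34, 0.34, 3.4))
  expect_equal(subfield_volume(m2, "DG")$volume_mm3, 2 * v$volume_mm3)
  expect_equal(subfield_volume(m, "EC")$volume_mm3, 0)
  expect_error(subfield_volume(m, "DG", icv = -1), "icv")
  m$eroded <- TRUE
  expect_warning(subfield_volume(m, "DG"), "eroded")
})

test_that("label_mask validates codes against the table", {
  a <- array(0L, c(4, 4, 4)); a[1, 1, 1] <- 55L
  expect_error(label_mask(a), "missing from label table")
})
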