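# Geometry core: NIfTI round trips, resampling, normalization, bounding
# boxes, crop/paste.

test_that("NIfTI round trip preserves data, spacing and origin", {
  v <- Volume(array(as.numeric(1:4096), c(16, 16, 16)),
              spacing = c(1, 1, 3), origin = c(5, -2, 0.5))
  p <- tempfile(fileext = ".nii.gz")
  writeVolume(v, p)
  v2 <- readVolume(p)
  expect_identical(voxelData(v2), voxelData(v))
  expect_equal(spacing(v2), c(1, 1, 3))
  expect_equal(origin(v2), c(5, -2, 0.5))

  # uncompressed variant and a zero volume
  z <- Volume(array(0, c(4, 4, 4)), spacing = 5)
  pz <- tempfile(fileext = ".nii")
  writeVolume(z, pz)
  expect_true(all(voxelData(readVolume(pz)) == 0))
  expect_equal(spacing(readVolume(pz)), c(5, 5, 5))
})

test_that("label masks are written as integers and survive re-reading", {
  set.seed(4)
  m <- LabelMask(array(sample(0:2, 512, TRUE), c(8, 8, 8)), spacing = 2)
  p <- tempfile(fileext = ".nii.gz")
  writeVolume(m, p)
  m2 <- readVolume(p, label = TRUE)
  expect_s4_class(m2, "LabelMask")
  expect_identical(m2@data, m@data)
  expect_setequal(unique(as.vector(m2@data)), c(0, 1, 2))
})

test_that("non-3D and malformed NIfTI files are rejected with diagnostics", {
  expect_error(readVolume(tempfile()), "not found")
  v <- Volume(array(0, c(4, 4, 4)))
  p <- tempfile(fileext = ".nii")
  writeVolume(v, p)
  # forge dim[0] = 4 (offset 40, little endian) to fake a 4D file
  raw <- readBin(p, raw(), file.size(p))
  raw[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")
  p4 <- tempfile(fileext = ".nii")
  writeBin(raw, p4)
  expect_error(readVolume(p4), "expected 3D")
  # truncated header
  pt <- tempfile(fileext = ".nii")
  writeBin(raw[1:100], pt)
  expect_error(readVolume(pt), "NIfTI")
})

test_that("resampling matches its contract and the index-map oracle", {
  set.seed(11)
  v <- Volume(array(rnorm(8^3), c(8, 8, 8)), spacing = 1)
  # identity is bit-identical
  expect_identical(voxelData(resampleVolume(v, c(1, 1, 1))), voxelData(v))
  # constant volumes stay constant under any spacing change
  cv <- Volume(array(7, c(6, 5, 4)), spacing = c(1, 2, 3))
  expect_lt(max(abs(voxelData(resampleVolume(cv, c(2.5, 1, 1), "linear")) - 7)),
            1e-12)
  expect_true(all(voxelData(resampleVolume(cv, c(0.7, 5, 2))) == 7))
  # 8^3 at 1 mm -> 5 mm gives 2^3, values equal to the oracle
  r <- resampleVolume(v, 5)
  expect_equal(dim(r), c(2L, 2L, 2L))
  expect_equal(voxelData(r), oResampleNearest(voxelData(v), c(1, 1, 1),
                                              c(5, 5, 5)))
  expect_equal(spacing(r), c(5, 5, 5))
  # random-size oracle equivalence
  for (i in 1:20) {
    d <- sample(3:12, 3, TRUE)
    insp <- runif(3, 0.5, 3)
    outsp <- runif(3, 0.5, 6)
    a <- array(rnorm(prod(d)), d)
    got <- resampleVolume(Volume(a, insp), outsp)
    expect_equal(voxelData(got), oResampleNearest(a, insp, outsp))
  }
})

test_that("nearest-neighbour label resampling never invents labels", {
  set.seed(21)
  for (i in 1:10) {
    ph <- generatePhantom(PhantomSpec(shape = sample(10:24, 1),
                                      spacing = runif(1, 1, 3), seed = i))
    target <- runif(3, 0.8, 6)
    r <- resampleVolume(ph$label, target)
    expect_s4_class(r, "LabelMask")
    expect_true(all(unique(as.vector(r@data)) %in%
                      unique(as.vector(ph$label@data))))
  }
  expect_error(resampleVolume(generatePhantom(PhantomSpec(shape = 8))$label,
                              2, "linear"), "never linearly")
  expect_error(resampleVolume(Volume(array(0, c(4, 4, 4))), c(0, 1, 1)),
               "positive")
})

test_that("down-then-up resampling of a smooth field has small error", {
  # separable sinusoid field, slowly varying over a 24^3 grid
  n <- 24
  g <- (0:(n - 1)) / n
  f <- outer(outer(sin(2 * pi * g), cos(2 * pi * g), "+"),
             sin(pi * g), "+") / 3
  v <- Volume(array(f, c(n, n, n)), spacing = 1)
  down <- resampleVolume(v, 2, "linear")
  up <- resampleVolume(down, 1, "linear")
  stopifnot(identical(dim(up), dim(v)))
  mae <- mean(abs(voxelData(up) - voxelData(v)))
  expect_lt(mae / diff(range(f)), 0.05)
})

test_that("intensity normalization follows the CT window formula and clips", {
  v <- Volume(array(c(40, 240, 5000, -1000, -160, 140, 90, 40), c(8, 1, 1)))
  out <- voxelData(normalizeIntensity(v, ctWindowSpec(40, 400)))
  expect_equal(out[1, 1, 1], 0)         # value at window level
  expect_equal(out[2, 1, 1], 1)         # (240-40)/200
  expect_equal(out[3, 1, 1], 1)         # clipped from 24.8
  expect_equal(out[4, 1, 1], -1)        # clipped low
  expect_equal(out[5, 1, 1], -1)        # exactly at the lower edge
  expect_equal(out[6, 1, 1], 0.5)
  expect_error(ctWindowSpec(40, 0), "windowWidth")
})

test_that("normalization is bounded and monotone for random volumes/specs", {
  set.seed(31)
  for (i in 1:8) {
    x <- array(rnorm(6^3, sd = 300), c(6, 6, 6))
    spec <- if (i %% 2 == 0)
      ctWindowSpec(runif(1, -100, 100), runif(1, 50, 800))
    else mriPercentileSpec(runif(1, 0, 10), runif(1, 90, 100))
    out <- voxelData(normalizeIntensity(Volume(x), spec))
    expect_true(all(out >= -1 & out <= 1))
    ord <- order(x)
    expect_true(all(diff(out[ord]) >= -1e-12))  # monotone non-decreasing
  }
  expect_error(normalizeIntensity(Volume(array(5, c(3, 3, 3))),
                                  mriPercentileSpec()), "distinct")
})

test_that("bounding boxes equal the exhaustive scan oracle", {
  # single voxel at 0-based (3,4,5)
  m <- array(0, c(8, 8, 8)); m[4, 5, 6] <- 1
  box <- boundingBoxOf(LabelMask(m))
  expect_equal(boxLo(box), c(3L, 4L, 5L))
  expect_equal(boxHi(box), c(4L, 5L, 6L))
  expect_error(boundingBoxOf(LabelMask(m), label = 2), "empty structure")
  # two blobs at opposite corners of a 32^3 grid
  m2 <- array(0, c(32, 32, 32))
  m2[1:3, 1:2, 1:4] <- 1; m2[30:32, 31:32, 28:32] <- 1
  b2 <- boundingBoxOf(LabelMask(m2))
  o <- oBBox(m2, 1)
  expect_equal(boxLo(b2), as.integer(o$lo))
  expect_equal(boxHi(b2), as.integer(o$hi))
  # random grids: oracle equivalence, with margins clamped to the grid
  set.seed(41)
  for (i in 1:15) {
    d <- sample(4:32, 3, TRUE)
    mm <- randomBlobMask(d)
    sp <- runif(3, 0.5, 3)
    got <- boundingBoxOf(LabelMask(mm, sp))
    o <- oBBox(mm, 1)
    expect_equal(boxLo(got), as.integer(o$lo))
    expect_equal(boxHi(got), as.integer(o$hi))
    marg <- runif(3, 0, 8)
    gm <- boundingBoxOf(LabelMask(mm, sp), marginMm = marg)
    expect_equal(boxLo(gm), pmax(as.integer(o$lo - ceiling(marg / sp)), 0L))
    expect_equal(boxHi(gm), pmin(as.integer(o$hi + ceiling(marg / sp)), d))
  }
})

test_that("crop and paste are exact inverses on the box", {
  ph <- generatePhantom(smallPhantomSpec(shape = 24, seed = 5))
  v <- ph$image
  full <- cropVolume(v, BoundingBox(c(0, 0, 0), dim(v)))
  expect_identical(voxelData(full), voxelData(v))
  box <- BoundingBox(c(3, 5, 0), c(15, 20, 10))
  crop <- cropVolume(v, box)
  expect_equal(dim(crop), boxShape(box))
  expect_equal(origin(crop), origin(v) + boxLo(box) * spacing(v))
  canvas <- Volume(array(0, dim(v)), spacing(v))
  back <- pasteVolume(canvas, crop, boxLo(box))
  expect_identical(voxelData(cropVolume(back, box)), voxelData(crop))
  # the organ's bounding box contains every organ voxel
  obox <- boundingBoxOf(ph$label, 1)
  lcrop <- cropVolume(ph$label, obox)
  expect_equal(sum(lcrop@data == 1), sum(ph$label@data == 1))
  expect_error(cropVolume(v, BoundingBox(c(40, 0, 0), c(44, 4, 4))),
               "intersect")
})
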