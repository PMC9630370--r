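# Synthetic CT-like phantoms: labelled ellipsoids with Gaussian noise.
#
# The phantom stands in for clinical CT cases: an air-analog background
# (-1000), a soft-tissue body ellipsoid (~40), and one or more "organ"
# ellipsoids of higher mean intensity (100-300) so the default CT window
# preset is exercised. Ellipsoids have closed-form membership, giving
# analytic oracles for volumes and bounding boxes.

# evaluate expr under a private RNG stream, restoring global state after
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a phantom specification
#'
#' Defaults describe a 64 mm cube at 1 mm spacing holding a body ellipsoid
#' of semi-axes 26 mm (mean 40, soft tissue analog) and one organ ellipsoid
#' of semi-axes about 10 mm (mean 200), on an air background of -1000, with
#' additive Gaussian noise of SD 10.
#'
#' @param shape grid shape (voxels); length 3 or 1.
#' @param spacing voxel spacing (mm); length 3 or 1.
#' @param body list with `center` (mm), `semiAxes` (mm), `intensity`.
#' @param organs list of lists with `label`, `center`, `semiAxes`,
#'   `intensity`. Labels must be contiguous 1..K; later organs override
#'   earlier ones where they overlap.
#' @param background background intensity (air analog).
#' @param noiseSd SD of additive Gaussian noise (intensity units).
#' @param seed integer seed; generation is bit-reproducible in it.
#' @return A [PhantomSpec-class].
#' @examples
#' ph <- generatePhantom(PhantomSpec(shape = 32, spacing = 2, seed = 7))
#' ph$image
#' @export
PhantomSpec <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                        body = NULL, organs = NULL, background = -1000,
                        noiseSd = 10, seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  extent <- shape * spacing
  if (is.null(body))
    body <- list(center = extent / 2, semiAxes = extent * 26 / 64,
                 intensity = 40)
  if (is.null(organs))
    organs <- list(list(label = 1, center = body$center + extent * c(3, -2, 2) / 64,
                        semiAxes = extent * c(10, 9, 8) / 64, intensity = 200))
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      body = body, organs = organs, background = as.numeric(background),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# 0/1 membership array of an ellipsoid on the spec grid (physical coords)
ellipsoidMask <- function(shape, spacing, center, semiAxes) {
  q <- lapply(1:3, function(a)
    (((seq_len(shape[a]) - 1) * spacing[a] - center[a]) / semiAxes[a])^2)
  outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
}

#' Generate one phantom image/label pair
#'
#' Voxels inside organ k (ellipsoid test in physical coordinates) get label
#' k, later organs overriding earlier on overlap; the image is the
#' structure mean plus seeded Gaussian noise. Identical specs give
#' bit-identical outputs, and generation does not perturb the global RNG.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `image` ([Volume-class]) and `label`
#'   ([LabelMask-class]).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  shape <- spec@shape; sp <- spec@spacing
  img <- array(spec@background, shape)
  lab <- array(0, shape)
  img[ellipsoidMask(shape, sp, spec@body$center, spec@body$semiAxes)] <-
    spec@body$intensity
  for (o in spec@organs) {
    m <- ellipsoidMask(shape, sp, o$center, o$semiAxes)
    img[m] <- o$intensity
    lab[m] <- o$label
  }
  if (spec@noiseSd > 0)
    img <- img + withLocalSeed(spec@seed,
                               array(rnorm(prod(shape), 0, spec@noiseSd), shape))
  list(image = Volume(img, sp), label = LabelMask(lab, sp))
}

# apply random geometry jitter to the organs (and return a valid spec or NULL)
jitterSpec <- function(spec, sizeFrac, shiftMm, caseSeed) {
  organs <- lapply(spec@organs, function(o) {
    o$semiAxes <- o$semiAxes * runif(3, 1 - sizeFrac, 1 + sizeFrac)
    o$center <- o$center + runif(3, -shiftMm, shiftMm)
    o
  })
  tryCatch({
    s <- new("PhantomSpec", shape = spec@shape, spacing = spec@spacing,
             body = spec@body, organs = organs, background = spec@background,
             noiseSd = spec@noiseSd, seed = as.integer(caseSeed))
    validObject(s)
    s
  }, error = function(e) NULL)
}

#' Generate a directory of phantom cases
#'
#' Writes `case_XXXX/image.nii.gz` and `case_XXXX/label.nii.gz` per case
#' plus a `manifest.json` listing cases, labels and the generating
#' parameters. Per-case geometry is jittered; jitter that pushes an organ
#' outside the body is re-drawn up to 20 times, then an error is raised.
#'
#' @param nCases number of cases (>= 1).
#' @param baseSpec the base [PhantomSpec-class].
#' @param jitter list with `sizeFrac` (fractional semi-axis jitter, e.g.
#'   0.2 for +/-20 percent) and `shiftMm` (centre shift range in mm).
#' @param seed integer seed; the run is reproducible from it.
#' @param outDir output directory (created if needed).
#' @return Character vector of case directories, invisibly.
#' @export
generateDataset <- function(nCases, baseSpec = PhantomSpec(),
                            jitter = list(sizeFrac = 0.2, shiftMm = 4),
                            seed = 1L, outDir) {
  stopifnot(nCases >= 1)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  caseDirs <- character(nCases)
  withLocalSeed(seed, {
    for (i in seq_len(nCases)) {
      caseSeed <- sample.int(2^31 - 1, 1)
      sp <- NULL
      for (try in 1:20) {
        sp <- if (jitter$sizeFrac == 0 && jitter$shiftMm == 0) {
          s <- baseSpec; s@seed <- as.integer(caseSeed); s
        } else jitterSpec(baseSpec, jitter$sizeFrac, jitter$shiftMm, caseSeed)
        if (!is.null(sp)) break
      }
      if (is.null(sp))
        stop("jitter violates organ containment after 20 retries (case ", i, ")")
      ph <- generatePhantom(sp)
      d <- file.path(outDir, sprintf("case_%04d", i))
      dir.create(d, showWarnings = FALSE)
      writeVolume(ph$image, file.path(d, "image.nii.gz"))
      writeVolume(ph$label, file.path(d, "label.nii.gz"))
      caseDirs[i] <- d
    }
  })
  manifest <- list(
    cases = basename(caseDirs),
    labels = vapply(baseSpec@organs, function(o) o$label, numeric(1)),
    spec = list(shape = baseSpec@shape, spacing = baseSpec@spacing,
                background = baseSpec@background, noiseSd = baseSpec@noiseSd,
                jitter = jitter, seed = seed))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(caseDirs)
}

#' List case directories recorded in a dataset manifest
#'
#' @param dir dataset directory written by [generateDataset()].
#' @return Character vector of case directory paths.
#' @export
listCases <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    file.path(dir, m$cases)
  } else {
    list.dirs(dir, recursive = FALSE)
  }
}
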