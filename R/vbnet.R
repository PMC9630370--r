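# VB-Net: a V-Net-style 3D encoder-decoder with bottleneck residual blocks
# and an optional adaptive input module (learned stride-2 down/up-sampling
# pair around the backbone).
#
# The network is stored as a flat named list of parameter arrays plus its
# generating NetworkSpec; forward and backward passes are hand-written and
# mirror each other block by block. All computation is single-sample on
# (X, Y, Z, C) arrays; mini-batches are averaged by the training loop.

#' Construct a NetworkSpec
#'
#' @param inChannels input channels (1 for a raw image, plus one per
#'   attention channel).
#' @param outClasses output classes including background (>= 2).
#' @param levels number of down-sampling steps (resolution levels - 1).
#' @param baseChannels channels at the finest level; doubled per level,
#'   capped at 16x.
#' @param bottlenecksPerBlock bottleneck residual units per down/up block;
#'   a scalar is recycled to all `2*levels` blocks.
#' @param adaptiveInput add the learned stride-2 resampling pair.
#' @return A [NetworkSpec-class].
#' @export
NetworkSpec <- function(inChannels = 1L, outClasses = 2L, levels = 3L,
                        baseChannels = 8L, bottlenecksPerBlock = 1L,
                        adaptiveInput = FALSE) {
  new("NetworkSpec", inChannels = as.integer(inChannels),
      outClasses = as.integer(outClasses), levels = as.integer(levels),
      baseChannels = as.integer(baseChannels),
      bottlenecksPerBlock = as.integer(bottlenecksPerBlock),
      adaptiveInput = adaptiveInput)
}

specChannels <- function(spec) {
  pmin(spec@baseChannels * 2^(0:spec@levels), 16L * spec@baseChannels)
}

specBottlenecks <- function(spec) {
  nb <- spec@bottlenecksPerBlock
  if (length(nb) == 1L) rep(nb, 2L * spec@levels) else nb
}

# side-length divisibility demanded by the down-sampling chain
specDivisor <- function(spec) 2L^(spec@levels + as.integer(spec@adaptiveInput))

initConvW <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        c(k, k, k, cin, cout))
}

#' Build a VB-Net from its specification
#'
#' The encoder halves resolution `levels` times with stride-2
#' convolutions, doubling channels (capped at 16x base); each down/up
#' block carries bottleneck residual units (1x1x1 reduce, 3x3x3 spatial,
#' 1x1x1 restore, residual addition). The decoder mirrors the encoder with
#' stride-2 transposed convolutions and channel-wise concatenation skip
#' connections at every resolution level. Instance normalization + ReLU
#' follow every convolution except the final 1x1x1 classifier. With
#' `adaptiveInput`, a learned stride-2 convolution halves each spatial
#' dimension before the backbone and a stride-2 transposed convolution
#' restores it after the classifier, doubling the backbone's receptive
#' field in input voxels at unchanged external shapes.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for weight initialization (He-normal).
#' @return A model object (class `vbnet_model`).
#' @export
buildVBNet <- function(spec, seed = 1L) {
  validObject(spec)
  L <- spec@levels
  ch <- specChannels(spec)
  nb <- specBottlenecks(spec)
  p <- list()
  withLocalSeed(seed, {
    if (spec@adaptiveInput) {
      p$pre.w <- initConvW(2, spec@inChannels, spec@inChannels)
      p$pre.b <- numeric(spec@inChannels)
      # transposed conv back to full resolution: dim (k,k,k, Cout, Cin)
      p$post.w <- initConvW(2, spec@outClasses, spec@outClasses)
      p$post.b <- numeric(spec@outClasses)
    }
    addCBR <- function(prefix, k, cin, cout) {
      p[[paste0(prefix, ".w")]] <<- initConvW(k, cin, cout)
      p[[paste0(prefix, ".b")]] <<- numeric(cout)
      p[[paste0(prefix, ".g")]] <<- rep(1, cout)
      p[[paste0(prefix, ".be")]] <<- numeric(cout)
    }
    addBottleneck <- function(prefix, C) {
      mid <- max(1L, C %/% 2L)
      addCBR(paste0(prefix, ".c1"), 1, C, mid)
      addCBR(paste0(prefix, ".c2"), 3, mid, mid)
      addCBR(paste0(prefix, ".c3"), 1, mid, C)
    }
    addCBR("in", 3, spec@inChannels, ch[1])
    for (l in seq_len(L)) {
      addCBR(paste0("down", l), 2, ch[l], ch[l + 1])
      for (m in seq_len(nb[l]))
        addBottleneck(sprintf("down%d.bn%d", l, m), ch[l + 1])
    }
    for (l in rev(seq_len(L))) {
      pre <- paste0("up", l)
      p[[paste0(pre, ".tw")]] <- initConvW(2, ch[l], ch[l + 1])
      p[[paste0(pre, ".tb")]] <- numeric(ch[l])
      p[[paste0(pre, ".tg")]] <- rep(1, ch[l])
      p[[paste0(pre, ".tbe")]] <- numeric(ch[l])
      addCBR(paste0(pre, ".m"), 1, 2L * ch[l], ch[l])
      for (m in seq_len(nb[L + (L - l + 1L)]))
        addBottleneck(sprintf("up%d.bn%d", l, m), ch[l])
    }
    p$out.w <- initConvW(1, ch[1], spec@outClasses)
    p$out.b <- numeric(spec@outClasses)
  })
  structure(list(spec = spec, params = p), class = "vbnet_model")
}

#' @rdname buildVBNet
#' @details `buildAdaptiveVBNet` is a convenience wrapper that forces
#'   `adaptiveInput = TRUE` on the spec.
#' @export
buildAdaptiveVBNet <- function(spec, seed = 1L) {
  spec@adaptiveInput <- TRUE
  buildVBNet(spec, seed)
}

#' Count trainable parameters of a model
#'
#' @param model a model built by [buildVBNet()].
#' @return Total number of trainable scalars.
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.vbnet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<vbnet_model> in=%d classes=%d levels=%d base=%d%s, %d parameters\n",
    s@inChannels, s@outClasses, s@levels, s@baseChannels,
    if (s@adaptiveInput) " (adaptive input)" else "", countParameters(x)))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

cbrFwP <- function(p, prefix, x, stride = 1L, pad = 0L) {
  w <- p[[paste0(prefix, ".w")]]
  y1 <- convFw(x, w, p[[paste0(prefix, ".b")]], stride, pad)
  nrm <- instNormFw(y1, p[[paste0(prefix, ".g")]], p[[paste0(prefix, ".be")]])
  list(y = reluFw(nrm$y), cache = list(x = x, pre = nrm$y, nc = nrm$cache,
                                       stride = stride, pad = pad))
}

cbrBwP <- function(p, G, prefix, cache, gy) {
  gy <- reluBw(cache$pre, gy)
  nb <- instNormBw(cache$nc, gy)
  gAdd(G, paste0(prefix, ".g"), nb$gg)
  gAdd(G, paste0(prefix, ".be"), nb$gb)
  cb <- convBw(cache$x, p[[paste0(prefix, ".w")]], nb$gx, cache$stride,
               cache$pad)
  gAdd(G, paste0(prefix, ".w"), cb$gw)
  gAdd(G, paste0(prefix, ".b"), cb$gb)
  cb$gx
}

gAdd <- function(G, name, g) {
  cur <- G$g[[name]]
  G$g[[name]] <- if (is.null(cur)) g else cur + g
  invisible()
}

bottleneckFwP <- function(p, prefix, x) {
  a <- cbrFwP(p, paste0(prefix, ".c1"), x)
  b <- cbrFwP(p, paste0(prefix, ".c2"), a$y, pad = 1L)
  w3 <- p[[paste0(prefix, ".c3.w")]]
  y3 <- convFw(b$y, w3, p[[paste0(prefix, ".c3.b")]])
  n3 <- instNormFw(y3, p[[paste0(prefix, ".c3.g")]], p[[paste0(prefix, ".c3.be")]])
  s <- x + n3$y
  list(y = reluFw(s), cache = list(a = a$cache, b = b$cache, b_y = b$y,
                                   n3c = n3$cache, s = s))
}

bottleneckBwP <- function(p, G, prefix, cache, gy) {
  gs <- reluBw(cache$s, gy)
  n3 <- instNormBw(cache$n3c, gs)
  gAdd(G, paste0(prefix, ".c3.g"), n3$gg)
  gAdd(G, paste0(prefix, ".c3.be"), n3$gb)
  c3 <- convBw(cache$b_y, p[[paste0(prefix, ".c3.w")]], n3$gx)
  gAdd(G, paste0(prefix, ".c3.w"), c3$gw)
  gAdd(G, paste0(prefix, ".c3.b"), c3$gb)
  g <- cbrBwP(p, G, paste0(prefix, ".c2"), cache$b, c3$gx)
  g <- cbrBwP(p, G, paste0(prefix, ".c1"), cache$a, g)
  g + gs  # residual skip
}

#' Forward pass: per-voxel class scores
#'
#' @param model a `vbnet_model`.
#' @param x input array (X, Y, Z, C) with C = `inChannels`; a 3D array is
#'   treated as single-channel. Spatial sides must be divisible by
#'   `2^levels` (`2^(levels+1)` with adaptive input).
#' @param withCache keep intermediate activations for [vbnetBackward()].
#' @return `list(scores, cache)`; `scores` has `outClasses` channels.
#' @export
vbnetForward <- function(model, x, withCache = FALSE) {
  spec <- model$spec
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (any(dim(x)[1:3] %% specDivisor(spec) != 0))
    stop(sprintf("input sides %s must be divisible by %d",
                 paste(dim(x)[1:3], collapse = "x"), specDivisor(spec)))
  p <- model$params
  L <- spec@levels
  nb <- specBottlenecks(spec)
  cache <- list()
  if (spec@adaptiveInput) {
    cache$x0 <- x
    x <- convFw(x, p$pre.w, p$pre.b, 2L, 0L)
    cache$pre_y <- x
  }
  e <- vector("list", L + 1)
  cc <- vector("list", L + 1)
  f <- cbrFwP(p, "in", x, pad = 1L)
  e[[1]] <- f$y; cc[[1]] <- list(cbr = f$cache)
  for (l in seq_len(L)) {
    f <- cbrFwP(p, paste0("down", l), e[[l]], stride = 2L)
    t <- f$y
    bns <- vector("list", nb[l])
    for (m in seq_len(nb[l])) {
      bf <- bottleneckFwP(p, sprintf("down%d.bn%d", l, m), t)
      t <- bf$y; bns[[m]] <- bf$cache
    }
    e[[l + 1]] <- t
    cc[[l + 1]] <- list(cbr = f$cache, bns = bns)
  }
  d <- e[[L + 1]]
  up <- vector("list", L)
  for (l in rev(seq_len(L))) {
    pre <- paste0("up", l)
    u1 <- tconvFw(d, p[[paste0(pre, ".tw")]], p[[paste0(pre, ".tb")]])
    un <- instNormFw(u1, p[[paste0(pre, ".tg")]], p[[paste0(pre, ".tbe")]])
    u <- reluFw(un$y)
    ct <- catChannels(u, e[[l]])
    mf <- cbrFwP(p, paste0(pre, ".m"), ct)
    t <- mf$y
    nbu <- nb[L + (L - l + 1L)]
    bns <- vector("list", nbu)
    for (m in seq_len(nbu)) {
      bf <- bottleneckFwP(p, sprintf("up%d.bn%d", l, m), t)
      t <- bf$y; bns[[m]] <- bf$cache
    }
    up[[l]] <- list(d_in = d, un_pre = un$y, unc = un$cache, u = u,
                    mcache = mf$cache, bns = bns, cu = dim(u)[4])
    d <- t
  }
  scores <- convFw(d, p$out.w, p$out.b)
  cache$dec_in <- d
  if (spec@adaptiveInput) {
    cache$scores_small <- scores
    scores <- tconvFw(scores, p$post.w, p$post.b)
  }
  if (withCache) {
    cache$enc <- cc; cache$e <- e; cache$up <- up
    list(scores = scores, cache = cache)
  } else list(scores = scores, cache = NULL)
}

#' Backward pass: parameter gradients from a score-space gradient
#'
#' @param model a `vbnet_model`.
#' @param cache the cache from `vbnetForward(..., withCache = TRUE)`.
#' @param gscores gradient of the loss in the class-score output.
#' @return Named list of gradients matching `model$params`.
#' @export
vbnetBackward <- function(model, cache, gscores) {
  spec <- model$spec
  p <- model$params
  L <- spec@levels
  nb <- specBottlenecks(spec)
  G <- new.env(); G$g <- list()
  if (spec@adaptiveInput) {
    tb <- tconvBw(cache$scores_small, p$post.w, gscores)
    gAdd(G, "post.w", tb$gw); gAdd(G, "post.b", tb$gb)
    gscores <- tb$gx
  }
  ob <- convBw(cache$dec_in, p$out.w, gscores)
  gAdd(G, "out.w", ob$gw); gAdd(G, "out.b", ob$gb)
  g <- ob$gx
  gskip <- vector("list", L + 1)  # gradients flowing into encoder features
  for (l in seq_len(L)) {
    pre <- paste0("up", l)
    uc <- cache$up[[l]]
    nbu <- nb[L + (L - l + 1L)]
    for (m in rev(seq_len(nbu)))
      g <- bottleneckBwP(p, G, sprintf("up%d.bn%d", l, m), uc$bns[[m]], g)
    g <- cbrBwP(p, G, paste0(pre, ".m"), uc$mcache, g)
    sp <- splitChannels(g, uc$cu)
    gskip[[l]] <- sp[[2]]
    gu <- reluBw(uc$un_pre, sp[[1]])
    un <- instNormBw(uc$unc, gu)
    gAdd(G, paste0(pre, ".tg"), un$gg)
    gAdd(G, paste0(pre, ".tbe"), un$gb)
    tb <- tconvBw(uc$d_in, p[[paste0(pre, ".tw")]], un$gx)
    gAdd(G, paste0(pre, ".tw"), tb$gw)
    gAdd(G, paste0(pre, ".tb"), tb$gb)
    g <- tb$gx
  }
  # g now flows into the deepest encoder feature e[[L+1]]
  for (l in rev(seq_len(L))) {
    ec <- cache$enc[[l + 1]]
    for (m in rev(seq_len(nb[l])))
      g <- bottleneckBwP(p, G, sprintf("down%d.bn%d", l, m), ec$bns[[m]], g)
    g <- cbrBwP(p, G, paste0("down", l), ec$cbr, g)
    g <- g + gskip[[l]]
  }
  g <- cbrBwP(p, G, "in", cache$enc[[1]]$cbr, g)
  if (spec@adaptiveInput) {
    cb <- convBw(cache$x0, p$pre.w, g, 2L, 0L)
    gAdd(G, "pre.w", cb$gw); gAdd(G, "pre.b", cb$gb)
  }
  G$g
}

#' Per-voxel class probabilities
#'
#' Softmax of the forward scores over the class channel.
#'
#' @inheritParams vbnetForward
#' @return Array (X, Y, Z, outClasses) of probabilities summing to 1 per
#'   voxel.
#' @export
predictProbs <- function(model, x) {
  softmaxChannels(vbnetForward(model, x)$scores)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds `params.rds` (the parameter archive) and
#' `spec.json` (the generating [NetworkSpec-class] plus any metadata, e.g.
#' the normalization used in training), so inference never guesses the
#' architecture.
#'
#' @param model a `vbnet_model`.
#' @param dir checkpoint directory (created if needed).
#' @param meta named list of extra metadata stored in `spec.json`.
#' @return `dir`, invisibly.
#' @export
saveCheckpoint <- function(model, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- model$spec
  js <- list(spec = list(inChannels = s@inChannels, outClasses = s@outClasses,
                         levels = s@levels, baseChannels = s@baseChannels,
                         bottlenecksPerBlock = s@bottlenecksPerBlock,
                         adaptiveInput = s@adaptiveInput),
             meta = meta)
  jsonlite::write_json(js, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint`: the restored model with a `meta` element.
#' @export
loadCheckpoint <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- NetworkSpec(inChannels = js$spec$inChannels,
                      outClasses = js$spec$outClasses,
                      levels = js$spec$levels,
                      baseChannels = js$spec$baseChannels,
                      bottlenecksPerBlock = js$spec$bottlenecksPerBlock,
                      adaptiveInput = js$spec$adaptiveInput)
  params <- readRDS(file.path(dir, "params.rds"))
  m <- structure(list(spec = spec, params = params), class = "vbnet_model")
  m$meta <- js$meta
  m
}
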