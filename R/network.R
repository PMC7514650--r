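#' @include AllClasses.R
NULL

# ---- parameter initialization -------------------------------------------

.heConv <- function(kh, kw, cin, cout) {
  lim <- sqrt(6 / (kh * kw * cin)) # He-uniform on fan-in
  array(runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
}

.convParams <- function(kh, kw, cin, cout)
  list(w = .heConv(kh, kw, cin, cout), b = numeric(cout))

.bnParams <- function(c) list(gamma = rep(1, c), beta = numeric(c))

.bnState <- function(c) list(mean = numeric(c), var = rep(1, c))

.relu <- function(x) { x[x < 0] <- 0; x }

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- analytic channel traces --------------------------------------------

#' Channel trace of a dense block
#'
#' In a dense block, layer i consumes the concatenation of the block input
#' and all previous layer outputs — `inChannels + (i-1) * growthRate`
#' channels — and contributes `growthRate` new feature maps; the block
#' output concatenates the input with every layer's output, so the block
#' adds exactly `layersPerBlock * growthRate` channels.
#'
#' @param inChannels channels entering the block.
#' @param layersPerBlock number of composite (BN-ReLU-conv) layers.
#' @param growthRate feature maps added per layer.
#' @return list with `trace` (input channels per layer) and `outChannels`.
#' @examples
#' denseBlockSpec(16, 5, 16) # trace 16 32 48 64 80, out 96
#' @export
denseBlockSpec <- function(inChannels, layersPerBlock, growthRate) {
  stopifnot(inChannels >= 1, layersPerBlock >= 1, growthRate >= 1)
  trace <- inChannels + growthRate * (seq_len(layersPerBlock) - 1L)
  list(trace = as.integer(trace),
       outChannels = as.integer(inChannels + layersPerBlock * growthRate))
}

# layer-table helper for ModelSpec
.specRow <- function(kind, h, w, cin, cout, nparams) {
  data.frame(kind = kind, height = h, width = w, inChannels = cin,
             outChannels = cout, nParams = nparams,
             stringsAsFactors = FALSE)
}

.denseBlockParamCount <- function(cin, l, k) {
  tr <- denseBlockSpec(cin, l, k)$trace
  sum(2 * tr) + sum(9 * tr * k + k) # BN gamma/beta + 3x3 conv w/b per layer
}

# Full analytic spec of the dense U-net: layer table + block traces.
.denseUnetSpec <- function(cfg) {
  k <- cfg@growthRate; l <- cfg@layersPerBlock; B <- cfg@nDenseBlocks
  s <- cfg@patchSize
  rows <- .specRow("stem_conv3x3", s, s, 1L, cfg@initChannels,
                   9 * cfg@initChannels + cfg@initChannels)
  blocks <- list()
  ch <- cfg@initChannels
  skips <- integer(B)
  for (b in seq_len(B)) {
    bs <- denseBlockSpec(ch, l, k)
    blocks[[paste0("down", b)]] <- bs
    rows <- rbind(rows, .specRow(paste0("dense_block_down", b), s, s, ch,
                                 bs$outChannels,
                                 .denseBlockParamCount(ch, l, k)))
    skips[b] <- bs$outChannels
    tdOut <- bs$outChannels %/% 2L
    rows <- rbind(rows, .specRow(paste0("transition_down", b), s, s,
                                 bs$outChannels, tdOut,
                                 2 * bs$outChannels +
                                   bs$outChannels * tdOut + tdOut))
    s <- s %/% 2L
    ch <- tdOut
  }
  bs <- denseBlockSpec(ch, l, k)
  blocks[["bottleneck"]] <- bs
  rows <- rbind(rows, .specRow("dense_block_bottleneck", s, s, ch,
                               bs$outChannels,
                               .denseBlockParamCount(ch, l, k)))
  newCh <- l * k # only the new feature maps ride the up path
  for (b in rev(seq_len(B))) {
    s <- s * 2L
    tuOut <- newCh %/% 2L
    rows <- rbind(rows, .specRow(paste0("transition_up", B - b + 1L), s, s,
                                 newCh, tuOut, newCh * tuOut + tuOut))
    cin <- tuOut + skips[b]
    bs <- denseBlockSpec(cin, l, k)
    blocks[[paste0("up", B - b + 1L)]] <- bs
    rows <- rbind(rows, .specRow(paste0("dense_block_up", B - b + 1L), s, s,
                                 cin, bs$outChannels,
                                 .denseBlockParamCount(cin, l, k)))
    ch <- bs$outChannels
  }
  rows <- rbind(rows, .specRow("head_conv1x1_sigmoid", s, s, ch, 1L, ch + 1L))
  list(layers = rows, blocks = blocks, skipChannels = skips)
}

.unetSpec <- function(depth, base, patchSize) {
  s <- patchSize
  rows <- NULL
  ch <- 1L
  enc <- integer(depth)
  convPair <- function(h, w, cin, cmid) {
    rbind(.specRow("conv3x3_bn_relu", h, w, cin, cmid,
                   9 * cin * cmid + cmid + 2 * cmid),
          .specRow("conv3x3_bn_relu", h, w, cmid, cmid,
                   9 * cmid * cmid + cmid + 2 * cmid))
  }
  for (i in seq_len(depth)) {
    ci <- base * 2L^(i - 1L)
    rows <- rbind(rows, convPair(s, s, ch, ci))
    enc[i] <- ci
    ch <- ci
    if (i < depth) {
      rows <- rbind(rows, .specRow("maxpool2", s, s, ci, ci, 0))
      s <- s %/% 2L
    }
  }
  for (i in rev(seq_len(depth - 1L))) {
    s <- s * 2L
    ci <- enc[i]
    rows <- rbind(rows, .specRow("up_conv1x1", s, s, ch, ci, ch * ci + ci))
    rows <- rbind(rows, convPair(s, s, 2L * ci, ci))
    ch <- ci
  }
  rows <- rbind(rows, .specRow("head_conv1x1_sigmoid", s, s, ch, 1L, ch + 1L))
  list(layers = rows, blocks = list(), encChannels = enc)
}

# ---- construction --------------------------------------------------------

.denseBlockInit <- function(cin, l, k) {
  tr <- denseBlockSpec(cin, l, k)$trace
  list(params = lapply(tr, function(ci)
         list(bn = .bnParams(ci), conv = .convParams(3, 3, ci, k))),
       state = lapply(tr, function(ci) .bnState(ci)))
}

#' Build the dense U-net
#'
#' Constructs the trainable network: a 3x3 stem convolution, `nDenseBlocks`
#' dense-block / transition-down pairs on the contracting path, a
#' bottleneck dense block, and mirrored transition-up / skip-concatenation /
#' dense-block stages on the expansive path, ending in a 1x1 convolution
#' with a per-pixel sigmoid. Transition down is BN-ReLU-1x1 conv (halving
#' channels) followed by 2x2 average pooling; transition up is 2x2
#' upsampling followed by a channel-halving 1x1 convolution. Weights are
#' He-uniform draws from the current RNG stream, so `set.seed()` beforehand
#' makes construction reproducible.
#'
#' @param config a [NetworkConfig-class].
#' @return A [VesselNet-class] with arch `"dense_unet"`.
#' @examples
#' set.seed(1)
#' net <- buildDenseUnet(NetworkConfig(growthRate = 4, initChannels = 4,
#'                                     layersPerBlock = 2, patchSize = 16))
#' @export
buildDenseUnet <- function(config) {
  stopifnot(is(config, "NetworkConfig"))
  k <- config@growthRate; l <- config@layersPerBlock; B <- config@nDenseBlocks
  spec <- .denseUnetSpec(config)
  params <- list(stem = .convParams(3, 3, 1, config@initChannels))
  state <- list(down = vector("list", B), up = vector("list", B))
  ch <- config@initChannels
  params$down <- vector("list", B)
  for (b in seq_len(B)) {
    db <- .denseBlockInit(ch, l, k)
    out <- ch + l * k
    tdOut <- out %/% 2L
    params$down[[b]] <- list(block = db$params,
                             td = list(bn = .bnParams(out),
                                       conv = .convParams(1, 1, out, tdOut)))
    state$down[[b]] <- list(block = db$state, td = .bnState(out))
    ch <- tdOut
  }
  db <- .denseBlockInit(ch, l, k)
  params$bottleneck <- db$params
  state$bottleneck <- db$state
  newCh <- l * k # transition up carries only the new feature maps
  ch <- ch + l * k
  params$up <- vector("list", B)
  for (u in seq_len(B)) {
    b <- B - u + 1L
    tuOut <- newCh %/% 2L
    cin <- tuOut + spec$skipChannels[b]
    db <- .denseBlockInit(cin, l, k)
    params$up[[u]] <- list(tu = .convParams(1, 1, newCh, tuOut),
                           block = db$params)
    state$up[[u]] <- list(block = db$state)
    ch <- cin + l * k
  }
  params$head <- .convParams(1, 1, ch, 1)
  new("VesselNet", arch = "dense_unet", config = config, params = params,
      state = state, spec = spec)
}

#' Build the plain U-net baseline
#'
#' A standard contracting/expansive U-net with two conv3x3-BN-ReLU layers
#' per resolution, 2x2 max pooling, 2x upsampling with a channel-halving
#' 1x1 convolution and concatenation skips — the parameter-matched baseline
#' against which the dense U-net is compared.
#'
#' @param depth number of resolution levels (default 3).
#' @param baseChannels channels at the finest resolution.
#' @param patchSize input spatial size; must be divisible by
#'   `2^(depth - 1)`.
#' @return A [VesselNet-class] with arch `"unet"`.
#' @examples
#' set.seed(1)
#' net <- buildUnet(depth = 2, baseChannels = 4, patchSize = 16)
#' @export
buildUnet <- function(depth = 3L, baseChannels = 16L, patchSize = 48L) {
  stopifnot(depth >= 1, baseChannels >= 1)
  if (patchSize %% 2L^(depth - 1L) != 0L)
    stop("patchSize must be divisible by 2^(depth - 1)")
  spec <- .unetSpec(as.integer(depth), as.integer(baseChannels),
                    as.integer(patchSize))
  cfg <- NetworkConfig(growthRate = baseChannels, initChannels = baseChannels,
                       nDenseBlocks = max(1L, depth - 1L), layersPerBlock = 2L,
                       patchSize = as.integer(patchSize), dropout = 0)
  params <- list(enc = vector("list", depth))
  state <- list(enc = vector("list", depth))
  ch <- 1L
  for (i in seq_len(depth)) {
    ci <- baseChannels * 2L^(i - 1L)
    params$enc[[i]] <- list(
      conv1 = .convParams(3, 3, ch, ci), bn1 = .bnParams(ci),
      conv2 = .convParams(3, 3, ci, ci), bn2 = .bnParams(ci))
    state$enc[[i]] <- list(bn1 = .bnState(ci), bn2 = .bnState(ci))
    ch <- ci
  }
  params$dec <- vector("list", depth - 1L)
  state$dec <- vector("list", depth - 1L)
  if (depth > 1L) for (u in seq_len(depth - 1L)) {
    i <- depth - u
    ci <- baseChannels * 2L^(i - 1L)
    params$dec[[u]] <- list(
      up = .convParams(1, 1, ch, ci),
      conv1 = .convParams(3, 3, 2L * ci, ci), bn1 = .bnParams(ci),
      conv2 = .convParams(3, 3, ci, ci), bn2 = .bnParams(ci))
    state$dec[[u]] <- list(bn1 = .bnState(ci), bn2 = .bnState(ci))
    ch <- ci
  }
  params$head <- .convParams(1, 1, ch, 1)
  new("VesselNet", arch = "unet", config = cfg, params = params,
      state = state, spec = spec)
}

setMethod("countParameters", "VesselNet", function(object) {
  n <- 0L
  count <- function(x) {
    if (is.list(x)) lapply(x, count) else n <<- n + length(x)
    invisible(NULL)
  }
  count(object@params)
  n
})

setMethod("modelSpec", "VesselNet", function(object) object@spec)

#' Find a parameter-matched U-net base width
#'
#' Searches over `baseChannels` for the plain U-net whose trainable
#' parameter count is closest to a reference dense U-net's, the harness
#' behind "approximately equal parameter count" baseline comparisons.
#'
#' @param denseNet reference [VesselNet-class] (dense U-net).
#' @param depth U-net depth.
#' @param candidates base widths to try.
#' @return list with `baseChannels`, `unetParams`, `denseParams`,
#'   `relError`.
#' @export
matchUnetParameters <- function(denseNet, depth = 3L,
                                candidates = 4:96) {
  target <- countParameters(denseNet)
  ps <- denseNet@config@patchSize
  best <- NULL
  for (bc in candidates) {
    n <- sum(.unetSpec(as.integer(depth), as.integer(bc), ps)$layers$nParams)
    rel <- abs(n - target) / target
    if (is.null(best) || rel < best$relError)
      best <- list(baseChannels = as.integer(bc), unetParams = n,
                   denseParams = target, relError = rel)
  }
  best
}

# ---- forward / backward ---------------------------------------------------

# Dense block on the float core: the concat tensor carries the block input
# as a channel prefix; each fused layer kernel reads its prefix and writes
# growthRate new channels in place. Caches hold only the batch moments and
# the dropout seed (masks are regenerated in backward).
.denseBlockFwd <- function(pb, sb, xft, k, dropout, training) {
  d <- ft_dims(xft)
  l <- length(pb)
  concat <- ft_new(c(d[1], d[2], d[3] + l * k, d[4]))
  ft_set_channels(concat, xft, 0L)
  caches <- vector("list", l)
  for (i in seq_len(l)) {
    ci <- d[3] + (i - 1L) * k
    seed <- if (training && dropout > 0) sample.int(.Machine$integer.max, 1L) else 0L
    if (training) {
      st <- ft_dense_layer_fwd(concat, ci, pb[[i]]$bn$gamma,
                               pb[[i]]$bn$beta, .BN_EPS, FALSE,
                               numeric(ci), numeric(ci), pb[[i]]$conv$w,
                               pb[[i]]$conv$b, dropout, seed)
      sb[[i]]$mean <- (1 - .BN_MOMENTUM) * sb[[i]]$mean + .BN_MOMENTUM * st$mean
      sb[[i]]$var <- (1 - .BN_MOMENTUM) * sb[[i]]$var + .BN_MOMENTUM * st$var
    } else {
      st <- ft_dense_layer_fwd(concat, ci, pb[[i]]$bn$gamma,
                               pb[[i]]$bn$beta, .BN_EPS, TRUE,
                               sb[[i]]$mean, sb[[i]]$var, pb[[i]]$conv$w,
                               pb[[i]]$conv$b, 0, 0L)
    }
    if (training)
      caches[[i]] <- list(mean = st$mean, var = st$var, seed = seed)
  }
  list(out = concat, caches = caches, state = sb)
}

# Backward mirrors forward in reverse; prefix gradients accumulate in place
# into dOut (a tensor owned by the caller, freshly allocated upstream).
.denseBlockBwd <- function(pb, concat, caches, dOut, k, c0, dropout) {
  l <- length(pb)
  grads <- vector("list", l)
  for (i in rev(seq_len(l))) {
    ci <- c0 + (i - 1L) * k
    r <- ft_dense_layer_bwd(concat, dOut, ci, pb[[i]]$bn$gamma,
                            pb[[i]]$bn$beta, caches[[i]]$mean,
                            caches[[i]]$var, .BN_EPS, pb[[i]]$conv$w,
                            if (caches[[i]]$seed > 0) dropout else 0,
                            caches[[i]]$seed)
    grads[[i]] <- list(bn = list(gamma = r$dgamma, beta = r$dbeta),
                       conv = list(w = r$dw, b = r$db))
  }
  list(dx = ft_get_channels(dOut, 0L, c0), grads = grads)
}

# BN-ReLU-1x1conv-avgpool (transition down)
.tdFwd <- function(pt, st, xft, training) {
  if (training) {
    bn <- ft_bnrelu_fwd(xft, pt$bn$gamma, pt$bn$beta, .BN_EPS, FALSE,
                        numeric(length(pt$bn$gamma)),
                        numeric(length(pt$bn$gamma)))
    st$mean <- (1 - .BN_MOMENTUM) * st$mean + .BN_MOMENTUM * bn$mean
    st$var <- (1 - .BN_MOMENTUM) * st$var + .BN_MOMENTUM * bn$var
  } else {
    bn <- ft_bnrelu_fwd(xft, pt$bn$gamma, pt$bn$beta, .BN_EPS, TRUE,
                        st$mean, st$var)
  }
  z <- ft_conv_fwd(bn$a, pt$conv$w, pt$conv$b, 0L)
  y <- ft_avgpool_fwd(z)
  list(y = y, cache = if (training)
    list(a = bn$a, mean = bn$mean, var = bn$var) else NULL, state = st)
}

.tdBwd <- function(pt, xft, cache, dy) {
  dz <- ft_avgpool_bwd(dy)
  cb <- ft_conv_bwd(cache$a, pt$conv$w, dz, 0L)
  bb <- ft_bnrelu_bwd(xft, pt$bn$gamma, pt$bn$beta, cache$mean, cache$var,
                      .BN_EPS, cb$dx)
  list(dx = bb$dx, grads = list(bn = list(gamma = bb$dgamma,
                                          beta = bb$dbeta),
                                conv = list(w = cb$dw, b = cb$db)))
}

.netForward <- function(net, x, training = FALSE) {
  if (net@arch == "dense_unet") .denseUnetForward(net, x, training)
  else .unetForward(net, x, training)
}

.denseUnetForward <- function(net, x, training) {
  cfg <- net@config
  p <- net@params; s <- net@state
  k <- cfg@growthRate; l <- cfg@layersPerBlock; B <- cfg@nDenseBlocks
  bilinear <- cfg@upsampleMode == "bilinear"
  xft <- ft_from(x)
  cache <- list(x = xft)
  f <- ft_conv_fwd(xft, p$stem$w, p$stem$b, 1L)
  skips <- vector("list", B)
  down <- vector("list", B)
  for (b in seq_len(B)) {
    db <- .denseBlockFwd(p$down[[b]]$block, s$down[[b]]$block, f, k,
                         cfg@dropout, training)
    s$down[[b]]$block <- db$state
    skips[[b]] <- db$out
    td <- .tdFwd(p$down[[b]]$td, s$down[[b]]$td, db$out, training)
    s$down[[b]]$td <- td$state
    down[[b]] <- list(blockIn = ft_dims(f)[3], block = db, td = td)
    f <- td$y
  }
  bot <- .denseBlockFwd(p$bottleneck, s$bottleneck, f, k, cfg@dropout,
                        training)
  s$bottleneck <- bot$state
  botIn <- ft_dims(f)[3]
  f <- bot$out
  newCh <- l * k
  up <- vector("list", B)
  for (u in seq_len(B)) {
    b <- B - u + 1L
    newf <- ft_get_channels(f, ft_dims(f)[3] - newCh, newCh)
    upsampled <- ft_upsample_fwd(newf, bilinear)
    t <- ft_conv_fwd(upsampled, p$up[[u]]$tu$w, p$up[[u]]$tu$b, 0L)
    cat <- ft_cat(t, skips[[b]])
    db <- .denseBlockFwd(p$up[[u]]$block, s$up[[u]]$block, cat, k,
                         cfg@dropout, training)
    s$up[[u]]$block <- db$state
    up[[u]] <- list(upsampled = upsampled, tuOut = ft_dims(t)[3],
                    blockIn = ft_dims(cat)[3], block = db)
    f <- db$out
  }
  z <- ft_array(ft_conv_fwd(f, p$head$w, p$head$b, 0L))
  prob <- 1 / (1 + exp(-z))
  cache$down <- down; cache$bot <- bot; cache$botIn <- botIn
  cache$up <- up; cache$headIn <- f; cache$prob <- prob
  list(prob = prob, cache = if (training) cache else NULL, state = s)
}

.denseUnetBackward <- function(net, cache, dz) {
  cfg <- net@config
  p <- net@params
  k <- cfg@growthRate; l <- cfg@layersPerBlock; B <- cfg@nDenseBlocks
  bilinear <- cfg@upsampleMode == "bilinear"
  newCh <- l * k
  g <- list()
  hb <- ft_conv_bwd(cache$headIn, p$head$w, ft_from(dz), 0L)
  g$head <- list(w = hb$dw, b = hb$db)
  df <- hb$dx
  g$up <- vector("list", B)
  dskips <- vector("list", B)
  for (u in rev(seq_len(B))) {
    b <- B - u + 1L
    uc <- cache$up[[u]]
    bw <- .denseBlockBwd(p$up[[u]]$block, uc$block$out, uc$block$caches,
                         df, k, uc$blockIn, cfg@dropout)
    dcat <- bw$dx
    dt <- ft_get_channels(dcat, 0L, uc$tuOut)
    dskips[[b]] <- ft_get_channels(dcat, uc$tuOut,
                                   ft_dims(dcat)[3] - uc$tuOut)
    tb <- ft_conv_bwd(uc$upsampled, p$up[[u]]$tu$w, dt, 0L)
    dnew <- ft_upsample_bwd(tb$dx, bilinear)
    g$up[[u]] <- list(tu = list(w = tb$dw, b = tb$db), block = bw$grads)
    # only the new feature maps fed the transition up; build the gradient
    # tensor for the preceding block's output accordingly
    prevOut <- if (u > 1L) cache$up[[u - 1L]]$block$out else cache$bot$out
    df <- ft_new(ft_dims(prevOut))
    ft_set_channels(df, dnew, ft_dims(prevOut)[3] - newCh)
  }
  bw <- .denseBlockBwd(p$bottleneck, cache$bot$out, cache$bot$caches, df,
                       k, cache$botIn, cfg@dropout)
  g$bottleneck <- bw$grads
  df <- bw$dx
  g$down <- vector("list", B)
  for (b in rev(seq_len(B))) {
    dc <- cache$down[[b]]
    td <- .tdBwd(p$down[[b]]$td, dc$block$out, dc$td$cache, df)
    dblockOut <- td$dx
    ft_add(dblockOut, dskips[[b]])
    bw <- .denseBlockBwd(p$down[[b]]$block, dc$block$out, dc$block$caches,
                         dblockOut, k, dc$blockIn, cfg@dropout)
    g$down[[b]] <- list(block = bw$grads, td = td$grads)
    df <- bw$dx
  }
  sb <- ft_conv_bwd(cache$x, p$stem$w, df, 1L)
  g$stem <- list(w = sb$dw, b = sb$db)
  g
}

# conv3x3 + BN + ReLU unit used by the plain U-net
.cbrFwd <- function(pc, pbn, st, x, training) {
  z <- cpp_conv2d_fwd(x, pc$w, pc$b, 1L)
  ci <- dim(z)[3]
  if (training) {
    bn <- cpp_bnrelu_fwd(z, ci, pbn$gamma, pbn$beta, .BN_EPS, FALSE,
                         numeric(ci), numeric(ci), TRUE)
    st$mean <- (1 - .BN_MOMENTUM) * st$mean + .BN_MOMENTUM * bn$mean
    st$var <- (1 - .BN_MOMENTUM) * st$var + .BN_MOMENTUM * bn$var
  } else {
    bn <- cpp_bnrelu_fwd(z, ci, pbn$gamma, pbn$beta, .BN_EPS, TRUE,
                         st$mean, st$var, TRUE)
  }
  list(a = bn$a, cache = if (training)
    list(x = x, z = z, mean = bn$mean, var = bn$var) else NULL,
    state = st)
}

.cbrBwd <- function(pc, pbn, cache, da) {
  bb <- cpp_bnrelu_bwd(cache$z, dim(cache$z)[3], pbn$gamma, pbn$beta,
                       cache$mean, cache$var, .BN_EPS, da, TRUE)
  cb <- cpp_conv2d_bwd(cache$x, pc$w, bb$dx, 1L)
  list(dx = cb$dx,
       gconv = list(w = cb$dw, b = cb$db),
       gbn = list(gamma = bb$dgamma, beta = bb$dbeta))
}

.unetForward <- function(net, x, training) {
  p <- net@params; s <- net@state
  depth <- length(p$enc)
  cache <- list()
  encOut <- vector("list", depth)
  encCache <- vector("list", depth)
  poolIdx <- vector("list", depth)
  f <- x
  for (i in seq_len(depth)) {
    c1 <- .cbrFwd(p$enc[[i]]$conv1, p$enc[[i]]$bn1, s$enc[[i]]$bn1, f,
                  training)
    s$enc[[i]]$bn1 <- c1$state
    c2 <- .cbrFwd(p$enc[[i]]$conv2, p$enc[[i]]$bn2, s$enc[[i]]$bn2, c1$a,
                  training)
    s$enc[[i]]$bn2 <- c2$state
    encOut[[i]] <- c2$a
    encCache[[i]] <- list(c1 = c1$cache, c2 = c2$cache)
    f <- c2$a
    if (i < depth) {
      mp <- cpp_maxpool2_fwd(f)
      poolIdx[[i]] <- mp$idx
      f <- mp$y
    }
  }
  decCache <- vector("list", depth - 1L)
  if (depth > 1L) for (u in seq_len(depth - 1L)) {
    i <- depth - u
    upsampled <- cpp_upsample2_fwd(f, TRUE)
    t <- cpp_conv2d_fwd(upsampled, p$dec[[u]]$up$w, p$dec[[u]]$up$b, 0L)
    cat <- .cat3(t, encOut[[i]])
    c1 <- .cbrFwd(p$dec[[u]]$conv1, p$dec[[u]]$bn1, s$dec[[u]]$bn1, cat,
                  training)
    s$dec[[u]]$bn1 <- c1$state
    c2 <- .cbrFwd(p$dec[[u]]$conv2, p$dec[[u]]$bn2, s$dec[[u]]$bn2, c1$a,
                  training)
    s$dec[[u]]$bn2 <- c2$state
    decCache[[u]] <- list(upsampled = upsampled, tuOut = dim(t)[3],
                          c1 = c1$cache, c2 = c2$cache)
    f <- c2$a
  }
  z <- cpp_conv2d_fwd(f, p$head$w, p$head$b, 0L)
  prob <- 1 / (1 + exp(-z))
  cache <- list(enc = encCache, poolIdx = poolIdx, dec = decCache,
                headIn = f, prob = prob)
  list(prob = prob, cache = if (training) cache else NULL, state = s)
}

.unetBackward <- function(net, cache, dz) {
  p <- net@params
  depth <- length(p$enc)
  g <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
  hb <- cpp_conv2d_bwd(cache$headIn, p$head$w, dz, 0L)
  g$head <- list(w = hb$dw, b = hb$db)
  df <- hb$dx
  dskips <- vector("list", depth)
  if (depth > 1L) for (u in rev(seq_len(depth - 1L))) {
    i <- depth - u
    dc <- cache$dec[[u]]
    b2 <- .cbrBwd(p$dec[[u]]$conv2, p$dec[[u]]$bn2, dc$c2, df)
    b1 <- .cbrBwd(p$dec[[u]]$conv1, p$dec[[u]]$bn1, dc$c1, b2$dx)
    dcat <- b1$dx
    dt <- dcat[, , seq_len(dc$tuOut), , drop = FALSE]
    dskips[[i]] <- dcat[, , dc$tuOut + seq_len(dim(dcat)[3] - dc$tuOut), ,
                        drop = FALSE]
    tb <- cpp_conv2d_bwd(dc$upsampled, p$dec[[u]]$up$w, dt, 0L)
    df <- cpp_upsample2_bwd(tb$dx, TRUE)
    g$dec[[u]] <- list(up = list(w = tb$dw, b = tb$db),
                       conv1 = b1$gconv, bn1 = b1$gbn,
                       conv2 = b2$gconv, bn2 = b2$gbn)
  }
  for (i in rev(seq_len(depth))) {
    if (i < depth) df <- cpp_maxpool2_bwd(df, cache$poolIdx[[i]])
    if (!is.null(dskips[[i]])) df <- df + dskips[[i]]
    b2 <- .cbrBwd(p$enc[[i]]$conv2, p$enc[[i]]$bn2, cache$enc[[i]]$c2, df)
    b1 <- .cbrBwd(p$enc[[i]]$conv1, p$enc[[i]]$bn1, cache$enc[[i]]$c1,
                  b2$dx)
    g$enc[[i]] <- list(conv1 = b1$gconv, bn1 = b1$gbn,
                       conv2 = b2$gconv, bn2 = b2$gbn)
    df <- b1$dx
  }
  g
}

.netBackward <- function(net, cache, dz) {
  if (net@arch == "dense_unet") .denseUnetBackward(net, cache, dz)
  else .unetBackward(net, cache, dz)
}

#' Predict vessel probabilities for a set of patches
#'
#' Runs the network forward in inference mode (batch-norm running
#' statistics, no dropout) over patches in chunks.
#'
#' @param net a trained [VesselNet-class].
#' @param patches array (h x w x n) of normalized patches, or a
#'   [PatchSet-class].
#' @param batchSize patches per forward chunk.
#' @return array (h x w x n) of probabilities in (0, 1).
#' @export
predictPatches <- function(net, patches, batchSize = 32L) {
  if (is(patches, "PatchSet")) patches <- patches@patches
  d <- dim(patches)
  out <- array(0, d)
  idx <- seq_len(d[3])
  for (chunk in split(idx, ceiling(idx / batchSize))) {
    x <- array(patches[, , chunk], c(d[1], d[2], 1L, length(chunk)))
    fw <- .netForward(net, x, training = FALSE)
    out[, , chunk] <- fw$prob
  }
  out
}
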