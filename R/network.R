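#' Network configuration
#'
#' Architecture of the star-convex polygon segmentation network: a
#' symmetric encoder--decoder.  The encoder alternates feature-extraction
#' blocks with 2x2 max pooling (`n_levels` times); an atrous spatial
#' pyramid pooling (ASPP) module sits at the bottleneck; the decoder
#' alternates bilinear 2x upsampling with feature-recognition blocks that
#' concatenate the matching encoder skip.  Two independent point-wise
#' convolutions produce the single-channel object probability (sigmoid)
#' and the `n_rays`-channel radial distances (ReLU).
#'
#' The encoder block is selected by `encoder_variant`:
#' \describe{
#'   \item{`"TCB"`}{two 3x3 conv-ReLU layers (traditional conv block).}
#'   \item{`"TCB+RC"`}{TCB plus a residual shortcut (1x1 projection when
#'     channel counts differ).}
#'   \item{`"TCB+FFA"`}{TCB gated by the feature-fusion attention unit,
#'     which fuses the deep features with shallow features computed from
#'     the original image resized to the block's resolution.}
#'   \item{`"RAE"`}{the full residual attention-embedding block:
#'     attention fusion plus the residual shortcut.}
#' }
#'
#' @param n_rays number of radial directions predicted per pixel.
#' @param base_channels channels of the first level; doubled per level.
#' @param n_levels number of downsampling steps.
#' @param aspp_rates dilation rates of the parallel ASPP branches.
#' @param encoder_variant encoder block type, see Details.
#' @param use_aspp enable the ASPP bottleneck.
#' @return an object of class `spc_config`.
#' @export
spc_network <- function(n_rays = 32, base_channels = 32, n_levels = 3,
                        aspp_rates = c(1, 6, 12, 18),
                        encoder_variant = c("RAE", "TCB", "TCB+RC", "TCB+FFA"),
                        use_aspp = TRUE) {
  encoder_variant <- match.arg(encoder_variant)
  stopifnot(n_levels >= 1, base_channels >= 1, n_rays >= 3)
  structure(list(n_rays = as.integer(n_rays),
                 base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 aspp_rates = as.integer(aspp_rates),
                 encoder_variant = encoder_variant,
                 use_aspp = isTRUE(use_aspp)),
            class = "spc_config")
}

#' @export
print.spc_config <- function(x, ...) {
  cat(sprintf("spc_config: %s encoder, %d levels, base %d ch, %d rays, ASPP %s\n",
              x$encoder_variant, x$n_levels, x$base_channels, x$n_rays,
              if (x$use_aspp) paste(x$aspp_rates, collapse = ",") else "off"))
  invisible(x)
}

.has_ffa <- function(cfg) cfg$encoder_variant %in% c("TCB+FFA", "RAE")
.has_rc <- function(cfg) cfg$encoder_variant %in% c("TCB+RC", "RAE")
.level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

.conv_param <- function(k, cin, cout, gain = 2, bias = 0, has_bias = TRUE) {
  sd <- sqrt(gain / (k * k * cin))
  list(w = array(rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = if (has_bias) rep(bias, cout) else NULL)
}

#' Initialize network parameters
#'
#' He-normal initialization; the probability head bias starts slightly
#' negative (mostly-background prior) and the distance head bias slightly
#' positive (distances are positive on foreground).
#'
#' @param config an [spc_network()] configuration.
#' @param seed integer seed for reproducible initialization.
#' @return named list of parameter arrays (class `spc_params`).
#' @export
spc_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "spc_config"))
  set.seed(seed)
  p <- list()
  L <- config$n_levels
  for (l in seq_len(L)) {
    cin <- if (l == 1) 1L else .level_channels(config, l - 1)
    c <- .level_channels(config, l)
    p[[sprintf("enc%d.fe1", l)]] <- .conv_param(3, cin, c)
    p[[sprintf("enc%d.fe2", l)]] <- .conv_param(3, c, c)
    if (.has_ffa(config)) {
      p[[sprintf("enc%d.fo1", l)]] <- .conv_param(3, 1, c)
      p[[sprintf("enc%d.fo2", l)]] <- .conv_param(3, c, c)
      p[[sprintf("enc%d.ffa.we", l)]] <- .conv_param(1, c, c, has_bias = FALSE)
      p[[sprintf("enc%d.ffa.wo", l)]] <- .conv_param(1, c, c)
      p[[sprintf("enc%d.ffa.phi", l)]] <- .conv_param(1, c, 1)
    }
    if (.has_rc(config) && cin != c)
      p[[sprintf("enc%d.proj", l)]] <- .conv_param(1, cin, c)
  }
  cb <- .level_channels(config, L + 1)
  p[["bott.c1"]] <- .conv_param(3, .level_channels(config, L), cb)
  p[["bott.c2"]] <- .conv_param(3, cb, cb)
  if (config$use_aspp) {
    for (k in seq_along(config$aspp_rates))
      p[[sprintf("aspp.r%d", k)]] <- .conv_param(3, cb, cb)
    p[["aspp.merge"]] <- .conv_param(1, cb * length(config$aspp_rates), cb)
  }
  for (l in seq_len(L)) {
    c <- .level_channels(config, l)
    cup <- .level_channels(config, l + 1)
    p[[sprintf("dec%d.c1", l)]] <- .conv_param(3, cup + c, c)
    p[[sprintf("dec%d.c2", l)]] <- .conv_param(3, c, c)
  }
  c1 <- .level_channels(config, 1)
  p[["head.prob"]] <- .conv_param(1, c1, 1, gain = 1, bias = -1)
  p[["head.dist"]] <- .conv_param(1, c1, config$n_rays, gain = 1, bias = 3)
  structure(p, class = "spc_params", config = config)
}

#' Count trainable parameters
#' @param params an `spc_params` object.
#' @return integer total number of scalar parameters.
#' @export
spc_num_params <- function(params) {
  sum(vapply(params, function(p) length(p$w) + length(p$b), 0))
}

.zb <- function(p, cout) if (is.null(p$b)) rep(0, cout) else p$b
.cv <- function(x, p, dil = 1L)
  cpp_conv2d(x, p$w, .zb(p, dim(p$w)[4]), as.integer(dil))
.relu <- function(x) { x[x < 0] <- 0; x }
.sigm <- function(x) 1 / (1 + exp(-x))
.cat3 <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

#' Feature-fusion attention unit
#'
#' Computes the spatial attention map
#' `Wa = sigmoid(phi(relu(We*Fe + Wo*Fo + bo)) + bphi)` (a single-channel
#' map in `(0,1)`) and returns the gated deep features `Fa = Wa * Fe`.
#'
#' @param fe deep feature array `H x W x C`.
#' @param fo shallow feature array `H x W x C` (same spatial size).
#' @param params list with elements `we` (1x1 conv, no bias), `wo` (1x1
#'   conv, bias `bo`) and `phi` (1x1 conv to one channel, bias `bphi`).
#' @return list with `fa`, the attention map `wa`, and intermediates used
#'   by the backward pass.
#' @export
ffa_attention <- function(fe, fo, params) {
  if (!all(dim(fe)[1:2] == dim(fo)[1:2]))
    stop("ffa_attention: Fe and Fo must have the same spatial size")
  u <- .cv(fe, params$we) + .cv(fo, params$wo)
  r <- .relu(u)
  psi <- .cv(r, params$phi)
  wa <- .sigm(psi)
  fa <- fe * as.vector(wa)
  list(fa = fa, wa = wa, u = u, r = r, fe = fe, fo = fo)
}

.rae_fw <- function(x, img_l, params, prefix, cfg) {
  cache <- list(x = x)
  a1 <- .relu(.cv(x, params[[paste0(prefix, ".fe1")]]))
  fe <- .relu(.cv(a1, params[[paste0(prefix, ".fe2")]]))
  cache$a1 <- a1; cache$fe <- fe
  if (.has_ffa(cfg)) {
    b1 <- .relu(.cv(img_l, params[[paste0(prefix, ".fo1")]]))
    fo <- .relu(.cv(b1, params[[paste0(prefix, ".fo2")]]))
    ffa <- ffa_attention(fe, fo, list(
      we = params[[paste0(prefix, ".ffa.we")]],
      wo = params[[paste0(prefix, ".ffa.wo")]],
      phi = params[[paste0(prefix, ".ffa.phi")]]))
    cache$img_l <- img_l; cache$b1 <- b1; cache$fo <- fo; cache$ffa <- ffa
    out <- ffa$fa
  } else {
    out <- fe
  }
  pj <- paste0(prefix, ".proj")
  if (.has_rc(cfg)) {
    out <- out + if (!is.null(params[[pj]])) .cv(x, params[[pj]]) else x
  }
  cache$out <- out
  cache
}

.rae_bw <- function(gout, cache, params, prefix, cfg, grads) {
  x <- cache$x
  pj <- paste0(prefix, ".proj")
  gx <- NULL
  if (.has_rc(cfg)) {
    if (!is.null(params[[pj]])) {
      bw <- cpp_conv2d_bw(x, params[[pj]]$w, gout, 1L)
      grads[[pj]] <- .acc(grads[[pj]], bw)
      gx <- bw$gx
    } else {
      gx <- gout
    }
  }
  if (.has_ffa(cfg)) {
    ffa <- cache$ffa
    gfa <- gout
    gwa <- array(rowSums(matrix(gfa * ffa$fe, ncol = dim(gfa)[3])),
                 c(dim(gfa)[1], dim(gfa)[2], 1))
    gfe <- gfa * as.vector(ffa$wa)
    gpsi <- gwa * ffa$wa * (1 - ffa$wa)
    pphi <- params[[paste0(prefix, ".ffa.phi")]]
    bw <- cpp_conv2d_bw(ffa$r, pphi$w, gpsi, 1L)
    grads[[paste0(prefix, ".ffa.phi")]] <- .acc(grads[[paste0(prefix, ".ffa.phi")]], bw)
    gu <- bw$gx * (ffa$u > 0)
    pwe <- params[[paste0(prefix, ".ffa.we")]]
    bw <- cpp_conv2d_bw(ffa$fe, pwe$w, gu, 1L)
    grads[[paste0(prefix, ".ffa.we")]] <-
      .acc(grads[[paste0(prefix, ".ffa.we")]], list(gw = bw$gw, gb = NULL))
    gfe <- gfe + bw$gx
    pwo <- params[[paste0(prefix, ".ffa.wo")]]
    bw <- cpp_conv2d_bw(ffa$fo, pwo$w, gu, 1L)
    grads[[paste0(prefix, ".ffa.wo")]] <- .acc(grads[[paste0(prefix, ".ffa.wo")]], bw)
    gfo <- bw$gx
    # shallow branch (input image is constant; only weight grads matter)
    gfo <- gfo * (cache$fo > 0)
    pfo2 <- params[[paste0(prefix, ".fo2")]]
    bw <- cpp_conv2d_bw(cache$b1, pfo2$w, gfo, 1L)
    grads[[paste0(prefix, ".fo2")]] <- .acc(grads[[paste0(prefix, ".fo2")]], bw)
    gb1 <- bw$gx * (cache$b1 > 0)
    pfo1 <- params[[paste0(prefix, ".fo1")]]
    bw <- cpp_conv2d_bw(cache$img_l, pfo1$w, gb1, 1L)
    grads[[paste0(prefix, ".fo1")]] <- .acc(grads[[paste0(prefix, ".fo1")]], bw)
  } else {
    gfe <- gout
  }
  gfe <- gfe * (cache$fe > 0)
  pfe2 <- params[[paste0(prefix, ".fe2")]]
  bw <- cpp_conv2d_bw(cache$a1, pfe2$w, gfe, 1L)
  grads[[paste0(prefix, ".fe2")]] <- .acc(grads[[paste0(prefix, ".fe2")]], bw)
  ga1 <- bw$gx * (cache$a1 > 0)
  pfe1 <- params[[paste0(prefix, ".fe1")]]
  bw <- cpp_conv2d_bw(x, pfe1$w, ga1, 1L)
  grads[[paste0(prefix, ".fe1")]] <- .acc(grads[[paste0(prefix, ".fe1")]], bw)
  gx <- if (is.null(gx)) bw$gx else gx + bw$gx
  list(gx = gx, grads = grads)
}

.acc <- function(slot, bw) {
  if (is.null(slot)) return(list(gw = bw$gw, gb = bw$gb))
  list(gw = slot$gw + bw$gw,
       gb = if (is.null(slot$gb)) NULL else slot$gb + bw$gb)
}

.reflect_pad <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(H2)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(W2)]
  img[ri, ci, drop = FALSE]
}

#' Network forward pass
#'
#' Runs the encoder--decoder on a single-channel image and returns the
#' predicted object probability map and radial distance stack, both at
#' the input resolution.  Inputs whose sides are not divisible by
#' `2^n_levels` are reflect-padded and the outputs cropped back.
#'
#' @param image numeric `H x W` matrix (intensities, any positive range;
#'   training uses `[0, 1]`).
#' @param params parameters from [spc_init()] or [spc_train()].
#' @param keep_cache keep intermediate activations for a backward pass
#'   (training only; requires divisible input sizes).
#' @return list with `prob` (`H x W`, in `(0,1)`), `dist`
#'   (`H x W x n_rays`, non-negative) and, if requested, `cache`.
#' @export
spc_forward <- function(image, params, keep_cache = FALSE) {
  cfg <- attr(params, "config")
  stopifnot(inherits(cfg, "spc_config"), is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  if (H < 1 || W < 1) stop("zero-sized input")
  f <- 2^cfg$n_levels
  H2 <- ceiling(H / f) * f; W2 <- ceiling(W / f) * f
  padded <- (H2 != H) || (W2 != W)
  if (padded) {
    if (keep_cache) stop("training requires input sides divisible by ", f)
    image <- .reflect_pad(image, H2, W2)
  }
  x <- array(image, c(H2, W2, 1))
  L <- cfg$n_levels
  caches <- vector("list", L)
  skips <- vector("list", L)
  pools <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    img_l <- if (l == 1) x else cpp_resize_bilinear(x, dim(cur)[1], dim(cur)[2])
    cc <- .rae_fw(cur, img_l, params, sprintf("enc%d", l), cfg)
    caches[[l]] <- cc
    skips[[l]] <- cc$out
    mp <- cpp_maxpool2(cc$out)
    pools[[l]] <- mp
    cur <- mp$y
  }
  bott_in <- cur
  b1 <- .relu(.cv(bott_in, params$bott.c1))
  bott <- .relu(.cv(b1, params$bott.c2))
  aspp_cache <- NULL
  if (cfg$use_aspp) {
    zs <- lapply(seq_along(cfg$aspp_rates), function(k)
      .relu(.cv(bott, params[[sprintf("aspp.r%d", k)]], cfg$aspp_rates[k])))
    zc <- Reduce(.cat3, zs)
    am <- .relu(.cv(zc, params$aspp.merge))
    aspp_cache <- list(zs = zs, zc = zc, am = am)
    cur <- am
  } else {
    cur <- bott
  }
  dec_caches <- vector("list", L)
  for (l in rev(seq_len(L))) {
    up <- cpp_resize_bilinear(cur, dim(cur)[1] * 2L, dim(cur)[2] * 2L)
    cat_ <- .cat3(up, skips[[l]])
    d1 <- .relu(.cv(cat_, params[[sprintf("dec%d.c1", l)]]))
    d2 <- .relu(.cv(d1, params[[sprintf("dec%d.c2", l)]]))
    dec_caches[[l]] <- list(prev = cur, up = up, cat = cat_, d1 = d1, d2 = d2)
    cur <- d2
  }
  prob_pre <- .cv(cur, params$head.prob)
  dist_pre <- .cv(cur, params$head.dist)
  prob <- .sigm(prob_pre)
  dist <- .relu(dist_pre)
  out <- list(prob = matrix(prob, H2, W2)[seq_len(H), seq_len(W), drop = FALSE],
              dist = dist[seq_len(H), seq_len(W), , drop = FALSE])
  if (keep_cache)
    out$cache <- list(x = x, caches = caches, pools = pools, skips = skips,
                      bott_in = bott_in, b1 = b1, bott = bott,
                      aspp = aspp_cache, dec = dec_caches, final = cur,
                      prob = prob, dist = dist)
  out
}

# Backward pass: takes gradients with respect to the two pre-activation
# head outputs and returns parameter gradients (same names as params).
spc_backward <- function(params, cache, gprob_pre, gdist_pre) {
  cfg <- attr(params, "config")
  grads <- list()
  final <- cache$final
  bw <- cpp_conv2d_bw(final, params$head.prob$w, gprob_pre, 1L)
  grads[["head.prob"]] <- .acc(NULL, bw)
  gfinal <- bw$gx
  bw <- cpp_conv2d_bw(final, params$head.dist$w, gdist_pre, 1L)
  grads[["head.dist"]] <- .acc(NULL, bw)
  gfinal <- gfinal + bw$gx
  L <- cfg$n_levels
  gskips <- vector("list", L)
  gcur <- gfinal
  for (l in seq_len(L)) {
    dc <- cache$dec[[l]]
    gd2 <- gcur * (dc$d2 > 0)
    bw <- cpp_conv2d_bw(dc$d1, params[[sprintf("dec%d.c2", l)]]$w, gd2, 1L)
    grads[[sprintf("dec%d.c2", l)]] <- .acc(grads[[sprintf("dec%d.c2", l)]], bw)
    gd1 <- bw$gx * (dc$d1 > 0)
    bw <- cpp_conv2d_bw(dc$cat, params[[sprintf("dec%d.c1", l)]]$w, gd1, 1L)
    grads[[sprintf("dec%d.c1", l)]] <- .acc(grads[[sprintf("dec%d.c1", l)]], bw)
    cup <- dim(dc$up)[3]
    gup <- bw$gx[, , seq_len(cup), drop = FALSE]
    gskips[[l]] <- bw$gx[, , cup + seq_len(dim(bw$gx)[3] - cup), drop = FALSE]
    gcur <- cpp_upsample2_bw(gup)
  }
  if (cfg$use_aspp) {
    ac <- cache$aspp
    gam <- gcur * (ac$am > 0)
    bw <- cpp_conv2d_bw(ac$zc, params$aspp.merge$w, gam, 1L)
    grads[["aspp.merge"]] <- .acc(NULL, bw)
    gzc <- bw$gx
    gbott <- 0
    off <- 0L
    cb <- dim(ac$zs[[1]])[3]
    for (k in seq_along(cfg$aspp_rates)) {
      gz <- gzc[, , off + seq_len(cb), drop = FALSE] * (ac$zs[[k]] > 0)
      bw <- cpp_conv2d_bw(cache$bott, params[[sprintf("aspp.r%d", k)]]$w, gz,
                          as.integer(cfg$aspp_rates[k]))
      grads[[sprintf("aspp.r%d", k)]] <- .acc(NULL, bw)
      gbott <- gbott + bw$gx
      off <- off + cb
    }
  } else {
    gbott <- gcur
  }
  gbott <- gbott * (cache$bott > 0)
  bw <- cpp_conv2d_bw(cache$b1, params$bott.c2$w, gbott, 1L)
  grads[["bott.c2"]] <- .acc(NULL, bw)
  gb1 <- bw$gx * (cache$b1 > 0)
  bw <- cpp_conv2d_bw(cache$bott_in, params$bott.c1$w, gb1, 1L)
  grads[["bott.c1"]] <- .acc(NULL, bw)
  gpool <- bw$gx
  for (l in rev(seq_len(L))) {
    d <- dim(cache$skips[[l]])
    gout <- cpp_maxpool2_bw(gpool, cache$pools[[l]]$idx, d[1], d[2], d[3]) +
      gskips[[l]]
    rb <- .rae_bw(gout, cache$caches[[l]], params, sprintf("enc%d", l), cfg,
                  grads)
    grads <- rb$grads
    gpool <- rb$gx
  }
  grads
}

#' Save and load checkpoints
#'
#' Parameters and their configuration are serialized together with
#' `saveRDS`.
#'
#' @param params `spc_params` object.
#' @param path file path (conventionally `.rds`).
#' @export
spc_save <- function(params, path) {
  saveRDS(list(params = unclass(params), config = attr(params, "config")),
          path)
  invisible(path)
}

#' @rdname spc_save
#' @export
spc_load <- function(path) {
  x <- readRDS(path)
  structure(x$params, class = "spc_params", config = x$config)
}
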