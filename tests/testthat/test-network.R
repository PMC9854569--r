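test_that("FFA attention obeys its formula and ranges", {
  set.seed(1)
  C <- 4
  fe <- array(rnorm(8 * 8 * C), c(8, 8, C))
  fo <- array(rnorm(8 * 8 * C), c(8, 8, C))
  pr <- list(we = list(w = array(rnorm(C * C), c(1, 1, C, C)), b = NULL),
             wo = list(w = array(rnorm(C * C), c(1, 1, C, C)), b = rnorm(C)),
             phi = list(w = array(rnorm(C), c(1, 1, C, 1)), b = 0.3))
  out <- ffa_attention(fe, fo, pr)
  expect_true(all(out$wa > 0 & out$wa < 1))
  expect_equal(dim(out$wa), c(8, 8, 1))
  expect_equal(out$fa, fe * as.vector(out$wa))
  # zero weights and zero bphi force Wa = 0.5 exactly
  pr0 <- list(we = list(w = array(0, c(1, 1, C, C)), b = NULL),
              wo = list(w = array(0, c(1, 1, C, C)), b = rep(0, C)),
              phi = list(w = array(0, c(1, 1, C, 1)), b = 0))
  out0 <- ffa_attention(fe, fo, pr0)
  expect_equal(as.vector(out0$wa), rep(0.5, 64))
  expect_equal(out0$fa, 0.5 * fe)
  # saturation: huge psi drives Wa to 1, Fa to Fe
  prs <- pr0; prs$phi$b <- 50
  expect_equal(ffa_attention(fe, fo, prs)$fa, fe, tolerance = 1e-12)
  expect_error(ffa_attention(fe, array(0, c(4, 4, C)), pr), "spatial size")
})

test_that("encoder block variants reduce as specified", {
  # TCB has no shallow branch, attention, or shortcut parameters
  p_tcb <- spc_init(spc_network(base_channels = 4, encoder_variant = "TCB"), 1)
  expect_false(any(grepl("ffa|fo|proj", names(p_tcb))))
  # with all conv weights zero and an identity shortcut, output == x
  cfg <- spc_network(n_rays = 4, base_channels = 1,
                     encoder_variant = "TCB+RC")
  pp <- spc_init(cfg, 1)
  pp[["enc1.fe1"]]$w[] <- 0; pp[["enc1.fe1"]]$b[] <- 0
  pp[["enc1.fe2"]]$w[] <- 0; pp[["enc1.fe2"]]$b[] <- 0
  x <- array(runif(16 * 16), c(16, 16, 1))
  cc <- starseg:::.rae_fw(x, x, pp, "enc1", cfg)
  expect_equal(cc$out, x)
  # spatial size is preserved by every variant
  for (v in c("TCB", "TCB+RC", "TCB+FFA", "RAE")) {
    cfgv <- spc_network(base_channels = 2, encoder_variant = v)
    pv <- spc_init(cfgv, 1)
    ccv <- starseg:::.rae_fw(x, x, pv, "enc1", cfgv)
    expect_equal(dim(ccv$out)[1:2], c(16, 16))
  }
})

test_that("parameter counts grow across the ablation variants", {
  n <- vapply(c("TCB", "TCB+RC", "TCB+FFA", "RAE"), function(v)
    spc_num_params(spc_init(spc_network(base_channels = 4,
                                        encoder_variant = v), 1)), 0)
  expect_lt(n["TCB"], n["TCB+RC"])
  expect_lte(n["TCB+RC"], n["TCB+FFA"])
  expect_lt(n["TCB+FFA"], n["RAE"])
})

test_that("forward pass honors the output contract", {
  net <- spc_network(n_rays = 8, base_channels = 2)
  params <- spc_init(net, 3)
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- spc_forward(img, params)
  expect_equal(dim(fw$prob), c(64, 64))
  expect_equal(dim(fw$dist), c(64, 64, 8))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  expect_true(all(fw$dist >= 0))
  # arbitrary (non divisible-by-8) sizes are padded and cropped back
  img2 <- matrix(runif(40 * 22), 40, 22)
  fw2 <- spc_forward(img2, params)
  expect_equal(dim(fw2$prob), c(40, 22))
  expect_equal(dim(fw2$dist), c(40, 22, 8))
  expect_error(spc_forward(matrix(numeric(0), 0, 0), params), "zero-sized")
  # determinism
  expect_identical(spc_forward(img, params)$prob, fw$prob)
})

test_that("network is translation covariant away from boundaries", {
  net <- spc_network(n_rays = 4, base_channels = 2,
                     encoder_variant = "TCB", use_aspp = FALSE)
  params <- spc_init(net, 5)
  set.seed(9)
  base <- matrix(runif(200 * 200), 200, 200)
  a <- spc_forward(base[1:160, 1:160], params)
  b <- spc_forward(base[9:168, 9:168], params)  # 8 px shift
  interior <- 72:88
  expect_equal(a$prob[interior + 8, interior + 8], b$prob[interior, interior],
               tolerance = 1e-4)
})

test_that("backward pass matches finite differences", {
  set.seed(4)
  net <- spc_network(n_rays = 4, base_channels = 2,
                     encoder_variant = "RAE", use_aspp = TRUE,
                     aspp_rates = c(1, 2))
  params <- spc_init(net, 2)
  img <- matrix(runif(16 * 16), 16, 16)
  lab <- matrix(0L, 16, 16); lab[4:9, 5:12] <- 1L
  enc <- encode_targets(lab, 4)
  lossf <- function(p) {
    fw <- spc_forward(img, p)
    total_loss(fw$prob, enc$prob, fw$dist, enc$dist)
  }
  fw <- spc_forward(img, params, keep_cache = TRUE)
  N <- 256
  gp <- array((fw$prob - enc$prob) * 0.5 / N, c(16, 16, 1))
  gd <- sign(fw$dist - enc$dist) * as.vector(enc$prob) / N
  gd[fw$dist <= 0] <- 0
  gr <- starseg:::spc_backward(params, fw$cache, gp, gd)
  e <- 1e-5
  for (nm in c("enc1.fe1", "enc2.ffa.phi", "enc1.proj", "aspp.merge",
               "dec1.c2", "head.dist")) {
    i <- min(2, length(params[[nm]]$w))
    p1 <- params; p1[[nm]]$w[i] <- p1[[nm]]$w[i] + e
    p2 <- params; p2[[nm]]$w[i] <- p2[[nm]]$w[i] - e
    num <- (lossf(p1) - lossf(p2)) / (2 * e)
    expect_equal(gr[[nm]]$gw[i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("checkpoints round-trip through save/load", {
  net <- spc_network(n_rays = 4, base_channels = 2)
  params <- spc_init(net, 7)
  f <- tempfile(fileext = ".rds")
  spc_save(params, f)
  back <- spc_load(f)
  expect_equal(unclass(back), unclass(params))
  cfg <- attr(back, "config")
  expect_equal(cfg$n_rays, 4L)
  img <- matrix(runif(16 * 16), 16, 16)
  expect_identical(spc_forward(img, params)$prob, spc_forward(img, back)$prob)
})
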