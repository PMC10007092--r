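tiny_cfg <- function(...) {
  sswan_config(num_blocks = 2L, width = 8L, reduction = 4L,
               num_classes = 2L, seed = 3L, ...)
}

test_that("shallow extraction follows its closed forms and the conv oracle", {
  cs <- dwt2(matrix(rnorm(32 * 32), 32))
  w <- 8L
  zp <- list(W = array(0, c(5, 5, 4, w)), b = numeric(w))
  expect_equal(shallow_extract(cs, zp), array(0, c(16, 16, w)))
  # zero coefficients -> leaky(bias) broadcast
  zc <- coeff_stack(matrix(0, 8, 8), matrix(0, 8, 8), matrix(0, 8, 8),
                    matrix(0, 8, 8))
  bp <- list(W = array(0, c(5, 5, 4, 2)), b = c(1.5, -2))
  out <- shallow_extract(zc, bp, alpha = 0.2)
  expect_equal(out[, , 1], matrix(1.5, 8, 8))
  expect_equal(out[, , 2], matrix(-0.4, 8, 8))
  # random case against the sliding-window oracle
  set.seed(44)
  cs2 <- dwt2(matrix(rnorm(16 * 16), 16))
  rp <- list(W = array(rnorm(5 * 5 * 4 * w, 0, 0.1), c(5, 5, 4, w)),
             b = rnorm(w, 0, 0.1))
  stacked <- array(0, c(8, 8, 4))
  stacked[, , 1] <- cs2$ll; stacked[, , 2] <- cs2$lh
  stacked[, , 3] <- cs2$hl; stacked[, , 4] <- cs2$hh
  or <- conv2d_oracle(stacked, rp$W, rp$b)
  or <- ifelse(or > 0, or, 0.2 * or)
  expect_equal(shallow_extract(cs2, rp, alpha = 0.2), or, tolerance = 1e-10)
})

test_that("the trunk collapses to the zero stack when all weights are zero", {
  cfg <- tiny_cfg()
  params <- sswan_init(cfg)
  for (nm in names(params)) params[[nm]][] <- 0
  i0 <- random_feat(8, 8, cfg$width, seed = 5)
  ic <- forward_trunk(i0, params, cfg)
  expect_s3_class(ic, "coeff_stack")
  expect_equal(max(abs(unlist(ic[c("ll", "lh", "hl", "hh")]))), 0)
})

test_that("concatenated width is w*T and the trunk composes oracled blocks", {
  for (T in c(1L, 2L, 4L)) {
    cfg <- sswan_config(num_blocks = T, width = 8L, reduction = 4L, seed = 1L)
    params <- sswan_init(cfg)
    expect_identical(dim(params[["fuse1.W"]])[3], 8L * T)
    i0 <- random_feat(6, 6, 8, seed = T)
    ic <- forward_trunk(i0, params, cfg)
    expect_identical(dim(ic$ll), c(6L, 6L))
  }
  # T = 1: trunk output equals hand-composed block + fusion convs
  cfg1 <- sswan_config(num_blocks = 1L, width = 8L, reduction = 4L, seed = 7L)
  p <- sswan_init(cfg1)
  i0 <- random_feat(6, 6, 8, seed = 9)
  b1 <- ssab_block(i0,
                   list(W = p[["block1.conv.W"]], b = p[["block1.conv.b"]]),
                   list(W1 = p[["block1.ch.W1"]], b1 = p[["block1.ch.b1"]],
                        W2 = p[["block1.ch.W2"]], b2 = p[["block1.ch.b2"]]),
                   list(W = p[["block1.sp.W"]], b = p[["block1.sp.b"]]),
                   alpha = cfg1$leaky_slope)
  z <- conv2d_oracle(b1, p[["fuse1.W"]], p[["fuse1.b"]])
  z <- ifelse(z > 0, z, cfg1$leaky_slope * z)
  ic_or <- conv2d_oracle(z, p[["fuse2.W"]], p[["fuse2.b"]])
  ic <- forward_trunk(i0, p, cfg1)
  expect_equal(ic$ll, ic_or[, , 1], tolerance = 1e-8)
  expect_equal(ic$hh, ic_or[, , 4], tolerance = 1e-8)
})

test_that("global residual reconstruction inverts the residual target", {
  base <- matrix(rnorm(32 * 32), 32)
  zero_ic <- coeff_stack(matrix(0, 16, 16), matrix(0, 16, 16),
                         matrix(0, 16, 16), matrix(0, 16, 16))
  expect_equal(reconstruct(zero_ic, base), base)
  full <- base + matrix(rnorm(32 * 32, 0, 0.3), 32)
  ic <- residual_target(full, base)
  expect_lt(max(abs(reconstruct(ic, base) - full)), 1e-6)
  set.seed(2)
  rnd <- coeff_stack(matrix(rnorm(64), 8), matrix(rnorm(64), 8),
                     matrix(rnorm(64), 8), matrix(rnorm(64), 8))
  expect_equal(reconstruct(rnd, matrix(0, 16, 16)), idwt2(rnd))
  expect_error(reconstruct(rnd, matrix(0, 8, 8)), "does not match")
})

test_that("segment emits a probability simplex, labels, and a reconstruction", {
  cfg <- tiny_cfg()
  params <- sswan_init(cfg)
  img <- generate_phantom(phantom_config(seed = 4))$image
  seg <- segment(img, params, cfg)
  expect_identical(dim(seg$class_probs), c(64L, 64L, 2L))
  expect_lt(max(abs(apply(seg$class_probs, c(1, 2), sum) - 1)), 1e-6)
  expect_true(all(seg$label_map %in% 0:1))
  expect_identical(dim(seg$reconstructed), dim(img))
  # zero head weights -> uniform probabilities 1/L per pixel
  p0 <- params
  p0[["head.W"]][] <- 0
  p0[["head.b"]][] <- 0
  seg0 <- segment(img, p0, cfg)
  expect_equal(max(abs(seg0$class_probs - 0.5)), 0, tolerance = 1e-12)
})

test_that("parameter counts are exact and monotone in depth and width", {
  cfg <- sswan_config(num_blocks = 1L, width = 8L, reduction = 4L,
                      num_classes = 2L)
  # hand enumeration: shallow 808; block 593+44+99; fuse1 4616; fuse2 292; head 18
  shallow <- 5 * 5 * 4 * 8 + 8
  block <- (9 * 64 + 8) + (8 * 2 + 2 + 2 * 8 + 8) + (7 * 7 * 2 + 1)
  fuse <- (9 * 8 * 8 + 8) + (9 * 8 * 4 + 4)
  head <- 8 * 2 + 2
  expect_identical(count_parameters(cfg), as.integer(shallow + block + fuse + head))
  # counts agree with the actual parameter arrays
  expect_identical(count_parameters(cfg),
                   as.integer(sum(sapply(sswan_init(cfg), length))))
  expect_lt(count_parameters(cfg),
            count_parameters(sswan_config(num_blocks = 2L, width = 8L,
                                          reduction = 4L)))
  expect_lt(count_parameters(cfg),
            count_parameters(sswan_config(num_blocks = 1L, width = 16L,
                                          reduction = 4L)))
})

test_that("initialization and short training runs are deterministic", {
  cfg <- tiny_cfg()
  expect_identical(sswan_init(cfg), sswan_init(cfg))
  samples <- generate_dataset(2, phantom_config(size = c(32, 32), seed = 0),
                              base_seed = 0)
  f1 <- sswan_train(samples, cfg, epochs = 5)
  f2 <- sswan_train(samples, cfg, epochs = 5)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
  expect_equal(nrow(f1$history), 5L)
})

test_that("every parameter group receives gradient after one step", {
  cfg <- tiny_cfg()
  samples <- generate_dataset(1, phantom_config(size = c(32, 32), seed = 1),
                              base_seed = 1)
  batch <- sswan:::.sswan_batch(samples, cfg)
  params <- sswan_init(cfg)
  res <- sswan:::.sswan_loss_and_grads(params, batch, cfg)
  for (nm in names(params)) {
    expect_true(any(res$grads[[nm]] != 0), info = nm)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- sswan_config(num_blocks = 1L, width = 4L, reduction = 2L,
                      num_classes = 2L, seed = 8L)
  samples <- generate_dataset(1, phantom_config(size = c(16, 16), seed = 2),
                              base_seed = 2)
  batch <- sswan:::.sswan_batch(samples, cfg)
  params <- sswan_init(cfg)
  res <- sswan:::.sswan_loss_and_grads(params, batch, cfg)
  f <- function(p) sswan:::.sswan_loss_and_grads(p, batch, cfg,
                                                 want_grads = FALSE)$loss
  set.seed(99)
  h <- 1e-5
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(2L, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      numeric_grad <- (f(pp) - f(pm)) / (2 * h)
      expect_equal(res$grads[[nm]][i], numeric_grad, tolerance = 1e-3,
                   info = paste(nm, i))
    }
  }
})

test_that("residual identity: zeroed final fusion conv returns the baseline", {
  cfg <- tiny_cfg()
  params <- sswan_init(cfg)
  params[["fuse2.W"]][] <- 0
  params[["fuse2.b"]][] <- 0
  img <- generate_phantom(phantom_config(seed = 12))$image
  prep <- sswan:::.prep_sample(img, cfg)
  seg <- segment(img, params, cfg)
  # reconstruction equals the (de-normalized) bicubic baseline exactly
  expected <- prep$bic * prep$sd + prep$mu
  expect_equal(seg$reconstructed, expected, tolerance = 1e-12)
})

test_that("checkpoints round-trip parameters and config through JSON", {
  cfg <- tiny_cfg()
  params <- sswan_init(cfg)
  tmp <- tempfile(fileext = ".json")
  save_checkpoint(list(params = params, config = cfg), tmp)
  back <- load_checkpoint(tmp)
  expect_equal(back$params, params, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$config$width, cfg$width)
  expect_identical(back$config$num_blocks, cfg$num_blocks)
  img <- generate_phantom(phantom_config(seed = 6))$image
  s1 <- segment(img, params, cfg)
  s2 <- segment(img, back$params, back$config)
  expect_equal(s1$class_probs, s2$class_probs, tolerance = 1e-10)
  expect_error(load_checkpoint(tempfile()), "not found")
})
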