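test_that("zero-weight closed forms hold for both attention gates", {
  f <- random_feat(8, 8, 4, seed = 21)
  ch0 <- zero_ch_params(channel_attention_params(4, 2, seed = 1))
  sp0 <- zero_sp_params(spatial_attention_params(seed = 1))
  expect_equal(channel_descriptor(f, ch0), rep(0.5, 4))
  expect_equal(channel_attention(f, ch0), 0.5 * f, tolerance = 1e-12)
  expect_equal(spatial_descriptor(f, sp0), matrix(0.5, 8, 8))
  expect_equal(spatial_attention(f, sp0), 0.5 * f, tolerance = 1e-12)
})

test_that("constant feature maps collapse the two pooled paths", {
  ch <- channel_attention_params(4, 2, seed = 2)
  f <- array(rep(c(1, -2, 0.5, 3), each = 36), c(6, 6, 4))
  # max-pool path equals avg-pool path, so descriptor = sigmoid(2 * MLP(p))
  p <- c(1, -2, 0.5, 3)
  leaky <- function(z) ifelse(z > 0, z, 0.2 * z)
  mlp <- as.vector(t(ch$W2) %*% leaky(t(ch$W1) %*% p + ch$b1)) + ch$b2
  expect_equal(channel_descriptor(f, ch), 1 / (1 + exp(-2 * mlp)),
               tolerance = 1e-12)
  # spatially uniform input: away from the zero-padded border the
  # descriptor is the closed form sigmoid(const * sum(kernel) + bias)
  sp <- spatial_attention_params(seed = 2)
  f1 <- array(1.7, c(14, 14, 1))
  d <- spatial_descriptor(f1, sp)
  expected <- 1 / (1 + exp(-(1.7 * sum(sp$W) + sp$b)))
  expect_equal(d[4:11, 4:11], matrix(expected, 8, 8), tolerance = 1e-12)
})

test_that("descriptors lie strictly in (0,1) and match loop oracles", {
  for (i in 1:10) {
    f <- random_feat(8, 8, 4, seed = 100 + i)
    ch <- channel_attention_params(4, 4, seed = 200 + i)
    sp <- spatial_attention_params(seed = 300 + i)
    dch <- channel_descriptor(f, ch, alpha = 0.1)
    dsp <- spatial_descriptor(f, sp)
    expect_true(all(dch > 0 & dch < 1))
    expect_true(all(dsp > 0 & dsp < 1))
    expect_equal(dch, channel_descriptor_oracle(f, ch, alpha = 0.1),
                 tolerance = 1e-10)
    expect_equal(dsp, spatial_descriptor_oracle(f, sp), tolerance = 1e-10)
    expect_equal(channel_attention(f, ch, alpha = 0.1),
                 f * rep(channel_descriptor_oracle(f, ch, 0.1), each = 64),
                 tolerance = 1e-10)
    expect_equal(spatial_attention(f, sp),
                 f * array(spatial_descriptor_oracle(f, sp), c(8, 8, 4)),
                 tolerance = 1e-10)
  }
})

test_that("the shared MLP makes the descriptor symmetric in its two pooled inputs", {
  # The sum in the gate is commutative: swapping which pooled vector feeds
  # which (identical, shared) MLP cannot change the result.
  for (i in 1:5) {
    f <- random_feat(6, 6, 8, seed = 400 + i)
    ch <- channel_attention_params(8, 4, seed = 500 + i)
    pmax_v <- apply(f, 3, max)
    pavg_v <- apply(f, 3, mean)
    leaky <- function(z) ifelse(z > 0, z, 0.2 * z)
    mlp <- function(p) as.vector(t(ch$W2) %*% leaky(t(ch$W1) %*% p + ch$b1)) + ch$b2
    swapped <- 1 / (1 + exp(-(mlp(pavg_v) + mlp(pmax_v))))
    expect_equal(channel_descriptor(f, ch), swapped, tolerance = 1e-12)
  }
})

test_that("ssab_block obeys its closed forms and composes its parts", {
  f <- random_feat(8, 8, 4, seed = 31)
  bp <- ssab_params(4, 2, seed = 3)
  # all weights zero -> identity
  z <- zero_ssab_params(bp)
  expect_equal(ssab_block(f, z$conv, z$ch, z$sp), f, tolerance = 1e-12)
  # identity conv + zero attention -> 1.25 * input
  idp <- identity_conv(z)
  expect_equal(ssab_block(f, idp$conv, idp$ch, idp$sp), 1.25 * f,
               tolerance = 1e-12)
  # random block equals the explicit composition of sub-operations
  conv_or <- conv2d_oracle(f, bp$conv$W, bp$conv$b)
  ch_or <- conv_or * rep(channel_descriptor_oracle(conv_or, bp$ch, 0.2), each = 64)
  sp_or <- ch_or * array(spatial_descriptor_oracle(ch_or, bp$sp), c(8, 8, 4))
  expect_equal(ssab_block(f, bp$conv, bp$ch, bp$sp), sp_or + f,
               tolerance = 1e-8)
})

test_that("attention operations preserve shape and validate widths", {
  for (dims in list(c(4, 6, 4), c(9, 5, 8), c(16, 16, 16))) {
    f <- random_feat(dims[1], dims[2], dims[3], seed = sum(dims))
    ch <- channel_attention_params(dims[3], 4, seed = 1)
    sp <- spatial_attention_params(seed = 1)
    expect_identical(dim(channel_attention(f, ch)), dim(f))
    expect_identical(dim(spatial_attention(f, sp)), dim(f))
  }
  f <- random_feat(4, 4, 4, seed = 2)
  ch8 <- channel_attention_params(8, 4, seed = 1)
  expect_error(channel_attention(f, ch8), "width")
  expect_error(channel_attention_params(6, 4), "divisible")
  bp <- ssab_params(8, 4, seed = 1)
  expect_error(ssab_block(f, bp$conv, bp$ch, bp$sp), "width|preserve")
})
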