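# Structural fidelity of the translation networks: exact layer sequences,
# kernel/stride/padding values, activation types, shape preservation, output
# range, conditioning, and an independent parameter-count oracle.

expected_generator_layers <- function(cin) list(
  # type, cin, cout, k, s, p, op (NA where not applicable)
  c("conv",  cin, 64, 7, 1, 3, NA), c("inorm", 64), c("relu"),
  c("conv",   64, 128, 3, 2, 1, NA), c("inorm", 128), c("relu"),
  c("conv",  128, 256, 3, 2, 1, NA), c("inorm", 256), c("relu"),
  c("conv",  256, 256, 3, 1, 1, NA), c("inorm", 256), c("relu"),
  c("conv",  256, 256, 3, 1, 1, NA), c("inorm", 256),
  c("convt", 256, 128, 3, 2, 1, 1), c("inorm", 128), c("relu"),
  c("convt", 128, 64, 3, 2, 1, 1), c("inorm", 64), c("relu"),
  c("conv",   64, 3, 7, 1, 3, NA), c("tanh")
)

expected_discriminator_layers <- function() list(
  c("conv",   3, 64, 7, 1, 3, NA), c("lrelu", 0.2),
  c("conv",  64, 128, 3, 2, 1, NA), c("inorm", 128), c("lrelu", 0.2),
  c("conv", 128, 256, 3, 2, 1, NA), c("inorm", 256), c("lrelu", 0.2),
  c("conv", 256, 512, 3, 2, 1, NA), c("inorm", 512), c("lrelu", 0.2),
  c("conv", 512, 1, 4, 1, 1, NA),
  c("gap")
)

check_layers <- function(net, expected) {
  expect_length(net$layers, length(expected))
  for (i in seq_along(expected)) {
    e <- expected[[i]]; l <- net$layers[[i]]
    expect_equal(l$type, e[1], label = sprintf("layer %d type", i))
    if (e[1] %in% c("conv", "convt")) {
      expect_equal(c(l$cin, l$cout, l$k, l$s, l$p),
                   as.integer(e[2:6]), label = sprintf("layer %d conv spec", i))
      if (e[1] == "convt") expect_equal(l$op, as.integer(e[7]))
    }
    if (e[1] == "inorm") expect_equal(l$channels, as.integer(e[2]))
    if (e[1] == "lrelu") expect_equal(l$alpha, as.numeric(e[2]))
  }
}

test_that("generator layer sequence matches the printed configuration exactly", {
  check_layers(build_generator(conditioned = FALSE)$net, expected_generator_layers(3))
  check_layers(build_generator(conditioned = TRUE)$net, expected_generator_layers(4))
})

test_that("discriminator layer sequence matches the printed configuration exactly", {
  check_layers(build_discriminator()$net, expected_discriminator_layers())
})

test_that("parameter counts match an independent hand computation", {
  # oracle computed straight from the layer lists: k*k*cin*cout + cout each
  count_from_spec <- function(spec) {
    sum(vapply(spec, function(e) {
      if (e[1] %in% c("conv", "convt")) {
        cin <- as.numeric(e[2]); cout <- as.numeric(e[3]); k <- as.numeric(e[4])
        k * k * cin * cout + cout
      } else 0
    }, numeric(1)))
  }
  expect_identical(parameter_count(build_generator(conditioned = FALSE)),
                   count_from_spec(expected_generator_layers(3)))
  expect_identical(parameter_count(build_generator(conditioned = TRUE)),
                   count_from_spec(expected_generator_layers(4)))
  expect_identical(parameter_count(build_discriminator()),
                   count_from_spec(expected_discriminator_layers()))
})

test_that("generator preserves 224x224 spatial size and emits 3 channels", {
  gen <- build_generator(conditioned = FALSE, width_multiplier = 0.25)
  x <- array(stats::runif(224 * 224 * 3, -1, 1), c(224, 224, 3, 1))
  y <- sc$generator_forward(gen, x, cache = FALSE)$out
  expect_equal(dim(y), c(224, 224, 3, 1))
  # conditioned 4-channel input at 64x64, full width
  gen4 <- build_generator(conditioned = TRUE, width_multiplier = 1.0)
  x4 <- condition_patch(array(stats::runif(64 * 64 * 3, -1, 1), c(64, 64, 3, 1)), "TUMOR")
  y4 <- sc$generator_forward(gen4, x4, cache = FALSE)$out
  expect_equal(dim(y4), c(64, 64, 3, 1))
  expect_true(all(y4 >= -1 & y4 <= 1))   # tanh output range
})

test_that("discriminator pre-pool map is 27x27 at 224 input and output is scalar", {
  disc <- build_discriminator(width_multiplier = 0.25)
  pre_pool <- sc$new_net(disc$net$layers[seq_len(length(disc$net$layers) - 1L)])
  x <- array(stats::runif(224 * 224 * 3, -1, 1), c(224, 224, 3, 1))
  m <- sc$net_forward(pre_pool, x, cache = FALSE)$out
  expect_equal(dim(m), c(27, 27, 1, 1))
  # 64 input: 64 -> 32 -> 16 -> 8 -> (8 + 2 - 4)/1 + 1 = 7
  disc_full <- build_discriminator(width_multiplier = 1.0)
  pre_full <- sc$new_net(disc_full$net$layers[seq_len(length(disc_full$net$layers) - 1L)])
  x64 <- array(stats::runif(64 * 64 * 3 * 3, -1, 1), c(64, 64, 3, 3))
  m64 <- sc$net_forward(pre_full, x64, cache = FALSE)$out
  expect_equal(dim(m64), c(7, 7, 1, 3))
  scores <- sc$net_forward(disc_full$net, x64, cache = FALSE)$out
  expect_equal(dim(scores), c(3L, 1L))   # one scalar per image
})

test_that("generator output stays within [-1, 1] for arbitrary inputs", {
  gen <- build_generator(conditioned = FALSE, width_multiplier = 0.25)
  for (scale in c(1, 50)) {
    x <- array(stats::rnorm(32 * 32 * 3 * 2, sd = scale), c(32, 32, 3, 2))
    y <- sc$generator_forward(gen, x, cache = FALSE)$out
    expect_true(all(y >= -1 & y <= 1))
  }
})

test_that("conditioning appends a constant +/-1 plane and strips back exactly", {
  x <- array(stats::runif(16 * 16 * 3 * 2, -1, 1), c(16, 16, 3, 2))
  ct <- condition_patch(x, c("TUMOR", "NORMAL"))
  expect_equal(dim(ct), c(16, 16, 4, 2))
  expect_true(all(ct[, , 4, 1] == 1))
  expect_true(all(ct[, , 4, 2] == -1))
  expect_identical(strip_label_channel(ct), x)
  expect_error(condition_patch(x, "MAYBE"), "unknown label")
})

test_that("pixel normalisation round-trips within quantisation error", {
  x <- array(sample(0:255, 300, replace = TRUE), c(10, 10, 3))
  expect_equal(denormalize_pixels(normalize_pixels(x)), x, tolerance = 1e-12)
  expect_true(all(normalize_pixels(x) >= -1 & normalize_pixels(x) <= 1))
})
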