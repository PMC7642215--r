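# Adversarial training machinery: closed-form loss values, oracle
# recomputation, no-op and determinism contracts, unpaired batch sampling,
# conditioning integrity, and full-image translation plumbing.

logit <- function(p) log(p / (1 - p))

test_that("discriminator BCE matches closed forms and an independent oracle", {
  # sigmoid(score) = 0.5 on both sides: ln 2 per term
  s <- logit(0.5)
  expect_equal(discriminator_loss(rep(s, 4), rep(s, 4)), log(2), tolerance = 1e-6)
  # perfect discrimination limit: loss ~ 0
  expect_equal(discriminator_loss(rep(40, 3), rep(-40, 3)), 0, tolerance = 1e-6)
  # arbitrary scores match an elementwise recomputation
  set.seed(31)
  r <- rnorm(7); f <- rnorm(5)
  oracle <- 0.5 * (mean(-log(1 / (1 + exp(-r)))) + mean(-log(1 - 1 / (1 + exp(-f)))))
  expect_equal(discriminator_loss(r, f), oracle, tolerance = 1e-12)
  expect_error(discriminator_loss(c(1, NaN), c(0)), "non-finite")
})

test_that("generator least-squares loss matches closed forms", {
  expect_equal(generator_adv_loss(rep(1, 5)), 0, tolerance = 1e-12)
  expect_equal(generator_adv_loss(rep(0, 5)), 1, tolerance = 1e-12)
  set.seed(32)
  s <- rnorm(9)
  expect_equal(generator_adv_loss(s), mean((s - 1)^2), tolerance = 1e-12)
})

test_that("cycle loss is zero at identity, |delta| under constant offset", {
  set.seed(33)
  x <- array(runif(4 * 4 * 3 * 2, -1, 1), c(4, 4, 3, 2))
  expect_equal(cycle_loss(x, x), 0)
  expect_equal(cycle_loss(x, x + 0.37), 0.37, tolerance = 1e-12)
  expect_equal(cycle_loss(x, x - 0.2, type = "L2"), 0.04, tolerance = 1e-12)
  expect_error(cycle_loss(x, x[, , , 1, drop = FALSE]), "shape")
  expect_gte(cycle_loss(x, x + rnorm(length(x))), 0)
})

test_that("epochs = 0 returns an initialised, untrained state", {
  pool <- array(runif(16 * 16 * 3 * 10, 0, 255), c(16, 16, 3, 10))
  cfg <- gan_config(epochs = 0, batch_size = 2, conditioned = FALSE,
                    width_multiplier = 0.1, seed = 3)
  fit <- train_cyclegan(pool, pool, config = cfg)
  expect_s3_class(fit, "cyclegan_fit")
  expect_equal(nrow(fit$loss_history), 0L)
  expect_equal(nrow(fit$epoch_history), 0L)
  # weights equal a fresh seeded build
  ref <- sc$with_seed(3, build_generator(FALSE, 0.1))
  expect_identical(fit$G_hk$net, ref$net)
})

test_that("two runs with one seed give identical loss histories", {
  set.seed(99)
  pool_a <- array(runif(16 * 16 * 3 * 12, 0, 255), c(16, 16, 3, 12))
  pool_b <- array(runif(16 * 16 * 3 * 12, 0, 255), c(16, 16, 3, 12))
  cfg <- gan_config(epochs = 2, steps_per_epoch = 3, batch_size = 2,
                    conditioned = FALSE, width_multiplier = 0.1, seed = 17)
  f1 <- train_cyclegan(pool_a, pool_b, config = cfg)
  f2 <- train_cyclegan(pool_a, pool_b, config = cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$G_hk$net, f2$G_hk$net)
  expect_true(all(is.finite(as.matrix(f1$loss_history[, -(1:2)]))))
})

test_that("HE and Ki-67 batches come from independent shuffles", {
  set.seed(7)
  pool_a <- array(runif(16 * 16 * 3 * 40, 0, 255), c(16, 16, 3, 40))
  pool_b <- array(runif(16 * 16 * 3 * 40, 0, 255), c(16, 16, 3, 40))
  cfg <- gan_config(epochs = 1, steps_per_epoch = 9, batch_size = 4,
                    conditioned = FALSE, width_multiplier = 0.1, seed = 23,
                    log_batch_indices = TRUE)
  fit <- train_cyclegan(pool_a, pool_b, config = cfg)
  he_seq <- unlist(lapply(fit$batch_log, `[[`, "he"))
  ki_seq <- unlist(lapply(fit$batch_log, `[[`, "ki"))
  expect_length(he_seq, 36L)
  # never the aligned pairing, and each shuffle is a permutation (no repeats
  # within one pass over the pool)
  expect_false(identical(he_seq, ki_seq))
  expect_false(any(duplicated(he_seq)))
  expect_false(any(duplicated(ki_seq)))
})

test_that("conditioned generator inputs always carry a constant label plane", {
  set.seed(8)
  pool <- array(runif(16 * 16 * 3 * 12, 0, 255), c(16, 16, 3, 12))
  cl <- patch_classifier(input_size = 16, seed = 1)
  seen <- new.env(); seen$n <- 0L
  cfg <- gan_config(epochs = 1, steps_per_epoch = 2, batch_size = 2,
                    conditioned = TRUE, width_multiplier = 0.1, seed = 5,
                    on_generator_input = function(x, tag) {
                      seen$n <- seen$n + 1L
                      stopifnot(dim(x)[3] == 4L)
                      planes <- apply(x[, , 4, , drop = FALSE], 4,
                                      function(p) length(unique(as.vector(p))))
                      stopifnot(all(planes == 1L),
                                all(x[, , 4, ] %in% c(-1, 1)))
                    })
  fit <- train_cyclegan(pool, pool, cl, cl, cfg)
  # 4 generator passes per step x 2 steps, plus validation passes
  expect_gte(seen$n, 8L)
  expect_error(train_cyclegan(pool, pool, NULL, NULL,
                              gan_config(conditioned = TRUE, epochs = 1,
                                         width_multiplier = 0.1)),
               "classifier")
})

test_that("an identity generator translates tiles back within 1/255", {
  pair <- render_slide_pair(slide_spec(width = 96, height = 96, n_cells = 20, seed = 4))
  identity_gen <- structure(list(net = sc$new_net(list()), conditioned = FALSE,
                                 width_multiplier = 1, residual = FALSE),
                            class = "sc_generator")
  out <- translate_image(pair$he, NULL, identity_gen, small_size = 32)
  expect_s3_class(out, "slide_image")
  expect_equal(out$domain, "KI67")
  expect_identical(dim(out$pixels), dim(pair$he$pixels))
  expect_true(max(abs(out$pixels - pair$he$pixels)) <= 1)
})

test_that("translation pads dropped borders back to the input size", {
  img <- array(runif(100 * 70 * 3, 0, 255), c(100, 70, 3))  # not tile multiples
  gen <- sc$with_seed(2, build_generator(FALSE, 0.1))
  out <- translate_image(img, NULL, gen, small_size = 32)
  expect_equal(dim(out$pixels), c(100, 70, 3))
  # uncovered border filled with the background colour
  pal <- stain_palette()
  expect_equal(unname(out$pixels[100, 70, ]), round(pal$background))
  expect_error(translate_image(img[1:20, 1:20, , drop = FALSE], NULL, gen, 32),
               "smaller")
})
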