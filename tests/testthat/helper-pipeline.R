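# The desk-scale study used by the acceptance tests: synthetic cohorts, MIL
# fits for both domains, and the toy conditional CycleGAN. Everything is
# memoised so the expensive stages run once per test session.

study_seed <- 20260928L

# MIL cohort geometry: 320 px bags on a 10 x 10 grid of 32 px instances;
# two training slides (20 bags each) and one validation slide per domain.
mil_slide_spec <- function(seed, w = 1600L, h = 1280L, n = 2800L) {
  slide_spec(width = w, height = h, tissue_fraction = 0.85, n_cells = n,
             tumor_region_fraction = 0.3, positive_fraction = 1.0, seed = seed)
}

mil_bags_for <- function(pair, domain) {
  build_bags(if (domain == "HE") pair$he else pair$ki67, pair$gt,
             large_size = 320L, small_size = 32L)
}

mil_slides <- function() fixture("mil_slides", list(
  train1 = render_slide_pair(mil_slide_spec(study_seed + 1L)),
  train2 = render_slide_pair(mil_slide_spec(study_seed + 2L)),
  val = render_slide_pair(mil_slide_spec(study_seed + 3L, w = 1280L, h = 960L,
                                         n = 1700L))
))

mil_fit_for <- function(domain) fixture(paste0("mil_fit_", domain), {
  sl <- mil_slides()
  bags_train <- c(mil_bags_for(sl$train1, domain), mil_bags_for(sl$train2, domain))
  bags_val <- mil_bags_for(sl$val, domain)
  train_mil(bags_train, bags_val, iterations = 10L, seed = study_seed,
            config = list(learning_rate = 3e-3, epochs_per_iteration = 6L,
                          batch_size = 8L))
})

# Translation cohort: 320 px slides tiled into 32 px patches, tumor region
# calibrated so the ground-truth positivity ratio is ~0.4 (all tumor nuclei
# positive: the class signal carried by the conditioning channel is the
# positivity signal).
gan_slide_spec <- function(seed) {
  slide_spec(width = 320L, height = 320L, tissue_fraction = 0.75,
             n_cells = 150L, tumor_region_fraction = 0.47,
             positive_fraction = 1.0, seed = seed)
}

gan_pools <- function() fixture("gan_pools", {
  he <- list(); ki <- list()
  for (i in 1:4) {
    p <- render_slide_pair(gan_slide_spec(study_seed + 10L + i))
    he <- c(he, tile_small_patches(p$he, 32L))
    ki <- c(ki, tile_small_patches(p$ki67, 32L))
  }
  list(he = he, ki = ki)
})

test_slides <- function() fixture("test_slides", lapply(1:3, function(i) {
  render_slide_pair(gan_slide_spec(study_seed + 30L + i))
}))

# 200-step toy fit (cycle-loss trend checks).
toy_gan_fit <- function() fixture("toy_gan_fit", {
  pools <- gan_pools()
  cfg <- gan_config(learning_rate = 1e-4, epochs = 1L, steps_per_epoch = 200L,
                    batch_size = 4L, cycle_weight = 10, seed = study_seed,
                    conditioned = TRUE, width_multiplier = 0.25)
  train_cyclegan(pools$he, pools$ki, mil_fit_for("HE"), mil_fit_for("KI67"), cfg)
})

# Longer toy fit used for end-to-end ratio recovery. The least-squares
# discriminator objective is used here: at quarter width the default BCE
# discriminator overpowers the generator (see the methods vignette).
e2e_gan_fit <- function() fixture("e2e_gan_fit", {
  pools <- gan_pools()
  cfg <- gan_config(learning_rate = 2e-4, epochs = 5L, steps_per_epoch = 200L,
                    batch_size = 4L, cycle_weight = 10, seed = study_seed,
                    conditioned = TRUE, width_multiplier = 0.25,
                    conditioned_discriminator = TRUE, symmetric_lsgan = TRUE)
  train_cyclegan(pools$he, pools$ki, mil_fit_for("HE"), mil_fit_for("KI67"), cfg)
})
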