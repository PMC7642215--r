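# Class-conditioned CycleGAN training: two generators (HE->Ki-67, Ki-67->HE)
# and two discriminators trained on independently sampled, unpaired patch
# batches. Discriminators minimise binary cross-entropy (real = 1, fake = 0);
# generators minimise least-squares adversarial loss toward the real target
# plus a weighted cycle-consistency penalty on the round-trip reconstruction.
# When conditioned, every generator input carries a constant class-label plane
# produced by the domain's MIL classifier; the reconstruction pass reuses the
# label of the source patch.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Discriminator loss: binary cross-entropy on sigmoid scores
#'
#' Real scores target 1, fake scores target 0; the two halves are averaged.
#'
#' @param real_scores,fake_scores raw (pre-sigmoid) discriminator outputs.
#' @return scalar loss.
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  if (!all(is.finite(real_scores)) || !all(is.finite(fake_scores)))
    stop("discriminator_loss: non-finite scores")
  0.5 * (mean(-log(pmax(sigmoid(real_scores), 1e-12))) +
           mean(-log(pmax(1 - sigmoid(fake_scores), 1e-12))))
}

#' Generator adversarial loss: mean squared error to the real target
#'
#' Least-squares form on raw discriminator scores of generated images,
#' target value 1.
#'
#' @param fake_scores raw discriminator outputs on generated images.
#' @return scalar loss.
#' @export
generator_adv_loss <- function(fake_scores) {
  if (!all(is.finite(fake_scores))) stop("generator_adv_loss: non-finite scores")
  mean((fake_scores - 1)^2)
}

#' Cycle-consistency loss between an image batch and its round trip
#'
#' @param original,reconstructed arrays of identical shape (3 pixel channels;
#'   label channels are never included).
#' @param type `"L1"` (mean absolute error, default) or `"L2"`.
#' @return scalar loss.
#' @export
cycle_loss <- function(original, reconstructed, type = c("L1", "L2")) {
  type <- match.arg(type)
  if (!identical(dim(original), dim(reconstructed)))
    stop("cycle_loss: shape mismatch")
  if (type == "L1") mean(abs(reconstructed - original))
  else mean((reconstructed - original)^2)
}

#' Configuration for CycleGAN training
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs; a checkpoint is recorded each epoch.
#' @param steps_per_epoch generator/discriminator update steps per epoch;
#'   default covers the smaller training pool once.
#' @param batch_size patches per domain per step.
#' @param cycle_weight weight of the cycle-consistency term (default 10).
#' @param d_lr_factor multiplier on the discriminator learning rate relative
#'   to the generator's (two-time-scale updates; 1 = same rate).
#' @param seed RNG seed for initialisation and batch shuffling.
#' @param conditioned label-channel conditioning of the generators (default
#'   TRUE).
#' @param conditioned_discriminator if TRUE the discriminators also receive
#'   the class-label plane (classic conditional-GAN practice), so a patch
#'   whose rendered class statistics contradict its label is directly
#'   detectable; requires `conditioned`. Default FALSE: discriminators see
#'   plain 3-channel images.
#' @param width_multiplier channel-width scale of generators/discriminators.
#' @param betas Adam moment decay rates.
#' @param cycle_type `"L1"` or `"L2"`.
#' @param symmetric_lsgan if TRUE the discriminators also use the
#'   least-squares objective instead of BCE.
#' @param val_fraction fraction of each pool held out to score epochs by
#'   validation cycle loss.
#' @param on_generator_input optional instrumentation hook
#'   `function(x, tag)` called with every generator input batch.
#' @param on_epoch_end optional callback `function(epoch, snapshot)` invoked
#'   after each epoch's validation pass with the current generators,
#'   classifiers and epoch history (e.g. to monitor translation quality).
#' @param log_batch_indices if TRUE the per-step sample indices of both
#'   domains are recorded in the fit.
#' @return list of class `gan_config`.
#' @export
gan_config <- function(learning_rate = 1e-4, epochs = 100L,
                       steps_per_epoch = NULL, batch_size = 4L,
                       cycle_weight = 10, d_lr_factor = 1.0, seed = 1L,
                       conditioned = TRUE, conditioned_discriminator = FALSE,
                       width_multiplier = 1.0, betas = c(0.5, 0.999),
                       cycle_type = "L1", symmetric_lsgan = FALSE,
                       val_fraction = 0.1, on_generator_input = NULL,
                       on_epoch_end = NULL, log_batch_indices = FALSE) {
  stopifnot(learning_rate > 0, cycle_weight >= 0, epochs >= 0, batch_size >= 1)
  if (conditioned_discriminator && !conditioned)
    stop("gan_config: conditioned_discriminator requires conditioned = TRUE")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 steps_per_epoch = steps_per_epoch,
                 batch_size = as.integer(batch_size),
                 cycle_weight = cycle_weight, d_lr_factor = d_lr_factor,
                 seed = as.integer(seed),
                 conditioned = conditioned,
                 conditioned_discriminator = conditioned_discriminator,
                 width_multiplier = width_multiplier, betas = betas,
                 cycle_type = cycle_type, symmetric_lsgan = symmetric_lsgan,
                 val_fraction = val_fraction,
                 on_generator_input = on_generator_input,
                 on_epoch_end = on_epoch_end,
                 log_batch_indices = log_batch_indices),
            class = "gan_config")
}

as_patch_pool <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  if (is.list(x)) return(patches_to_batch(x))
  stop("patch pool must be an (H, W, 3, N) array or a list of small patches")
}

# Discriminator gradient at its raw scores.
disc_score_grad <- function(real_scores, fake_scores, symmetric) {
  nr <- length(real_scores); nf <- length(fake_scores)
  if (symmetric) {
    list(real = (real_scores - 1) / nr, fake = fake_scores / nf,
         loss = 0.5 * (mean((real_scores - 1)^2) + mean(fake_scores^2)))
  } else {
    list(real = 0.5 * (sigmoid(real_scores) - 1) / nr,
         fake = 0.5 * sigmoid(fake_scores) / nf,
         loss = discriminator_loss(real_scores, fake_scores))
  }
}

#' Train the class-conditioned CycleGAN
#'
#' Each step draws one HE batch and one Ki-67 batch from independent shuffles
#' (aligned pairs are never presented together, matching the unpaired
#' consecutive-section setting); when conditioned, each real patch is
#' labelled by its domain's MIL classifier and the label plane follows the
#' patch through both generator passes of its cycle. Generators are updated
#' on the least-squares adversarial loss plus the weighted cycle loss of both
#' directions; discriminators on BCE against the detached fakes. Models are
#' checkpointed every epoch and the epoch with the lowest validation cycle
#' loss is kept as the best.
#'
#' @param he_patches,ki67_patches training pools: (H, W, 3, N) arrays of
#'   pixels in \[0, 255\], or lists of `small_patch` objects. Sides must be
#'   divisible by 4.
#' @param he_classifier,ki67_classifier fitted `patch_classifier` or
#'   `mil_fit` objects (required when `config$conditioned`).
#' @param config a [gan_config()].
#' @return object of class `cyclegan_fit`.
#' @export
train_cyclegan <- function(he_patches, ki67_patches, he_classifier = NULL,
                           ki67_classifier = NULL, config = gan_config()) {
  he <- as_patch_pool(he_patches)
  ki <- as_patch_pool(ki67_patches)
  if (dim(he)[4] == 0 || dim(ki)[4] == 0) stop("train_cyclegan: empty patch pool")
  if (dim(he)[1] %% 4 != 0 || dim(ki)[1] %% 4 != 0)
    stop("train_cyclegan: patch side must be divisible by 4")
  if (inherits(he_classifier, "mil_fit")) he_classifier <- he_classifier$classifier
  if (inherits(ki67_classifier, "mil_fit")) ki67_classifier <- ki67_classifier$classifier
  if (config$conditioned && (is.null(he_classifier) || is.null(ki67_classifier)))
    stop("train_cyclegan: conditioned training requires both domain classifiers")

  lam <- config$cycle_weight
  bs <- config$batch_size
  hook <- config$on_generator_input

  with_seed(config$seed, {
    G_hk <- build_generator(config$conditioned, config$width_multiplier)
    G_kh <- build_generator(config$conditioned, config$width_multiplier)
    d_in <- if (config$conditioned_discriminator) 4L else 3L
    D_he <- build_discriminator(config$width_multiplier, d_in)
    D_ki <- build_discriminator(config$width_multiplier, d_in)
    opt <- list(G_hk = adam_init(G_hk$net), G_kh = adam_init(G_kh$net),
                D_he = adam_init(D_he$net), D_ki = adam_init(D_ki$net))

    # hold out validation patches for epoch scoring
    n_he <- dim(he)[4]; n_ki <- dim(ki)[4]
    n_he_val <- max(1L, min(n_he - 1L, ceiling(n_he * config$val_fraction)))
    n_ki_val <- max(1L, min(n_ki - 1L, ceiling(n_ki * config$val_fraction)))
    he_val_idx <- (n_he - n_he_val + 1L):n_he
    ki_val_idx <- (n_ki - n_ki_val + 1L):n_ki
    he_tr_idx <- setdiff(seq_len(n_he), he_val_idx)
    ki_tr_idx <- setdiff(seq_len(n_ki), ki_val_idx)

    steps <- config$steps_per_epoch %||%
      max(1L, min(length(he_tr_idx), length(ki_tr_idx)) %/% bs)

    cond_labels <- function(classifier, x) {
      if (!config$conditioned) return(NULL)
      classify_batch(classifier, x)
    }
    gen_in <- function(xn, labels, tag) {
      xin <- if (config$conditioned) condition_patch(xn, labels) else xn
      if (!is.null(hook)) hook(xin, tag)
      xin
    }

    # forward one full cycle; returns losses, caches and batch tensors
    run_cycle <- function(x_src_n, labels, G_fwd, G_bwd, D_tgt) {
      in1 <- gen_in(x_src_n, labels, "forward")
      f1 <- generator_forward(G_fwd, in1)
      fake <- f1$out
      in2 <- gen_in(fake, labels, "reverse")
      f2 <- generator_forward(G_bwd, in2)
      rec <- f2$out
      d_in_fake <- if (config$conditioned_discriminator)
        condition_patch(fake, labels) else fake
      d_f <- net_forward(D_tgt$net, d_in_fake)
      list(in1 = in1, f1 = f1, fake = fake, in2 = in2, f2 = f2, rec = rec,
           d_fake_cache = d_f, fake_scores = as.numeric(d_f$out))
    }

    # gradient of adversarial + cycle loss back to the two generators
    cycle_backward <- function(cy, x_src_n, G_fwd, G_bwd, D_tgt) {
      nfs <- length(cy$fake_scores)
      dscore <- matrix(2 * (cy$fake_scores - 1) / nfs, nfs, 1)
      dfake_adv <- net_backward(D_tgt$net, cy$d_fake_cache$cache, dscore)$dx
      if (config$conditioned_discriminator)
        dfake_adv <- strip_label_channel(dfake_adv)
      nel <- length(cy$rec)
      drec <- if (config$cycle_type == "L1") {
        lam * sign(cy$rec - x_src_n) / nel
      } else {
        lam * 2 * (cy$rec - x_src_n) / nel
      }
      bk2 <- generator_backward(G_bwd, cy$f2$cache, drec)
      dfake_cyc <- if (config$conditioned) strip_label_channel(bk2$dx) else bk2$dx
      bk1 <- generator_backward(G_fwd, cy$f1$cache, dfake_adv + dfake_cyc)
      list(g_fwd = bk1$grads, g_bwd = bk2$grads)
    }

    update_disc <- function(D, opt_state, x_real_n, fake_detached,
                            labels_real, labels_fake) {
      if (config$conditioned_discriminator) {
        x_real_n <- condition_patch(x_real_n, labels_real)
        fake_detached <- condition_patch(fake_detached, labels_fake)
      }
      fr <- net_forward(D$net, x_real_n)
      ff <- net_forward(D$net, fake_detached)
      sg <- disc_score_grad(as.numeric(fr$out), as.numeric(ff$out),
                            config$symmetric_lsgan)
      if (!is.finite(sg$loss)) stop("train_cyclegan: non-finite discriminator loss")
      g_r <- net_backward(D$net, fr$cache, matrix(sg$real, ncol = 1))$grads
      g_f <- net_backward(D$net, ff$cache, matrix(sg$fake, ncol = 1))$grads
      upd <- adam_step(D$net, add_grads(g_r, g_f), opt_state,
                       config$learning_rate * config$d_lr_factor,
                       config$betas[1], config$betas[2])
      list(net = upd$net, state = upd$state, loss = sg$loss)
    }

    val_cycle_loss <- function() {
      xv_he <- normalize_pixels(he[, , , he_val_idx, drop = FALSE])
      xv_ki <- normalize_pixels(ki[, , , ki_val_idx, drop = FALSE])
      lab_he <- cond_labels(he_classifier, he[, , , he_val_idx, drop = FALSE])
      lab_ki <- cond_labels(ki67_classifier, ki[, , , ki_val_idx, drop = FALSE])
      fake_ki <- generator_forward(G_hk, if (config$conditioned)
        condition_patch(xv_he, lab_he) else xv_he, cache = FALSE)$out
      rec_he <- generator_forward(G_kh, if (config$conditioned)
        condition_patch(fake_ki, lab_he) else fake_ki, cache = FALSE)$out
      fake_he <- generator_forward(G_kh, if (config$conditioned)
        condition_patch(xv_ki, lab_ki) else xv_ki, cache = FALSE)$out
      rec_ki <- generator_forward(G_hk, if (config$conditioned)
        condition_patch(fake_he, lab_ki) else fake_he, cache = FALSE)$out
      0.5 * (cycle_loss(xv_he, rec_he, config$cycle_type) +
               cycle_loss(xv_ki, rec_ki, config$cycle_type))
    }

    shuffle_he <- sample(he_tr_idx); pos_he <- 1L
    shuffle_ki <- sample(ki_tr_idx); pos_ki <- 1L
    draw <- function(shuffled, pos, pool_idx) {
      if (pos + bs - 1L > length(shuffled)) {
        shuffled <- sample(pool_idx); pos <- 1L
      }
      idx <- shuffled[pos:(pos + bs - 1L)]
      list(idx = idx, shuffled = shuffled, pos = pos + bs)
    }

    loss_history <- list()
    epoch_history <- list()
    batch_log <- if (config$log_batch_indices) list() else NULL
    best_val <- Inf; best_epoch <- NA_integer_
    best_G_hk <- G_hk; best_G_kh <- G_kh
    step_global <- 0L

    for (epoch in seq_len(config$epochs)) {
      for (step in seq_len(steps)) {
        step_global <- step_global + 1L
        dh <- draw(shuffle_he, pos_he, he_tr_idx)
        shuffle_he <- dh$shuffled; pos_he <- dh$pos
        dk <- draw(shuffle_ki, pos_ki, ki_tr_idx)
        shuffle_ki <- dk$shuffled; pos_ki <- dk$pos
        if (!is.null(batch_log))
          batch_log[[step_global]] <- list(he = dh$idx, ki = dk$idx)

        x_he <- he[, , , dh$idx, drop = FALSE]
        x_ki <- ki[, , , dk$idx, drop = FALSE]
        lab_he <- cond_labels(he_classifier, x_he)
        lab_ki <- cond_labels(ki67_classifier, x_ki)
        x_he_n <- normalize_pixels(x_he)
        x_ki_n <- normalize_pixels(x_ki)

        # ---- generator update (both directions jointly) ----
        cy_hk <- run_cycle(x_he_n, lab_he, G_hk, G_kh, D_ki)
        cy_kh <- run_cycle(x_ki_n, lab_ki, G_kh, G_hk, D_he)
        adv_g <- generator_adv_loss(cy_hk$fake_scores) +
          generator_adv_loss(cy_kh$fake_scores)
        cyc <- cycle_loss(x_he_n, cy_hk$rec, config$cycle_type) +
          cycle_loss(x_ki_n, cy_kh$rec, config$cycle_type)
        if (!is.finite(adv_g) || !is.finite(cyc))
          stop(sprintf("train_cyclegan: non-finite generator loss at epoch %d step %d",
                       epoch, step))
        bk_hk <- cycle_backward(cy_hk, x_he_n, G_hk, G_kh, D_ki)
        bk_kh <- cycle_backward(cy_kh, x_ki_n, G_kh, G_hk, D_he)
        g_hk <- add_grads(bk_hk$g_fwd, bk_kh$g_bwd)
        g_kh <- add_grads(bk_hk$g_bwd, bk_kh$g_fwd)
        up <- adam_step(G_hk$net, g_hk, opt$G_hk, config$learning_rate,
                        config$betas[1], config$betas[2])
        G_hk$net <- up$net; opt$G_hk <- up$state
        up <- adam_step(G_kh$net, g_kh, opt$G_kh, config$learning_rate,
                        config$betas[1], config$betas[2])
        G_kh$net <- up$net; opt$G_kh <- up$state

        # ---- discriminator updates on detached fakes ----
        ud <- update_disc(D_ki, opt$D_ki, x_ki_n, cy_hk$fake, lab_ki, lab_he)
        D_ki$net <- ud$net; opt$D_ki <- ud$state; d_ki_loss <- ud$loss
        ud <- update_disc(D_he, opt$D_he, x_he_n, cy_kh$fake, lab_he, lab_ki)
        D_he$net <- ud$net; opt$D_he <- ud$state; d_he_loss <- ud$loss

        loss_history[[step_global]] <- data.frame(
          step = step_global, epoch = epoch, adv_g = adv_g,
          adv_d_he = d_he_loss, adv_d_ki = d_ki_loss, cycle = cyc)
      }
      vcl <- val_cycle_loss()
      hist_ep <- do.call(rbind, loss_history)
      ep_rows <- hist_ep[hist_ep$epoch == epoch, , drop = FALSE]
      epoch_history[[epoch]] <- data.frame(
        epoch = epoch, adv_g = mean(ep_rows$adv_g),
        adv_d = mean((ep_rows$adv_d_he + ep_rows$adv_d_ki) / 2),
        cycle = mean(ep_rows$cycle), val_cycle = vcl)
      if (is.finite(vcl) && vcl < best_val) {
        best_val <- vcl; best_epoch <- epoch
        best_G_hk <- G_hk; best_G_kh <- G_kh
      }
      if (!is.null(config$on_epoch_end)) {
        snap <- structure(list(G_hk = G_hk, G_kh = G_kh,
                               he_classifier = he_classifier,
                               ki67_classifier = ki67_classifier,
                               epoch_history = do.call(rbind, epoch_history),
                               config = config),
                          class = "cyclegan_fit")
        config$on_epoch_end(epoch, snap)
      }
    }

    structure(list(
      G_hk = if (is.na(best_epoch)) G_hk else best_G_hk,
      G_kh = if (is.na(best_epoch)) G_kh else best_G_kh,
      final_G_hk = G_hk, final_G_kh = G_kh,
      D_he = D_he, D_ki = D_ki,
      he_classifier = he_classifier, ki67_classifier = ki67_classifier,
      epoch = config$epochs,
      loss_history = if (length(loss_history)) do.call(rbind, loss_history)
        else data.frame(step = integer(), epoch = integer(), adv_g = numeric(),
                        adv_d_he = numeric(), adv_d_ki = numeric(), cycle = numeric()),
      epoch_history = if (length(epoch_history)) do.call(rbind, epoch_history)
        else data.frame(epoch = integer(), adv_g = numeric(), adv_d = numeric(),
                        cycle = numeric(), val_cycle = numeric()),
      best_checkpoint = best_epoch,
      batch_log = batch_log,
      config = config), class = "cyclegan_fit")
  })
}

#' @export
print.cyclegan_fit <- function(x, ...) {
  cat(sprintf("Conditional CycleGAN fit: %d epochs, width %.2f, %s\n",
              x$epoch, x$config$width_multiplier,
              if (x$config$conditioned) "conditioned" else "unconditioned"))
  if (nrow(x$loss_history) > 0)
    cat(sprintf("  final step losses: adv_g %.4f, cycle %.4f; best epoch %s\n",
                tail(x$loss_history$adv_g, 1), tail(x$loss_history$cycle, 1),
                x$best_checkpoint))
  invisible(x)
}

#' @export
summary.cyclegan_fit <- function(object, ...) {
  print(object)
  if (nrow(object$epoch_history) > 0) {
    cat("  per-epoch means:\n")
    print(object$epoch_history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.cyclegan_fit <- function(x, ...) {
  h <- x$loss_history
  if (nrow(h) == 0) return(invisible(x))
  plot(h$step, h$cycle, type = "l", xlab = "step", ylab = "loss",
       ylim = range(c(h$cycle, h$adv_g)), ...)
  lines(h$step, h$adv_g, lty = 2)
  legend("topright", legend = c("cycle", "adversarial (G)"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Translate a full HE slide into a synthetic Ki-67 slide
#'
#' Tiles the whole image (background included), classifies each tile for
#' conditioning, runs the generator, de-normalises and stitches the output
#' tiles back by origin. Border remainders not covered by the tile grid are
#' filled with the background colour, so output dimensions equal input
#' dimensions.
#'
#' @param image HE `slide_image` or (H, W, 3) array in \[0, 255\].
#' @param classifier the HE-domain `patch_classifier` or `mil_fit` (may be
#'   NULL for an unconditioned generator).
#' @param generator an `sc_generator` (e.g. `fit$G_hk`).
#' @param small_size tile side in pixels (must divide by 4).
#' @param batch_size tiles per generator batch.
#' @return a `slide_image` with domain `"KI67"`.
#' @export
translate_image <- function(image, classifier, generator, small_size = 224L,
                            batch_size = 32L) {
  px <- as_pixels(image)
  if (inherits(classifier, "mil_fit")) classifier <- classifier$classifier
  h <- dim(px)[1]; w <- dim(px)[2]
  if (small_size > h || small_size > w)
    stop("translate_image: image smaller than tile size")
  tiles <- tile_small_patches(px, small_size, domain = "HE")
  out_tiles <- vector("list", length(tiles))
  for (s in seq(1, length(tiles), by = batch_size)) {
    e <- min(s + batch_size - 1L, length(tiles))
    x <- patches_to_batch(tiles[s:e])
    xn <- normalize_pixels(x)
    xin <- if (generator$conditioned) {
      condition_patch(xn, classify_batch(classifier, x))
    } else xn
    y <- generator_forward(generator, xin, cache = FALSE)$out
    y <- denormalize_pixels(y)
    for (i in s:e) {
      out_tiles[[i]] <- list(pixels = y[, , , i - s + 1L],
                             origin = tiles[[i]]$origin)
    }
  }
  canvas <- stitch_patches(out_tiles, h, w)
  new_slide_image(round(canvas), "KI67")
}

#' Translate with a fitted CycleGAN
#'
#' @param object a `cyclegan_fit`.
#' @param newdata a `slide_image` or (H, W, 3) array (HE for
#'   `direction = "he2ki"`).
#' @param direction `"he2ki"` (default) or `"ki2he"`.
#' @param small_size tile side in pixels.
#' @param ... unused.
#' @export
predict.cyclegan_fit <- function(object, newdata, direction = c("he2ki", "ki2he"),
                                 small_size = 32L, ...) {
  direction <- match.arg(direction)
  if (direction == "he2ki")
    translate_image(newdata, object$he_classifier, object$G_hk, small_size)
  else {
    out <- translate_image(newdata, object$ki67_classifier, object$G_kh, small_size)
    out$domain <- "HE"
    out
  }
}
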