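# Weakly supervised patch classification by iterative top-instance selection:
# each iteration scores every instance of every bag, selects the instance with
# the largest tumor-class probability per bag, assigns it the bag's weak
# label, and fine-tunes the classifier on the selected set.

#' Create an untrained patch classifier
#'
#' @param backbone `"small_cnn"`: three stride-2 convolution blocks with
#'   instance normalisation and ReLU, global average pooling and a linear
#'   head over the two classes (NORMAL, TUMOR).
#' @param input_size expected patch side in pixels.
#' @param seed RNG seed for weight initialisation.
#' @return object of class `patch_classifier`.
#' @export
patch_classifier <- function(backbone = "small_cnn", input_size = 32L, seed = 1L) {
  backbone <- tolower(backbone)
  if (backbone != "small_cnn")
    stop("patch_classifier: unsupported backbone '", backbone,
         "' (only \"small_cnn\" is implemented)")
  cl <- with_seed(seed, build_small_cnn(input_size))
  cl$seed <- as.integer(seed)
  cl
}

#' Class probabilities for a batch of patches
#'
#' @param classifier a `patch_classifier`.
#' @param x (H, W, 3, N) array of pixels in \[0, 255\] (or a single
#'   (H, W, 3) patch, or a list of `small_patch` objects).
#' @return N x 2 matrix with columns `NORMAL`, `TUMOR`, rows summing to 1.
#' @export
predict_proba <- function(classifier, x) {
  if (is.list(x) && !is.array(x)) x <- patches_to_batch(x)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != classifier$input_size || dim(x)[2] != classifier$input_size)
    stop("predict_proba: patch size ", dim(x)[1], "x", dim(x)[2],
         " does not match classifier input_size ", classifier$input_size)
  logits <- net_predict(classifier$net, normalize_pixels(x))
  p <- softmax(logits)
  colnames(p) <- c("NORMAL", "TUMOR")
  p
}

#' Classify a single patch
#'
#' @param patch a `small_patch` or (H, W, 3) array in \[0, 255\].
#' @param classifier a `patch_classifier`.
#' @return list with `label` (`"TUMOR"` iff the tumor probability exceeds
#'   0.5; exact ties resolve to `"NORMAL"`, the lower class index) and
#'   `probability` of the returned class.
#' @export
classify_patch <- function(patch, classifier) {
  px <- if (inherits(patch, "small_patch")) patch$pixels else patch
  p <- predict_proba(classifier, px)
  tumor <- p[1, "TUMOR"] > 0.5
  list(label = if (tumor) "TUMOR" else "NORMAL",
       probability = unname(if (tumor) p[1, "TUMOR"] else p[1, "NORMAL"]))
}

# Batch labels for conditioning: TUMOR iff tumor probability > 0.5.
classify_batch <- function(classifier, x, chunk = 256L) {
  n <- dim(x)[4]
  labs <- character(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- predict_proba(classifier, x[, , , s:e, drop = FALSE])
    labs[s:e] <- ifelse(p[, "TUMOR"] > 0.5, "TUMOR", "NORMAL")
  }
  labs
}

#' Evaluation step: top-instance selection per bag
#'
#' Scores every instance of every bag with the classifier's TUMOR-class
#' probability and selects, per bag, the instance with the largest score
#' (ties break to the lowest instance index). The selected instance is
#' assigned the bag's weak label. Deterministic given fixed weights.
#'
#' @param bags list of `bag` objects.
#' @param classifier a `patch_classifier`.
#' @return data.frame with columns `bag_id`, `instance_index`,
#'   `assigned_label`, `score`, plus a `patches` attribute holding the
#'   selected pixel arrays (consumed by [training_step()]).
#' @export
evaluation_step <- function(bags, classifier) {
  sel <- vector("list", length(bags))
  patches <- vector("list", length(bags))
  for (i in seq_along(bags)) {
    bag <- bags[[i]]
    if (length(bag$instances) == 0)
      stop("evaluation_step: empty bag ", bag$bag_id)
    p <- predict_proba(classifier, bag$instances)
    scores <- p[, "TUMOR"]
    j <- which.max(scores)             # ties -> lowest index
    sel[[i]] <- data.frame(bag_id = bag$bag_id, instance_index = j,
                           assigned_label = bag$weak_label,
                           score = unname(scores[j]), stringsAsFactors = FALSE)
    patches[[i]] <- bag$instances[[j]]$pixels
  }
  out <- do.call(rbind, sel)
  attr(out, "patches") <- patches
  out
}

#' Training step: fine-tune the classifier on the selected instances
#'
#' Runs `config$epochs_per_iteration` epochs of Adam updates with softmax
#' cross-entropy on the selected-instance set. A single-class selection
#' proceeds with a warning (an expected early-iteration state); a non-finite
#' loss aborts.
#'
#' @param selected output of [evaluation_step()].
#' @param classifier a `patch_classifier`.
#' @param config list; fields `learning_rate` (default 1e-4), `batch_size`
#'   (default 16), `epochs_per_iteration` (default 1).
#' @param opt_state optional Adam state carried across MIL iterations.
#' @return list with the updated `classifier`, final mean `loss`, and
#'   `opt_state`.
#' @export
training_step <- function(selected, classifier, config = list(), opt_state = NULL) {
  if (is.null(selected) || nrow(selected) == 0)
    stop("training_step: empty selection")
  lr <- config$learning_rate %||% 1e-4
  bs <- config$batch_size %||% 16L
  epochs <- config$epochs_per_iteration %||% 1L
  patches <- attr(selected, "patches")
  labels <- ifelse(selected$assigned_label == "TUMOR", 2L, 1L)
  if (length(unique(labels)) < 2)
    warning("training_step: selection contains a single class")
  n <- length(labels)
  d <- dim(patches[[1]])
  x <- array(0, c(d[1], d[2], 3L, n))
  for (i in seq_len(n)) x[, , , i] <- patches[[i]]
  x <- normalize_pixels(x)
  if (is.null(opt_state)) opt_state <- adam_init(classifier$net)
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq(1, n, by = bs)) {
      idx <- ord[s:min(s + bs - 1L, n)]
      f <- net_forward(classifier$net, x[, , , idx, drop = FALSE])
      ce <- cross_entropy(f$out, labels[idx])
      if (!is.finite(ce$loss))
        stop("training_step: non-finite loss; aborting")
      bk <- net_backward(classifier$net, f$cache, ce$dlogits)
      upd <- adam_step(classifier$net, bk$grads, opt_state, lr,
                       beta1 = 0.9, beta2 = 0.999)
      classifier$net <- upd$net
      opt_state <- upd$state
      losses <- c(losses, ce$loss)
    }
    loss <- mean(losses)
  }
  list(classifier = classifier, loss = loss, opt_state = opt_state)
}

# Bag-level prediction: TUMOR iff the max instance TUMOR-probability >= 0.5.
bag_predictions <- function(bags, classifier) {
  vapply(bags, function(bag) {
    p <- predict_proba(classifier, bag$instances)
    if (max(p[, "TUMOR"]) >= 0.5) "TUMOR" else "NORMAL"
  }, character(1))
}

#' Fit a tumor/normal patch classifier from weakly labelled bags
#'
#' Alternates [evaluation_step()] and [training_step()] for
#' `iterations` rounds, computing bag-level validation accuracy (max-instance
#' rule, threshold 0.5) after each round; the returned classifier is the
#' checkpoint with the best validation accuracy (earliest on ties).
#'
#' @param bags_train,bags_val non-empty lists of `bag` objects.
#' @param iterations number of MIL iterations.
#' @param seed RNG seed governing initialisation and batch order.
#' @param backbone passed to [patch_classifier()].
#' @param config optional list passed to [training_step()]; fields
#'   `learning_rate`, `batch_size`, `epochs_per_iteration`, and `restart`
#'   (logical, default FALSE: fine-tune across iterations rather than
#'   re-initialising the classifier each round).
#' @return object of class `mil_fit`.
#' @export
train_mil <- function(bags_train, bags_val, iterations = 10L, seed = 1L,
                      backbone = "small_cnn", config = list()) {
  if (length(bags_train) == 0 || length(bags_val) == 0)
    stop("train_mil: both bag splits must be non-empty")
  input_size <- dim(bags_train[[1]]$instances[[1]]$pixels)[1]
  restart <- isTRUE(config$restart)
  with_seed(seed, {
    classifier <- with_seed(seed, patch_classifier(backbone, input_size, seed))
    opt_state <- NULL
    selection_history <- list()
    val_history <- numeric(0)
    best_acc <- -Inf; best_classifier <- classifier; best_iter <- 0L
    val_labels <- vapply(bags_val, function(b) b$weak_label, character(1))
    for (it in seq_len(iterations)) {
      if (restart && it > 1) {
        classifier <- patch_classifier(backbone, input_size, seed + it)
        opt_state <- NULL
      }
      selected <- evaluation_step(bags_train, classifier)
      ts <- training_step(selected, classifier, config, opt_state)
      classifier <- ts$classifier
      opt_state <- ts$opt_state
      acc <- mean(bag_predictions(bags_val, classifier) == val_labels)
      selection_history[[it]] <- selected
      val_history <- c(val_history, acc)
      if (acc > best_acc) {
        best_acc <- acc; best_classifier <- classifier; best_iter <- it
      }
    }
    structure(list(classifier = best_classifier,
                   final_classifier = classifier,
                   iteration = iterations,
                   best_iteration = best_iter,
                   selection_history = selection_history,
                   validation_metric_history = val_history,
                   backbone = backbone, seed = seed, config = config),
              class = "mil_fit")
  })
}

#' @export
print.mil_fit <- function(x, ...) {
  cat(sprintf("MIL patch classifier (%s), %d iterations\n", x$backbone, x$iteration))
  if (x$iteration > 0)
    cat(sprintf("  best validation bag accuracy %.3f at iteration %d\n",
                max(x$validation_metric_history), x$best_iteration))
  invisible(x)
}

#' @export
summary.mil_fit <- function(object, ...) {
  cat(sprintf("MIL fit: backbone %s, input %dpx, seed %d\n",
              object$backbone, object$classifier$input_size, object$seed))
  cat(sprintf("  parameters: %d\n", parameter_count(object$classifier)))
  if (object$iteration > 0) {
    cat("  validation bag accuracy by iteration:\n")
    print(round(object$validation_metric_history, 3))
  }
  invisible(object)
}

#' Predict tumor/normal labels for patches with a fitted MIL classifier
#' @param object a `mil_fit`.
#' @param newdata patches: (H, W, 3, N) array, single patch, or list of
#'   `small_patch`.
#' @param type `"label"` or `"prob"`.
#' @param ... unused.
#' @export
predict.mil_fit <- function(object, newdata, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object$classifier, newdata)
  if (type == "prob") p else ifelse(p[, "TUMOR"] > 0.5, "TUMOR", "NORMAL")
}

#' @export
plot.mil_fit <- function(x, ...) {
  plot(seq_along(x$validation_metric_history), x$validation_metric_history,
       type = "b", xlab = "MIL iteration", ylab = "validation bag accuracy",
       ylim = c(0, 1), ...)
  invisible(x)
}

#' Tumor-probability heatmap overlay for a slide
#'
#' Tiles the slide, colours each mostly-foreground tile red (TUMOR) or blue
#' (NORMAL) by the classifier's prediction, and alpha-blends the colours over
#' the source image. Background tiles are left uncoloured. Visualisation
#' only.
#'
#' @param image `slide_image` or (H, W, 3) array.
#' @param classifier a `patch_classifier` or `mil_fit`.
#' @param small_size tile side in pixels.
#' @param alpha blend weight of the class colour.
#' @param min_fg_fraction minimum foreground coverage for a tile to be
#'   coloured.
#' @return (H, W, 3) array in \[0, 255\].
#' @export
render_heatmap <- function(image, classifier, small_size = 224L, alpha = 0.4,
                           min_fg_fraction = 0.5) {
  if (inherits(classifier, "mil_fit")) classifier <- classifier$classifier
  px <- as_pixels(image)
  fg <- otsu_foreground(px)$mask
  out <- px
  tiles <- tile_small_patches(px, small_size)
  for (tl in tiles) {
    rows <- (tl$origin[1] + 1):(tl$origin[1] + small_size)
    cols <- (tl$origin[2] + 1):(tl$origin[2] + small_size)
    if (mean(fg[rows, cols]) < min_fg_fraction) next
    lab <- classify_patch(tl$pixels, classifier)$label
    col <- if (lab == "TUMOR") c(255, 0, 0) else c(0, 0, 255)
    for (ch in 1:3)
      out[rows, cols, ch] <- (1 - alpha) * out[rows, cols, ch] + alpha * col[ch]
  }
  round(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
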