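# Top-instance MIL: selection matches an exhaustive oracle, tie-breaks are
# deterministic, labels are conserved, and training behaves (loss decreases,
# zero learning rate is a bit-exact no-op).

test_that("evaluation_step equals exhaustive rescoring + argmax", {
  cl <- patch_classifier(input_size = 16, seed = 3)
  for (s in 1:5) {
    bags <- random_bags(n_bags = 4, n_inst = 6, size = 16, seed = 10 + s)
    sel <- evaluation_step(bags, cl)
    oracle <- brute_force_selection(bags, cl)
    expect_equal(sel$instance_index, oracle$instance_index)
    expect_equal(sel$score, oracle$score, tolerance = 1e-12)
    expect_equal(sel$assigned_label, oracle$assigned_label)
  }
})

test_that("selection assigns the bag's weak label and conserves label counts", {
  cl <- patch_classifier(input_size = 16, seed = 1)
  bags <- random_bags(n_bags = 8, n_inst = 5, size = 16, seed = 2)
  sel <- evaluation_step(bags, cl)
  expect_equal(sel$assigned_label, vapply(bags, function(b) b$weak_label, character(1)))
  expect_equal(table(sel$assigned_label),
               table(vapply(bags, function(b) b$weak_label, character(1))))
  expect_true(all(sel$score >= 0 & sel$score <= 1))
})

test_that("argmax ties break to the lowest instance index", {
  cl <- patch_classifier(input_size = 16, seed = 1)
  bag <- random_bags(1, 4, size = 16, seed = 5)[[1]]
  # make all instances identical: identical scores, index 1 must win
  for (j in 2:4) bag$instances[[j]]$pixels <- bag$instances[[1]]$pixels
  sel <- evaluation_step(list(bag), cl)
  expect_equal(sel$instance_index, 1L)
})

test_that("empty bags are rejected by name", {
  cl <- patch_classifier(input_size = 16, seed = 1)
  bag <- structure(list(bag_id = "empty_one", weak_label = "NORMAL",
                        large_patch_origin = c(0L, 0L), instances = list()),
                   class = "bag")
  expect_error(evaluation_step(list(bag), cl), "empty_one")
})

test_that("training on a separable selected set decreases the loss", {
  # two colour-separable classes
  sc$with_seed(42, {
    n <- 16
    x <- vector("list", n)
    labels <- rep(c("TUMOR", "NORMAL"), each = n / 2)
    for (i in seq_len(n)) {
      base <- if (labels[i] == "TUMOR") c(200, 60, 60) else c(60, 60, 200)
      x[[i]] <- array(rep(base, each = 16 * 16) + stats::rnorm(16 * 16 * 3, 0, 10),
                      c(16, 16, 3))
    }
    sel <- data.frame(bag_id = sprintf("b%d", seq_len(n)), instance_index = 1L,
                      assigned_label = labels, score = 0.5,
                      stringsAsFactors = FALSE)
    attr(sel, "patches") <- x
    cl <- patch_classifier(input_size = 16, seed = 7)
    losses <- numeric(5)
    st <- NULL
    for (ep in 1:5) {
      out <- training_step(sel, cl, list(learning_rate = 1e-3, batch_size = 8), st)
      cl <- out$classifier; st <- out$opt_state; losses[ep] <- out$loss
    }
    expect_lt(losses[5], losses[1])
    expect_lt(mean(diff(losses)), 0)   # decreasing trend
  })
})

test_that("zero learning rate leaves the weights bit-exact", {
  bags <- random_bags(2, 3, size = 16, seed = 4)
  cl <- patch_classifier(input_size = 16, seed = 9)
  sel <- evaluation_step(bags, cl)
  out <- training_step(sel, cl, list(learning_rate = 0, batch_size = 4))
  expect_identical(out$classifier$net, cl$net)
})

test_that("degenerate selections are handled", {
  cl <- patch_classifier(input_size = 16, seed = 1)
  expect_error(training_step(NULL, cl), "empty")
  bags <- random_bags(3, 3, size = 16, seed = 6)
  for (i in seq_along(bags)) bags[[i]]$weak_label <- "NORMAL"
  sel <- evaluation_step(bags, cl)
  expect_warning(training_step(sel, cl, list(learning_rate = 1e-4)), "single class")
})

test_that("train_mil with zero iterations returns the initial state", {
  bags <- random_bags(4, 3, size = 16, seed = 8)
  fit <- train_mil(bags[1:2], bags[3:4], iterations = 0, seed = 5)
  expect_s3_class(fit, "mil_fit")
  expect_length(fit$selection_history, 0L)
  expect_length(fit$validation_metric_history, 0L)
  # untouched random classifier: identical to a fresh seeded build
  ref <- patch_classifier(input_size = 16, seed = 5)
  expect_identical(fit$classifier$net, ref$net)
})

test_that("train_mil histories are bit-identical across reruns with one seed", {
  bags <- random_bags(6, 4, size = 16, seed = 12)
  f1 <- train_mil(bags[1:4], bags[5:6], iterations = 3, seed = 21,
                  config = list(learning_rate = 1e-3))
  f2 <- train_mil(bags[1:4], bags[5:6], iterations = 3, seed = 21,
                  config = list(learning_rate = 1e-3))
  expect_identical(f1$validation_metric_history, f2$validation_metric_history)
  expect_identical(f1$classifier$net, f2$classifier$net)
  # histories have equal length = iterations
  expect_length(f1$selection_history, 3L)
  expect_length(f1$validation_metric_history, 3L)
})

test_that("classify_patch is consistent with predict_proba and ties to NORMAL", {
  cl <- patch_classifier(input_size = 16, seed = 2)
  patch <- array(stats::runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  p <- predict_proba(cl, patch)
  expect_equal(rowSums(p), 1, tolerance = 1e-6)
  out <- classify_patch(patch, cl)
  expect_equal(out$label, if (p[1, "TUMOR"] > 0.5) "TUMOR" else "NORMAL")
  # a forced exact tie resolves to NORMAL: zero the head weights
  cl0 <- cl
  lin <- length(cl0$net$layers)
  cl0$net$layers[[lin]]$w[] <- 0
  cl0$net$layers[[lin]]$b[] <- 0
  expect_equal(classify_patch(patch, cl0)$label, "NORMAL")
  expect_error(predict_proba(cl, array(0, c(8, 8, 3))), "input_size")
})

test_that("render_heatmap colours foreground tiles and skips background", {
  pair <- render_slide_pair(slide_spec(width = 128, height = 128, n_cells = 30,
                                       tissue_fraction = 0.5, seed = 13))
  cl <- patch_classifier(input_size = 32, seed = 3)
  hm <- render_heatmap(pair$he, cl, small_size = 32, alpha = 0.5)
  expect_equal(dim(hm), dim(pair$he$pixels))
  fg <- otsu_foreground(pair$he)$mask
  tiles <- tile_small_patches(pair$he, 32)
  for (tl in tiles) {
    rows <- (tl$origin[1] + 1):(tl$origin[1] + 32)
    cols <- (tl$origin[2] + 1):(tl$origin[2] + 32)
    if (mean(fg[rows, cols]) < 0.5) {
      expect_identical(hm[rows, cols, ], pair$he$pixels[rows, cols, ])
    } else {
      expect_false(identical(hm[rows, cols, ], pair$he$pixels[rows, cols, ]))
    }
  }
})
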