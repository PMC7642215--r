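# Shared fixtures, memoised so expensive objects are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

sc <- asNamespace("staincycle")

# A small rendered slide pair with mixed tumor/normal cells.
small_pair <- function() fixture("small_pair", render_slide_pair(
  slide_spec(width = 320, height = 320, tissue_fraction = 0.75, n_cells = 150,
             tumor_region_fraction = 0.47, positive_fraction = 1.0, seed = 7)))

# Random bags with known per-instance pixels, for selection-oracle tests.
random_bags <- function(n_bags, n_inst, size = 16L, seed = 1L) {
  sc$with_seed(seed, lapply(seq_len(n_bags), function(i) {
    structure(list(
      bag_id = sprintf("bag%02d", i),
      weak_label = sample(c("TUMOR", "NORMAL"), 1),
      large_patch_origin = c(0L, 0L),
      instances = lapply(seq_len(n_inst), function(j) {
        structure(list(pixels = array(runif(size * size * 3, 0, 255),
                                      c(size, size, 3)),
                       origin = c(0L, (j - 1L) * size), domain = "HE"),
                  class = "small_patch")
      })), class = "bag")
  }))
}

# Independent brute-force re-implementation of top-instance selection used as
# the oracle: rescapes every instance one at a time through predict_proba.
brute_force_selection <- function(bags, classifier) {
  do.call(rbind, lapply(bags, function(bag) {
    scores <- vapply(bag$instances, function(inst) {
      unname(predict_proba(classifier, inst$pixels)[1, "TUMOR"])
    }, numeric(1))
    best <- which(scores == max(scores))[1]
    data.frame(bag_id = bag$bag_id, instance_index = best,
               assigned_label = bag$weak_label, score = scores[best],
               stringsAsFactors = FALSE)
  }))
}
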