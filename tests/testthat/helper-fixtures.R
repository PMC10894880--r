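# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# Two well-separated tile textures (the generator's default class laws).
fixture_textures <- function() {
  list(A = list(blob_density = 45, stripe_freq = 0, stain_mix = c(1.0, 0.5)),
       B = list(blob_density = 6, stripe_freq = 6, stain_mix = c(0.45, 1.0)))
}

# Desk-scale training configuration for the CNN tests: same schedule
# semantics as the published setup, sized so ~200 tiles suffice.
fixture_train_config <- function(...) {
  train_config(epochs = 20, batch_size = 32, eta_max = 0.1, seed = 4, ...)
}

# 64 px tiles are enough for the 32 px network input.
fixture_tile_set <- function(n_per_class = 120, size = 64) {
  key <- sprintf("tiles_%d_%d", n_per_class, size)
  if (is.null(.fixtures[[key]])) {
    tex <- fixture_textures()
    gen <- function(n, tx, off) {
      lapply(seq_len(n), function(i) generate_tile_image(tx, seed = off + i,
                                                         size = size))
    }
    .fixtures[[key]] <- list(
      A = gen(n_per_class, tex$A, 1000),
      B = gen(n_per_class, tex$B, 2000))
  }
  .fixtures[[key]]
}

# One trained patch CNN on 100+100 tiles, reused by every test needing it.
fixture_cnn <- function() {
  if (is.null(.fixtures$cnn)) {
    ts <- fixture_tile_set()
    tiles <- c(ts$A[1:100], ts$B[1:100])
    labels <- rep(c("A", "B"), each = 100)
    .fixtures$cnn <- list(
      model = train_patch_classifier(tiles, labels, fixture_train_config()),
      holdout_tiles = c(ts$A[101:120], ts$B[101:120]),
      holdout_labels = rep(c("A", "B"), each = 20))
  }
  .fixtures$cnn
}

# A small separable binary likelihood cohort shared across fusion/signature
# tests (Beta(8,2) vs Beta(2,8)).
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    spec <- synthetic_spec(
      n_cases_per_class = c(pos = 40, neg = 40),
      slides_per_case = c(1, 2), tiles_per_slide = c(30, 60),
      likelihood_law = list(pos = c(8, 2), neg = c(2, 8)), seed = 2)
    gen <- generate_likelihood_table(spec)
    gen$cohort <- split_cohort(gen$cohort, 0.7, seed = 2)
    .fixtures$cohort <- gen
  }
  .fixtures$cohort
}

# Brute-force pairwise AUC oracle (ties count half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

angle_deg <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi
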