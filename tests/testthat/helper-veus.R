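## Shared fixtures, all generated in code. Heavier phantom datasets are
## memoized so several test files can reuse them.

.fixture_env <- new.env()

## small 64x64 phantom dataset (deterministic)
tiny_dataset <- function(n = 12, seed = 7) {
  key <- paste0("ds_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    p <- phantom_params(image_size = 64L, seed = seed)
    .fixture_env[[key]] <- generate_dataset(p, n, 0.5, seed = seed)
  }
  .fixture_env[[key]]
}

## coarse 32x32 parameters: cheap bulk generation for rate/statistics tests
coarse_params <- function(...) phantom_params(image_size = 32L, ...)

## brute-force Mann-Whitney AUC with ties counted one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

## random valid RGB image fixture
random_rgb <- function(h, w) array(sample(0:255, h * w * 3, TRUE), dim = c(h, w, 3))
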