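# In-code fixtures shared across test files.

# tiny labeled dataset: 3 pathogenic on chr1, 3 controls (chr1/chr2)
toy_dataset <- function() {
  variant_dataset(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 500L, 9000L, 120L, 100L, 5000L),
    ref = c("A", "C", "G", "T", "A", "C"),
    alt = c("G", "T", "A", "C", "T", "G"),
    label = c(1L, 1L, 1L, -1L, -1L, -1L),
    maf = c(0.001, 0.002, NA, 0.01, 0.0099, 0.25),
    coding = c(1L, 0L, 1L, 0L, 0L, 1L)))
}

# two-group features for toy_dataset: X informative-ish, Y noise
toy_features <- function(seed = 1) {
  set.seed(seed)
  feature_group_set(list(
    X = matrix(rnorm(6 * 3) + rep(c(1, 0), each = 3), 6, 3),
    Y = matrix(rnorm(6 * 2), 6, 2)))
}

# separable two-class gaussian problem as (features, labels)
separable_problem <- function(n_per_class = 20, q = 4, shift = 4,
                              seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(1, -1), each = n_per_class)
  x <- matrix(rnorm(n * q), n, q)
  x[y == 1, ] <- x[y == 1, ] + shift / sqrt(q)
  list(features = feature_group_set(list(A = x)), labels = y, x = x)
}

# independent SVM oracle: libsvm via e1071 on raw (unscaled) features,
# positive class first so decision values share the package's sign
libsvm_phi <- function(x_train, y_train, x_test, C, tolerance = 1e-12) {
  fit <- e1071::svm(x_train, factor(y_train, levels = c(1, -1)),
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  as.vector(attr(predict(fit, x_test, decision.values = TRUE),
                 "decision.values"))
}

subset_dataset_empty <- function() {
  variant_dataset(data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             label = integer()))
}

subset_rows_ds <- function(d, idx) {
  out <- as.data.frame(d)[idx, , drop = FALSE]
  rownames(out) <- NULL
  variant_dataset(out)
}

# brute-force AUC by pairwise enumeration (Mann-Whitney with 1/2 ties)
auc_enumerate <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
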