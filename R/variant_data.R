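# Variant data model and dataset-assembly rules: MAF filtering of controls,
# overlap removal, positional-window negative selection, coding/non-coding
# partition and balanced training-set assembly.

#' Construct a labeled variant dataset
#'
#' A `variant_dataset` is a `data.frame` of biallelic single-nucleotide
#' variants with one row per variant and columns `chrom`, `pos`, `ref`,
#' `alt`, `label`, `maf`, `coding`. Labels are coded `+1` (pathogenic),
#' `-1` (control) and `0` (unlabeled). `maf` is the minor allele frequency
#' in `[0, 0.5]` (`NA` when unknown) and `coding` is `1` when the variant
#' introduces an amino-acid substitution, `0` when it does not and `NA`
#' when unannotated. The key `(chrom, pos, ref, alt)` must be unique;
#' row order is preserved.
#'
#' @param df data.frame with at least columns `chrom`, `pos`, `ref`, `alt`,
#'   `label`; optional `maf` and `coding` default to `NA`.
#' @return a `variant_dataset` (a validated `data.frame`).
#' @examples
#' variant_dataset(data.frame(chrom = "chr1", pos = 100, ref = "A",
#'                            alt = "G", label = 1))
#' @export
variant_dataset <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_("missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"maf" %in% names(df)) df$maf <- rep(NA_real_, nrow(df))
  if (!"coding" %in% names(df)) df$coding <- rep(NA_integer_, nrow(df))
  df <- df[, c(req, "maf", "coding")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$label <- as.integer(df$label)
  df$maf <- as.numeric(df$maf)
  df$coding <- as.integer(df$coding)
  validate_variant_dataset(df)
  rownames(df) <- NULL
  class(df) <- c("variant_dataset", "data.frame")
  df
}

validate_variant_dataset <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$pos) || any(df$pos < 1L))
    stop_("positions must be integers >= 1 (1-based coordinates)")
  nt <- c("A", "C", "G", "T")
  if (!all(df$ref %in% nt) || !all(df$alt %in% nt))
    stop_("ref/alt must be single nucleotides (A, C, G, T)")
  if (any(df$ref == df$alt))
    stop_("ref and alt alleles must differ")
  if (!all(df$label %in% c(-1L, 0L, 1L)))
    stop_("labels must be +1 (pathogenic), -1 (control) or 0 (unlabeled)")
  bad_maf <- !is.na(df$maf) & (df$maf < 0 | df$maf > 0.5)
  if (any(bad_maf))
    stop_("maf must lie in [0, 0.5]; offending rows: ",
          paste(which(bad_maf), collapse = ", "))
  if (!all(is.na(df$coding) | df$coding %in% c(0L, 1L)))
    stop_("coding flag must be 1, 0 or NA")
  k <- variant_keys(df)
  if (anyDuplicated(k)) {
    dup <- unique(k[duplicated(k)])
    stop_("duplicate variant keys: ", paste(dup, collapse = ", "),
          class = "mklvariant_duplicate_key")
  }
  invisible(df)
}

#' Variant keys
#'
#' Returns the `chrom:pos:ref:alt` identifier of each variant.
#'
#' @param dataset a `variant_dataset` (or data.frame with the key columns).
#' @return character vector of keys.
#' @export
variant_keys <- function(dataset) {
  variant_key_(dataset$chrom, dataset$pos, dataset$ref, dataset$alt)
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat("variant_dataset:", nrow(x), "variants (",
      sum(x$label == 1L), "pathogenic,", sum(x$label == -1L), "control,",
      sum(x$label == 0L), "unlabeled )\n")
  NextMethod()
}

subset_dataset <- function(dataset, idx) {
  out <- as.data.frame(dataset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_dataset", "data.frame")
  out
}

#' Filter control variants by minor allele frequency
#'
#' Retains every control (label `-1`) whose MAF is at least `min_maf`
#' (inclusive boundary, so a control at exactly 1\% is kept when
#' `min_maf = 0.01`). Pathogenic and unlabeled variants pass through
#' untouched; row order is preserved.
#'
#' @param dataset a `variant_dataset`.
#' @param min_maf minimum minor allele frequency for controls; default 0.01.
#' @param missing_maf what to do with controls lacking a MAF value:
#'   `"drop"` (default; the number dropped is reported via a message) or
#'   `"error"`.
#' @return the filtered `variant_dataset`.
#' @export
filter_controls_by_maf <- function(dataset, min_maf = 0.01,
                                   missing_maf = c("drop", "error")) {
  missing_maf <- match.arg(missing_maf)
  is_ctrl <- dataset$label == -1L
  no_maf <- is_ctrl & is.na(dataset$maf)
  if (any(no_maf)) {
    if (missing_maf == "error")
      stop_(sum(no_maf), " control variant(s) have missing maf")
    message("dropping ", sum(no_maf), " control variant(s) with missing maf")
  }
  keep <- !is_ctrl | (!is.na(dataset$maf) & dataset$maf >= min_maf)
  subset_dataset(dataset, keep)
}

#' Remove controls that also occur in the pathogenic set
#'
#' Drops every control variant whose `(chrom, pos, ref, alt)` key also
#' appears in `pathogenic`; the remaining controls keep their original
#' relative order.
#'
#' @param controls,pathogenic `variant_dataset` objects.
#' @return `controls` minus the shared keys.
#' @export
remove_pathogenic_overlap <- function(controls, pathogenic) {
  keep <- !(variant_keys(controls) %in% variant_keys(pathogenic))
  subset_dataset(controls, keep)
}

#' Select negatives within a window of some positive
#'
#' Retains a negative example iff some positive on the same chromosome lies
#' within `window` nucleotides: `|pos_neg - pos_pos| <= window` (symmetric,
#' inclusive). `window = Inf` keeps every negative sharing a chromosome with
#' at least one positive; `window = 0` keeps only exact-coordinate matches.
#'
#' @param negatives,positives `variant_dataset` objects.
#' @param window nonnegative distance in nucleotides; default 1000.
#' @return the filtered negatives.
#' @export
select_negatives_within_window <- function(negatives, positives,
                                           window = 1000) {
  stopifnot(window >= 0)
  if (nrow(negatives) == 0) return(negatives)
  pos_by_chr <- split(positives$pos, positives$chrom)
  keep <- vapply(seq_len(nrow(negatives)), function(i) {
    pp <- pos_by_chr[[negatives$chrom[i]]]
    if (is.null(pp)) return(FALSE)
    if (is.infinite(window)) return(TRUE)
    min(abs(pp - negatives$pos[i])) <= window
  }, logical(1))
  subset_dataset(negatives, keep)
}

#' Partition a dataset by coding status
#'
#' Splits variants into those introducing an amino-acid substitution
#' (`coding == 1`) and the remainder (`coding == 0`). The flag is an input
#' annotation; consequence calling is upstream of this package.
#'
#' @param dataset a `variant_dataset`; every variant must carry a coding flag.
#' @return list with elements `coding` and `noncoding`, both
#'   `variant_dataset`s whose union is the input (order preserved within
#'   each part).
#' @export
split_by_coding <- function(dataset) {
  if (anyNA(dataset$coding)) {
    bad <- variant_keys(dataset)[is.na(dataset$coding)]
    stop_("variants with missing coding flag: ", paste(bad, collapse = ", "))
  }
  list(coding = subset_dataset(dataset, dataset$coding == 1L),
       noncoding = subset_dataset(dataset, dataset$coding == 0L))
}

#' Assemble a (optionally balanced) training set with complete feature groups
#'
#' Keeps only variants that have at least one observed value in every
#' selected feature group (no group-level missingness), then optionally
#' draws a class-balanced sample without replacement.
#'
#' @param dataset a `variant_dataset` with labels in `{-1, +1}` for sampled
#'   classes.
#' @param features the companion [feature_group_set()].
#' @param groups character vector of group names to require; default all.
#' @param balanced draw equally many examples per class?
#' @param n_per_class per-class sample size, or `"max"` for the largest
#'   balanced set the data support.
#' @param seed integer seed making the sample reproducible.
#' @return list with `train` (the `variant_dataset`) and `features`
#'   (the matching row subset of the feature groups).
#' @export
assemble_training_set <- function(dataset, features, groups = NULL,
                                  balanced = FALSE, n_per_class = "max",
                                  seed = NULL) {
  stopifnot(inherits(features, "feature_group_set"))
  if (is.null(groups)) groups <- features$group_names
  unknown <- setdiff(groups, features$group_names)
  if (length(unknown))
    stop_("unknown feature groups: ", paste(unknown, collapse = ", "))
  if (nrow(features$group_missing) != nrow(dataset))
    stop_("features and dataset have different numbers of variants")
  complete <- !apply(features$group_missing[, groups, drop = FALSE], 1, any)
  idx <- which(complete)
  if (balanced) {
    pos <- idx[dataset$label[idx] == 1L]
    neg <- idx[dataset$label[idx] == -1L]
    if (length(pos) == 0L || length(neg) == 0L)
      stop_("a class has zero examples complete in the selected groups")
    n_take <- if (identical(n_per_class, "max")) min(length(pos), length(neg))
              else min(length(pos), length(neg), as.integer(n_per_class))
    idx <- local_seed(seed, {
      sort(c(sample(pos, n_take), sample(neg, n_take)))
    })
  }
  list(train = subset_dataset(dataset, idx),
       features = features_subset(features, idx, groups))
}
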