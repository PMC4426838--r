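# Synthetic labeled-variant generator: class-shifted Gaussian feature
# groups of controlled informativeness, Beta-distributed minor allele
# frequencies with a low-frequency contaminant component (mislabeled
# true positives among the controls), genomic clustering of negatives
# around positives, and group/value-level missingness.

#' Synthetic study configuration
#'
#' Defines the generative model used throughout the test-bench: each
#' feature group draws class-conditional multivariate normals with
#' identity covariance; an informative group separates the latent
#' classes by `effect_size` (the Euclidean norm of the between-class
#' mean difference, in units of the per-feature s.d., spread evenly
#' across the group's features), while `noise_only` groups have zero
#' separation. A fraction `contamination_rate` of the negatives are
#' *contaminants*: latent positives carrying the label -1, with MAF
#' drawn from a lower-mean Beta than the clean controls — the mechanism
#' by which confident "false positives" end up shifted toward rare
#' alleles. Positives are scattered over chromosomes and a fraction
#' `cluster_fraction` of the negatives is placed within
#' `cluster_window` nucleotides of some positive.
#'
#' Defaults describe the reference study conditions used by the
#' package's own benchmarks: 200 variants per class, four groups of 10
#' features with one informative group at `effect_size = 2` (single
#' group Bayes AUC about 0.92, so the classes genuinely overlap),
#' 5\% contamination, clean-control MAF ~ 0.5*Beta(2, 5) (mean 0.14)
#' versus contaminant MAF ~ 0.5*Beta(1, 9) (mean 0.05).
#'
#' @param n_pos,n_neg class sizes (default 200 each).
#' @param group_specs list of per-group lists with `n_features`,
#'   `effect_size`, `noise_only`; default one informative group `A`
#'   (effect 2) plus noise groups `B`-`D`, 10 features each.
#' @param group_missing_rate per-group probability that a variant lacks
#'   the whole group (recycled; default 0).
#' @param value_missing_rate per-cell missingness probability among
#'   non-group-missing rows (default 0).
#' @param maf_control,maf_contaminant `c(shape1, shape2)` of the Beta
#'   MAF models (scaled to `[0, 0.5]`).
#' @param contamination_rate fraction of negatives that are latent
#'   positives (default 0.05).
#' @param cluster_window,cluster_fraction negatives are placed within
#'   `cluster_window` nt of a random positive with probability
#'   `cluster_fraction` (defaults 1000 nt, 0.9).
#' @param coding_fraction probability a variant is flagged coding.
#' @param n_chrom,chrom_length chromosome count and length for position
#'   scattering.
#' @param seed integer seed; generation is fully reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 200, n_neg = 200,
                             group_specs = NULL,
                             group_missing_rate = 0,
                             value_missing_rate = 0,
                             maf_control = c(2, 5),
                             maf_contaminant = c(1, 9),
                             contamination_rate = 0.05,
                             cluster_window = 1000,
                             cluster_fraction = 0.9,
                             coding_fraction = 0.5,
                             n_chrom = 2, chrom_length = 1e6,
                             seed = 1) {
  if (is.null(group_specs))
    group_specs <- c(list(A = list(n_features = 10, effect_size = 2,
                                   noise_only = FALSE)),
                     lapply(stats::setNames(nm = c("B", "C", "D")),
                            function(g) list(n_features = 10,
                                             effect_size = 0,
                                             noise_only = TRUE)))
  if (is.null(names(group_specs)))
    names(group_specs) <- LETTERS[seq_along(group_specs)]
  cfg <- list(n_pos = n_pos, n_neg = n_neg, group_specs = group_specs,
              group_missing_rate = rep_len(group_missing_rate,
                                           length(group_specs)),
              value_missing_rate = value_missing_rate,
              maf_control = maf_control, maf_contaminant = maf_contaminant,
              contamination_rate = contamination_rate,
              cluster_window = cluster_window,
              cluster_fraction = cluster_fraction,
              coding_fraction = coding_fraction,
              n_chrom = n_chrom, chrom_length = chrom_length, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_pos < 1 || n_neg < 1) stop_("class sizes must be positive")
    if (length(group_specs) < 1) stop_("need at least one feature group")
    rates <- c(group_missing_rate, value_missing_rate, contamination_rate,
               cluster_fraction, coding_fraction)
    if (any(rates < 0 | rates > 1)) stop_("rates must lie in [0, 1]")
    if (any(vapply(group_specs, `[[`, numeric(1), "effect_size") < 0))
      stop_("effect_size must be nonnegative")
  })
  invisible(cfg)
}

#' Generate a synthetic labeled study
#'
#' Draws variants, feature-group matrices and per-variant ground truth
#' from a [synthetic_config()]. Bit-identical for a fixed seed.
#'
#' @param config a `synthetic_config`.
#' @return list with `dataset` (a [variant_dataset()]), `features`
#'   (a [feature_group_set()]) and `truth` (data.frame with the latent
#'   class `latent` in -1/+1 and the `contaminated` flag).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  local_seed(config$seed, generate_synthetic_(config))
}

generate_synthetic_ <- function(cfg) {
  n <- cfg$n_pos + cfg$n_neg
  label <- rep(c(1L, -1L), c(cfg$n_pos, cfg$n_neg))
  contaminated <- label == -1L &
    stats::runif(n) < ifelse(label == -1L, cfg$contamination_rate, 0)
  latent <- ifelse(label == 1L | contaminated, 1L, -1L)

  # MAF: pathogenic and contaminant variants from the low-mean Beta,
  # clean controls from the control Beta
  low <- latent == 1L
  maf <- numeric(n)
  maf[low] <- 0.5 * stats::rbeta(sum(low), cfg$maf_contaminant[1],
                                 cfg$maf_contaminant[2])
  maf[!low] <- 0.5 * stats::rbeta(sum(!low), cfg$maf_control[1],
                                  cfg$maf_control[2])

  # positions: positives scattered; most negatives near some positive
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  chrom <- character(n)
  pos <- integer(n)
  ip <- which(label == 1L)
  chrom[ip] <- sample(chrom_names, length(ip), replace = TRUE)
  pos[ip] <- sample.int(cfg$chrom_length, length(ip), replace = TRUE)
  for (i in which(label == -1L)) {
    if (stats::runif(1) < cfg$cluster_fraction && length(ip)) {
      anchor <- if (length(ip) == 1L) ip else sample(ip, 1)
      chrom[i] <- chrom[anchor]
      pos[i] <- max(1L, pos[anchor] +
                      sample.int(2L * cfg$cluster_window + 1L, 1) -
                      cfg$cluster_window - 1L)
    } else {
      chrom[i] <- sample(chrom_names, 1)
      pos[i] <- sample.int(cfg$chrom_length, 1)
    }
  }
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  # resolve key collisions by nudging positions
  key <- variant_key_(chrom, pos, ref, alt)
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    pos[d] <- pos[d] + 1L
    key <- variant_key_(chrom, pos, ref, alt)
  }

  dataset <- variant_dataset(data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, label = label,
    maf = maf,
    coding = as.integer(stats::runif(n) < cfg$coding_fraction),
    stringsAsFactors = FALSE))

  # features: identity-covariance normals; informative groups shift the
  # latent-positive mean by effect_size / sqrt(n_features) per feature
  mats <- lapply(cfg$group_specs, function(sp) {
    q <- sp$n_features
    shift <- if (isTRUE(sp$noise_only)) 0 else sp$effect_size / sqrt(q)
    m <- matrix(stats::rnorm(n * q), n, q)
    m[latent == 1L, ] <- m[latent == 1L, ] + shift
    m
  })
  p <- length(mats)
  group_missing <- matrix(FALSE, n, p)
  for (g in seq_len(p)) {
    gm <- stats::runif(n) < cfg$group_missing_rate[g]
    mats[[g]][gm, ] <- NA_real_
    if (cfg$value_missing_rate > 0) {
      vm <- matrix(stats::runif(n * ncol(mats[[g]])) <
                     cfg$value_missing_rate, n)
      vm[gm, ] <- FALSE
      # keep at least one observed value so value-missingness does not
      # silently escalate to group-level missingness
      full <- !gm & rowSums(!vm) == 0
      vm[cbind(which(full), 1L)] <- FALSE
      mats[[g]][vm] <- NA_real_
    }
    group_missing[, g] <- gm
  }
  colnames(group_missing) <- names(mats)

  list(dataset = dataset,
       features = feature_group_set(mats, group_missing = group_missing),
       truth = data.frame(latent = latent, contaminated = contaminated))
}
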