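test_that("variant_dataset enforces its invariants", {
  d <- toy_dataset()
  expect_s3_class(d, "variant_dataset")
  expect_equal(nrow(d), 6)

  expect_error(variant_dataset(data.frame(chrom = "1", pos = 0, ref = "A",
                                          alt = "G", label = 1)),
               "1-based")
  expect_error(variant_dataset(data.frame(chrom = "1", pos = 5, ref = "A",
                                          alt = "A", label = 1)),
               "differ")
  expect_error(variant_dataset(data.frame(chrom = "1", pos = 5, ref = "A",
                                          alt = "G", label = 1, maf = 0.7)),
               "maf")
  dup <- rbind(as.data.frame(toy_dataset()), as.data.frame(toy_dataset())[1, ])
  expect_error(variant_dataset(dup), "duplicate",
               class = "mklvariant_duplicate_key")
})

test_that("tsv and vcf dialects round-trip to the same dataset", {
  d <- toy_dataset()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(d, tsv, dialect = "tsv")
  write_variant_table(d, vcf, dialect = "vcf")
  d_tsv <- read_variant_table(tsv, dialect = "tsv")
  d_vcf <- read_variant_table(vcf, dialect = "vcf")
  expect_equal(as.data.frame(d_tsv), as.data.frame(d))
  expect_equal(as.data.frame(d_vcf), as.data.frame(d_tsv))
})

test_that("malformed variant tables are rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt\tlabel", "chr1\t5\tA\tG"), f)
  expect_error(read_variant_table(f), "line 2")

  writeLines(c("#chrom\tpos\tref\talt\tlabel", "chr1\t5\tA\tG\tmaybe"), f)
  expect_error(read_variant_table(f), "label token 'maybe' at line 2")

  d <- toy_dataset()
  dupfile <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(d, dupfile)
  lines <- readLines(dupfile)
  writeLines(c(lines, lines[2]), dupfile)
  expect_error(read_variant_table(dupfile), "duplicate variant keys: chr1:100:A:G")
})

test_that("control MAF filter keeps the inclusive >= 1% boundary", {
  d <- toy_dataset()
  f <- suppressMessages(filter_controls_by_maf(d))
  # control at exactly 0.01 retained, 0.0099 removed, missing-maf control
  # absent here; pathogenic rows (incl. one with NA maf) pass untouched
  expect_true("chr1:120:T:C" %in% variant_keys(f))
  expect_false("chr2:100:A:T" %in% variant_keys(f))
  expect_equal(sum(f$label == 1L), 3)
  expect_message(filter_controls_by_maf(
    variant_dataset(data.frame(chrom = "1", pos = 1, ref = "A", alt = "G",
                               label = -1))), "dropping 1")
  expect_error(filter_controls_by_maf(
    variant_dataset(data.frame(chrom = "1", pos = 1, ref = "A", alt = "G",
                               label = -1)), missing_maf = "error"),
    "missing maf")
  # empty dataset -> empty dataset
  empty <- subset_dataset_empty()
  expect_equal(nrow(filter_controls_by_maf(empty)), 0)
  # idempotence
  expect_equal(suppressMessages(filter_controls_by_maf(f)), f)
})

test_that("pathogenic overlap removal is an order-preserving key difference", {
  ctrl <- variant_dataset(data.frame(
    chrom = "chr1", pos = 1:5, ref = "A", alt = "G", label = -1L))
  path <- variant_dataset(data.frame(
    chrom = "chr1", pos = c(2L, 4L, 9L), ref = "A", alt = "G", label = 1L))
  out <- remove_pathogenic_overlap(ctrl, path)
  expect_equal(out$pos, c(1L, 3L, 5L))          # brute-force set difference
  # disjoint -> unchanged; subset -> empty
  expect_equal(remove_pathogenic_overlap(ctrl, subset_dataset_empty()), ctrl)
  expect_equal(nrow(remove_pathogenic_overlap(ctrl, ctrl)), 0)
  expect_equal(remove_pathogenic_overlap(out, path), out)  # idempotent
})

test_that("window selection uses symmetric inclusive distance on the same chromosome", {
  pos <- variant_dataset(data.frame(chrom = "chr1", pos = 10000L, ref = "A",
                                    alt = "G", label = 1L))
  neg <- variant_dataset(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(10000L, 11000L, 11001L, 10000L),
    ref = "C", alt = "T", label = -1L))
  kept <- select_negatives_within_window(neg, pos, window = 1000)
  # identical coordinate kept; distance 1000 kept (inclusive); 1001 removed;
  # same coordinate on the wrong chromosome removed
  expect_equal(variant_keys(kept),
               c("chr1:10000:C:T", "chr1:11000:C:T"))
  # window = Inf keeps everything sharing a chromosome with a positive
  expect_equal(nrow(select_negatives_within_window(neg, pos, Inf)), 3)
  # window = 0 keeps only exact-coordinate matches
  expect_equal(variant_keys(select_negatives_within_window(neg, pos, 0)),
               "chr1:10000:C:T")
  expect_equal(select_negatives_within_window(kept, pos, 1000), kept)
})

test_that("coding split partitions and errors on missing flags", {
  d <- toy_dataset()
  sp <- split_by_coding(d)
  expect_equal(nrow(sp$coding) + nrow(sp$noncoding), nrow(d))
  expect_equal(sort(c(variant_keys(sp$coding), variant_keys(sp$noncoding))),
               sort(variant_keys(d)))
  expect_true(all(sp$coding$coding == 1L))
  all_coding <- as.data.frame(d)
  all_coding$coding <- 1L
  sp2 <- split_by_coding(variant_dataset(all_coding))
  expect_equal(nrow(sp2$coding), 6)
  expect_equal(nrow(sp2$noncoding), 0)
  d2 <- as.data.frame(d)
  d2$coding[2] <- NA_integer_
  expect_error(split_by_coding(variant_dataset(d2)), "chr1:500:C:T")
})

test_that("training-set assembly enforces group completeness and balanced sampling", {
  set.seed(5)
  n <- 30
  lab <- rep(c(1L, -1L), c(10L, 20L))
  d <- variant_dataset(data.frame(chrom = "chr1", pos = seq_len(n),
                                  ref = "A", alt = "G", label = lab))
  m1 <- matrix(rnorm(n * 2), n)
  m2 <- matrix(rnorm(n * 2), n)
  m2[lab == -1L, ][seq_len(16), ] <- NA   # only 4 negatives complete in G2
  fs <- feature_group_set(list(G1 = m1, G2 = m2))

  # completeness filter only
  out <- assemble_training_set(d, fs)
  expect_false(any(out$features$group_missing))
  expect_equal(nrow(out$train), 14)

  # balanced to the smaller class: 4 + 4
  bal <- assemble_training_set(d, fs, balanced = TRUE, seed = 11)
  expect_equal(as.vector(table(bal$train$label)), c(4, 4))
  # reproducible for a fixed seed, (almost surely) different across seeds
  bal2 <- assemble_training_set(d, fs, balanced = TRUE, seed = 11)
  expect_identical(variant_keys(bal$train), variant_keys(bal2$train))
  bal3 <- assemble_training_set(d, fs, balanced = TRUE, seed = 12)
  expect_false(identical(variant_keys(bal$train), variant_keys(bal3$train)))

  # requiring only the complete group is the identity (no balancing)
  ident <- assemble_training_set(d, fs, groups = "G1")
  expect_equal(nrow(ident$train), n)

  # n_per_class caps the draw; a class with zero complete examples errors
  capped <- assemble_training_set(d, fs, balanced = TRUE, n_per_class = 2,
                                  seed = 1)
  expect_equal(nrow(capped$train), 4)
  m2[lab == -1L, ] <- NA
  fs2 <- feature_group_set(list(G1 = m1, G2 = m2))
  expect_error(assemble_training_set(d, fs2, balanced = TRUE),
               "zero examples")
})

test_that("feature-group files round-trip with value and group missingness", {
  sim <- generate_synthetic(synthetic_config(
    n_pos = 15, n_neg = 15, group_missing_rate = c(0, 0.3, 0, 0),
    value_missing_rate = 0.1, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_feature_groups(sim$features, sim$dataset, dir)
  back <- read_feature_groups(paths, sim$dataset)
  expect_equal(back$group_missing, sim$features$group_missing)
  for (g in back$group_names)
    expect_equal(back$matrices[[g]], sim$features$matrices[[g]],
                 tolerance = 1e-6)
  # alignment is by key, not file order
  perm <- sample(nrow(sim$dataset))
  write_feature_groups(features_subset(sim$features, perm),
                       subset_rows_ds(sim$dataset, perm), dir)
  back2 <- read_feature_groups(paths, sim$dataset)
  expect_equal(back2$matrices$A, sim$features$matrices$A, tolerance = 1e-6)
  # a dataset variant absent from a feature file is an error
  short <- features_subset(sim$features, 1:10)
  write_feature_groups(short, subset_rows_ds(sim$dataset, 1:10), dir)
  expect_error(read_feature_groups(paths, sim$dataset), "absent")
})
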