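# Feature-group container: one numeric matrix per annotation source,
# aligned to a variant_dataset, with group-level and value-level missingness.

#' Construct a set of per-variant feature-group matrices
#'
#' Each annotation source (e.g. vertebrate conservation scores, ChIP-seq
#' peak indicators) contributes one `variants x features` numeric matrix.
#' `NA` cells are value-level missing; a variant with *no* value in a group
#' is group-level missing there, and at prediction time the kernel weights
#' of its missing groups are renormalized away (see [rescale_weights()]).
#'
#' @param matrices named list of numeric matrices sharing the same row
#'   (variant) order.
#' @param group_missing optional `n x p` logical matrix; default: a row is
#'   group-missing iff all its cells in that group are `NA`. When supplied,
#'   rows flagged group-missing are forced to all-`NA`.
#' @return a `feature_group_set` with fields `group_names`, `matrices`,
#'   `group_missing`.
#' @export
feature_group_set <- function(matrices, group_missing = NULL) {
  if (is.null(names(matrices)) || anyDuplicated(names(matrices)) ||
      any(names(matrices) == ""))
    stop_("matrices must be a uniquely named list")
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- unique(vapply(matrices, nrow, integer(1)))
  if (length(n) != 1L)
    stop_("all feature-group matrices must have the same number of rows")
  p <- length(matrices)
  derived <- vapply(matrices, function(m) rowSums(!is.na(m)) == 0, logical(n))
  derived <- matrix(derived, nrow = n, ncol = p,
                    dimnames = list(NULL, names(matrices)))
  if (is.null(group_missing)) {
    group_missing <- derived
  } else {
    group_missing <- matrix(as.logical(group_missing), nrow = n, ncol = p,
                            dimnames = list(NULL, names(matrices)))
    # flagged group-missing => every cell of that row is value-missing
    for (g in seq_len(p)) matrices[[g]][group_missing[, g], ] <- NA_real_
    if (any(derived & !group_missing))
      group_missing <- group_missing | derived
  }
  structure(list(group_names = names(matrices), matrices = matrices,
                 group_missing = group_missing),
            class = "feature_group_set")
}

#' @export
print.feature_group_set <- function(x, ...) {
  cat("feature_group_set:", nrow(x$group_missing), "variants,",
      length(x$group_names), "groups\n")
  for (g in x$group_names)
    cat(sprintf("  %s: %d features, %d group-missing rows\n", g,
                ncol(x$matrices[[g]]), sum(x$group_missing[, g])))
  invisible(x)
}

#' Subset a feature group set by rows and/or groups
#'
#' @param features a `feature_group_set`.
#' @param idx row indices (logical or integer); default all.
#' @param groups group names to keep; default all.
#' @return a `feature_group_set`.
#' @export
features_subset <- function(features, idx = NULL, groups = NULL) {
  if (is.null(groups)) groups <- features$group_names
  if (is.null(idx)) idx <- seq_len(nrow(features$group_missing))
  feature_group_set(
    lapply(stats::setNames(groups, groups),
           function(g) features$matrices[[g]][idx, , drop = FALSE]),
    group_missing = features$group_missing[idx, groups, drop = FALSE]
  )
}

#' Read / write variant tables
#'
#' `read_variant_table()` reads a labeled variant table in either the
#' tab-delimited dialect (columns `chrom pos ref alt label maf coding`,
#' `#`-prefixed header, `.` for missing values) or a minimal VCF dialect
#' (fixed columns `CHROM POS ID REF ALT QUAL FILTER INFO` with
#' `LABEL=`/`MAF=`/`CODING=` keys in INFO). `write_variant_table()` writes
#' either dialect; the two round-trip to the same dataset.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `read_variant_table()`: a [variant_dataset()];
#'   `write_variant_table()`: the path, invisibly.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "tsv") parse_variant_tsv(lines) else parse_variant_vcf(lines)
}

dot_na <- function(x, as = as.numeric) {
  x[x == "."] <- NA
  suppressWarnings(as(x))
}

parse_variant_tsv <- function(lines) {
  hdr_i <- grep("^#", lines)
  if (!length(hdr_i)) stop_("no '#'-prefixed header line found")
  header <- strsplit(sub("^#\\s*", "", lines[hdr_i[1]]), "\t")[[1]]
  body_i <- setdiff(seq_along(lines), grep("^#|^\\s*$", lines))
  req <- c("chrom", "pos", "ref", "alt", "label")
  if (!all(req %in% header))
    stop_("header must contain columns: ", paste(req, collapse = ", "))
  if (!length(body_i))
    return(variant_dataset(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      label = integer())))
  rows <- strsplit(lines[body_i], "\t")
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop_("malformed row at line ", body_i[bad[1]], ": expected ",
          length(header), " fields, found ", lengths(rows)[bad[1]])
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- header
  badlab <- which(!tab$label %in% c("1", "-1", "0", "+1"))
  if (length(badlab))
    stop_("unknown label token '", tab$label[badlab[1]], "' at line ",
          body_i[badlab[1]])
  df <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                   ref = tab$ref, alt = tab$alt,
                   label = as.integer(sub("^\\+", "", tab$label)),
                   stringsAsFactors = FALSE)
  df$maf <- if ("maf" %in% header) dot_na(tab$maf) else NA_real_
  df$coding <- if ("coding" %in% header) dot_na(tab$coding, as.integer)
               else NA_integer_
  variant_dataset(df)
}

parse_variant_vcf <- function(lines) {
  body_i <- setdiff(seq_along(lines), grep("^#|^\\s*$", lines))
  if (!length(body_i))
    return(variant_dataset(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      label = integer())))
  rows <- strsplit(lines[body_i], "\t")
  bad <- which(lengths(rows) < 8L)
  if (length(bad))
    stop_("malformed VCF record at line ", body_i[bad[1]],
          ": fewer than 8 fields")
  tab <- do.call(rbind, lapply(rows, `[`, 1:8))
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else ".", character(1))
  }
  lab <- info_get(tab[, 8], "LABEL")
  badlab <- which(!lab %in% c("1", "-1", "0", "+1"))
  if (length(badlab))
    stop_("unknown or missing LABEL token at line ", body_i[badlab[1]])
  variant_dataset(data.frame(
    chrom = tab[, 1], pos = as.integer(tab[, 2]), ref = tab[, 4],
    alt = tab[, 5], label = as.integer(sub("^\\+", "", lab)),
    maf = dot_na(info_get(tab[, 8], "MAF")),
    coding = dot_na(info_get(tab[, 8], "CODING"), as.integer),
    stringsAsFactors = FALSE))
}

#' @rdname read_variant_table
#' @param dataset a [variant_dataset()] to write.
#' @export
write_variant_table <- function(dataset, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  na_dot <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                     scientific = FALSE))
  if (dialect == "tsv") {
    lines <- c("#chrom\tpos\tref\talt\tlabel\tmaf\tcoding",
               paste(dataset$chrom, dataset$pos, dataset$ref, dataset$alt,
                     dataset$label, na_dot(dataset$maf),
                     na_dot(dataset$coding), sep = "\t"))
  } else {
    info <- paste0("LABEL=", dataset$label, ";MAF=", na_dot(dataset$maf),
                   ";CODING=", na_dot(dataset$coding))
    lines <- c("##fileformat=VCFv4.2",
               "##INFO=<ID=LABEL,Number=1,Type=Integer,Description=\"Class label\">",
               "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
               "##INFO=<ID=CODING,Number=1,Type=Integer,Description=\"Amino acid substitution flag\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               paste(dataset$chrom, dataset$pos, ".", dataset$ref,
                     dataset$alt, ".", ".", info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write feature-group matrices
#'
#' One tab-delimited file per group: a `#`-prefixed header, first four
#' columns the variant key (`chrom pos ref alt`), remaining columns numeric
#' features with `.` for a missing value. A fully-`.` feature row encodes
#' group-level missingness. Rows are aligned to `dataset` by key; every
#' dataset variant must appear exactly once in every file.
#'
#' @param paths named character vector of file paths (names = group names).
#' @param dataset the companion [variant_dataset()].
#' @return a [feature_group_set()].
#' @export
read_feature_groups <- function(paths, dataset) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop_("paths must be named by feature group")
  keys <- variant_keys(dataset)
  mats <- lapply(paths, function(p) {
    if (!file.exists(p)) stop_("file not found: ", p)
    lines <- readLines(p)
    body <- lines[!grepl("^#|^\\s*$", lines)]
    rows <- strsplit(body, "\t")
    if (length(unique(lengths(rows))) > 1L)
      stop_("ragged rows in ", p)
    tab <- do.call(rbind, rows)
    fk <- variant_key_(tab[, 1], as.integer(tab[, 2]), toupper(tab[, 3]),
                       toupper(tab[, 4]))
    if (anyDuplicated(fk)) stop_("duplicate variant keys in ", p)
    missing <- setdiff(keys, fk)
    if (length(missing))
      stop_("variants absent from ", p, ": ",
            paste(utils::head(missing, 3), collapse = ", "))
    vals <- tab[match(keys, fk), -(1:4), drop = FALSE]
    vals[vals == "."] <- NA
    matrix(as.numeric(vals), nrow = length(keys))
  })
  feature_group_set(mats)
}

#' @rdname read_feature_groups
#' @param features a [feature_group_set()] to write.
#' @param dir output directory; one `<group>.tsv` file per group.
#' @export
write_feature_groups <- function(features, dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(features$group_names, function(g) {
    m <- features$matrices[[g]]
    v <- matrix(ifelse(is.na(m), ".",
                       format(m, trim = TRUE, scientific = FALSE)),
                nrow = nrow(m))
    p <- file.path(dir, paste0(g, ".tsv"))
    writeLines(c(paste0("#chrom\tpos\tref\talt\t",
                        paste0("f", seq_len(ncol(m)), collapse = "\t")),
                 do.call(paste, c(list(dataset$chrom, dataset$pos,
                                       dataset$ref, dataset$alt),
                                  asplit(v, 2), sep = "\t"))),
               p)
    p
  }, character(1))
  invisible(paths)
}
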