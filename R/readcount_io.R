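#' Construct a per-sample read-count profile
#'
#' A sample profile holds nucleotide read counts at every position of the
#' mitochondrial reference axis (positions absent from the input have depth
#' 0) together with the sample metadata used by downstream paired and
#' case/control analyses.
#'
#' @param counts Integer matrix with `L` rows and columns
#'   `A, C, G, T, DEL` (missing columns are added as zeros).
#' @param sample_id Sample identifier (string).
#' @param patient_id Patient identifier for paired tissue analyses.
#' @param tissue One of `"blood"`, `"tumor"`, `"normal_liver"`.
#' @param group One of `"HCC"`, `"NC"`, `"unknown"` (case/control label).
#' @param grade Optional neoplasm histologic grade, integer in 1..4.
#' @param L Genome length; defaults to [rcrs_length()].
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(counts, sample_id, patient_id = sample_id,
                           tissue = "blood", group = "unknown",
                           grade = NA_integer_, L = rcrs_length()) {
  L <- as.integer(L)
  stopifnot(L >= 1)
  if (is.null(dim(counts))) stop("'counts' must be a matrix")
  m <- matrix(0L, nrow = L, ncol = length(MT_SYMBOLS),
              dimnames = list(NULL, MT_SYMBOLS))
  keep <- intersect(colnames(counts), MT_SYMBOLS)
  if (length(keep) == 0) stop("'counts' has no A/C/G/T/DEL columns")
  if (nrow(counts) != L) stop("'counts' must have L rows")
  m[, keep] <- as.integer(round(counts[, keep]))
  if (any(m < 0)) stop("negative read counts are not allowed")
  tissue <- match.arg(tissue, c("blood", "tumor", "normal_liver"))
  group <- match.arg(group, c("HCC", "NC", "unknown"))
  structure(list(
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    tissue = tissue, group = group,
    grade = if (is.na(grade)) NA_integer_ else as.integer(grade),
    L = L, counts = m
  ), class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cs <- coverage_summary(x)
  cat(sprintf(
    "<sample_profile> %s (patient %s, %s, %s)\n  L = %d | covered %.2f%% | mean depth %.1f | polymorphic sites %d\n",
    x$sample_id, x$patient_id, x$tissue, x$group, x$L,
    100 * cs$fraction_covered, cs$mean_depth, cs$n_polymorphic_sites))
  invisible(x)
}

site_depths <- function(profile) rowSums(profile$counts)

#' Parse a bam-readcount-style TSV into a sample profile
#'
#' Consumes the tab-separated dialect written by bam-readcount: columns
#' `chrom, position, ref_base, depth`, then one colon-delimited field per
#' base in which only the base label and its count subfield are used
#' (e.g. `A:49` or `A:49:...`). Positions not present in the stream get
#' depth 0. A stated depth that disagrees with the sum of base counts
#' raises a warning and the depth is recomputed from the counts.
#'
#' @param path Path to the TSV file, or a character vector of lines.
#' @param sample_id,patient_id,tissue,group,grade,L Metadata passed to
#'   [sample_profile()].
#' @return A `sample_profile`.
#' @export
parse_readcounts <- function(path, sample_id, patient_id = sample_id,
                             tissue = "blood", group = "unknown",
                             grade = NA_integer_, L = rcrs_length()) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  m <- matrix(0L, nrow = L, ncol = length(MT_SYMBOLS),
              dimnames = list(NULL, MT_SYMBOLS))
  seen <- integer(0)
  depth_mismatch <- integer(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t|[ ]+")[[1]]
    if (length(f) < 4)
      stop(sprintf("line %d: expected at least 4 fields, got %d", i, length(f)))
    pos <- suppressWarnings(as.integer(f[[2]]))
    if (is.na(pos) || pos < 1 || pos > L)
      stop(sprintf("line %d: position '%s' outside [1, %d]", i, f[[2]], L))
    if (pos %in% seen)
      stop(sprintf("line %d: duplicate position %d", i, pos))
    seen <- c(seen, pos)
    stated_depth <- suppressWarnings(as.integer(f[[4]]))
    if (length(f) >= 5) {
      for (fld in f[5:length(f)]) {
        sub <- strsplit(fld, ":", fixed = TRUE)[[1]]
        sym <- toupper(sub[[1]])
        if (sym == "-" || sym == "=") next  # bam-readcount placeholder fields
        if (substr(sym, 1, 1) == "-") sym <- "DEL"
        if (!sym %in% MT_SYMBOLS) next     # N and insertion fields ignored
        cnt <- suppressWarnings(as.integer(sub[[2]]))
        if (is.na(cnt)) stop(sprintf("line %d: malformed count field '%s'", i, fld))
        if (cnt < 0) stop(sprintf("line %d: negative count in field '%s'", i, fld))
        m[pos, sym] <- m[pos, sym] + cnt
      }
    }
    if (!is.na(stated_depth) && stated_depth != sum(m[pos, ]))
      depth_mismatch <- c(depth_mismatch, pos)
  }
  if (length(depth_mismatch))
    warning(sprintf(
      "depth column disagrees with base-count sum at %d position(s) (e.g. %d); depth recomputed from counts",
      length(depth_mismatch), depth_mismatch[[1]]))
  sample_profile(m, sample_id, patient_id, tissue, group, grade, L)
}

#' Write a profile in the bam-readcount-style dialect
#'
#' Writes one row per covered position (`chrom, position, ref, depth`,
#' then `SYMBOL:count` fields), so that [parse_readcounts()] round-trips
#' the profile exactly. The reference base is written as `N` because the
#' pipeline never consumes it.
#'
#' @param profile A `sample_profile`.
#' @param path Output file path.
#' @param chrom Chromosome label to write (default `"chrM"`).
#' @return `path`, invisibly.
#' @export
write_readcounts <- function(profile, path, chrom = "chrM") {
  depth <- site_depths(profile)
  pos <- which(depth > 0)
  lines <- vapply(pos, function(p) {
    cnts <- profile$counts[p, ]
    flds <- paste0(MT_SYMBOLS, ":", cnts)[cnts > 0]
    paste(c(chrom, p, "N", depth[[p]], flds), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the canonical per-sample counts table
#'
#' Plain TSV with columns `position, A, C, G, T, DEL, depth`, one row per
#' position (including zero-depth positions).
#'
#' @inheritParams write_readcounts
#' @export
write_counts_table <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$L), profile$counts,
                   depth = site_depths(profile), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coverage and polymorphism summary of a profile
#'
#' @param profile A `sample_profile`.
#' @param model An [error_model()] applied before polymorphic sites are
#'   counted (a polymorphic site carries at least two symbols with
#'   nonzero count after filtering); `NULL` counts on the raw counts.
#'   Coverage itself is always computed on the unfiltered counts, since
#'   sample QC precedes filtering calibration.
#' @return List with `fraction_covered`, `mean_depth`,
#'   `n_polymorphic_sites`.
#' @export
coverage_summary <- function(profile, model = error_model()) {
  depth <- site_depths(profile)
  cnts <- if (is.null(model)) profile$counts else filter_profile(profile, model)$counts
  n_poly <- sum(rowSums(cnts > 0) >= 2)
  list(
    fraction_covered = mean(depth >= 1),
    mean_depth = mean(depth),
    n_polymorphic_sites = as.integer(n_poly)
  )
}

#' Coverage-based sample QC
#'
#' Partitions a cohort into samples covering at least `min_fraction` of the
#' genome (depth >= 1) and the rest. Mirrors the pre-processing rule that
#' removes samples with less than 95% of the mtDNA covered.
#'
#' @param cohort List of `sample_profile` objects.
#' @param min_fraction Minimum fraction of covered positions, in (0, 1].
#' @return List with elements `kept` and `dropped`.
#' @export
qc_filter <- function(cohort, min_fraction = 0.95) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (length(cohort) == 0) {
    warning("empty cohort")
    return(list(kept = list(), dropped = list()))
  }
  frac <- vapply(cohort, function(p) coverage_summary(p)$fraction_covered, numeric(1))
  keep <- frac >= min_fraction
  list(kept = cohort[keep], dropped = cohort[!keep])
}

#' Read a cohort manifest
#'
#' TSV with columns `sample_id, patient_id, tissue, group, grade, path`;
#' `path` points at a bam-readcount-style file, resolved relative to the
#' manifest location.
#'
#' @param path Manifest file path.
#' @param L Genome length.
#' @return List of `sample_profile` objects.
#' @export
load_cohort <- function(path, L = rcrs_length()) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "group", "grade", "path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$path[[i]]
    if (!file.exists(f)) f <- file.path(base, man$path[[i]])
    if (!file.exists(f)) stop("manifest path not found: ", man$path[[i]])
    parse_readcounts(f, man$sample_id[[i]], man$patient_id[[i]],
                     man$tissue[[i]], man$group[[i]],
                     if (is.na(man$grade[[i]])) NA_integer_ else man$grade[[i]], L)
  })
}
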