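# On-disk formats: tab-delimited UTF-8 tables (with `#` comments allowed),
# a `length score` TSV for score tables with a JSON metadata sidecar, and
# fragment-length extraction from coordinate-sorted paired-end alignments.

COMPARTMENTS <- c("tissue", "bcp", "preop_plasma", "postop_plasma")

read_tsv_checked <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE)
}

#' Read and write fragment-length tables
#'
#' Fragment tables are TSVs with columns `sample_id`, `length`, `count`;
#' repeated length rows are summed. `write_fragment_table()` /
#' `read_fragment_table()` round-trip any pool exactly.
#'
#' @param path Path to a `.tsv` file.
#' @param source Provenance label for the returned pool.
#' @return `read_fragment_table()` returns a [fragment_pool()].
#' @export
read_fragment_table <- function(path, source = "nonmalignant") {
  tbl <- read_tsv_checked(path, readr::cols(sample_id = "c", length = "d",
                                            count = "d"))
  if (nrow(tbl) == 0) {
    warn(sprintf("fragment table '%s' has no rows; returning an empty pool", path))
    return(fragment_pool(integer(0), sample_id = "empty", source = source))
  }
  bad <- which(tbl$count < 0 | tbl$length != round(tbl$length) | tbl$length < 1)
  if (length(bad) > 0) {
    abort(sprintf("invalid fragment table '%s': non-integer length or negative count at data line %d",
                  path, bad[1]))
  }
  if (dplyr::n_distinct(tbl$sample_id) > 1) {
    abort(sprintf("fragment table '%s' mixes sample_ids; one sample per file", path))
  }
  fragment_pool(counts = tbl[, c("length", "count")],
                sample_id = tbl$sample_id[1], source = source)
}

#' @rdname read_fragment_table
#' @param pool A [fragment_pool()].
#' @export
write_fragment_table <- function(pool, path) {
  tbl <- tibble::tibble(sample_id = attr(pool, "sample_id") %||% "sample",
                        length = pool$length, count = pool$count)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read and write per-compartment variant observation tables
#'
#' Variant tables are TSVs with columns `patient_id`, `compartment`
#' (`tissue`, `bcp`, `preop_plasma`, `postop_plasma`), `chrom`, `pos`
#' (1-based), `ref`, `alt`, `alt_reads`, `depth`, `pipeline_called`.
#' `pipeline_called` distinguishes variants reported by the upstream caller
#' from those with raw supporting reads only. Coordinates are taken as
#' given; allele normalisation is the caller's responsibility.
#'
#' @param path Path to a `.tsv` file.
#' @return A tibble of validated variant observations.
#' @export
read_variant_table <- function(path) {
  tbl <- read_tsv_checked(path, readr::cols(
    patient_id = "c", compartment = "c", chrom = "c", pos = "d",
    ref = "c", alt = "c", alt_reads = "d", depth = "d",
    pipeline_called = "l"))
  validate_variant_table(tbl, path)
}

validate_variant_table <- function(tbl, path = "<in-memory>") {
  bad <- setdiff(unique(tbl$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    abort(sprintf("unknown compartment '%s' in '%s'; allowed: %s",
                  bad[1], path, paste(COMPARTMENTS, collapse = ", ")))
  }
  if (any(tbl$alt_reads > tbl$depth)) {
    abort(sprintf("alt_reads > depth in '%s' (line %d)", path,
                  which(tbl$alt_reads > tbl$depth)[1]))
  }
  if (any(tbl$pos < 1) || any(tbl$alt_reads < 0)) {
    abort(sprintf("positions must be >= 1 and alt_reads >= 0 in '%s'", path))
  }
  dplyr::mutate(tbl, pos = as.integer(.data$pos),
                alt_reads = as.integer(.data$alt_reads),
                depth = as.integer(.data$depth))
}

#' @rdname read_variant_table
#' @param variants A variant observation tibble.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(validate_variant_table(tibble::as_tibble(variants)), path)
  invisible(path)
}

#' Read and write supporting-fragment tables
#'
#' One row per alt-supporting fragment: `patient_id`, `compartment`,
#' `chrom`, `pos`, `ref`, `alt`, `fragment_length`. These are the fragment
#' lengths that enter the variant-level fragmentation score.
#'
#' @param path Path to a `.tsv` file.
#' @return A tibble of supporting fragments.
#' @export
read_support_table <- function(path) {
  tbl <- read_tsv_checked(path, readr::cols(
    patient_id = "c", compartment = "c", chrom = "c", pos = "d",
    ref = "c", alt = "c", fragment_length = "d"))
  bad <- setdiff(unique(tbl$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    abort(sprintf("unknown compartment '%s' in '%s'", bad[1], path))
  }
  if (any(tbl$fragment_length < 1)) {
    abort(sprintf("fragment_length must be >= 1 in '%s'", path))
  }
  dplyr::mutate(tbl, pos = as.integer(.data$pos),
                fragment_length = as.integer(.data$fragment_length))
}

#' @rdname read_support_table
#' @param support A supporting-fragment tibble.
#' @export
write_support_table <- function(support, path) {
  readr::write_tsv(tibble::as_tibble(support), path)
  invisible(path)
}

#' Read and write cohort metadata
#'
#' Columns: `patient_id`, `recurrence` (logical), `followup_months` (>= 0),
#' `adjuvant_status`, `group`.
#'
#' @param path Path to a `.tsv` file.
#' @return A metadata tibble.
#' @export
read_cohort_metadata <- function(path) {
  tbl <- read_tsv_checked(path, readr::cols(
    patient_id = "c", recurrence = "l", followup_months = "d",
    adjuvant_status = "c", group = "c"))
  if (any(is.na(tbl$recurrence))) {
    abort(sprintf("recurrence must be defined for every patient in '%s'", path))
  }
  if (any(tbl$followup_months < 0)) {
    abort(sprintf("followup_months must be >= 0 in '%s'", path))
  }
  tbl
}

#' @rdname read_cohort_metadata
#' @param metadata A cohort metadata tibble.
#' @export
write_cohort_metadata <- function(metadata, path) {
  readr::write_tsv(tibble::as_tibble(metadata), path)
  invisible(path)
}

#' Read and write fragmentation score tables
#'
#' Score tables are TSVs with columns `length`, `score`, plus a JSON
#' sidecar (`<path>.meta.json`) recording the build parameters (n_boot,
#' n_sample, cap, min_count, length_cap, seed). The sidecar is restored on
#' read when present.
#'
#' @param path Path to a `.tsv` file.
#' @return `read_score_table()` returns an `fs_table`.
#' @export
read_score_table <- function(path) {
  tbl <- read_tsv_checked(path, readr::cols(length = "d", score = "d"))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(length_cap = max(tbl$length))
  }
  length_cap <- as.integer(meta$length_cap %||% max(tbl$length))
  full <- numeric(length_cap)
  keep <- tbl$length >= 1 & tbl$length <= length_cap
  full[tbl$length[keep]] <- tbl$score[keep]
  new_fs_table(tibble::tibble(length = seq_len(length_cap), score = full),
               meta)
}

#' @rdname read_score_table
#' @param table An `fs_table` from [build_score_table()].
#' @export
write_score_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table)[, c("length", "score")], path)
  meta <- fs_table_meta(table)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Extract fragment lengths from a paired-end alignment file
#'
#' Harvests one length per unique fragment — the absolute template length
#' (TLEN) of properly-paired, first-in-pair reads — from a deduplicated
#' coordinate-sorted BAM (or SAM, converted on the fly). Duplicate-flagged,
#' secondary and supplementary records are ignored; lengths of 0 or above
#' `length_cap` are discarded.
#'
#' @param path Path to a BAM or SAM file (BAM must be indexed or indexable).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param length_cap Maximum fragment length retained (default 600 bp,
#'   covering the mono- and di-nucleosomal range with margin).
#' @param sample_id Sample identifier for the returned pool.
#' @param source Provenance label.
#' @return A [fragment_pool()].
#' @export
read_fragment_lengths_bam <- function(path, min_mapq = 20, length_cap = 600,
                                      sample_id = NULL,
                                      source = "patient_postop") {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  n_paired <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isPaired = TRUE)))$records
  n_total <- Rsamtools::countBam(path)$records
  if (n_total > 0 && n_paired == 0) {
    abort(paste("alignment file contains only single-end reads;",
                "fragment lengths require paired-end template lengths"))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
      isDuplicate = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE),
    what = "isize", mapqFilter = as.integer(min_mapq))
  lens <- abs(Rsamtools::scanBam(path, param = param)[[1]]$isize)
  lens <- lens[!is.na(lens) & lens > 0 & lens <= length_cap]
  fragment_pool(lens,
                sample_id = sample_id %||% sub("\\.bam$", "", basename(path)),
                source = source)
}

#' Write a fragment pool as a minimal paired-end SAM file
#'
#' Emits one read pair per fragment with TLEN equal to the fragment length,
#' on a single synthetic contig. Intended for generating alignment fixtures
#' from synthetic pools; not a general-purpose SAM writer.
#'
#' @param pool A [fragment_pool()].
#' @param path Output `.sam` path.
#' @param contig,contig_len Synthetic reference name and length.
#' @param seed Optional seed for the random start positions.
#' @return `path`, invisibly.
#' @export
write_sam_fixture <- function(pool, path, contig = "chrS",
                              contig_len = 1e6L, seed = NULL) {
  lens <- rep.int(pool$length, pool$count)
  with_seed_if(seed, {
    pos <- sample.int(contig_len - max(c(lens, 1L)) - 1L, length(lens),
                      replace = TRUE)
    rl <- pmin(lens, 50L)
    mpos <- pos + lens - rl
    qn <- sprintf("frag%06d", seq_along(lens))
    seq1 <- vapply(rl, function(n) strrep("A", n), character(1))
    rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                    qn, contig, pos, rl, mpos, lens, seq1)
    rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                    qn, contig, mpos, rl, pos, -lens, seq1)
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
    writeLines(c(hdr, rec1, rec2), path)
  })
  invisible(path)
}
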