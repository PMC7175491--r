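# Readers and writers for the package's plain-text interchange formats.

#' Write / read a beta matrix as TSV
#'
#' Rows are probes (first column `probe_id`), columns samples; values are
#' written with 4 decimals and missing entries as `NA`.
#'
#' @param betas beta matrix.
#' @param path output file.
#' @return `write_beta_tsv` returns `path` invisibly; `read_beta_tsv`
#'   returns a numeric matrix with probe rownames.
#' @export
write_beta_tsv <- function(betas, path) {
  assert_beta_matrix(betas)
  df <- data.frame(probe_id = rownames(betas),
                   format(round(betas, 4), trim = TRUE, nsmall = 4),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  m
}

#' Write / read a probe manifest as CSV
#'
#' Columns mirror the standard manifest roles: probe id, chromosome, 1-based
#' coordinate, gene symbol, gene-region group, CpG-island relation, SNP flag.
#'
#' @param manifest manifest data.frame.
#' @param path file path.
#' @export
write_manifest_csv <- function(manifest, path) {
  assert_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$gene[is.na(df$gene)] <- ""
  df$snp_flagged <- as.logical(df$snp_flagged)
  assert_manifest(df)
  df
}

#' Write / read a sample sheet (sample_id, group) as CSV
#' @param sheet data.frame with `sample_id` and `group`.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(all(c("sample_id", "group") %in% names(sheet)))
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a long-format intensity TSV
#'
#' Expected columns: `probe_id`, `sample_id`, `M`, `U`, `detection_p`.
#' @param path file path.
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("probe_id", "sample_id", "M", "U", "detection_p")
  if (!all(required %in% names(df))) {
    stop("intensity TSV must have columns probe_id, sample_id, M, U, detection_p",
         call. = FALSE)
  }
  df
}

#' Write a DiffTable as TSV
#' @param table DiffTable from [call_dms()] / [call_dmr()].
#' @param path file path.
#' @export
write_diff_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export flagged units as BED
#'
#' Converts the 1-based inclusive manifest coordinates to BED's 0-based
#' half-open intervals.  Site units span a single CpG; region units span
#' from the smallest to the largest member-probe position.
#'
#' @param table DiffTable.
#' @param annot probe annotation.
#' @param path output BED file.
#' @param regions optional region definition (from [aggregate_regions()])
#'   when `table` holds region units.
#' @param flagged_only export only flagged (DMS/DMR) units (default TRUE).
#' @export
write_bed <- function(table, annot, path, regions = NULL, flagged_only = TRUE) {
  assert_manifest(annot, "annot")
  flag_col <- intersect(c("is_dms", "is_dmr"), names(table))[1]
  tab <- if (flagged_only) table[table[[flag_col]], , drop = FALSE] else table
  if (is.null(regions)) {
    idx <- match(tab$unit_id, annot$probe_id)
    bed <- data.frame(chrom = annot$chrom[idx],
                      start = annot$pos[idx] - 1L,
                      end = annot$pos[idx],
                      name = tab$unit_id,
                      score = 0L,
                      strand = ".")
  } else {
    ridx <- match(tab$unit_id, regions$region_id)
    coords <- lapply(regions$members[ridx], function(ids) {
      p <- annot$pos[match(ids, annot$probe_id)]
      ch <- annot$chrom[match(ids, annot$probe_id)]
      c(chrom = ch[1], start = min(p) - 1L, end = max(p))
    })
    bed <- data.frame(chrom = vapply(coords, `[[`, character(1), "chrom"),
                      start = as.integer(vapply(coords, `[[`, character(1), "start")),
                      end = as.integer(vapply(coords, `[[`, character(1), "end")),
                      name = tab$unit_id,
                      score = 0L,
                      strand = ".")
  }
  bed <- bed[!is.na(bed$chrom), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a nested report as JSON
#' @param report a list.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
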