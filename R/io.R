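# --- plain-text writers/readers ----------------------------------------------
# All BED-like outputs use 1-based inclusive coordinates, declared in a
# header comment line.

#' Write and read a founder panel
#'
#' `write_panel_tsv()` stores the marker map and 8 founder allele columns
#' as TSV; `write_panel_vcf()` writes a minimal VCF with one sample column
#' per founder (homozygous 0/0 / 1/1 genotypes); `read_panel_tsv()` reads
#' the TSV form back.
#'
#' @param panel a `founder_panel`
#' @param path output file path
#' @return the path, invisibly (`read_panel_tsv()` returns a
#'   `founder_panel`)
#' @export
write_panel_tsv <- function(panel, path) {
  validate_panel(panel)
  df <- cbind(data.frame(marker = panel$map$marker, chrom = panel$chrom,
                         pos_bp = panel$map$pos_bp, cM = panel$map$cM),
              as.data.frame(panel$alleles))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @param chrom_length_bp chromosome length for the reconstructed panel
#' @export
read_panel_tsv <- function(path, chrom_length_bp = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = NA)
  alleles <- as.matrix(df[, do_founders()])
  structure(list(
    chrom = as.character(df$chrom[1]),
    map = tibble::tibble(marker = as.character(df$marker),
                         pos_bp = as.integer(df$pos_bp), cM = df$cM),
    alleles = alleles,
    ibd_truth = check_ibd_spec(NULL, Inf),
    chrom_length_bp = chrom_length_bp %||% max(df$pos_bp)
  ), class = "founder_panel")
}

#' @rdname write_panel_tsv
#' @export
write_panel_vcf <- function(panel, path) {
  validate_panel(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom,
            as.integer(panel$chrom_length_bp)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", do_founders()), collapse = "\t")
  ), con)
  gt <- matrix(c("0/0", "1/1")[panel$alleles + 1L], nrow(panel$alleles), 8)
  body <- cbind(panel$chrom, panel$map$pos_bp, panel$map$marker, "A", "T",
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a sample x marker matrix as TSV
#'
#' Header row is `sample` followed by marker ids; one row per sample.
#'
#' @param mat samples x markers matrix with dimnames
#' @param path output path
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  m
}

#' Write allele depths as a pair of TSV matrices
#'
#' @param depths an `allele_depths` object
#' @param prefix path prefix; writes `<prefix>.ref.tsv` and
#'   `<prefix>.alt.tsv`
#' @export
write_depths_tsv <- function(depths, prefix) {
  write_matrix_tsv(depths$ref, paste0(prefix, ".ref.tsv"))
  write_matrix_tsv(depths$alt, paste0(prefix, ".alt.tsv"))
  invisible(prefix)
}

#' Write mosaics as BED-like segments
#'
#' Columns: chrom, start_bp, end_bp (1-based inclusive), sample, homolog,
#' founder.
#'
#' @param mosaics a `do_cohort`
#' @param path output path
#' @export
write_mosaics_bed <- function(mosaics, path) {
  chrom <- attr(mosaics, "chrom") %||% "1"
  rows <- purrr::imap(unclass(mosaics), function(m, i) {
    dplyr::mutate(tidy.do_mosaic(m), sample = sprintf("S%03d", as.integer(i)),
                  chrom = chrom)
  }) |> purrr::list_rbind()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  write.table(rows[, c("chrom", "start_bp", "end_bp", "sample", "homolog", "founder")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write IBD segments as BED-like TSV
#'
#' @param segments an `ibd_segments` tibble
#' @param path output path
#' @export
write_ibd_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  write.table(as.data.frame(segments)[, c("chrom", "start_bp", "end_bp",
                                          "founder1", "founder2", "lod",
                                          "n_markers")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
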