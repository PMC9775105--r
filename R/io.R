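#' Write the two parental genotype tables as a joint VCF
#'
#' Emits a VCF v4.2 file with two sample columns (`MOTHER`, `FATHER`) and
#' a `GT:DP:GQ` FORMAT, one record per site shared by the two tables.
#'
#' @param parents An `"mzt_parents"` object, or a list with `maternal`
#'   and `paternal` genotype data frames on identical sites.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parents_vcf <- function(parents, path) {
  m <- parents$maternal; f <- parents$paternal
  stopifnot(identical(m[c("chrom", "pos", "ref", "alt")],
                      f[c("chrom", "pos", "ref", "alt")]))
  contigs <- unique(m$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "MOTHER", "FATHER", sep = "\t")
  )
  body <- paste(m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", ".",
                "GT:DP:GQ",
                paste(m$gt, m$dp, m$gq, sep = ":"),
                paste(f$gt, f$dp, f$gq, sep = ":"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a joint parental VCF back into two genotype tables
#'
#' @param path VCF file with two sample columns (mother first) and a
#'   `GT:DP:GQ` FORMAT, as written by [write_parents_vcf()].
#' @return A list with `maternal` and `paternal` genotype data frames
#'   (`chrom`, `pos`, `ref`, `alt`, `gt`, `dp`, `gq`).
#' @export
read_parents_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  mk <- function(j) {
    g <- unname(gt[, j])
    g[is.na(g)] <- "./."  # vcfR renders missing genotypes as NA
    data.frame(
      chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
      alt = fix$ALT, gt = g, dp = as.integer(dp[, j]),
      gq = as.integer(gq[, j]), stringsAsFactors = FALSE
    )
  }
  list(maternal = mk(1), paternal = mk(2))
}

#' Write and read gene annotation as BED6
#'
#' Gene intervals are stored 0-based half-open in memory, matching the BED
#' convention directly: a gene covering 1-based bases 1..100 is written as
#' start 0, end 100.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the gene
#'   data frame.
#' @export
write_genes_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand == ".", "*", genes$strand)
  )
  gr$name <- genes$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(strand == "*", ".", strand),
    stringsAsFactors = FALSE
  )
}

#' Tabular writers and readers for allele counts, markers and expression
#'
#' Plain TSV round-trips for the pipeline's tabular interchange formats:
#' per-sample allele counts at marker sites (positions 1-based), the
#' marker table, and gene-by-sample expression matrices.
#'
#' @param x The table/matrix to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the object.
#' @name tabular_io
NULL

#' @rdname tabular_io
#' @export
write_allele_counts <- function(x, path) {
  cols <- c("sample", "stage", "replicate", "chrom", "pos",
            "maternal_reads", "paternal_reads", "other_reads")
  stopifnot(all(cols %in% names(x)))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_allele_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(sample = "character", stage = "character",
                                   chrom = "character"))
}

#' @rdname tabular_io
#' @export
write_markers <- function(x, path) {
  cols <- intersect(c("chrom", "pos", "maternal_allele", "paternal_allele",
                      "gene_id"), names(x))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_markers <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname tabular_io
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tabular_io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  m
}

#' Write a per-cytosine methylation report
#'
#' Bismark-style CpG report: one row per cytosine with 1-based position,
#' strand, context and methylated/unmethylated read counts, tab-separated
#' with a header line.
#'
#' @param sites Site table (`chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_unmethylated`).
#' @param path File path.
#' @return `path`, invisibly.
#' @seealso [read_cpg_report()]
#' @export
write_cpg_report <- function(sites, path) {
  cols <- c("chrom", "pos", "strand", "context",
            "count_methylated", "count_unmethylated")
  stopifnot(all(cols %in% names(sites)))
  utils::write.table(sites[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a full set of synthetic fixtures to a directory
#'
#' Serializes whichever simulator outputs are supplied: the parental VCF,
#' gene BED, marker TSV, allele-count TSV, expression TSVs and CpG reports.
#'
#' @param dir Output directory (created if missing).
#' @param parents,embryos,methylomes,sperm_expr Simulator outputs
#'   (any may be `NULL`).
#' @return Character vector of written file paths, invisibly.
#' @export
write_fixtures <- function(dir, parents = NULL, embryos = NULL,
                           methylomes = NULL, sperm_expr = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(0)
  if (!is.null(parents)) {
    paths <- c(paths,
               write_parents_vcf(parents, file.path(dir, "parents.vcf")),
               write_genes_bed(parents$genes, file.path(dir, "genes.bed")),
               write_markers(parents$markers, file.path(dir, "markers.tsv")))
  }
  if (!is.null(embryos)) {
    paths <- c(paths,
               write_allele_counts(embryos$allele_counts,
                                   file.path(dir, "allele_counts.tsv")))
    for (cr in names(embryos$expression))
      paths <- c(paths, write_expression(
        embryos$expression[[cr]],
        file.path(dir, paste0("expression_", cr, ".tsv"))))
  }
  if (!is.null(methylomes)) {
    for (g in c("X", "Y"))
      for (i in seq_along(methylomes[[g]]))
        paths <- c(paths, write_cpg_report(
          methylomes[[g]][[i]],
          file.path(dir, sprintf("cpg_%s_r%d.tsv", g, i))))
  }
  if (!is.null(sperm_expr)) {
    paths <- c(paths, write_expression(sperm_expr$counts,
                                       file.path(dir, "sperm_expression.tsv")))
  }
  invisible(paths)
}
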