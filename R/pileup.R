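#' Pileup counting and allele frequencies
#'
#' Assigned reads are condensed into per-position base counts; only
#' bases with phred quality >= 30 contribute to either the allele counts
#' or the depth, and primer-derived offsets are masked by default. The
#' resulting count table is also the package's external input format, so
#' users who prefer a bwa/samtools/bam-readcount mapping stage can feed
#' its per-position counts in directly.
#'
#' @name pileup_counts
NULL

#' Build per-position base counts from assigned reads
#'
#' Reads are placed on their amplicon at the assigned offset in amplicon
#' orientation; each covered position contributes the read base when its
#' quality passes `min_base_q`. N bases and sub-threshold bases are
#' excluded from both the allele count and the depth. Placement is
#' ungapped: the rare read whose best alignment requires an indel still
#' contributes its matching positions, and indel alleles are supported
#' through the external count-table route.
#'
#' @param assigned output of [assign_reads()].
#' @param panel `amplicon_panel` (anchored panels yield genomic
#'   coordinates and plus-strand alleles).
#' @param min_base_q minimum phred base quality to count.
#' @param mask_primers drop primer-derived offsets (see
#'   [primer_mask_offsets()]).
#' @return a count table: one row per (sample, amplicon, offset, allele)
#'   with columns `sample_id`, `amplicon`, `offset`, `chrom`, `pos`,
#'   `ref`, `allele`, `count`, `depth`. `ref` and `allele` are reported
#'   on the genomic plus strand when the panel is anchored, otherwise in
#'   amplicon orientation.
#' @export
build_pileup <- function(assigned, panel, min_base_q = 30L,
                         mask_primers = TRUE) {
  stopifnot(inherits(panel, "amplicon_panel"))
  asg <- assigned[assigned$assigned, , drop = FALSE]
  empty <- data.frame(sample_id = character(0), amplicon = character(0),
                      offset = integer(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      allele = character(0), count = integer(0),
                      depth = integer(0), stringsAsFactors = FALSE)
  if (nrow(asg) == 0L) return(empty)
  amp_len <- setNames(panel$amplicons$length, panel$amplicons$name)
  pieces <- vector("list", nrow(asg))
  for (r in seq_len(nrow(asg))) {
    minus <- asg$strand[r] == "-"
    bases <- if (minus) revcomp(asg$bases[r]) else asg$bases[r]
    q <- phred_ints(asg$quals[r])
    if (minus) q <- rev(q)
    len <- nchar(bases)
    off <- asg$offset[r] + seq_len(len) - 1L
    keep <- off <= amp_len[[asg$amplicon[r]]]
    pieces[[r]] <- data.table(sample_id = asg$sample_id[r],
                              amplicon = asg$amplicon[r],
                              offset = off[keep],
                              base = strsplit(bases, "", fixed = TRUE)[[1L]][keep],
                              q = q[keep])
  }
  dt <- rbindlist(pieces)
  dt <- dt[q >= min_base_q & base %chin% DNA_BASES]
  if (nrow(dt) == 0L) return(empty)
  counts <- dt[, .(count = .N), by = .(sample_id, amplicon, offset, base)]
  counts[, depth := sum(count), by = .(sample_id, amplicon, offset)]
  setnames(counts, "base", "allele")
  finalize_count_table(as.data.frame(counts), panel,
                       mask_primers = mask_primers)
}

# attach amplicon-space reference base, genomic coordinates and
# plus-strand alleles; optionally drop primer-masked offsets
finalize_count_table <- function(df, panel, mask_primers = TRUE) {
  a <- panel$amplicons
  i <- panel_row(panel, df$amplicon)
  if (mask_primers) {
    fwd <- a$fwd_primer_len[i]
    rev <- a$rev_primer_len[i]
    keep <- df$offset > fwd & df$offset <= a$length[i] - rev
    df <- df[keep, , drop = FALSE]
    i <- i[keep]
  }
  ref_amp <- substring(a$sequence[i], df$offset, df$offset)
  if (is_anchored(panel)) {
    g <- amplicon_to_genome(panel, df$amplicon, df$offset)
    minus <- a$strand[i] == "-"
    df$chrom <- g$chrom
    df$pos <- g$pos
    df$ref <- ifelse(minus, complement_base(ref_amp), ref_amp)
    df$allele <- ifelse(minus & df$allele %in% DNA_BASES,
                        complement_base(df$allele), df$allele)
  } else {
    df$chrom <- NA_character_
    df$pos <- NA_integer_
    df$ref <- ref_amp
  }
  cols <- c("sample_id", "amplicon", "offset", "chrom", "pos", "ref",
            "allele", "count", "depth")
  df <- df[order(df$sample_id, df$amplicon, df$offset, df$allele),
           cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Compute allele frequencies from a count table
#'
#' One variant observation is emitted per non-reference allele with at
#' least one supporting read; the allele frequency is the allele count
#' divided by the position depth. Columns shallower than `min_depth`
#' are skipped entirely: their logit allele frequencies are too
#' unstable to inform the noise model.
#'
#' @param counts count table from [build_pileup()],
#'   [simulate_pileup_counts()] or [read_count_table()].
#' @param panel optional `amplicon_panel`; when supplied with
#'   `mask_primers = TRUE`, primer-derived offsets are excluded (used
#'   for externally produced count tables that still contain them).
#' @param min_depth minimum qualifying depth for a column to yield
#'   observations.
#' @param mask_primers see `panel`.
#' @return data frame of variant observations: `sample_id`, `amplicon`,
#'   `offset`, `chrom`, `pos`, `ref`, `alt`, `count`, `depth`, `af`.
#' @export
compute_af <- function(counts, panel = NULL, min_depth = 100L,
                       mask_primers = TRUE) {
  df <- as.data.frame(counts)
  if (!is.null(panel) && mask_primers && nrow(df)) {
    a <- panel$amplicons
    i <- panel_row(panel, df$amplicon)
    df <- df[df$offset > a$fwd_primer_len[i] &
               df$offset <= a$length[i] - a$rev_primer_len[i], , drop = FALSE]
  }
  df <- df[df$depth >= min_depth & df$allele != df$ref & df$count >= 1L, ,
           drop = FALSE]
  out <- data.frame(sample_id = df$sample_id, amplicon = df$amplicon,
                    offset = as.integer(df$offset), chrom = df$chrom,
                    pos = df$pos, ref = df$ref, alt = df$allele,
                    count = as.integer(df$count),
                    depth = as.integer(df$depth),
                    af = df$count / df$depth,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read the count-table TSV
#'
#' The TSV carries exactly the count-table columns
#' (`sample_id`, `amplicon`, `offset`, `chrom`, `pos`, `ref`, `allele`,
#' `count`, `depth`). A bam-readcount line maps onto it as: field 1 ->
#' `chrom`, field 2 -> `pos`, field 3 -> `ref`, field 4 -> `depth`, and
#' one row per per-base block with its base as `allele` and its count as
#' `count`; `amplicon`/`offset` then follow from [genome_to_amplicon()].
#'
#' @param counts count table.
#' @param path TSV path.
#' @return `path` (writer, invisibly) or the count table (reader).
#' @export
write_count_table <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path,
                               call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  chrom = "character"))
  needed <- c("sample_id", "amplicon", "offset", "ref", "allele",
              "count", "depth")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("count table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(df$chrom)) df$chrom <- NA_character_
  if (is.null(df$pos)) df$pos <- NA_integer_
  df
}
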