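#' Exporting calls as TSV and VCF
#'
#' @name reporting
NULL

#' Assemble the flat calls table of a run
#'
#' @param run an `amplicall_run`.
#' @param annotated_only keep only mutations surviving annotation.
#' @return data frame with columns `sample_id`, `patient_id`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `af`, `count`, `depth`, `residual`,
#'   `z_excess`, `status`, `reason`, `recurrence`.
#' @export
calls_table <- function(run, annotated_only = TRUE) {
  calls <- run$calls
  if (annotated_only)
    calls <- calls[calls$status == "annotated", , drop = FALSE]
  sheet <- run$sample_sheet
  m <- match(calls$sample_id, sheet$sample_id)
  calls$patient_id <- sheet$patient_id[m]
  rec <- run$recurrence
  if (!is.null(rec) && nrow(calls)) {
    rk <- paste(rec$patient_id, rec$chrom, rec$pos, rec$ref, rec$alt,
                sep = ":")
    ck <- paste(calls$patient_id, calls$chrom, calls$pos, calls$ref,
                calls$alt, sep = ":")
    calls$recurrence <- rec$classification[match(ck, rk)]
  } else {
    calls$recurrence <- rep(NA_character_, nrow(calls))
  }
  cols <- c("sample_id", "patient_id", "gene", "chrom", "pos", "ref",
            "alt", "af", "count", "depth", "residual", "z_excess",
            "status", "reason", "recurrence")
  out <- calls[, cols, drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$pos, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write calls to TSV or VCF 4.2
#'
#' The TSV carries one row per (sample, mutation) with model
#' diagnostics; the VCF carries one record per distinct mutation with
#' per-sample `AF:DP:AD` genotype fields and the maximum residual
#' excess in `INFO/ZEXC`.
#'
#' @param x an `amplicall_run` or a calls table ([calls_table()]).
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  tab <- if (inherits(x, "amplicall_run")) calls_table(x) else
    as.data.frame(x)
  if (format == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_calls_vcf(tab, path)
  }
  invisible(path)
}

#' Read a calls TSV back
#' @param path TSV written by [write_calls()].
#' @return calls table data frame.
#' @export
read_calls <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(sample_id = "character",
                            chrom = "character"))
}

write_calls_vcf <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- sort(unique(tab$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=amplicall",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Catalogue gene symbol\">",
    "##INFO=<ID=ZEXC,Number=1,Type=Float,Description=\"Maximum residual excess over the noise model, in residual SDs\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Qualifying read depth\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(header, con)
  if (nrow(tab) == 0L) return(invisible(path))
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  for (k in unique(key[order(tab$chrom, tab$pos, tab$alt)])) {
    rows <- tab[key == k, , drop = FALSE]
    gt <- setNames(rep("./.:.:.", length(samples)), samples)
    ok <- match(rows$sample_id, samples)
    gt[ok] <- sprintf("%.6g:%d:%d", rows$af, rows$depth, rows$count)
    gene <- rows$gene[1L]
    info <- sprintf("GENE=%s;ZEXC=%.4f",
                    if (is.na(gene)) "." else gene, max(rows$z_excess))
    writeLines(paste(c(rows$chrom[1L], rows$pos[1L], ".", rows$ref[1L],
                       rows$alt[1L], ".", "PASS", info, "AF:DP:AD", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
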