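#' Catalogue annotation of called mutations
#'
#' Only alterations already recorded in the somatic-mutation catalogue
#' are reported, and catalogue entries flagged as germline SNPs are
#' excluded. Matching is exact on `(chrom, pos, ref, alt)` -- position
#' alone would annotate a different substitution at a shared hotspot.
#'
#' @param calls output of [call_mutations()]; rows must carry genomic
#'   coordinates (i.e. the panel was anchored).
#' @param catalogue data frame from [load_catalogue()].
#' @return the calls table with `gene` and `variant_id` columns;
#'   `called` rows become `annotated` when they match a non-SNP
#'   catalogue entry, otherwise `rejected` with reason
#'   `"not-in-catalogue"` or `"snp"`. Rows that were not `called` pass
#'   through unchanged. Annotation never alters allele frequencies,
#'   residuals or coordinates, and is idempotent.
#' @export
annotate_and_filter <- function(calls, catalogue) {
  calls <- as.data.frame(calls)
  calls$gene <- calls$gene %||% NA_character_
  calls$variant_id <- calls$variant_id %||% NA_character_
  todo <- calls$status %in% c("called", "annotated")
  if (!any(todo)) return(calls)
  if (anyNA(calls$chrom[todo]) || anyNA(calls$pos[todo]))
    stop("annotation requires genomic coordinates; anchor the panel first",
         call. = FALSE)
  hit <- catalogue_lookup(catalogue, calls$chrom[todo], calls$pos[todo],
                          calls$ref[todo], calls$alt[todo])
  status <- ifelse(is.na(hit), "rejected",
                   ifelse(catalogue$is_snp[hit], "rejected", "annotated"))
  reason <- ifelse(is.na(hit), "not-in-catalogue",
                   ifelse(catalogue$is_snp[hit], "snp", NA_character_))
  calls$status[todo] <- status
  calls$reason[todo] <- reason
  calls$gene[todo] <- ifelse(is.na(hit), NA_character_, catalogue$gene[hit])
  calls$variant_id[todo] <- ifelse(is.na(hit), NA_character_,
                                   catalogue$variant_id[hit])
  calls
}
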