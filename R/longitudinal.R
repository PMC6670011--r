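#' Longitudinal tracking of mutations across serial samples
#'
#' Annotated mutations are followed over a patient's serial cfDNA
#' samples: a mutation key present in at least two samples of the same
#' patient is *recurrent* (not necessarily in consecutive samples), one
#' present in exactly one sample is *sporadic*. Cohort summaries report
#' the mutation burden per sample, the allele-frequency distribution,
#' and a rank-based comparison of recurrent vs sporadic allele
#' frequencies; replicate concordance quantifies reproducibility of
#' independent library preparations of the same sample.
#'
#' @name longitudinal
NULL

#' Load a sample sheet
#'
#' TSV with header `sample_id`, `patient_id`, `time_index`,
#' `clinical_status` (`regressive`/`stable`/`progressive`/`unknown`)
#' and optional `replicate_of`.
#'
#' @param path sample-sheet TSV path.
#' @return validated data frame ordered by patient and time.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path,
                               call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  required <- c("sample_id", "patient_id", "time_index")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(df$clinical_status)) df$clinical_status <- "unknown"
  if (is.null(df$replicate_of)) df$replicate_of <- NA_character_
  df$time_index <- as.numeric(df$time_index)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  dup_time <- stats::aggregate(time_index ~ patient_id, df,
                               function(x) anyDuplicated(x) > 0L)
  if (any(dup_time$time_index))
    stop("time points must be strictly increasing within a patient: ",
         paste(dup_time$patient_id[dup_time$time_index], collapse = ", "),
         call. = FALSE)
  df[order(df$patient_id, df$time_index), , drop = FALSE]
}

mutation_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

annotated_only <- function(calls) {
  calls[calls$status == "annotated", , drop = FALSE]
}

#' Classify a patient's mutations as recurrent or sporadic
#'
#' @param annotated annotated calls ([annotate_and_filter()]), any
#'   number of patients; rows with `status != "annotated"` are ignored.
#' @param sample_sheet data frame mapping `sample_id` to `patient_id`
#'   and `time_index`.
#' @param patient_id single patient to classify.
#' @return data frame with one row per distinct mutation key:
#'   `patient_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `n_samples`,
#'   `classification` (`recurrent`/`sporadic`). For single-sample
#'   patients classification is undefined: all rows carry `NA` (the
#'   unavailable sentinel).
#' @export
classify_recurrence <- function(annotated, sample_sheet, patient_id) {
  sheet <- sample_sheet[sample_sheet$patient_id == patient_id, ,
                        drop = FALSE]
  ann <- annotated_only(annotated)
  ann <- ann[ann$sample_id %in% sheet$sample_id, , drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(patient_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      n_samples = integer(0),
                      classification = character(0),
                      stringsAsFactors = FALSE))
  key <- mutation_key(ann)
  first <- !duplicated(key)
  n_samples <- vapply(split(ann$sample_id, key), function(x)
    length(unique(x)), integer(1))[key[first]]
  cls <- if (nrow(sheet) < 2L) rep(NA_character_, sum(first)) else
    ifelse(n_samples >= 2L, "recurrent", "sporadic")
  out <- data.frame(patient_id = patient_id, chrom = ann$chrom[first],
                    pos = ann$pos[first], ref = ann$ref[first],
                    alt = ann$alt[first], gene = ann$gene[first],
                    n_samples = unname(n_samples),
                    classification = unname(cls),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

classify_all <- function(annotated, sample_sheet) {
  out <- do.call(rbind, lapply(unique(sample_sheet$patient_id),
                               function(p)
                                 classify_recurrence(annotated,
                                                     sample_sheet, p)))
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  out
}

#' Cohort-level summary of annotated mutations
#'
#' @param annotated annotated calls across the cohort.
#' @param sample_sheet cohort sample sheet; samples without any
#'   annotated mutation count as zero-burden samples.
#' @return a `cohort_summary` list: `n_samples`, `n_mutations`,
#'   `mean_mutations_per_sample`, `af_median`/`af_min`/`af_max`,
#'   `per_gene` counts, `by_status` (mutation counts and AF summaries
#'   per clinical status), and `recurrence` with mean AFs of recurrent
#'   vs sporadic mutations and the two-sample Wilcoxon rank-sum
#'   p-value comparing their allele frequencies.
#' @export
summarize_cohort <- function(annotated, sample_sheet) {
  ann <- annotated_only(annotated)
  ann <- ann[ann$sample_id %in% sample_sheet$sample_id, , drop = FALSE]
  per_sample <- table(factor(ann$sample_id,
                             levels = sample_sheet$sample_id))
  status_of <- setNames(sample_sheet$clinical_status,
                        sample_sheet$sample_id)
  by_status <- if (nrow(ann)) {
    sp <- split(ann$af, status_of[ann$sample_id])
    data.frame(clinical_status = names(sp),
               n_mutations = lengths(sp),
               af_median = vapply(sp, median, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else NULL
  cls <- classify_all(ann, sample_sheet)
  recurrence <- list(n_recurrent = NA_integer_, n_sporadic = NA_integer_,
                     af_recurrent_median = NA_real_,
                     af_sporadic_median = NA_real_,
                     wilcox_p = NA_real_)
  if (!is.null(cls) && nrow(cls) && !all(is.na(cls$classification))) {
    cls_of <- setNames(cls$classification,
                       paste(cls$patient_id, cls$chrom, cls$pos, cls$ref,
                             cls$alt, sep = ":"))
    patient_of <- setNames(sample_sheet$patient_id,
                           sample_sheet$sample_id)
    ann_cls <- cls_of[paste(patient_of[ann$sample_id], mutation_key(ann),
                            sep = ":")]
    af_rec <- ann$af[!is.na(ann_cls) & ann_cls == "recurrent"]
    af_spo <- ann$af[!is.na(ann_cls) & ann_cls == "sporadic"]
    recurrence$n_recurrent <- sum(cls$classification == "recurrent",
                                  na.rm = TRUE)
    recurrence$n_sporadic <- sum(cls$classification == "sporadic",
                                 na.rm = TRUE)
    recurrence$af_recurrent_median <-
      if (length(af_rec)) median(af_rec) else NA_real_
    recurrence$af_sporadic_median <-
      if (length(af_spo)) median(af_spo) else NA_real_
    if (length(af_rec) && length(af_spo))
      recurrence$wilcox_p <- wilcox.test(af_rec, af_spo,
                                         exact = FALSE)$p.value
  }
  structure(list(
    n_samples = nrow(sample_sheet),
    n_mutations = nrow(ann),
    mean_mutations_per_sample = mean(per_sample),
    mutations_per_sample = as.data.frame(per_sample,
                                         responseName = "n_mutations",
                                         stringsAsFactors = FALSE),
    af_median = if (nrow(ann)) median(ann$af) else NA_real_,
    af_min = if (nrow(ann)) min(ann$af) else NA_real_,
    af_max = if (nrow(ann)) max(ann$af) else NA_real_,
    per_gene = if (nrow(ann))
      as.data.frame(sort(table(ann$gene), decreasing = TRUE),
                    responseName = "n_mutations",
                    stringsAsFactors = FALSE) else NULL,
    by_status = by_status,
    recurrence = recurrence), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d sample(s), %d annotated mutation(s)\n",
              x$n_samples, x$n_mutations))
  cat(sprintf("  mean %.2f mutations/sample; AF median %.3g (range %.3g-%.3g)\n",
              x$mean_mutations_per_sample, x$af_median, x$af_min, x$af_max))
  r <- x$recurrence
  if (!is.na(r$n_recurrent))
    cat(sprintf("  %d recurrent vs %d sporadic mutations (Wilcoxon p = %.3g)\n",
                r$n_recurrent, r$n_sporadic, r$wilcox_p))
  invisible(x)
}

#' Concordance of two replicate call sets
#'
#' @param calls1,calls2 annotated calls of two independent replicates of
#'   the same sample (same panel).
#' @param mode `"intersection"` computes the correlations over mutations
#'   detected in both replicates (how replicate scatter plots are
#'   usually drawn); `"union"` scores absent calls as allele frequency
#'   zero.
#' @return list with `pearson_r`, `spearman_rho`, `n_shared`,
#'   `n_unique_1`, `n_unique_2` and the per-key AF table.
#'   With fewer than 3 keys to correlate, correlations are `NA`.
#' @export
replicate_concordance <- function(calls1, calls2,
                                  mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  a1 <- annotated_only(as.data.frame(calls1))
  a2 <- annotated_only(as.data.frame(calls2))
  k1 <- setNames(a1$af, mutation_key(a1))
  k2 <- setNames(a2$af, mutation_key(a2))
  shared <- intersect(names(k1), names(k2))
  keys <- if (mode == "union") union(names(k1), names(k2)) else shared
  af1 <- ifelse(keys %in% names(k1), k1[keys], 0)
  af2 <- ifelse(keys %in% names(k2), k2[keys], 0)
  ok <- length(keys) >= 3L
  list(pearson_r = if (ok) cor(af1, af2) else NA_real_,
       spearman_rho = if (ok) cor(af1, af2, method = "spearman") else
         NA_real_,
       n_shared = length(shared),
       n_unique_1 = length(setdiff(names(k1), names(k2))),
       n_unique_2 = length(setdiff(names(k2), names(k1))),
       af = data.frame(key = keys, af_1 = unname(af1), af_2 = unname(af2),
                       stringsAsFactors = FALSE))
}

#' Long-format trajectory table for plotting per-patient AF courses
#'
#' @param annotated annotated calls.
#' @param sample_sheet cohort sample sheet.
#' @return data frame `patient_id`, `mutation`, `gene`, `time_index`,
#'   `clinical_status`, `af`, suitable for per-patient trajectory plots.
#' @export
trajectory_table <- function(annotated, sample_sheet) {
  ann <- annotated_only(annotated)
  ann <- ann[ann$sample_id %in% sample_sheet$sample_id, , drop = FALSE]
  m <- match(ann$sample_id, sample_sheet$sample_id)
  out <- data.frame(patient_id = sample_sheet$patient_id[m],
                    mutation = mutation_key(ann),
                    gene = ann$gene,
                    time_index = sample_sheet$time_index[m],
                    clinical_status = sample_sheet$clinical_status[m],
                    af = ann$af, stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$mutation, out$time_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
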