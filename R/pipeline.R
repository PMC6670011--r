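#' End-to-end calling pipeline
#'
#' Ties the stages together: trim reads, assign them to amplicons,
#' build the pileup, compute allele frequencies, fit the per-amplicon
#' noise models, call and annotate mutations, and summarise the cohort
#' longitudinally. Every read and observation dropped along the way is
#' accounted for in a stage-by-stage audit, and a run is deterministic
#' given its inputs.
#'
#' @name cli_reporting
NULL

default_params <- function() {
  list(end_q = 15L, window = 4L, window_q = 15, min_len = 70L,
       max_edit_frac = 0.10, min_margin = 2L, min_base_q = 30L,
       min_depth = 100L, mask_primers = TRUE, sd_threshold = 3,
       min_af = 0.005, loss = "huber", robust_sd = FALSE,
       pool_residuals = TRUE)
}

#' Load a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) naming the
#' panel, optional reference, catalogue, sample sheet and either FASTQ
#' files or a count table, plus a `params` block that surfaces every
#' threshold of the workflow with its published default (`end_q` 15,
#' `window` 4 / `window_q` 15, `min_len` 70, `min_base_q` 30,
#' `sd_threshold` 3, `min_af` 0.005, and the assignment margin rule).
#'
#' @param config path to a YAML file or a list.
#' @return normalised configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  params <- default_params()
  for (nm in names(config$params %||% list()))
    params[[nm]] <- config$params[[nm]]
  config$params <- params
  config
}

resolve_input <- function(x, loader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

#' Run the full calling pipeline
#'
#' @param config configuration list or YAML path (see [load_config()]).
#'   Required entries: `panel`, `catalogue`, `sample_sheet`, and either
#'   `counts` (count-table TSV/data frame) or `fastq` (named list
#'   mapping sample id to FASTQ path, or a read table). `reference`
#'   (FASTA) is required unless the supplied panel is already anchored
#'   or counts carry genomic coordinates.
#' @return an `amplicall_run`: the annotated `calls`, per-amplicon
#'   `fits`, cohort `summary`, `recurrence` classification,
#'   `trajectories`, the `audit` of per-stage counts, and the inputs
#'   used.
#' @export
run_call_pipeline <- function(config) {
  config <- load_config(config)
  p <- config$params
  panel <- resolve_input(config$panel, load_panel)
  if (!inherits(panel, "amplicon_panel"))
    stop("config must name a panel file or supply an amplicon_panel",
         call. = FALSE)
  if (!is.null(config$reference) && !is_anchored(panel))
    panel <- anchor_amplicons(panel, config$reference)
  catalogue <- resolve_input(config$catalogue, load_catalogue)
  sheet <- resolve_input(config$sample_sheet, load_sample_sheet)
  if (is.null(catalogue) || is.null(sheet))
    stop("config must provide a catalogue and a sample sheet",
         call. = FALSE)
  sheet <- validate_sample_sheet(sheet)

  audit <- list()
  if (!is.null(config$counts)) {
    counts <- resolve_input(config$counts, read_count_table)
  } else if (!is.null(config$fastq)) {
    reads <- config$fastq
    if (!is.data.frame(reads)) {
      if (is.null(names(reads)))
        stop("config$fastq must be named by sample id", call. = FALSE)
      reads <- do.call(rbind, lapply(names(reads), function(s)
        read_fastq(reads[[s]], sample_id = s)))
    }
    audit$reads_in <- nrow(reads)
    trimmed <- trim_reads(reads, end_q = p$end_q, window = p$window,
                          window_q = p$window_q, min_len = p$min_len)
    audit$reads_discarded_trim <- sum(trimmed$discarded)
    assigned <- assign_reads(trimmed, panel,
                             max_edit_frac = p$max_edit_frac,
                             min_margin = p$min_margin)
    audit$reads_assigned <- sum(assigned$assigned)
    audit$reads_unassigned <- sum(!assigned$assigned)
    counts <- build_pileup(assigned, panel, min_base_q = p$min_base_q,
                           mask_primers = p$mask_primers)
  } else {
    stop("config must provide either counts or fastq input",
         call. = FALSE)
  }
  shared <- intersect(unique(counts$sample_id), sheet$sample_id)
  if (length(shared) == 0L)
    stop("no sample is shared between the sample sheet and the data",
         call. = FALSE)
  counts <- counts[counts$sample_id %in% shared, , drop = FALSE]

  obs <- compute_af(counts, panel = panel, min_depth = p$min_depth,
                    mask_primers = p$mask_primers)
  audit$observations <- nrow(obs)
  fits <- fit_noise_models(obs, loss = p$loss, robust_sd = p$robust_sd)
  calls <- call_mutations(fits, sd_threshold = p$sd_threshold,
                          min_af = p$min_af,
                          pool_residuals = p$pool_residuals)
  if (is.null(calls)) calls <- call_mutations(list())
  audit$called <- sum(calls$status == "called")
  audit$rejected_noise <- sum(calls$reason %in% "within-noise")
  audit$rejected_af <- sum(calls$reason %in% "below-min-af")
  audit$rejected_unfittable <- sum(calls$reason %in% "insufficient-data")
  calls <- annotate_and_filter(calls, catalogue)
  audit$annotated <- sum(calls$status == "annotated")
  audit$rejected_catalogue <- sum(calls$reason %in% "not-in-catalogue")
  audit$rejected_snp <- sum(calls$reason %in% "snp")

  recurrence <- classify_all(calls, sheet)
  structure(list(panel = panel, catalogue = catalogue,
                 sample_sheet = sheet, counts = counts,
                 observations = obs, fits = fits, calls = calls,
                 summary = summarize_cohort(calls, sheet),
                 recurrence = recurrence,
                 trajectories = trajectory_table(calls, sheet),
                 audit = audit, params = p),
            class = "amplicall_run")
}

#' @export
print.amplicall_run <- function(x, ...) {
  cat("amplicall_run\n")
  a <- x$audit
  if (!is.null(a$reads_in))
    cat(sprintf("  reads: %d in = %d assigned + %d unassigned + %d trimmed away\n",
                a$reads_in, a$reads_assigned, a$reads_unassigned,
                a$reads_discarded_trim))
  cat(sprintf("  observations: %d -> %d called -> %d annotated\n",
              a$observations, a$called, a$annotated))
  print(x$summary)
  invisible(x)
}

#' Stage-by-stage audit counts of a run
#'
#' The counts telescope: reads in equals assigned + unassigned +
#' discarded by trimming, and observations equals called + each
#' rejection reason, with called equalling annotated + the two
#' catalogue rejections.
#'
#' @param run an `amplicall_run`.
#' @return named list of counters.
#' @export
audit_log <- function(run) run$audit
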