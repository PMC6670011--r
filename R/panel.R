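#' Amplicon panel: loading, validation and genome anchoring
#'
#' An amplicon panel is the set of PCR inserts a custom cfDNA assay
#' targets. Each amplicon carries its insert sequence (including the
#' primer-binding regions), a multiplex pool label, and -- after anchoring
#' against a reference genome -- a unique genomic interval and strand.
#' All coordinates in the package are 1-based and fully closed, matching
#' VCF/COSMIC conventions.
#'
#' @name panel_model
NULL

new_amplicon_panel <- function(amplicons, version = "") {
  structure(list(amplicons = amplicons, version = version),
            class = "amplicon_panel")
}

validate_panel_table <- function(df) {
  required <- c("name", "sequence", "pool", "fwd_primer_len", "rev_primer_len")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("panel file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$sequence <- toupper(df$sequence)
  bad_seq <- grepl("[^ACGT]", df$sequence)
  if (any(bad_seq))
    stop("non-ACGT characters in amplicon sequence(s): ",
         paste(df$name[bad_seq], collapse = ", "),
         " (line ", paste(which(bad_seq) + 1L, collapse = ", "), ")",
         call. = FALSE)
  dup <- duplicated(df$name)
  if (any(dup))
    stop("duplicate amplicon name(s): ",
         paste(unique(df$name[dup]), collapse = ", "), call. = FALSE)
  df$length <- nchar(df$sequence)
  out_of_range <- df$length < 100L | df$length > 175L
  if (any(out_of_range))
    warning("amplicon length outside the expected 100-175 nt design range: ",
            paste(df$name[out_of_range], collapse = ", "), call. = FALSE)
  # strand-symmetric assignment relies on no amplicon being its own
  # reverse complement
  pal <- df$sequence == revcomp(df$sequence)
  if (any(pal))
    stop("palindromic amplicon sequence(s) (strand would be ambiguous): ",
         paste(df$name[pal], collapse = ", "), call. = FALSE)
  if (any(df$fwd_primer_len < 0 | df$rev_primer_len < 0) ||
      any(df$fwd_primer_len + df$rev_primer_len >= df$length))
    stop("primer lengths must be non-negative and leave a non-empty insert",
         call. = FALSE)
  df
}

#' Load an amplicon panel from its TSV definition
#'
#' The panel file is a TSV with header columns `name`, `sequence`, `pool`,
#' `fwd_primer_len`, `rev_primer_len`. Sequences must be ACGT-only and
#' names unique; lengths outside 100-175 nt raise a warning (the intended
#' design range), not an error.
#'
#' @param path path to the panel TSV.
#' @param version free-text panel version recorded on the object.
#' @return an `amplicon_panel` object (unanchored: `chrom`/`start`/`strand`
#'   are `NA` until [anchor_amplicons()] is run).
#' @seealso [anchor_amplicons()], [genome_to_amplicon()]
#' @export
load_panel <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("failed to parse panel file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  df$fwd_primer_len <- as.integer(df$fwd_primer_len)
  df$rev_primer_len <- as.integer(df$rev_primer_len)
  df$pool <- as.integer(df$pool)
  df <- validate_panel_table(df)
  df$chrom <- NA_character_
  df$start <- NA_integer_
  df$strand <- NA_character_
  new_amplicon_panel(df[, c("name", "sequence", "length", "pool",
                            "fwd_primer_len", "rev_primer_len",
                            "chrom", "start", "strand")],
                     version = version)
}

#' Build a panel object directly from a data frame
#'
#' Programmatic counterpart of [load_panel()]; used by the simulators.
#'
#' @param df data frame with at least `name`, `sequence`, `pool`,
#'   `fwd_primer_len`, `rev_primer_len`.
#' @param version free-text version label.
#' @return an `amplicon_panel`.
#' @export
amplicon_panel <- function(df, version = "in-memory") {
  df <- validate_panel_table(as.data.frame(df, stringsAsFactors = FALSE))
  for (col in c("chrom", "start", "strand"))
    if (is.null(df[[col]])) df[[col]] <- NA
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$strand <- as.character(df$strand)
  new_amplicon_panel(df[, c("name", "sequence", "length", "pool",
                            "fwd_primer_len", "rev_primer_len",
                            "chrom", "start", "strand")],
                     version = version)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  a <- x$amplicons
  cat(sprintf("amplicon_panel: %d amplicons (version '%s'), %s\n",
              nrow(a), x$version,
              if (is_anchored(x)) "anchored" else "not anchored"))
  cat(sprintf("  length %d-%d nt, %d multiplex pool(s)\n",
              min(a$length), max(a$length), length(unique(a$pool))))
  invisible(x)
}

#' Is every amplicon of a panel anchored to the genome?
#' @param panel an `amplicon_panel`.
#' @return logical scalar.
#' @export
is_anchored <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  !anyNA(panel$amplicons$chrom) && !anyNA(panel$amplicons$start)
}

load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    if (!file.exists(reference))
      stop("reference FASTA not found: ", reference, call. = FALSE)
    return(Biostrings::readDNAStringSet(reference))
  }
  stop("reference must be a FASTA path or a DNAStringSet", call. = FALSE)
}

#' Anchor panel amplicons to a reference genome at 100% identity
#'
#' Each amplicon sequence is located in the reference by exact substring
#' search on both strands. Exactly one hit is required: zero hits or
#' multiple hits abort with the offending amplicon named, since an
#' ambiguously placed amplicon cannot be used for variant annotation.
#' Near-matches are deliberately not accepted.
#'
#' @param panel an `amplicon_panel`.
#' @param reference FASTA path or `Biostrings::DNAStringSet`.
#' @return the panel with `chrom`, `start` (1-based leftmost genomic
#'   position of the amplicon interval) and `strand` filled in. Anchored
#'   intervals must not overlap.
#' @export
anchor_amplicons <- function(panel, reference) {
  stopifnot(inherits(panel, "amplicon_panel"))
  genome <- load_reference(reference)
  if (is.null(names(genome)) || anyNA(names(genome)))
    stop("reference sequences must be named", call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  a <- panel$amplicons
  for (i in seq_len(nrow(a))) {
    fwd <- Biostrings::startIndex(Biostrings::vmatchPattern(a$sequence[i],
                                                            genome))
    rev <- Biostrings::startIndex(Biostrings::vmatchPattern(
      revcomp(a$sequence[i]), genome))
    fwd <- lapply(fwd, function(x) x %||% integer(0))
    rev <- lapply(rev, function(x) x %||% integer(0))
    hits <- data.frame(
      chrom = c(rep(names(genome), lengths(fwd)),
                rep(names(genome), lengths(rev))),
      start = c(unlist(fwd, use.names = FALSE),
                unlist(rev, use.names = FALSE)),
      strand = rep(c("+", "-"), c(sum(lengths(fwd)), sum(lengths(rev)))),
      stringsAsFactors = FALSE)
    if (nrow(hits) == 0L)
      stop("amplicon '", a$name[i],
           "' has no exact match in the reference (anchoring requires ",
           "100% identity)", call. = FALSE)
    if (nrow(hits) > 1L)
      stop("amplicon '", a$name[i], "' matches the reference at ",
           nrow(hits), " locations; anchoring must be unambiguous",
           call. = FALSE)
    a$chrom[i] <- hits$chrom
    a$start[i] <- as.integer(hits$start)
    a$strand[i] <- hits$strand
  }
  # anchored intervals must not overlap (panel invariant)
  ends <- a$start + a$length - 1L
  o <- order(a$chrom, a$start)
  same_chrom <- a$chrom[o][-1L] == a$chrom[o][-nrow(a)]
  if (nrow(a) > 1L &&
      any(same_chrom & a$start[o][-1L] <= ends[o][-nrow(a)]))
    stop("anchored amplicon intervals overlap; panel is invalid",
         call. = FALSE)
  panel$amplicons <- a
  panel
}

panel_row <- function(panel, name) {
  i <- match(name, panel$amplicons$name)
  if (anyNA(i)) stop("unknown amplicon name(s): ",
                     paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Map a genomic position into amplicon-local coordinates
#'
#' Offsets are 1-based distances from the amplicon's own 5' end, i.e.
#' they run along the amplicon sequence as written in the panel file,
#' regardless of which genomic strand it anchors to.
#'
#' @param panel anchored `amplicon_panel`.
#' @param chrom,pos vectors of genomic coordinates (1-based).
#' @return data frame with columns `amplicon` and `offset`; rows falling
#'   outside every amplicon get `NA` in both (the "no amplicon" sentinel).
#' @export
genome_to_amplicon <- function(panel, chrom, pos) {
  stopifnot(is_anchored(panel))
  a <- panel$amplicons
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  out <- data.frame(amplicon = rep(NA_character_, n),
                    offset = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(a))) {
    hit <- chrom == a$chrom[i] & pos >= a$start[i] &
      pos <= a$start[i] + a$length[i] - 1L
    if (!any(hit)) next
    out$amplicon[hit] <- a$name[i]
    out$offset[hit] <- if (a$strand[i] == "+") {
      pos[hit] - a$start[i] + 1L
    } else {
      a$start[i] + a$length[i] - pos[hit]
    }
  }
  out
}

#' Map amplicon-local offsets back to genomic coordinates
#'
#' Inverse of [genome_to_amplicon()] for in-range offsets.
#'
#' @param panel anchored `amplicon_panel`.
#' @param amplicon,offset vectors of amplicon names and 1-based offsets.
#' @return data frame with `chrom`, `pos`, `strand`.
#' @export
amplicon_to_genome <- function(panel, amplicon, offset) {
  stopifnot(is_anchored(panel))
  i <- panel_row(panel, amplicon)
  a <- panel$amplicons
  offset <- as.integer(offset)
  if (any(offset < 1L | offset > a$length[i]))
    stop("offset outside amplicon length", call. = FALSE)
  pos <- ifelse(a$strand[i] == "+",
                a$start[i] + offset - 1L,
                a$start[i] + a$length[i] - offset)
  data.frame(chrom = a$chrom[i], pos = as.integer(pos),
             strand = a$strand[i], stringsAsFactors = FALSE)
}

#' Amplicon offsets masked as primer-derived
#'
#' Primer-binding bases are synthetic oligonucleotide, not template, so
#' they cannot carry a template variant; by default the pipeline excludes
#' the first `fwd_primer_len` and last `rev_primer_len` offsets of every
#' amplicon from variant counting.
#'
#' @param panel an `amplicon_panel`.
#' @param name single amplicon name.
#' @return integer vector of masked offsets (possibly empty).
#' @export
primer_mask_offsets <- function(panel, name) {
  i <- panel_row(panel, name)
  a <- panel$amplicons
  c(seq_len(a$fwd_primer_len[i]),
    if (a$rev_primer_len[i] > 0L)
      (a$length[i] - a$rev_primer_len[i] + 1L):a$length[i])
}

#' Unmasked (template-derived) offsets of an amplicon
#' @inheritParams primer_mask_offsets
#' @return integer vector of callable offsets.
#' @export
callable_offsets <- function(panel, name) {
  i <- panel_row(panel, name)
  setdiff(seq_len(panel$amplicons$length[i]), primer_mask_offsets(panel, name))
}

#' Write a panel back to its TSV representation
#' @param panel an `amplicon_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("name", "sequence", "pool", "fwd_primer_len", "rev_primer_len")
  write.table(panel$amplicons[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load a somatic-mutation catalogue (COSMIC-style TSV)
#'
#' The catalogue is a TSV with header `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `variant_id`, `is_snp` (`y`/`n`). Entries flagged `is_snp = y`
#' mark germline polymorphisms that are excluded from somatic calls at
#' the annotation stage.
#'
#' @param path path to the catalogue TSV.
#' @return data frame keyed by `(chrom, pos, ref, alt)` with logical
#'   `is_snp`.
#' @export
load_catalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path,
                               call. = FALSE)
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("failed to parse catalogue ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  required <- c("chrom", "pos", "ref", "alt", "gene", "variant_id", "is_snp")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("catalogue is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$pos <- as.integer(df$pos)
  df$is_snp <- tolower(as.character(df$is_snp)) %in% c("y", "yes", "true", "1")
  validate_catalogue(df)
}

validate_catalogue <- function(df) {
  if (any(df$ref == df$alt))
    stop("catalogue entries with ref == alt at row(s) ",
         paste(which(df$ref == df$alt), collapse = ", "), call. = FALSE)
  if (any(df$pos < 1L))
    stop("catalogue positions must be >= 1", call. = FALSE)
  df
}

#' Look up catalogue entries by variant key
#' @param catalogue data frame from [load_catalogue()].
#' @param chrom,pos,ref,alt vectors forming variant keys.
#' @return integer vector of catalogue row indices (`NA` where absent).
#' @export
catalogue_lookup <- function(catalogue, chrom, pos, ref, alt) {
  match(paste(chrom, pos, ref, alt, sep = ":"),
        paste(catalogue$chrom, catalogue$pos, catalogue$ref, catalogue$alt,
              sep = ":"))
}
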