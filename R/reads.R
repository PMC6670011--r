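#' Read processing: quality trimming and panel-aware assignment
#'
#' Single-end reads are quality-trimmed with the classic three-rule
#' scheme (leading/trailing base trim at q < 15, 4-base sliding-window
#' cut at mean q < 15, minimum length 70) and then assigned to the
#' amplicon they were amplified from. Because the target space is a
#' known, small panel rather than a whole genome, mapping ambiguity is
#' measured directly as the edit-distance margin between the best and
#' second-best amplicon instead of a general-purpose mapping quality.
#'
#' @name read_processing
NULL

phred_ints <- function(qual) utf8ToInt(qual) - 33L

ints_to_qual <- function(q) intToUtf8(q + 33L)

#' Read a FASTQ file into the package's read table
#'
#' @param path FASTQ path (phred33).
#' @param sample_id sample label attached to every read.
#' @return data frame with columns `read_id`, `sample_id`, `bases`,
#'   `quals` (phred33 string).
#' @export
read_fastq <- function(path, sample_id = basename(path)) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x) %||% as.character(seq_along(x)),
             sample_id = sample_id,
             bases = as.character(x),
             quals = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#' @param reads read table as returned by [read_fastq()] / [simulate_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$bases, "\n+\n",
                    reads$quals), con)
  invisible(path)
}

trim_one <- function(q, end_q, window, window_q) {
  n <- length(q)
  from <- 1L
  while (from <= n && q[from] < end_q) from <- from + 1L
  to <- n
  while (to >= from && q[to] < end_q) to <- to - 1L
  if (from > to) return(c(1L, 0L))
  q <- q[from:to]
  m <- length(q)
  if (m >= window) {
    # rolling mean over windows of `window` bases, 5'->3'
    cs <- cumsum(c(0, q))
    wm <- (cs[(window + 1L):(m + 1L)] - cs[1:(m - window + 1L)]) / window
    cut <- which(wm < window_q)
    if (length(cut)) to <- from + cut[1L] - 2L
  }
  c(from, to)
}

#' Quality-trim reads
#'
#' Rules are applied in a fixed order: (1) leading bases with
#' `q < end_q` removed, (2) trailing bases with `q < end_q` removed,
#' (3) scanning 5' to 3', the read is cut at the start of the first
#' window of `window` bases whose mean quality falls below `window_q`,
#' (4) reads shorter than `min_len` after trimming are discarded.
#' Trimming is idempotent and only ever returns a contiguous substring
#' of the input.
#'
#' @param reads read table (`read_id`, `sample_id`, `bases`, `quals`).
#' @param end_q phred threshold for the leading/trailing trim.
#' @param window sliding-window width in bases.
#' @param window_q mean-quality threshold for the window cut.
#' @param min_len minimum surviving read length.
#' @return the read table with trimmed `bases`/`quals` and a logical
#'   column `discarded` (such rows keep their untrimmed sequence for
#'   auditing; their trimmed length is in `trimmed_len`).
#' @export
trim_reads <- function(reads, end_q = 15L, window = 4L, window_q = 15,
                       min_len = 70L) {
  if (nrow(reads) == 0L) {
    reads$discarded <- logical(0)
    reads$trimmed_len <- integer(0)
    return(reads)
  }
  bounds <- vapply(reads$quals, function(s)
    trim_one(phred_ints(s), end_q, window, window_q),
    integer(2), USE.NAMES = FALSE)
  from <- bounds[1L, ]; to <- bounds[2L, ]
  len <- pmax(to - from + 1L, 0L)
  keep <- len >= min_len
  reads$bases[keep] <- substring(reads$bases[keep], from[keep], to[keep])
  reads$quals[keep] <- substring(reads$quals[keep], from[keep], to[keep])
  reads$discarded <- !keep
  reads$trimmed_len <- len
  reads
}

build_seed_index <- function(panel, k) {
  a <- panel$amplicons
  recs <- lapply(seq_len(nrow(a)), function(i) {
    for_seq <- a$sequence[i]
    rev_seq <- revcomp(for_seq)
    n <- nchar(for_seq)
    starts <- 1:(n - k + 1L)
    data.table(
      kmer = c(substring(for_seq, starts, starts + k - 1L),
               substring(rev_seq, starts, starts + k - 1L)),
      amp = a$name[i],
      strand = rep(c("+", "-"), each = length(starts)))
  })
  idx <- unique(rbindlist(recs))
  setkey(idx, kmer)
  idx
}

edit_substitution_matrix <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(-1, length(b), length(b), dimnames = list(b, b))
  diag(m) <- 0
  m
}

#' Assign trimmed reads to panel amplicons
#'
#' Each read is seeded against a k-mer index of the panel (both strands)
#' and candidate amplicons are scored by the edit distance between the
#' read and its best-matching amplicon substring. A read is assigned to
#' the unique best amplicon only if that distance is at most
#' `ceiling(max_edit_frac * read length)` *and* the second-best amplicon
#' is at least `min_margin` edits worse -- the panel-aware analogue of a
#' mapping-quality cutoff. Reads with no seed hit anywhere are scored
#' against the full panel before being declared unassigned.
#'
#' @param reads trimmed read table (rows with `discarded = TRUE` are
#'   ignored).
#' @param panel an `amplicon_panel`.
#' @param max_edit_frac maximum edit distance as a fraction of read
#'   length.
#' @param min_margin minimum (second best - best) edit-distance gap.
#' @param seed_k seed k-mer length.
#' @return data frame with one row per input read: `read_id`,
#'   `sample_id`, `bases`, `quals`, `amplicon`, `strand`, `offset`
#'   (1-based alignment start on the amplicon), `edit_distance`,
#'   `margin`, `assigned`.
#' @export
assign_reads <- function(reads, panel, max_edit_frac = 0.10,
                         min_margin = 2L, seed_k = 16L) {
  stopifnot(inherits(panel, "amplicon_panel"))
  if (!is.null(reads$discarded)) reads <- reads[!reads$discarded, ]
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id, sample_id = reads$sample_id,
                    bases = reads$bases, quals = reads$quals,
                    amplicon = NA_character_, strand = NA_character_,
                    offset = NA_integer_, edit_distance = NA_integer_,
                    margin = NA_integer_, assigned = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  idx <- build_seed_index(panel, seed_k)
  a <- panel$amplicons
  amp_fwd <- setNames(a$sequence, a$name)
  amp_rev <- setNames(revcomp(a$sequence), a$name)
  for (r in seq_len(n)) {
    read <- reads$bases[r]
    len <- nchar(read)
    if (len < seed_k) next
    starts <- unique(pmin(seq(1L, max(len - seed_k + 1L, 1L), by = seed_k),
                          len - seed_k + 1L))
    seeds <- substring(read, starts, starts + seed_k - 1L)
    cand <- unique(idx[J(seeds), .(amp, strand), nomatch = NULL])
    if (nrow(cand) == 0L)  # no seed anywhere: brute-force the whole panel
      cand <- data.table(amp = rep(a$name, 2L),
                         strand = rep(c("+", "-"), each = nrow(a)))
    cand$dist <- vapply(seq_len(nrow(cand)), function(j) {
      subj <- if (cand$strand[j] == "+") amp_fwd[[cand$amp[j]]]
              else amp_rev[[cand$amp[j]]]
      as.integer(utils::adist(read, subj, partial = TRUE))
    }, integer(1))
    # best strand per amplicon, then best vs second-best amplicon
    per_amp <- cand[, .(dist = min(dist), strand = strand[which.min(dist)]),
                    by = amp]
    ord <- order(per_amp$dist)
    best <- per_amp[ord[1L]]
    second <- if (nrow(per_amp) > 1L) per_amp$dist[ord[2L]] else len
    margin <- min(second - best$dist, len)
    out$edit_distance[r] <- best$dist
    out$margin[r] <- as.integer(margin)
    if (best$dist <= ceiling(max_edit_frac * len) && margin >= min_margin) {
      out$amplicon[r] <- best$amp
      out$strand[r] <- best$strand
      out$assigned[r] <- TRUE
    }
  }
  # alignment offsets for assigned reads, batched per amplicon
  sub_mat <- edit_substitution_matrix()
  for (amp in unique(out$amplicon[out$assigned])) {
    rows <- which(out$assigned & out$amplicon == amp)
    oriented <- ifelse(out$strand[rows] == "+", out$bases[rows],
                       revcomp(out$bases[rows]))
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(oriented),
      subject = Biostrings::DNAString(amp_fwd[[amp]]),
      type = "global-local", substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = 1)
    out$offset[rows] <- BiocGenerics::start(Biostrings::subject(pa))
  }
  out
}

#' Export assigned reads as a SAM-like TSV (debugging aid)
#' @param assigned output of [assign_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assigned, path) {
  cols <- c("read_id", "sample_id", "amplicon", "offset", "strand",
            "edit_distance", "margin", "assigned")
  write.table(assigned[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
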