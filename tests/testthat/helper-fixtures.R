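# Small deterministic fixtures shared across the suite. Everything is
# built in code; nothing is read from disk except files the tests
# themselves write to tempdir().

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# three-amplicon toy panel with known sequences; primer lengths zero so
# unit tests can reason about every offset
tiny_panel_df <- function(primer = 0L) {
  data.frame(
    name = c("KRAS_ex2", "TP53_ex5", "APC_ex16"),
    sequence = c(rand_dna(120, 11), rand_dna(140, 22), rand_dna(110, 33)),
    pool = c(1L, 1L, 2L),
    fwd_primer_len = primer, rev_primer_len = primer,
    stringsAsFactors = FALSE)
}

tiny_panel <- function(primer = 0L) amplicon_panel(tiny_panel_df(primer))

# reference embedding the tiny panel: amplicon 1 forward on chrA,
# amplicon 2 reverse-complemented on chrA, amplicon 3 forward on chrB
tiny_reference <- function(panel = tiny_panel()) {
  a <- panel$amplicons
  Biostrings::DNAStringSet(c(
    chrA = paste0(rand_dna(200, 44), a$sequence[1], rand_dna(150, 55),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(a$sequence[2]))),
                  rand_dna(100, 66)),
    chrB = paste0(rand_dna(120, 77), a$sequence[3], rand_dna(90, 88))))
}

anchored_tiny_panel <- function(primer = 0L) {
  anchor_amplicons(tiny_panel(primer), tiny_reference(tiny_panel(primer)))
}

# uniform-quality read table
make_reads <- function(bases, q = 30L, ids = NULL, sample_id = "s1") {
  data.frame(read_id = ids %||% sprintf("r%03d", seq_along(bases)),
             sample_id = sample_id, bases = bases,
             quals = vapply(nchar(bases), function(n)
               intToUtf8(rep(q + 33L, n)), character(1)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

qual_str <- function(q) intToUtf8(q + 33L)

# observations whose logits lie exactly on beta0 + beta1 * offset (+
# sample shifts expressed as exact odds ratios), built from integer
# count/depth pairs so no rounding enters
plane_obs <- function() {
  # odds 1/100, 1/10, 1/1 at offsets 10, 20, 30 -> slope log(10)/10
  data.frame(sample_id = "s1", amplicon = "A", offset = c(10L, 20L, 30L),
             chrom = NA_character_, pos = NA_integer_, ref = "A",
             alt = "T", count = c(100L, 100L, 100L),
             depth = c(10100L, 1100L, 200L),
             af = c(100 / 10100, 100 / 1100, 100 / 200),
             stringsAsFactors = FALSE)
}

obs_from_counts <- function(count, depth, offset,
                            sample_id = "s1", amplicon = "A") {
  data.frame(sample_id = sample_id, amplicon = amplicon,
             offset = as.integer(offset), chrom = NA_character_,
             pos = NA_integer_, ref = "A", alt = "T",
             count = as.integer(count), depth = as.integer(depth),
             af = count / depth, stringsAsFactors = FALSE)
}

# observations built from target logit values eta via large depths
# (rounding error ~1e-5 on the logit scale, negligible for the tests
# that use this)
obs_from_eta <- function(eta, offset, sample_id = "s1", amplicon = "A",
                         depth = 1e6) {
  a <- plogis(eta)
  count <- pmax(round(a * depth), 1L)
  obs_from_counts(count, depth, offset, sample_id, amplicon)
}

# dilution genotypes: first four catalogue amplicons, two sites per
# genotype, expressed in amplicon orientation
dilution_genotypes <- function(sp) {
  cat_ok <- sp$catalogue[!sp$catalogue$is_snp, , drop = FALSE]
  loc <- genome_to_amplicon(sp$panel, cat_ok$chrom, cat_ok$pos)
  cat_ok$amplicon <- loc$amplicon
  cat_ok$offset <- loc$offset
  i <- match(cat_ok$amplicon, sp$panel$amplicons$name)
  minus <- sp$panel$amplicons$strand[i] == "-"
  cat_ok$alt_amp <- ifelse(minus, chartr("ACGT", "TGCA", cat_ok$alt),
                           cat_ok$alt)
  pick <- cat_ok[!duplicated(cat_ok$amplicon), , drop = FALSE][1:4, ]
  list(a = data.frame(amplicon = pick$amplicon[1:2],
                      offset = pick$offset[1:2],
                      alt = pick$alt_amp[1:2], stringsAsFactors = FALSE),
       b = data.frame(amplicon = pick$amplicon[3:4],
                      offset = pick$offset[3:4],
                      alt = pick$alt_amp[3:4], stringsAsFactors = FALSE))
}

# catalogue sites usable as injected variants, in amplicon orientation
catalogue_sites <- function(sp) {
  ct <- sp$catalogue[!sp$catalogue$is_snp, , drop = FALSE]
  loc <- genome_to_amplicon(sp$panel, ct$chrom, ct$pos)
  ct$amplicon <- loc$amplicon
  ct$offset <- loc$offset
  i <- match(ct$amplicon, sp$panel$amplicons$name)
  minus <- sp$panel$amplicons$strand[i] == "-"
  ct$alt_amp <- ifelse(minus, chartr("ACGT", "TGCA", ct$alt), ct$alt)
  ct
}
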