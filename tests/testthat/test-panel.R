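test_that("panel TSV loading preserves order and validates content", {
  df <- tiny_panel_df(primer = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- load_panel(path)
  expect_s3_class(panel, "amplicon_panel")
  expect_identical(panel$amplicons$name, df$name)
  expect_identical(panel$amplicons$sequence, df$sequence)
  expect_false(is_anchored(panel))

  dup <- df[c(1, 1, 2), ]
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(path), "duplicate amplicon name.*KRAS_ex2")

  bad <- df
  bad$sequence[2] <- sub("A", "X", bad$sequence[2])
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(path), "non-ACGT")

  short <- df
  short$sequence[1] <- substr(short$sequence[1], 1, 60)
  write.table(short, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(load_panel(path), "100-175")
})

test_that("a full-size 43-amplicon panel file loads intact", {
  sp <- synthetic_panel(n_amplicons = 43L, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(sp$panel, path)
  panel <- load_panel(path)
  expect_equal(nrow(panel$amplicons), 43L)
  expect_identical(panel$amplicons$name, sp$panel$amplicons$name)
})

test_that("anchoring finds planted matches on both strands and agrees with a brute-force scan", {
  panel <- tiny_panel()
  ref <- tiny_reference(panel)
  anchored <- anchor_amplicons(panel, ref)
  a <- anchored$amplicons
  expect_identical(a$strand, c("+", "-", "+"))
  expect_identical(a$chrom, c("chrA", "chrA", "chrB"))

  # brute-force oracle: fixed-string search of both orientations
  ref_chr <- as.character(ref)
  for (i in seq_len(nrow(a))) {
    fwd_hits <- lapply(ref_chr, function(s)
      gregexpr(a$sequence[i], s, fixed = TRUE)[[1]])
    rev_hits <- lapply(ref_chr, function(s)
      gregexpr(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(a$sequence[i]))), s, fixed = TRUE)[[1]])
    found <- c(unlist(lapply(seq_along(fwd_hits), function(k)
      if (fwd_hits[[k]][1] > 0)
        paste(names(ref_chr)[k], fwd_hits[[k]], "+"))),
      unlist(lapply(seq_along(rev_hits), function(k)
        if (rev_hits[[k]][1] > 0)
          paste(names(ref_chr)[k], rev_hits[[k]], "-"))))
    expect_identical(found, paste(a$chrom[i], a$start[i], a$strand[i]))
  }
})

test_that("ambiguous or absent amplicons abort anchoring by name", {
  panel <- tiny_panel()
  seqs <- panel$amplicons$sequence
  twice <- Biostrings::DNAStringSet(c(
    chrA = paste0(rand_dna(100, 1), seqs[1], rand_dna(100, 2), seqs[1],
                  rand_dna(50, 3), seqs[2], rand_dna(50, 4), seqs[3],
                  rand_dna(50, 5))))
  expect_error(anchor_amplicons(panel, twice), "KRAS_ex2.*2 locations")

  absent <- Biostrings::DNAStringSet(c(
    chrA = paste0(rand_dna(100, 1), seqs[1], rand_dna(60, 2), seqs[2],
                  rand_dna(60, 6))))
  expect_error(anchor_amplicons(panel, absent), "APC_ex16.*no exact match")
})

test_that("anchoring is idempotent and order-independent", {
  panel <- tiny_panel()
  ref <- tiny_reference(panel)
  once <- anchor_amplicons(panel, ref)
  twice <- anchor_amplicons(once, ref)
  expect_identical(once$amplicons, twice$amplicons)

  shuffled <- panel
  shuffled$amplicons <- panel$amplicons[c(3, 1, 2), ]
  re <- anchor_amplicons(shuffled, ref)
  m <- match(once$amplicons$name, re$amplicons$name)
  expect_identical(once$amplicons$start, re$amplicons$start[m])
  expect_identical(once$amplicons$strand, re$amplicons$strand[m])
})

test_that("genome/amplicon coordinate mapping round-trips on both strands", {
  panel <- anchored_tiny_panel()
  a <- panel$amplicons
  for (i in seq_len(nrow(a))) {
    # boundary offsets and a sweep of interior ones
    offs <- c(1L, 7L, a$length[i] %/% 2L, a$length[i])
    g <- amplicon_to_genome(panel, rep(a$name[i], length(offs)), offs)
    back <- genome_to_amplicon(panel, g$chrom, g$pos)
    expect_identical(back$amplicon, rep(a$name[i], length(offs)))
    expect_identical(back$offset, offs)
  }
  # offset 1 of a plus-strand amplicon is its genomic start
  expect_identical(amplicon_to_genome(panel, a$name[1], 1L)$pos, a$start[1])
  expect_identical(amplicon_to_genome(panel, a$name[1], a$length[1])$pos,
                   a$start[1] + a$length[1] - 1L)
  # a position between amplicons returns the no-amplicon sentinel
  miss <- genome_to_amplicon(panel, "chrA", 5L)
  expect_true(is.na(miss$amplicon) && is.na(miss$offset))
  expect_error(amplicon_to_genome(panel, a$name[1], a$length[1] + 1L),
               "outside")
})

test_that("primer masking removes exactly the primer-derived offsets", {
  panel <- tiny_panel(primer = 20L)
  L <- panel$amplicons$length[1]
  masked <- primer_mask_offsets(panel, "KRAS_ex2")
  expect_identical(masked, c(1:20, (L - 19):L))
  expect_identical(callable_offsets(panel, "KRAS_ex2"), 21:(L - 20L))
})

test_that("catalogue loading indexes entries and preserves the SNP flag", {
  df <- data.frame(chrom = "chrA", pos = c(10L, 20L, 30L, 40L, 50L),
                   ref = c("A", "C", "G", "T", "A"),
                   alt = c("T", "T", "A", "C", "G"),
                   gene = c("KRAS", "KRAS", "TP53", "TP53", "APC"),
                   variant_id = sprintf("V%02d", 1:5),
                   is_snp = c("n", "y", "n", "n", "y"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- load_catalogue(path)
  expect_equal(nrow(ct), 5L)
  expect_identical(ct$is_snp, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(catalogue_lookup(ct, "chrA", 30L, "G", "A"), 3L)
  expect_true(is.na(catalogue_lookup(ct, "chrA", 30L, "G", "C")))
  expect_true(is.na(catalogue_lookup(ct, "chrZ", 30L, "G", "A")))

  bad <- df
  bad$alt[1] <- bad$ref[1]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalogue(bad_path <- path), "ref == alt")
})
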