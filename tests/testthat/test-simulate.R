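test_that("count simulation is a pure, byte-stable function of seed", {
  sp <- synthetic_panel(n_amplicons = 3L, seed = 50)
  c1 <- simulate_pileup_counts(sp$panel, c("s1", "s2"), depth = 1000,
                               seed = 51)
  c2 <- simulate_pileup_counts(sp$panel, c("s1", "s2"), depth = 1000,
                               seed = 51)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(c1, p1)
  write_count_table(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  c3 <- simulate_pileup_counts(sp$panel, c("s1", "s2"), depth = 1000,
                               seed = 52)
  expect_false(identical(c1, c3))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1)
  invisible(simulate_pileup_counts(sp$panel, "s1", depth = 200,
                                   seed = 53))
  expect_identical(runif(1), a)
})

test_that("with all structure switched off, error fractions match the binomial oracle", {
  sp <- synthetic_panel(n_amplicons = 2L, seed = 54)
  em <- error_model(base_rate = 0.001, beta1_true = 0, sample_sd = 0,
                    resid_sd = 0)
  depth <- 1e6
  counts <- simulate_pileup_counts(sp$panel, "s1", error = em,
                                   depth = depth, seed = 55)
  alt <- counts[counts$allele != counts$ref, ]
  af <- alt$count / alt$depth
  tol <- 3 * sqrt(0.001 * 0.999 / depth)
  expect_true(all(abs(af - 0.001) < tol))
  # every simulated position carries its error observation at this depth
  expect_equal(nrow(alt), sum(sp$panel$amplicons$length))
})

test_that("an injected variant at 50% MAF lands within 3 binomial SDs", {
  sp <- synthetic_panel(n_amplicons = 2L, seed = 56)
  site <- catalogue_sites(sp)[1, ]
  depth <- 1e4
  counts <- simulate_pileup_counts(
    sp$panel, "s1",
    variants = data.frame(amplicon = site$amplicon, offset = site$offset,
                          alt = site$alt_amp, maf = 0.5,
                          sample_id = NA_character_),
    depth = depth, seed = 57)
  obs <- compute_af(counts, panel = sp$panel)
  hit <- obs[obs$pos == site$pos & obs$alt == site$alt, ]
  expect_lt(abs(hit$af - 0.5), 3 * sqrt(0.25 / depth) + 0.002)
})

test_that("negative-binomial depths spread like a deep multiplex run", {
  sp <- synthetic_panel(n_amplicons = 43L, seed = 58)
  counts <- simulate_pileup_counts(sp$panel, sprintf("s%d", 1:10),
                                   seed = 59)
  d <- unique(counts[, c("sample_id", "amplicon", "depth")])
  # one depth per sample x amplicon... modulo the rare clamped column
  depths <- data.table::as.data.table(d)[
    , .(depth = max(depth)), by = .(sample_id, amplicon)]$depth
  expect_equal(length(depths), 430L)
  expect_gt(median(depths), 4000)
  expect_lt(median(depths), 11000)
  expect_lt(quantile(depths, 0.01), 2000)
  expect_gt(quantile(depths, 0.99), 15000)
})

test_that("dilution series implements the monoallelic mix arithmetic", {
  sp <- synthetic_panel(n_amplicons = 6L, seed = 60)
  g <- dilution_genotypes(sp)
  sim <- simulate_dilution_series(sp$panel, g$a, g$b,
                                  fractions = c(0.5, 0.0125, 0),
                                  depth = 2000, seed = 61)
  tr <- sim$truth
  # f = 0.0125: minor genotype at maf 0.00625
  expect_equal(unique(tr$maf[tr$genotype == "B" &
                               tr$sample_id == "mix_1.25"]), 0.00625)
  expect_equal(unique(tr$maf[tr$genotype == "A" &
                               tr$sample_id == "mix_1.25"]),
               (1 - 0.0125) / 2)
  # f = 0.5: both genotypes at 0.25
  expect_equal(unique(tr$maf[tr$sample_id == "mix_50"]), 0.25)
  # f = 0: B absent, noise only
  expect_false(any(tr$genotype == "B" & tr$sample_id == "mix_0"))
  # overlapping genotype definitions are rejected
  expect_error(simulate_dilution_series(sp$panel, g$a, g$a, depth = 100,
                                        seed = 1), "overlap")
})

test_that("FASTQ simulation is deterministic and honours planted truth", {
  sp <- synthetic_panel(n_amplicons = 3L, seed = 62)
  r1 <- simulate_fastq(sp$panel, reads_per_amplicon = 50L, seed = 63)
  r2 <- simulate_fastq(sp$panel, reads_per_amplicon = 50L, seed = 63)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f1)
  write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # error-free reads pile up all-reference
  clean <- simulate_fastq(sp$panel, reads_per_amplicon = 20L,
                          error_rate = 0, seed = 64)
  pu <- build_pileup(assign_reads(trim_reads(clean), sp$panel), sp$panel,
                     mask_primers = FALSE)
  expect_true(all(pu$allele == pu$ref))

  # 1000 reads with 1% forced alt at a covered offset -> AF 0.01
  amp <- sp$panel$amplicons[sp$panel$amplicons$length <= 150, ][1, ]
  alt <- setdiff(c("A", "C", "G", "T"),
                 substr(amp$sequence, 20, 20))[1]
  reads <- simulate_fastq(
    sp$panel, setNames(1000L, amp$name), error_rate = 0,
    quality_sd = 0,   # uniform q35: no base lost to the q30 floor
    variants = data.frame(amplicon = amp$name, offset = 20L, alt = alt,
                          fraction = 0.01), seed = 65)
  pu <- build_pileup(assign_reads(trim_reads(reads), sp$panel), sp$panel,
                     mask_primers = FALSE)
  col <- pu[pu$amplicon == amp$name & pu$offset == 20L &
              pu$allele != pu$ref, ]
  expect_equal(col$count / col$depth, 0.01, tolerance = 1e-9)
})

test_that("serial cohorts record a complete, reportable truth table", {
  sp <- synthetic_panel(n_amplicons = 8L, seed = 66)
  sim <- simulate_serial_cohort(sp$panel, sp$catalogue, n_patients = 4L,
                                timepoints = 2L, n_recurrent = 2L,
                                n_sporadic = 1L, depth = 1500,
                                seed = 67)
  # distinct mutation keys: 3 per patient
  keys <- unique(paste(sim$truth$patient_id, sim$truth$chrom,
                       sim$truth$pos, sim$truth$alt))
  expect_equal(length(keys), 3L * 4L)
  # recurrent mutations appear at every time point, sporadic at one
  per <- table(paste(sim$truth$patient_id, sim$truth$pos,
                     sim$truth$alt), sim$truth$class)
  expect_true(all(per[, "recurrent"] %in% c(0L, 2L)))
  expect_true(all(per[, "sporadic"] %in% c(0L, 1L)))
  # truncation keeps every injected MAF in the reportable range
  expect_true(all(sim$truth$maf >= 0.005))
  expect_true(all(sim$truth$maf <= 0.967))
  expect_equal(nrow(sim$sample_sheet), 8L)
  expect_identical(sort(unique(sim$counts$sample_id)),
                   sort(sim$sample_sheet$sample_id))
})
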