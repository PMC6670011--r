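#' Synthetic amplicon sequencing data
#'
#' Generators for count tables, FASTQ reads, two-genotype dilution
#' series and serial-sample cohorts that realise exactly the error
#' structure the noise model assumes: a baseline PCR/sequencing error
#' rate, a linear position trend on the logit scale, sample-level logit
#' offsets, and observation-level Gaussian logit noise, with depths
#' spread like a real multiplex amplicon run. All generators are pure
#' functions of their parameters and an explicit seed.
#'
#' @name synthetic_data
NULL

# run expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

default_substitution_bias <- function() {
  # transitions twice as likely as either transversion
  list(A = c(G = 2, C = 1, T = 1), G = c(A = 2, C = 1, T = 1),
       C = c(T = 2, A = 1, G = 1), T = c(C = 2, A = 1, G = 1))
}

#' Error model driving the count simulators
#'
#' @param base_rate mean per-position error fraction at amplicon
#'   position zero (must lie in (0, 0.05)).
#' @param beta1_true linear position trend of the error rate on the
#'   logit scale, per base.
#' @param sample_sd SD of per-sample logit offsets.
#' @param resid_sd SD of observation-level logit noise.
#' @param substitution_bias named list of alt-allele weights per
#'   reference base; the default favours transitions 2:1.
#' @return an `error_model` object.
#' @export
error_model <- function(base_rate = 0.001, beta1_true = 0.005,
                        sample_sd = 0.2, resid_sd = 0.3,
                        substitution_bias = default_substitution_bias()) {
  stopifnot(base_rate > 0, base_rate < 0.05, sample_sd >= 0, resid_sd >= 0)
  structure(list(base_rate = base_rate, beta1_true = beta1_true,
                 sample_sd = sample_sd, resid_sd = resid_sd,
                 substitution_bias = substitution_bias),
            class = "error_model")
}

crc_panel_genes <- function() {
  c("TP53", "APC", "KRAS", "NRAS", "BRAF", "PIK3CA", "SMAD4", "FBXW7",
    "CTNNB1", "RNF43", "ERBB2", "DPYD", "TYMS", "TYMP", "UPP1", "MLH1",
    "MSH6", "PMS2")
}

#' Generate a synthetic panel, reference genome and mutation catalogue
#'
#' Random amplicon inserts (100-175 nt with 19-27 nt primer-binding ends,
#' named after genes of a colorectal-cancer hotspot panel) are embedded
#' once each into a synthetic multi-chromosome reference, a fraction of
#' them on the minus strand, and a COSMIC-style catalogue of hotspot
#' substitutions (some flagged as SNPs) is placed at callable offsets.
#' This is a fully synthetic stand-in for a real panel/genome/catalogue
#' triple, sized like the assay it emulates.
#'
#' @param n_amplicons number of amplicons (real panel size: 43).
#' @param seed RNG seed.
#' @param entries_per_amplicon catalogue entries placed per amplicon.
#' @param snp_fraction fraction of catalogue entries flagged `is_snp`.
#' @param minus_fraction fraction of amplicons anchored on the minus
#'   strand.
#' @param n_chrom number of synthetic chromosomes.
#' @return list with `panel` (anchored `amplicon_panel`), `reference`
#'   (`DNAStringSet`) and `catalogue` (data frame).
#' @export
synthetic_panel <- function(n_amplicons = 43L, seed = 1L,
                            entries_per_amplicon = 2L,
                            snp_fraction = 0.15, minus_fraction = 0.3,
                            n_chrom = 3L) {
  with_seed(seed, {
    genes <- rep_len(crc_panel_genes(), n_amplicons)
    name <- sprintf("%s_amp%02d", genes, seq_len(n_amplicons))
    len <- sample(100:175, n_amplicons, replace = TRUE)
    fwd <- sample(19:27, n_amplicons, replace = TRUE)
    rev <- sample(19:27, n_amplicons, replace = TRUE)
    seqs <- vapply(len, random_dna, character(1))
    pool <- rep_len(1:6, n_amplicons)
    panel <- amplicon_panel(
      data.frame(name = name, sequence = seqs, pool = pool,
                 fwd_primer_len = fwd, rev_primer_len = rev,
                 stringsAsFactors = FALSE),
      version = sprintf("synthetic-%d", seed))
    # embed each amplicon once, some reverse-complemented
    minus <- runif(n_amplicons) < minus_fraction
    chrom_of <- sort(rep_len(seq_len(n_chrom), n_amplicons))
    chroms <- vapply(seq_len(n_chrom), function(ci) {
      idx <- which(chrom_of == ci)
      parts <- character(2L * length(idx) + 1L)
      parts[1L] <- random_dna(sample(200:400, 1))
      for (j in seq_along(idx)) {
        s <- seqs[idx[j]]
        parts[2L * j] <- if (minus[idx[j]]) revcomp(s) else s
        parts[2L * j + 1L] <- random_dna(sample(200:400, 1))
      }
      paste(parts, collapse = "")
    }, character(1))
    reference <- Biostrings::DNAStringSet(setNames(
      chroms, sprintf("chr%d_sim", seq_len(n_chrom))))
    panel <- anchor_amplicons(panel, reference)
    # catalogue entries at central callable offsets (primers are designed
    # to bind 50-75 bp up- and downstream of the mutation of interest,
    # so hotspots sit mid-insert), reported on the plus strand
    entries <- lapply(seq_len(n_amplicons), function(i) {
      offs <- callable_offsets(panel, name[i])
      central <- offs[offs >= stats::quantile(offs, 0.35) &
                        offs <= stats::quantile(offs, 0.65)]
      offs <- sample(central, entries_per_amplicon)
      ref_amp <- substring(seqs[i], offs, offs)
      alt_amp <- vapply(ref_amp, function(b)
        sample(setdiff(DNA_BASES, b), 1), character(1), USE.NAMES = FALSE)
      g <- amplicon_to_genome(panel, rep(name[i], length(offs)), offs)
      is_minus <- panel$amplicons$strand[panel_row(panel, name[i])] == "-"
      data.frame(chrom = g$chrom, pos = g$pos,
                 ref = if (is_minus) complement_base(ref_amp) else ref_amp,
                 alt = if (is_minus) complement_base(alt_amp) else alt_amp,
                 gene = genes[i], stringsAsFactors = FALSE)
    })
    catalogue <- do.call(rbind, entries)
    catalogue$variant_id <- sprintf("SIMC%04d", seq_len(nrow(catalogue)))
    catalogue$is_snp <- runif(nrow(catalogue)) < snp_fraction
    list(panel = panel, reference = reference,
         catalogue = validate_catalogue(catalogue))
  })
}

check_variant_table <- function(variants, panel, samples) {
  if (is.null(variants) || nrow(variants) == 0L) return(NULL)
  variants <- as.data.frame(variants)
  stopifnot(all(c("amplicon", "offset", "alt", "maf") %in% names(variants)))
  if (is.null(variants$sample_id)) variants$sample_id <- NA_character_
  i <- panel_row(panel, variants$amplicon)
  a <- panel$amplicons
  if (any(variants$offset < 1L | variants$offset > a$length[i]))
    stop("injected variant offset outside its amplicon", call. = FALSE)
  masked <- variants$offset <= a$fwd_primer_len[i] |
    variants$offset > a$length[i] - a$rev_primer_len[i]
  if (any(masked))
    warning("injected variant(s) fall in primer-masked offsets and will ",
            "not be callable", call. = FALSE)
  ref_amp <- substring(a$sequence[i], variants$offset, variants$offset)
  if (any(ref_amp == variants$alt))
    stop("injected variant alt equals the reference base", call. = FALSE)
  if (any(variants$maf <= 0 | variants$maf > 1))
    stop("injected maf must lie in (0, 1]", call. = FALSE)
  bad <- !is.na(variants$sample_id) & !(variants$sample_id %in% samples)
  if (any(bad))
    stop("injected variant targets unknown sample(s): ",
         paste(unique(variants$sample_id[bad]), collapse = ", "),
         call. = FALSE)
  variants
}

#' Simulate a per-position count table
#'
#' For every (sample, amplicon, offset) a sequencing depth is drawn
#' (negative-binomial across amplicons, or fixed via `depth`), an error
#' probability is drawn on the logit scale as
#' `qlogis(base_rate) + beta1_true * offset + sample offset +
#' N(0, resid_sd^2)`, and the error count is binomial at that
#' probability with one alt allele per position drawn from the
#' substitution bias. Injected variants add independent binomial counts
#' at their mutant allele fraction on top of the noise. The
#' negative-binomial defaults (`depth_mean = 7500`, `depth_size = 2`)
#' spread depths over roughly 500-21000 between the 1st and 99th
#' percentile, matching the depth spread of a real multiplex run.
#'
#' @param panel `amplicon_panel` (anchored panels yield genomic
#'   coordinates).
#' @param samples character vector of sample ids.
#' @param error an [error_model()].
#' @param variants optional data frame of injected variants
#'   (`amplicon`, `offset` -- amplicon orientation --, `alt`, `maf`,
#'   optional `sample_id`; `NA` sample means every sample).
#' @param depth fixed depth overriding the negative-binomial draw.
#' @param depth_mean,depth_size negative-binomial depth parameters
#'   (one draw per sample x amplicon).
#' @param seed RNG seed (required; generation is deterministic given
#'   parameters and seed).
#' @return a count table (see [build_pileup()] for columns) with an
#'   attached `"truth"` attribute listing every injected variant per
#'   sample in genomic plus-strand coordinates.
#' @export
simulate_pileup_counts <- function(panel, samples, error = error_model(),
                                   variants = NULL, depth = NULL,
                                   depth_mean = 7500, depth_size = 2,
                                   seed) {
  stopifnot(inherits(panel, "amplicon_panel"), length(samples) >= 1L)
  variants <- check_variant_table(variants, panel, samples)
  fixed_depth <- depth
  a <- panel$amplicons
  with_seed(seed, {
    sample_off <- setNames(rnorm(length(samples), 0, error$sample_sd),
                           samples)
    grid <- CJ(sample_id = samples, amp_i = seq_len(nrow(a)))
    grid <- grid[, .(offset = seq_len(a$length[amp_i])),
                 by = .(sample_id, amp_i)]
    grid[, amplicon := a$name[amp_i]]
    grid[, ref_amp := substring(a$sequence[amp_i], offset, offset)]
    # one depth draw per sample x amplicon
    d <- CJ(sample_id = samples, amp_i = seq_len(nrow(a)))
    d[, depth := if (is.null(fixed_depth))
      rnbinom(.N, mu = depth_mean, size = depth_size) + 1L else
        as.integer(fixed_depth)]
    grid <- d[grid, on = c("sample_id", "amp_i")]
    eps <- rnorm(nrow(grid), 0, error$resid_sd)
    p_err <- plogis(qlogis(error$base_rate) + error$beta1_true * grid$offset +
                      sample_off[grid$sample_id] + eps)
    grid[, err_count := rbinom(.N, depth, p_err)]
    # one drawn alt allele per position carries the whole error count
    bias <- error$substitution_bias
    grid[, err_alt := {
      alts <- names(bias[[ref_amp[1L]]])
      w <- bias[[ref_amp[1L]]]
      sample(alts, .N, replace = TRUE, prob = w / sum(w))
    }, by = ref_amp]
    alt_rows <- grid[err_count > 0L,
                     .(sample_id, amplicon, offset, allele = err_alt,
                       count = err_count)]
    if (!is.null(variants)) {
      vdf <- variants
      na_s <- is.na(vdf$sample_id)
      if (any(na_s)) {  # NA sample -> variant carried by every sample
        rep_rows <- vdf[na_s, , drop = FALSE]
        rep_rows <- rep_rows[rep(seq_len(nrow(rep_rows)),
                                 each = length(samples)), , drop = FALSE]
        rep_rows$sample_id <- rep(samples, sum(na_s))
        vdf <- rbind(vdf[!na_s, , drop = FALSE], rep_rows)
      }
      v <- as.data.table(vdf[, c("sample_id", "amplicon", "offset",
                                 "alt", "maf")])
      v <- grid[, .(sample_id, amplicon, offset, depth)][
        v, on = c("sample_id", "amplicon", "offset"), nomatch = NULL]
      v[, count := rbinom(.N, depth, maf)]
      alt_rows <- rbind(alt_rows,
                        v[count > 0L, .(sample_id, amplicon, offset,
                                        allele = alt, count)])
      alt_rows <- alt_rows[, .(count = sum(count)),
                           by = .(sample_id, amplicon, offset, allele)]
    }
    base <- grid[, .(sample_id, amplicon, offset, ref_amp, depth)]
    alt_rows <- base[alt_rows, on = c("sample_id", "amplicon", "offset")]
    alt_sum <- alt_rows[, .(alt_total = sum(count)),
                        by = .(sample_id, amplicon, offset)]
    ref_rows <- alt_sum[base, on = c("sample_id", "amplicon", "offset")]
    ref_rows[is.na(alt_total), alt_total := 0L]
    ref_rows[, count := pmax(depth - alt_total, 0L)]
    out <- rbind(
      ref_rows[, .(sample_id, amplicon, offset, allele = ref_amp, count,
                   total = alt_total + count)],
      alt_rows[alt_sum, on = c("sample_id", "amplicon", "offset")][
        , .(sample_id, amplicon, offset, allele, count,
            total = pmax(depth - alt_total, 0L) + alt_total)])
    out <- out[count > 0L]
    setnames(out, "total", "depth")
    counts <- finalize_count_table(as.data.frame(out), panel,
                                   mask_primers = FALSE)
    attr(counts, "truth") <- variant_truth(variants, panel, samples)
    counts
  })
}

# genomic plus-strand truth table for injected variants
variant_truth <- function(variants, panel, samples) {
  if (is.null(variants) || nrow(variants) == 0L)
    return(data.frame(sample_id = character(0), amplicon = character(0),
                      offset = integer(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), maf = numeric(0),
                      stringsAsFactors = FALSE))
  v <- as.data.frame(variants)
  expand <- lapply(seq_len(nrow(v)), function(j) {
    sids <- if (is.na(v$sample_id[j])) samples else v$sample_id[j]
    data.frame(sample_id = sids, amplicon = v$amplicon[j],
               offset = as.integer(v$offset[j]), alt_amp = v$alt[j],
               maf = v$maf[j], stringsAsFactors = FALSE)
  })
  tv <- do.call(rbind, expand)
  i <- panel_row(panel, tv$amplicon)
  a <- panel$amplicons
  ref_amp <- substring(a$sequence[i], tv$offset, tv$offset)
  if (is_anchored(panel)) {
    g <- amplicon_to_genome(panel, tv$amplicon, tv$offset)
    minus <- a$strand[i] == "-"
    tv$chrom <- g$chrom
    tv$pos <- g$pos
    tv$ref <- ifelse(minus, complement_base(ref_amp), ref_amp)
    tv$alt <- ifelse(minus, complement_base(tv$alt_amp), tv$alt_amp)
  } else {
    tv$chrom <- NA_character_
    tv$pos <- NA_integer_
    tv$ref <- ref_amp
    tv$alt <- tv$alt_amp
  }
  tv[, c("sample_id", "amplicon", "offset", "chrom", "pos", "ref", "alt",
         "maf")]
}

#' Simulate a two-genotype dilution series
#'
#' Emulates mixing sheared genomic DNA of two cell lines with disjoint
#' monoallelic variant sets: at mix fraction `f` of genotype B into
#' genotype A, B's monoallelic variants have true mutant allele
#' fraction `f / 2` and A's `(1 - f) / 2`. One sample is generated per
#' fraction, all sharing the error model, so the caller can be scored
#' against the known detection floor.
#'
#' @param panel `amplicon_panel`.
#' @param genotype_a,genotype_b data frames (`amplicon`, `offset`,
#'   `alt`) of the two genotypes' monoallelic variants; the
#'   (amplicon, offset) sets must be disjoint.
#' @param fractions minor-genotype mix fractions in (0, 1); 0 is
#'   allowed and yields a noise-only sample for genotype B.
#' @param depth fixed per-amplicon depth of the series.
#' @param error an [error_model()].
#' @param seed RNG seed.
#' @return list with `counts` (count table of all mixes), `truth`
#'   (injected-variant truth table), and `sample_fractions` (named
#'   vector mapping sample id to mix fraction).
#' @export
simulate_dilution_series <- function(panel, genotype_a, genotype_b,
                                     fractions = c(0.2, 0.1, 0.05, 0.025,
                                                   0.0125),
                                     depth = 7500, error = error_model(),
                                     seed) {
  genotype_a <- as.data.frame(genotype_a)
  genotype_b <- as.data.frame(genotype_b)
  key_a <- paste(genotype_a$amplicon, genotype_a$offset)
  key_b <- paste(genotype_b$amplicon, genotype_b$offset)
  if (length(intersect(key_a, key_b)))
    stop("genotype variant definitions overlap", call. = FALSE)
  stopifnot(all(fractions >= 0), all(fractions < 1))
  samples <- sprintf("mix_%g", fractions * 100)
  one_geno <- function(g, maf_of, geno) {
    do.call(rbind, lapply(seq_along(fractions), function(k) {
      maf <- maf_of(fractions[k])
      if (maf <= 0 || nrow(g) == 0L) return(NULL)
      data.frame(amplicon = g$amplicon, offset = g$offset, alt = g$alt,
                 maf = maf, sample_id = samples[k], genotype = geno,
                 stringsAsFactors = FALSE)
    }))
  }
  variants <- rbind(one_geno(genotype_b, function(f) f / 2, "B"),
                    one_geno(genotype_a, function(f) (1 - f) / 2, "A"))
  counts <- simulate_pileup_counts(panel, samples, error = error,
                                   variants = variants, depth = depth,
                                   seed = seed)
  truth <- attr(counts, "truth")
  truth$genotype <- variants$genotype[match(
    paste(truth$sample_id, truth$amplicon, truth$offset),
    paste(variants$sample_id, variants$amplicon, variants$offset))]
  attr(counts, "truth") <- truth
  list(counts = counts, truth = truth,
       sample_fractions = setNames(fractions, samples))
}

#' Simulate FASTQ reads from panel amplicons
#'
#' Reads are 150 nt (or full-length for shorter amplicons) copies of an
#' amplicon starting at either primer (random strand), with per-base
#' substitution errors at probability `10^(-q/10)` under phred qualities
#' drawn from a clipped normal. Variants can be forced into a fraction
#' of the covering reads, and a low-quality tail can be appended to
#' exercise the trimming rules.
#'
#' @param panel `amplicon_panel`.
#' @param reads_per_amplicon scalar or named vector of read counts.
#' @param sample_id sample label for all reads.
#' @param quality_mean,quality_sd parameters of the per-base quality
#'   distribution (clipped to 2-40).
#' @param error_rate per-base substitution probability; the default
#'   `NULL` derives it from the base quality as `10^(-q/10)`, and `0`
#'   yields error-free reads.
#' @param variants optional data frame `amplicon`, `offset`, `alt`
#'   (amplicon orientation), `fraction` of covering reads to carry the
#'   alt base.
#' @param low_quality_tail number of low-quality (phred 2-10) random
#'   bases appended to each read.
#' @param seed RNG seed.
#' @return read table (`read_id`, `sample_id`, `bases`, `quals`) ready
#'   for [trim_reads()] or [write_fastq()].
#' @export
simulate_fastq <- function(panel, reads_per_amplicon = 500L,
                           sample_id = "sim", quality_mean = 35,
                           quality_sd = 3, error_rate = NULL,
                           variants = NULL, low_quality_tail = 0L, seed) {
  stopifnot(inherits(panel, "amplicon_panel"))
  a <- panel$amplicons
  nreads <- if (length(reads_per_amplicon) == 1L)
    setNames(rep(as.integer(reads_per_amplicon), nrow(a)), a$name) else
      reads_per_amplicon[a$name]
  if (!is.null(variants)) {
    variants <- as.data.frame(variants)
    stopifnot(all(c("amplicon", "offset", "alt", "fraction") %in%
                    names(variants)))
  }
  with_seed(seed, {
    out <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) {
      n <- nreads[[a$name[i]]]
      if (is.na(n) || n == 0L) next
      L <- a$length[i]
      read_len <- min(150L, L)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      tmpl_fwd <- strsplit(substring(a$sequence[i], 1L, read_len),
                           "")[[1L]]
      tmpl_rev_src <- strsplit(substring(a$sequence[i], L - read_len + 1L,
                                         L), "")[[1L]]
      # base matrix in amplicon orientation; reverse-complement at the end
      m <- matrix(tmpl_fwd, nrow = n, ncol = read_len, byrow = TRUE)
      is_rev <- strand == "-"
      if (any(is_rev))
        m[is_rev, ] <- matrix(tmpl_rev_src, nrow = sum(is_rev),
                              ncol = read_len, byrow = TRUE)
      # amplicon offset covered by each matrix column
      off_fwd <- seq_len(read_len)
      off_rev <- (L - read_len + 1L):L
      if (!is.null(variants)) {
        vv <- variants[variants$amplicon == a$name[i], , drop = FALSE]
        for (j in seq_len(nrow(vv))) {
          col_f <- match(vv$offset[j], off_fwd)
          col_r <- match(vv$offset[j], off_rev)
          covers <- (!is_rev & !is.na(col_f)) | (is_rev & !is.na(col_r))
          pick <- which(covers)
          pick <- pick[seq_len(round(vv$fraction[j] * length(pick)))]
          for (r in pick)
            m[r, if (is_rev[r]) col_r else col_f] <- vv$alt[j]
        }
      }
      q <- matrix(pmin(40L, pmax(2L, round(rnorm(n * read_len,
                                                 quality_mean,
                                                 quality_sd)))),
                  nrow = n)
      p_err <- if (is.null(error_rate)) 10^(-q / 10) else error_rate
      err <- matrix(runif(n * read_len) < p_err, nrow = n)
      if (any(err)) {
        idx <- which(err)
        m[idx] <- vapply(m[idx], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1),
          USE.NAMES = FALSE)
      }
      if (any(is_rev)) {  # emit minus-strand reads 5'->3'
        comp <- matrix(complement_base(m[is_rev, , drop = FALSE]),
                       nrow = sum(is_rev))
        m[is_rev, ] <- comp[, rev(seq_len(read_len)), drop = FALSE]
      }
      if (low_quality_tail > 0L) {
        tail_b <- matrix(sample(DNA_BASES, n * low_quality_tail,
                                replace = TRUE), nrow = n)
        tail_q <- matrix(sample(2:10, n * low_quality_tail,
                                replace = TRUE), nrow = n)
        m <- cbind(m, tail_b)
        q <- cbind(q, tail_q)
      }
      out[[i]] <- data.frame(
        read_id = sprintf("%s_r%05d", a$name[i], seq_len(n)),
        sample_id = sample_id,
        bases = apply(m, 1L, paste, collapse = ""),
        quals = apply(q, 1L, ints_to_qual),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

truncated_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  pmin(pmax(rlnorm(n, meanlog, sdlog), lower), upper)
}

#' Simulate a serial-sample cohort with recurrent and sporadic mutations
#'
#' Each patient carries a persistent (recurrent) mutation set present at
#' every time point, drawn from the higher of two truncated log-normal
#' allele-fraction distributions, plus transient (sporadic) mutations
#' each present at a single random time point at lower allele
#' fractions. Mutation sites are taken from the non-SNP entries of the
#' catalogue so that recovered calls survive annotation. The defaults
#' centre recurrent mutant allele fractions on 2.25% (the scale of a
#' real metastatic cfDNA cohort), truncated to the reportable range.
#'
#' @param panel anchored `amplicon_panel`.
#' @param catalogue catalogue data frame ([load_catalogue()] /
#'   [synthetic_panel()]).
#' @param n_patients,timepoints cohort dimensions.
#' @param n_recurrent,n_sporadic mutations per patient of each class.
#' @param recurrent_meanlog,recurrent_sdlog log-normal parameters of
#'   recurrent mutant allele fractions.
#' @param sporadic_meanlog,sporadic_sdlog idem for sporadic mutations.
#' @param min_maf,max_maf truncation bounds for all mutant allele
#'   fractions.
#' @param depth,depth_mean,depth_size depth model, as in
#'   [simulate_pileup_counts()].
#' @param error an [error_model()].
#' @param seed RNG seed.
#' @return list with `counts`, `sample_sheet` and `truth` (one row per
#'   injected mutation per sample, with `class` recurrent/sporadic).
#' @export
simulate_serial_cohort <- function(panel, catalogue, n_patients = 5L,
                                   timepoints = 2L, n_recurrent = 2L,
                                   n_sporadic = 1L,
                                   recurrent_meanlog = log(0.0225),
                                   recurrent_sdlog = 0.8,
                                   sporadic_meanlog = log(0.01),
                                   sporadic_sdlog = 0.6,
                                   min_maf = 0.005, max_maf = 0.967,
                                   depth = NULL, depth_mean = 7500,
                                   depth_size = 2,
                                   error = error_model(), seed) {
  stopifnot(is_anchored(panel), timepoints >= 1L)
  sites <- catalogue[!catalogue$is_snp, , drop = FALSE]
  loc <- genome_to_amplicon(panel, sites$chrom, sites$pos)
  sites$amplicon <- loc$amplicon
  sites$offset <- loc$offset
  sites <- sites[!is.na(sites$amplicon), , drop = FALSE]
  i <- panel_row(panel, sites$amplicon)
  minus <- panel$amplicons$strand[i] == "-"
  sites$alt_amp <- ifelse(minus, complement_base(sites$alt), sites$alt)
  per_patient <- n_recurrent + n_sporadic
  if (nrow(sites) < per_patient)
    stop("catalogue holds too few usable sites", call. = FALSE)
  with_seed(seed, {
    design <- vector("list", n_patients)
    sheet <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      sample_ids <- sprintf("%s_T%d", pid, seq_len(timepoints))
      sheet[[p]] <- data.frame(
        sample_id = sample_ids, patient_id = pid,
        time_index = seq_len(timepoints),
        clinical_status = sample(c("regressive", "stable", "progressive"),
                                 timepoints, replace = TRUE),
        replicate_of = NA_character_, stringsAsFactors = FALSE)
      pick <- sites[sample(nrow(sites), per_patient), , drop = FALSE]
      rec <- pick[seq_len(n_recurrent), , drop = FALSE]
      spo <- pick[n_recurrent + seq_len(n_sporadic), , drop = FALSE]
      rec_rows <- if (n_recurrent) do.call(rbind, lapply(
        seq_len(n_recurrent), function(j) {
          maf <- truncated_lnorm(1L, recurrent_meanlog, recurrent_sdlog,
                                 min_maf, max_maf)
          data.frame(amplicon = rec$amplicon[j], offset = rec$offset[j],
                     alt = rec$alt_amp[j], maf = maf,
                     sample_id = sample_ids, class = "recurrent",
                     patient_id = pid, stringsAsFactors = FALSE)
        })) else NULL
      spo_rows <- if (n_sporadic) do.call(rbind, lapply(
        seq_len(n_sporadic), function(j) {
          maf <- truncated_lnorm(1L, sporadic_meanlog, sporadic_sdlog,
                                 min_maf, max_maf)
          data.frame(amplicon = spo$amplicon[j], offset = spo$offset[j],
                     alt = spo$alt_amp[j], maf = maf,
                     sample_id = sample(sample_ids, 1L),
                     class = "sporadic", patient_id = pid,
                     stringsAsFactors = FALSE)
        })) else NULL
      design[[p]] <- rbind(rec_rows, spo_rows)
    }
    design <- do.call(rbind, design)
    sheet <- do.call(rbind, sheet)
    counts <- simulate_pileup_counts(
      panel, sheet$sample_id, error = error,
      variants = design[, c("amplicon", "offset", "alt", "maf",
                            "sample_id")],
      depth = depth, depth_mean = depth_mean, depth_size = depth_size,
      seed = seed + 1L)
    truth <- attr(counts, "truth")
    m <- match(paste(truth$sample_id, truth$amplicon, truth$offset),
               paste(design$sample_id, design$amplicon, design$offset))
    truth$class <- design$class[m]
    truth$patient_id <- design$patient_id[m]
    attr(counts, "truth") <- truth
    list(counts = counts, sample_sheet = sheet, truth = truth)
  })
}
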