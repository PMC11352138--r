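test_that("3'-terminal discrimination gates allele-specific amplification", {
  m <- fx_model()
  db <- fx_db()
  ssp <- rhd_ssp_assays()
  w1 <- ssp[ssp$assay_name == "RHD*01W.1", ]
  hap_w1 <- make_sample("x", "RHD*01W.1", "RHD*01", m, db)$haplotypes[[1]]
  hap_ref <- make_sample("x", "RHD*01", "RHD*01", m, db)$haplotypes[[1]]
  amp <- find_amplicon(hap_w1$rhd, w1$fwd_seq, w1$rev_seq)
  expect_false(is.null(amp))
  expect_null(find_amplicon(hap_ref$rhd, w1$fwd_seq, w1$rev_seq))
  expect_null(find_amplicon(NA_character_, w1$fwd_seq, w1$rev_seq))

  # the DVII assay discriminates at the reverse primer's 3' end
  dvii <- ssp[ssp$assay_name == "RHD*07.01", ]
  hap_dvii <- make_sample("x", "RHD*07.01", "RHD*07.01",
                          m, db)$haplotypes[[1]]
  expect_false(is.null(find_amplicon(hap_dvii$rhd, dvii$fwd_seq,
                                     dvii$rev_seq)))
  expect_null(find_amplicon(hap_ref$rhd, dvii$fwd_seq, dvii$rev_seq))
})

test_that("find_amplicon agrees with the brute-force scan oracle", {
  withr::with_seed(20240806, {
    for (i in 1:100) {
      case <- random_pcr_case()
      got <- find_amplicon(case$template, case$fwd, case$rev)
      want <- oracle_find_amplicon(case$template, case$fwd, case$rev)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
      }
    }
  })
})

test_that("tails are excluded from matching but restored on the product", {
  withr::with_seed(5, {
    templ <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = "")
  })
  fwd_core <- "GCTTCCGTGTTAACTCCATAGAG"
  rev_core <- "GGGGGAATCTTTTTCCTT"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_core)))
  templ <- paste0(substr(templ, 1, 50), fwd_core, substr(templ, 51, 250),
                  rc, substr(templ, 251, 400))
  tailed <- paste0(M13_TAIL, fwd_core)
  amp <- find_amplicon(templ, tailed, rev_core)
  expect_false(is.null(amp))
  expect_equal(amp$start, 50L)
  expect_equal(amp$length, nchar(amp$insert) + nchar(M13_TAIL))
  expect_true(startsWith(amp$product, M13_TAIL))
  # tail must not be required on the template
  expect_false(grepl(M13_TAIL, templ, fixed = TRUE))
})

test_that("melt curve synthesis and peak calling behave as specified", {
  one <- synthesize_melt_curve(data.frame(tm = 83.0, amplitude = 1.0))
  expect_equal(nrow(one$peaks), 1L)
  expect_lt(abs(one$peaks$tm - 83.0), 0.1 + 1e-9)
  two <- synthesize_melt_curve(data.frame(tm = c(80, 85),
                                          amplitude = c(1, 1)))
  expect_equal(nrow(two$peaks), 2L)
  flat <- synthesize_melt_curve(data.frame(tm = numeric(),
                                           amplitude = numeric()))
  expect_equal(nrow(flat$peaks), 0L)
  expect_true(all(flat$signal == 0))
})

test_that("melt classification matches standards within tolerance", {
  std <- c("RHD*01W.1" = 83.0, control = 80.7)
  expect_equal(classify_melt(c(83.0, 80.7), std), c("RHD*01W.1", "control"))
  expect_equal(classify_melt(80.7, std), "control")
  expect_equal(classify_melt(77.0, std), "unclassified_peak")
  expect_error(classify_melt(80, c(a = 80, b = 81.5), tolerance = 1.0),
               "2 x tolerance")
})

test_that("classification recovers synthesized labels (round trip)", {
  withr::with_seed(99, {
    for (i in 1:25) {
      k <- sample(2:5, 1)
      tms <- sort(70 + cumsum(runif(k, min = 2.5, max = 5)))
      tms <- tms[tms < 94]
      std <- stats::setNames(tms, paste0("p", seq_along(tms)))
      curve <- synthesize_melt_curve(data.frame(tm = tms,
                                                amplitude = 1.0))
      expect_equal(classify_melt(curve, std, tolerance = 1.0),
                   names(std))
    }
  })
})

test_that("SSP assay calls and labels follow the control logic", {
  m <- fx_model(); db <- fx_db()
  ssp <- rhd_ssp_assays()
  w3_sample <- make_sample("s", "RHD*01W.3", "RHD*01W.3", m, db)
  r <- run_ssp_assay(w3_sample, ssp[ssp$assay_name == "RHD*01W.3", ])
  expect_equal(r$call, "POSITIVE")
  expect_equal(r$genotype_label, "RHD*01W.3")

  ref_sample <- make_sample("s", "RHD*01", "RHD*01", m, db)
  r2 <- run_ssp_assay(ref_sample, ssp[ssp$assay_name == "RHD*01W.2", ])
  expect_equal(r2$call, "NEGATIVE")
  expect_equal(r2$genotype_label, "non-RHD*01W.2")
  expect_lt(abs(r2$observed_tms - 86.0), 0.1 + 1e-9)

  ntc <- run_ssp_assay(make_ntc(), ssp[1, ])
  expect_equal(length(ntc$observed_tms), 0L)
  expect_equal(ntc$call, "INVALID")
})

test_that("SSP positivity equals truth-variant presence over the panel", {
  panel <- fx_panel()
  db <- fx_db()
  ssp <- rhd_ssp_assays()
  for (s in panel) {
    for (a in seq_len(nrow(ssp))) {
      res <- run_ssp_assay(s, ssp[a, ])
      # a sample with a control locus can never be INVALID
      expect_true(res$call %in% c("POSITIVE", "NEGATIVE"))
      truth_pos <- ssp$assay_name[a] %in% s$truth
      expect_equal(res$call == "POSITIVE", truth_pos,
                   info = paste(s$sample_id, ssp$assay_name[a]))
    }
  }
})

test_that("exon profiles reflect the structural allele classes", {
  m <- fx_model(); db <- fx_db()
  full <- amplify_exons(make_sample("a", "RHD*01", "RHD*01", m, db))
  expect_true(all(full$present))
  none <- amplify_exons(make_sample("b", "RHD*01N.01", "RHD*01N.01", m, db))
  expect_false(any(none$present))
  hyb <- amplify_exons(make_sample("c", "RHD*04.03", "RHD*04.03", m, db))
  expect_equal(hyb$exon[!hyb$present], 6:9)
  # heterozygous deletion: the full-gene haplotype rescues all exons
  hemi <- amplify_exons(make_sample("d", "RHD*01W.1", "RHD*01N.01", m, db))
  expect_true(all(hemi$present))
})

test_that("nearest-neighbor Tm estimate matches independent recomputation", {
  # frozen values verified against an independent implementation of the
  # unified NN parameters with the 0.368 (N-1) ln[Na+] entropy correction
  expect_equal(estimate_tm("ACGTACGTACGTACGTACGT"), 55.2220, tolerance = 1e-4)
  expect_equal(estimate_tm("GGGCCCGGGCCCGGGCCCGG"), 75.6823, tolerance = 1e-4)
  expect_equal(estimate_tm("ATATATATATATATATATAT"), 26.3470, tolerance = 1e-4)
  expect_equal(estimate_tm("CTGGGCAGGTTGGTATCAGGAGAGTCAGTGCC"), 67.4561,
               tolerance = 1e-4)

  # independent per-dinucleotide recomputation on a fresh random sequence
  withr::with_seed(3, {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  })
  dh_tab <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2, CA = -8.5,
              CC = -8.0, CG = -10.6, CT = -7.8, GA = -8.2, GC = -9.8,
              GG = -8.0, GT = -8.4, TA = -7.2, TC = -8.2, TG = -8.5,
              TT = -7.9)
  ds_tab <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4, CA = -22.7,
              CC = -19.9, CG = -27.2, CT = -21.0, GA = -22.2, GC = -24.4,
              GG = -19.9, GT = -22.4, TA = -21.3, TC = -22.2, TG = -22.7,
              TT = -22.2)
  ch <- strsplit(s, "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(ch) - 1)) {
    key <- paste0(ch[i], ch[i + 1])
    dh <- dh + dh_tab[[key]]; ds <- ds + ds_tab[[key]]
  }
  for (b in ch[c(1, length(ch))]) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(ch) - 1) * log(0.05)
  want <- 1000 * dh / (ds + 1.987 * log(2.5e-7 / 4)) - 273.15
  expect_equal(estimate_tm(s), want, tolerance = 1e-10)
})

test_that("Tm estimate is monotone in GC content and length", {
  low_gc <- "ATTAGCTAATTAGCTAATTAGCTAATTAGCTA"
  high_gc <- "GCCAGCTGGCCAGCTGGCCAGCTGGCCAGCTG"
  expect_lt(estimate_tm(low_gc), estimate_tm(high_gc))
  amp <- "CTGGGCAGGTTGGTATCAGGAGAGTCAGTGCC"
  expect_gte(estimate_tm(paste0(amp, amp)), estimate_tm(amp))
  expect_error(estimate_tm(""), "at least two")
  expect_error(estimate_tm("ACGTN"), "non-ACGT")
})
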