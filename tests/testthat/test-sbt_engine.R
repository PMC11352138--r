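make_toy_trace <- function(bases, qv, exon = 7L, start = 0L) {
  t <- list(sample_id = "toy", exon = exon, genomic_start = start,
            orientation = "forward", bases = bases, qv = qv)
  class(t) <- "rhd_trace"
  t
}

test_that("QV filtering partitions calls at the inclusive threshold", {
  tr <- make_toy_trace(c("A", "C", "G", "R", "T"),
                       c(20L, 19L, 45L, 40L, 0L))
  f <- filter_read(tr, qv_threshold = 20L)
  expect_equal(f$status,
               c("accepted", "low_quality", "accepted", "mixed_base",
                 "low_quality"))
  # the accepted error probability bound
  expect_true(all(phred_error_prob(f$qv[f$status == "accepted"]) <= 0.01))
  # idempotence
  f2 <- filter_read(f, qv_threshold = 20L)
  expect_identical(f2$status, f$status)
})

test_that("raising the threshold never accepts more positions", {
  withr::with_seed(17, {
    tr <- make_toy_trace(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                         sample(0:60, 200, replace = TRUE))
  })
  n_prev <- Inf
  for (thr in c(0L, 10L, 20L, 30L, 60L)) {
    n <- sum(filter_read(tr, thr)$status == "accepted")
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("variant calling recovers panel genotypes from traces", {
  m <- fx_model(); db <- fx_db()
  dnb <- make_sample("2023-33", "RHD*25", "RHD*01", m, db)
  reads <- lapply(simulate_sample_traces(dnb, m, seed = 7), filter_read)
  vc <- call_variants(reads, m)
  expect_equal(nrow(vc$calls), 1L)
  expect_equal(vc$calls$cds_pos, 1063L)
  expect_equal(vc$calls$zygosity, "heterozygous")
  expect_equal(vc$calls$alt, "A")
  expect_length(vc$uncovered, 0L)
  expect_equal(summarize_cds(vc), "NM_016124.6:c.[1063G>A];[1063=]")

  ref <- make_sample("r", "RHD*01", "RHD*01", m, db)
  vc0 <- call_variants(lapply(simulate_sample_traces(ref, m, seed = 8),
                              filter_read), m)
  expect_equal(nrow(vc0$calls), 0L)
  expect_equal(summarize_cds(vc0), "NM_016124.6:c.1_1254=")

  w11 <- make_sample("w11", "RHD*11", "RHD*11", m, db)
  vc11 <- call_variants(lapply(simulate_sample_traces(w11, m, seed = 9),
                               filter_read), m)
  expect_equal(summarize_cds(vc11), "NM_016124.6:c.885G>T")
})

test_that("injected variants round-trip through tracing and calling", {
  m <- fx_model(); db <- fx_db()
  bases <- c("A", "C", "G", "T")
  ref_cds <- strsplit(extract_cds(m), "")[[1]]
  withr::with_seed(2024, {
    for (i in 1:50) {
      n_var <- sample(1:3, 1)
      pos <- sort(sample(1254L, n_var))
      zyg <- sample(c("hom", "het"), n_var, replace = TRUE)
      alt <- vapply(pos, function(p) sample(setdiff(bases, ref_cds[p]), 1),
                    character(1))
      g <- strsplit(m$genomic, "")[[1]]
      h1 <- g; h2 <- g
      gpos <- cds_to_genomic(m, pos)
      for (j in seq_len(n_var)) {
        h1[gpos[j] + 1L] <- alt[j]
        if (zyg[j] == "hom") h2[gpos[j] + 1L] <- alt[j]
      }
      s <- sample_from_sequences(paste0("sim", i),
                                 paste(h1, collapse = ""),
                                 paste(h2, collapse = ""), m)
      vc <- call_variants(lapply(simulate_sample_traces(s, m, seed = i),
                                 filter_read), m)
      expect_equal(vc$calls$cds_pos, pos)
      expect_equal(vc$calls$alt, alt)
      expect_equal(vc$calls$zygosity,
                   ifelse(zyg == "hom", "homozygous_or_hemizygous",
                          "heterozygous"))
      expect_length(vc$uncovered, 0L)
    }
  })
})

test_that("incomplete coverage is qualified, misplacement is an error", {
  m <- fx_model(); db <- fx_db()
  ref <- make_sample("r", "RHD*01", "RHD*01", m, db)
  reads <- lapply(simulate_sample_traces(ref, m, exons = c(1:6, 8:10),
                                         seed = 3), filter_read)
  vc <- call_variants(reads, m)
  expect_length(vc$uncovered, 134L) # all of exon 7
  expect_match(summarize_cds(vc), "incomplete", fixed = TRUE)

  bad <- simulate_trace(ref, 5L, m, seed = 4)
  bad$genomic_start <- bad$genomic_start + 1L
  expect_error(call_variants(list(bad), m), "exon 5")
})

test_that("degraded traces never yield a wrong accepted call", {
  m <- fx_model(); db <- fx_db()
  w5 <- make_sample("w5", "RHD*01W.5", "RHD*01W.5", m, db)
  vc <- call_variants(lapply(
    simulate_sample_traces(w5, m, profile = qv_profile("degraded"),
                           seed = 77), filter_read), m)
  # every call that was accepted must be the true variant; low-quality
  # positions (potential miscalls) become coverage gaps, not calls
  expect_true(all(vc$calls$cds_pos == 446L))
  expect_gt(length(vc$uncovered), 0L)
})
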