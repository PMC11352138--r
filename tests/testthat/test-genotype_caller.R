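fake_profile <- function(present) {
  p <- data.frame(exon = 1:10, present = present,
                  observed_tm = ifelse(present, rhd_exon_assays()$tm,
                                       NA_real_))
  class(p) <- c("rhd_exon_profile", class(p))
  p
}

fake_ssp <- function(calls) {
  assays <- rhd_ssp_assays()$assay_name
  lapply(seq_along(assays), function(i) {
    r <- list(assay_name = assays[i], call = calls[i],
              observed_tms = numeric(), genotype_label = assays[i])
    class(r) <- "rhd_ssp_result"
    r
  })
}

test_that("triage routes follow the two-stage decision rule", {
  db <- fx_db()
  pos_w1 <- fake_ssp(c("POSITIVE", "NEGATIVE", "NEGATIVE", "NEGATIVE"))
  neg <- fake_ssp(rep("NEGATIVE", 4))

  t1 <- triage(pos_w1, fake_profile(rep(TRUE, 10)), db, mode = "routine")
  expect_equal(t1$route, "REPORT_FROM_SSP")
  expect_equal(t1$allele, "RHD*01W.1")
  # study mode still sequences SSP positives
  t1s <- triage(pos_w1, fake_profile(rep(TRUE, 10)), db, mode = "study")
  expect_equal(t1s$route, "SEQUENCE")

  t2 <- triage(neg, fake_profile(rep(FALSE, 10)), db)
  expect_equal(t2$route, "SUSPECT_DELETION")
  expect_equal(t2$allele, "RHD*01N.01")
  expect_true("confirmation_required" %in% t2$flags)

  t3 <- triage(neg, fake_profile(!(1:10 %in% 6:9)), db)
  expect_equal(t3$route, "SUSPECT_HYBRID")
  expect_equal(t3$allele, "RHD*04.03")
  expect_true("confirmation_required" %in% t3$flags)

  t4 <- triage(neg, fake_profile(!(1:10 %in% 3L)), db)
  expect_equal(t4$route, "SEQUENCE")
  expect_true("unexplained_dropout" %in% t4$flags)

  expect_error(triage(fake_ssp(rep("INVALID", 4)),
                      fake_profile(rep(TRUE, 10)), db), "invalid")
})

test_that("final reports carry allele, phenotype and evidence", {
  run <- fx_run_study()
  rep_ <- run$reports
  expect_equal(rep_$genotype[rep_$sample_id == "2020-34"], "RHD*07.01")
  expect_equal(rep_$phenotype[rep_$sample_id == "2020-34"], "DVII")
  expect_equal(rep_$genotype[rep_$sample_id == "2021-32"], "RHD*01EL.01")
  expect_equal(rep_$phenotype[rep_$sample_id == "2021-32"], "Del")
  expect_equal(rep_$phenotype[rep_$sample_id == "2023-33"], "DNB het.")
  expect_equal(rep_$hgvs_summary[rep_$sample_id == "2023-33"],
               "NM_016124.6:c.[1063G>A];[1063=]")
  # deletion genotypes cite the exon profile, never SSP negativity
  del <- rep_[rep_$route == "SUSPECT_DELETION", ]
  expect_equal(nrow(del), 5L)
  expect_true(all(del$exon_profile == "0000000000"))
  expect_true(all(grepl("NEGATIVE", del$ssp_calls)))
  expect_true(all(grepl("confirmation_required", del$flags)))
})

test_that("contradictory SSP and sequencing evidence raises a flag", {
  m <- fx_model(); db <- fx_db()
  s <- make_sample("r", "RHD*01", "RHD*01", m, db)
  profile <- amplify_exons(s)
  ssp_pos <- fake_ssp(c("POSITIVE", "NEGATIVE", "NEGATIVE", "NEGATIVE"))
  dec <- triage(ssp_pos, profile, db, mode = "study")
  vc <- call_variants(lapply(simulate_sample_traces(s, m, seed = 2),
                             filter_read), m)
  rep_ <- type_sample(s, ssp_pos, profile, dec, vc, db)
  expect_match(rep_$flags, "discordant")
  # and the honest case is unflagged
  ssp_neg <- fake_ssp(rep("NEGATIVE", 4))
  dec2 <- triage(ssp_neg, profile, db, mode = "study")
  rep2 <- type_sample(s, ssp_neg, profile, dec2, vc, db)
  expect_false(grepl("discordant", rep2$flags))
})

test_that("study-mode panel run reproduces the evaluation arithmetic", {
  run <- fx_run_study()
  s <- run$summary
  expect_true(s$run_valid)
  expect_equal(as.integer(s$routes[["SEQUENCE"]]), 18L)
  expect_equal(s$chromatograms, 180L)
  expect_equal(as.integer(s$ssp_positives[["RHD*01W.1"]]), 2L)
  # conservation: routes partition the panel
  expect_equal(sum(as.integer(s$routes)), 24L)
})

test_that("routine mode reports SSP positives without sequencing them", {
  routine <- run_panel(fx_panel(), fx_model(), fx_db(), mode = "routine")
  study <- fx_run_study()
  expect_equal(sum(as.integer(routine$summary$routes)), 24L)
  expect_equal(as.integer(routine$summary$routes[["REPORT_FROM_SSP"]]), 5L)
  expect_equal(as.integer(routine$summary$routes[["SEQUENCE"]]), 13L)
  expect_lt(routine$summary$chromatograms, study$summary$chromatograms)
  # identical final genotypes in both modes
  expect_equal(routine$reports$genotype, study$reports$genotype)
})
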