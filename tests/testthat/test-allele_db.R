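test_that("HGVS substitution parsing and formatting are mutual inverses", {
  v <- hgvs_parse("NM_016124.6:c.809T>G")
  expect_equal(v$cds_pos, 809L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "G")
  expect_equal(attr(v, "ref_id"), "NM_016124.6")

  v8 <- hgvs_parse("NM_016124.6:c.8C>G")
  expect_equal(unlist(v8[1, ]), c(cds_pos = "8", ref = "C", alt = "G"))

  expect_equal(hgvs_format(v), "NM_016124.6:c.809T>G")
  expect_equal(hgvs_format(v[0, ]), "NM_016124.6:c.1_1254=")
  expect_equal(nrow(hgvs_parse("NM_016124.6:c.1_1254=")), 0L)

  withr::with_seed(11, {
    for (i in 1:50) {
      pos <- sample(1254L, 1)
      rb <- sample(c("A", "C", "G", "T"), 2)
      df <- data.frame(cds_pos = pos, ref = rb[1], alt = rb[2])
      rt <- hgvs_parse(hgvs_format(df))
      expect_equal(rt$cds_pos, pos)
      expect_equal(rt$ref, rb[1])
      expect_equal(rt$alt, rb[2])
    }
  })
})

test_that("non-substitution and malformed HGVS are rejected explicitly", {
  expect_error(hgvs_parse("NM_016124.6:c.809delT"), "unsupported")
  expect_error(hgvs_parse("NM_016124.6:c.809_810insA"), "unsupported")
  expect_error(hgvs_parse("NM_016124.6:c.809dup"), "unsupported")
  expect_error(hgvs_parse("NM_016124.6:c.1300T>G"), "outside")
  expect_error(hgvs_parse("NM_016124.6:c.809T>T"), "identical")
  expect_error(hgvs_parse("garbage"), "not an HGVS")
})

test_that("the packaged allele database holds the full panel allele set", {
  db <- fx_db()
  expect_s3_class(db, "rhd_allele_db")
  needed <- c("RHD*01", "RHD*01N.01", "RHD*01W.1", "RHD*01W.2", "RHD*01W.3",
              "RHD*01W.5", "RHD*07.01", "RHD*04.03", "RHD*01EL.01",
              "RHD*19", "RHD*25", "RHD*11")
  expect_true(all(needed %in% db$allele_name))
  w1 <- db[db$allele_name == "RHD*01W.1", ]
  expect_equal(w1$variants[[1]]$cds_pos, 809L)
  expect_equal(w1$variants[[1]]$alt, "G")
  expect_equal(w1$phenotype_label, "weak D type 1")
  ref <- db[db$allele_name == "RHD*01", ]
  expect_equal(nrow(ref$variants[[1]]), 0L)
  expect_equal(ref$category, "normal")
  hyb <- db[db$allele_name == "RHD*04.03", ]
  expect_equal(hyb$dropped_exons[[1]], 6:9)
})

test_that("malformed allele tables are rejected with the record index", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  base <- readLines(system.file("extdata", "rhd_alleles.tsv",
                                package = "rhdtyper"))
  writeLines(c(base, base[3]), tmp) # duplicate RHD*01W.1 row
  expect_error(load_allele_db(tmp), "duplicate")

  writeLines(c(base[1],
               "X*BAD\tNM_016124.6:c.1300T>G\tFULL_GENE\t\tweak D\tx\t"),
             tmp)
  expect_error(load_allele_db(tmp), "record 1")

  writeLines(c(base[1],
               "X*BAD\tNM_016124.6:c.809T>G\tGENE_ABSENT\t\tweak D\tx\t"),
             tmp)
  expect_error(load_allele_db(tmp), "GENE_ABSENT")

  writeLines(c(base[1], "X*BAD\t\tEXON_DROPOUT\t2;5\tpartial D\tx\t"), tmp)
  expect_error(load_allele_db(tmp), "contiguous")
})

test_that("variant matching reproduces the typing assignment rules", {
  db <- fx_db()
  # lone heterozygous DNB variant: in trans to an unaltered reference allele
  obs <- data.frame(cds_pos = 1063L, ref = "G", alt = "A",
                    zygosity = "heterozygous")
  ac <- match_variants(obs, db)
  expect_equal(ac$allele_pair, c("RHD*25", "RHD*01"))
  expect_equal(ac$note, "heterozygous_phase_assumed")

  # no deviation from the reference CDS
  ac0 <- match_variants(NULL, db)
  expect_equal(ac0$allele_pair, c("RHD*01", "unresolved"))

  # a combination defined by no listed allele is a novel candidate,
  # reported verbatim and never an error
  obs2 <- data.frame(cds_pos = c(809L, 1154L), ref = c("T", "G"),
                     alt = c("G", "C"),
                     zygosity = rep("homozygous_or_hemizygous", 2))
  ac2 <- match_variants(obs2, db)
  expect_equal(ac2$note, "novel_candidate")
  expect_equal(ac2$unmatched$cds_pos, c(809L, 1154L))
})

test_that("single-variant alleles match by zygosity, order-independently", {
  db <- fx_db()
  single <- db[db$structural_class == "FULL_GENE" &
                 vapply(db$variants, nrow, integer(1)) == 1L, ]
  for (i in seq_len(nrow(single))) {
    v <- single$variants[[i]]
    hom <- data.frame(cds_pos = v$cds_pos, ref = v$ref, alt = v$alt,
                      zygosity = "homozygous_or_hemizygous")
    het <- data.frame(cds_pos = v$cds_pos, ref = v$ref, alt = v$alt,
                      zygosity = "heterozygous")
    expect_equal(match_variants(hom, db)$allele_pair,
                 c(single$allele_name[i], "unresolved"))
    expect_equal(match_variants(het, db)$allele_pair,
                 c(single$allele_name[i], "RHD*01"))
  }
  # order independence of the observed set
  obs <- data.frame(cds_pos = c(1154L, 809L), ref = c("G", "T"),
                    alt = c("C", "G"),
                    zygosity = rep("homozygous_or_hemizygous", 2))
  expect_equal(match_variants(obs, db)$unmatched$cds_pos,
               match_variants(obs[2:1, ], db)$unmatched$cds_pos)
})
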