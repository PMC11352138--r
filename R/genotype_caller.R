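#' Triage a sample after the SSP and exon amplification stages
#'
#' Routing rule of the two-stage scheme. In routine mode, any positive
#' allele-specific PCR reports the sample directly without sequencing. A
#' sample with no RHD amplification across exons 1-10 is suspected to carry
#' the whole-gene deletion; a contiguous absent-exon set exactly matching an
#' exon-dropout allele in the database raises suspicion of that hybrid
#' allele. Both structural suspicions require confirmation by exon-specific
#' PCR and are flagged accordingly. Everything else is routed to sequencing.
#' In study mode (the evaluation design) SSP-positive samples are sequenced
#' as well; triage is otherwise identical.
#'
#' @param ssp_results list of `rhd_ssp_result` (one per SSP assay).
#' @param exon_profile an `rhd_exon_profile` from [amplify_exons()].
#' @param db an `rhd_allele_db`.
#' @param mode `"study"` or `"routine"`.
#' @return object of class `rhd_triage`: list with `route` (one of
#'   `REPORT_FROM_SSP`, `SUSPECT_DELETION`, `SUSPECT_HYBRID`, `SEQUENCE`),
#'   `allele` (for the first two SSP/structural routes, else `NA`) and
#'   `flags`.
#' @export
triage <- function(ssp_results, exon_profile, db,
                   mode = c("study", "routine")) {
  mode <- match.arg(mode)
  stopifnot(inherits(exon_profile, "rhd_exon_profile"))
  calls <- vapply(ssp_results, function(r) r$call, character(1))
  if (any(calls == "INVALID")) {
    stop("invalid SSP reaction (internal control failed); repeat the assay",
         call. = FALSE)
  }
  positives <- vapply(ssp_results, function(r) r$assay_name,
                      character(1))[calls == "POSITIVE"]
  flags <- character()
  absent <- exon_profile$exon[!exon_profile$present]

  out <- function(route, allele = NA_character_, flags = character()) {
    structure(list(route = route, allele = allele, flags = flags),
              class = "rhd_triage")
  }
  if (mode == "routine" && length(positives) > 0L) {
    if (length(positives) > 1L) flags <- c(flags, "multiple_ssp_positives")
    return(out("REPORT_FROM_SSP", positives[1], flags))
  }
  if (length(absent) == 10L) {
    return(out("SUSPECT_DELETION", "RHD*01N.01", "confirmation_required"))
  }
  if (length(absent) > 0L) {
    hybrids <- db[db$structural_class == "EXON_DROPOUT", , drop = FALSE]
    hit <- which(vapply(hybrids$dropped_exons,
                        function(d) identical(sort(d), sort(absent)),
                        logical(1)))
    if (length(hit) == 1L) {
      return(out("SUSPECT_HYBRID", hybrids$allele_name[hit],
                 "confirmation_required"))
    }
    flags <- c(flags, "unexplained_dropout")
  }
  out("SEQUENCE", flags = flags)
}

#' @export
print.rhd_triage <- function(x, ...) {
  cat("Triage: ", x$route,
      if (!is.na(x$allele)) paste0(" (", x$allele, ")") else "",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
      else "", "\n", sep = "")
  invisible(x)
}

genotype_string <- function(pair) {
  if (!is.na(pair[2]) && pair[2] == "RHD*01" && pair[1] != "RHD*01") {
    paste0(pair[1], "/", pair[2])
  } else {
    pair[1]
  }
}

phenotype_for <- function(allele, db, het_with_reference = FALSE) {
  if (is.na(allele) || !allele %in% db$allele_name) return(NA_character_)
  label <- db_allele(db, allele)$phenotype_label
  if (het_with_reference) paste0(label, " het.") else label
}

#' Assemble the final typing report for one sample
#'
#' Combines the stage outputs into a per-well report: observed melt Tms, SSP
#' calls, the exon profile, the CDS summary (if sequenced), and the final
#' allele pair with predicted phenotype. On the sequencing route the allele
#' pair comes from [match_variants()]; on the SSP route from the positive
#' assay's identity; on structural routes from the suspected allele.
#' Contradictory evidence (an SSP-positive assay whose defining variant is
#' absent from the sequencing calls, or vice versa) raises a `discordant`
#' flag, never an error.
#'
#' @param sample an `rhd_sample`.
#' @param ssp_results list of `rhd_ssp_result`.
#' @param exon_profile an `rhd_exon_profile`.
#' @param decision an `rhd_triage`.
#' @param vc an `rhd_variant_calls`, or `NULL` when not sequenced.
#' @param db an `rhd_allele_db`.
#' @param well well position label (e.g. `"A1"`).
#' @return one-row data.frame of class `rhd_typing_report`.
#' @export
type_sample <- function(sample, ssp_results, exon_profile, decision, vc,
                        db, well = NA_character_) {
  stopifnot(inherits(sample, "rhd_sample"), inherits(decision, "rhd_triage"))
  flags <- decision$flags
  ssp_calls <- vapply(ssp_results, function(r)
    paste0(r$assay_name, "=", r$call), character(1))
  ssp_tms <- vapply(ssp_results, function(r)
    paste(format(round(r$observed_tms, 1), trim = TRUE), collapse = "/"),
    character(1))
  profile_str <- paste(as.integer(exon_profile$present), collapse = "")
  hgvs <- NA_character_
  note <- NA_character_

  if (decision$route == "SEQUENCE" && !is.null(vc)) {
    obs <- vc$calls[, c("cds_pos", "ref", "alt", "zygosity")]
    ac <- match_variants(obs, db)
    pair <- ac$allele_pair
    note <- ac$note
    if (ac$note == "novel_candidate") flags <- c(flags, "novel_candidate")
    hgvs <- summarize_cds(vc)
    genotype <- genotype_string(pair)
    phenotype <- phenotype_for(pair[1], db,
                               het_with_reference =
                                 ac$note == "heterozygous_phase_assumed")
    # SSP vs sequencing concordance for the four targeted variants
    ssp <- rhd_ssp_assays()
    for (i in seq_along(ssp_results)) {
      j <- match(ssp_results[[i]]$assay_name, ssp$assay_name)
      if (is.na(j)) next
      v <- hgvs_parse(ssp$snp[j])
      seen <- any(vc$calls$cds_pos == v$cds_pos & vc$calls$alt == v$alt)
      if (xor(ssp_results[[i]]$call == "POSITIVE", seen)) {
        flags <- c(flags, "discordant")
      }
    }
  } else if (decision$route == "REPORT_FROM_SSP") {
    pair <- c(decision$allele, "unresolved")
    genotype <- decision$allele
    phenotype <- phenotype_for(decision$allele, db)
  } else { # structural suspicion routes
    pair <- c(decision$allele, "unresolved")
    genotype <- decision$allele
    phenotype <- phenotype_for(decision$allele, db)
  }

  report <- data.frame(
    sample_id = sample$sample_id,
    well_position = well,
    route = decision$route,
    ssp_calls = paste(ssp_calls, collapse = "|"),
    ssp_tms = paste(ssp_tms, collapse = "|"),
    exon_profile = profile_str,
    hgvs_summary = hgvs,
    allele_1 = pair[1],
    allele_2 = pair[2],
    genotype = genotype,
    phenotype = phenotype,
    match_note = note,
    flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(report) <- c("rhd_typing_report", class(report))
  report
}

plate_wells <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Run the full two-stage typing pipeline over a panel
#'
#' For every sample: the four allele-specific PCR assays, the exon 1-10
#' amplification screen, triage, simulated sequencing plus variant calling
#' for sequencing-routed samples, and the final report. A no-template
#' control is processed alongside the panel; any NTC peak invalidates the
#' whole run. In study mode every amplifiable sample is sequenced regardless
#' of the SSP outcome, and the chromatogram count is ten reads per
#' sequencing-routed sample.
#'
#' @param panel list of `rhd_sample` (e.g. from [make_eqa_panel()]).
#' @param model an `rhd_gene_model`.
#' @param db an `rhd_allele_db`.
#' @param mode `"study"` or `"routine"`.
#' @param seed master seed for trace simulation.
#' @param profile a [qv_profile()].
#' @param traces optional precomputed traces: named list (by sample id) of
#'   lists of `rhd_trace`; when supplied, no simulation is performed.
#' @return object of class `rhd_run`: list with `reports` (data.frame, one
#'   row per sample), `summary` (route counts, genotype counts, chromatogram
#'   count, SSP positives per assay, `run_valid`), and `ntc` (its SSP
#'   results).
#' @export
run_panel <- function(panel, model, db, mode = c("study", "routine"),
                      seed = 20240806L, profile = qv_profile("clean"),
                      traces = NULL) {
  mode <- match.arg(mode)
  assays <- rhd_ssp_assays()
  wells <- plate_wells()

  ntc <- make_ntc()
  ntc_results <- lapply(seq_len(nrow(assays)), function(i)
    run_ssp_assay(ntc, assays[i, ]))
  ntc_peaks <- sum(vapply(ntc_results, function(r) length(r$observed_tms),
                          integer(1)))
  run_valid <- ntc_peaks == 0L

  reports <- vector("list", length(panel))
  chromatograms <- 0L
  for (i in seq_along(panel)) {
    sample <- panel[[i]]
    ssp_results <- lapply(seq_len(nrow(assays)), function(a)
      run_ssp_assay(sample, assays[a, ]))
    exon_profile <- amplify_exons(sample)
    decision <- triage(ssp_results, exon_profile, db, mode)
    vc <- NULL
    if (decision$route == "SEQUENCE") {
      exons <- exon_profile$exon[exon_profile$present]
      tr <- if (!is.null(traces)) traces[[sample$sample_id]] else
        simulate_sample_traces(sample, model, exons = exons,
                               profile = profile, seed = seed + 1000L * i)
      chromatograms <- chromatograms + length(tr)
      filtered <- lapply(tr, filter_read)
      vc <- call_variants(filtered, model)
    }
    reports[[i]] <- type_sample(sample, ssp_results, exon_profile, decision,
                                vc, db, well = wells[i])
  }
  reports <- do.call(rbind, reports)
  if (!run_valid) {
    reports$flags <- paste0(reports$flags,
                            ifelse(nzchar(reports$flags), ";", ""),
                            "run_invalid_ntc")
  }
  ssp_pos <- table(factor(unlist(lapply(seq_len(nrow(reports)), function(i) {
    calls <- strsplit(reports$ssp_calls[i], "|", fixed = TRUE)[[1]]
    sub("=POSITIVE$", "", calls[grepl("=POSITIVE$", calls)])
  })), levels = assays$assay_name))
  summary <- list(
    mode = mode,
    n_samples = nrow(reports),
    routes = table(factor(reports$route,
                          levels = c("REPORT_FROM_SSP", "SUSPECT_DELETION",
                                     "SUSPECT_HYBRID", "SEQUENCE"))),
    genotypes = table(reports$genotype),
    ssp_positives = ssp_pos,
    chromatograms = chromatograms,
    run_valid = run_valid
  )
  out <- list(reports = reports, summary = summary, ntc = ntc_results)
  class(out) <- "rhd_run"
  out
}

#' @export
print.rhd_run <- function(x, ...) {
  s <- x$summary
  cat("RHD typing run (", s$mode, " mode): ", s$n_samples, " samples; ",
      "run ", if (s$run_valid) "valid" else "INVALID (NTC)", "\n", sep = "")
  cat("routes: ", paste(names(s$routes), as.integer(s$routes),
                        sep = "=", collapse = ", "), "\n", sep = "")
  cat("chromatograms: ", s$chromatograms, "\n", sep = "")
  invisible(x)
}
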