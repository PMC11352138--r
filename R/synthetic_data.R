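IUPAC_PAIRS <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_code <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  code <- IUPAC_PAIRS[key]
  if (any(is.na(code))) stop("not a two-base combination: ", key,
                             call. = FALSE)
  unname(code)
}

iupac_bases <- function(code) {
  i <- match(code, IUPAC_PAIRS)
  if (is.na(i)) return(code)
  strsplit(names(IUPAC_PAIRS)[i], "")[[1]]
}

complement_iupac <- function(chars) {
  map <- c(A = "T", C = "G", G = "C", T = "A",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K", N = "N")
  unname(map[chars])
}

#' Construct a diploid RHD sample from two allele names
#'
#' Each haplotype is built from the synthetic reference: sequence-defined
#' alleles have their defining variants applied at the mapped genomic
#' positions; whole-gene deletion haplotypes carry no RHD sequence (the
#' beta-globin control locus is retained, as it sits elsewhere in the
#' genome); exon-dropout hybrid haplotypes have the dropped exons' region --
#' including the internal primer binding sites -- replaced by non-matching
#' sequence, emulating replacement by the homologous RHCE stretch.
#'
#' @param sample_id sample identifier.
#' @param allele_a,allele_b ISBT allele names present in `db`.
#' @param model an `rhd_gene_model`.
#' @param db an `rhd_allele_db`.
#' @return object of class `rhd_sample`: list with `sample_id`, `haplotypes`
#'   (two lists of `allele`, `rhd` sequence or `NA`, `masked_exons`),
#'   `truth` (allele name pair), `control` and `role`.
#' @export
make_sample <- function(sample_id, allele_a, allele_b, model, db) {
  stopifnot(inherits(model, "rhd_gene_model"), inherits(db, "rhd_allele_db"))
  haps <- list(make_haplotype(allele_a, model, db),
               make_haplotype(allele_b, model, db))
  s <- list(sample_id = sample_id, haplotypes = haps,
            truth = c(allele_a, allele_b),
            control = model$control_sequence, role = "sample")
  class(s) <- "rhd_sample"
  s
}

make_haplotype <- function(allele_name, model, db) {
  rec <- db_allele(db, allele_name)
  cls <- rec$structural_class
  if (cls == "GENE_ABSENT") {
    return(list(allele = allele_name, rhd = NA_character_,
                masked_exons = integer()))
  }
  g <- strsplit(model$genomic, "")[[1]]
  v <- rec$variants[[1]]
  if (nrow(v) > 0L) {
    gpos <- cds_to_genomic(model, v$cds_pos)
    stopifnot(all(g[gpos + 1L] == v$ref))
    g[gpos + 1L] <- v$alt
  }
  masked <- rec$dropped_exons[[1]]
  if (cls == "EXON_DROPOUT") {
    g <- mask_exons(g, masked, model)
  }
  list(allele = allele_name, rhd = paste(g, collapse = ""),
       masked_exons = masked)
}

# Replace the region from the first dropped exon's forward primer site to the
# last dropped exon's reverse primer site with random sequence, then verify
# no primer binding site was (re)created by accident.
mask_exons <- function(g, dropped, model) {
  exa <- rhd_exon_assays()
  sites <- model$primer_sites
  first <- min(dropped); last <- max(dropped)
  w_start <- sites$start[sites$primer_id == exa$fwd_id[first]]
  w_end <- sites$end[sites$primer_id == exa$rev_id[last]]
  stopifnot(length(w_start) == 1L, length(w_end) == 1L, w_start < w_end)
  ssp <- rhd_ssp_assays()
  cores <- toupper(c(primer_core(exa$fwd_seq), primer_core(exa$rev_seq),
                     primer_core(ssp$fwd_seq), primer_core(ssp$rev_seq)))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  reference_counts <- NULL
  for (attempt in 0:24) {
    set.seed(model$seed + 7919L * first + attempt)
    cand <- g
    cand[(w_start + 1L):w_end] <-
      sample(c("A", "C", "G", "T"), w_end - w_start, replace = TRUE)
    hap <- paste(cand, collapse = "")
    counts <- vapply(unique(cores), count_occurrences, integer(1),
                     sequence = hap)
    if (is.null(reference_counts)) {
      reference_counts <- vapply(unique(cores), count_occurrences,
                                 integer(1),
                                 sequence = paste(g, collapse = ""))
    }
    if (all(counts <= reference_counts)) return(cand)
  }
  stop("could not mask exons without creating a spurious primer site",
       call. = FALSE)
}

#' No-template control well
#'
#' A sample with no nucleic acid at all: no RHD haplotypes and no control
#' locus. A clean run must show zero peaks in every NTC reaction.
#' @param sample_id identifier (default `"NTC"`).
#' @return an `rhd_sample` with role `"NTC"`.
#' @export
make_ntc <- function(sample_id = "NTC") {
  s <- list(sample_id = sample_id,
            haplotypes = list(
              list(allele = NA_character_, rhd = NA_character_,
                   masked_exons = integer()),
              list(allele = NA_character_, rhd = NA_character_,
                   masked_exons = integer())),
            truth = c(NA_character_, NA_character_),
            control = NULL, role = "NTC")
  class(s) <- "rhd_sample"
  s
}

#' @export
print.rhd_sample <- function(x, ...) {
  cat("RHD sample ", x$sample_id, " [", x$role, "]: ",
      paste(x$truth, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Definition of the 24-sample EQA proficiency panel
#'
#' Six yearly proficiency sets of four samples each (identifiers
#' `"2019-31"` .. `"2024-34"`), with the expected final genotype and
#' phenotype for each. Zygosity is a fixture choice: the DNB sample 2023-33
#' is heterozygous (RHD*25 in trans to the reference allele); all other
#' samples are built homozygous, matching the hemizygous-or-homozygous
#' ambiguity that sequencing cannot resolve.
#'
#' @return data.frame with columns `sample_id`, `allele_a`, `allele_b`,
#'   `genotype`, `phenotype`.
#' @export
eqa_panel_definition <- function() {
  def <- rbind(
    c("2019-31", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2019-32", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2019-33", "RHD*04.03", "RHD*04.03", "RHD*04.03", "DIV type 3"),
    c("2019-34", "RHD*01W.5", "RHD*01W.5", "RHD*01W.5", "weak D type 5"),
    c("2020-31", "RHD*01N.01", "RHD*01N.01", "RHD*01N.01", "D-"),
    c("2020-32", "RHD*01N.01", "RHD*01N.01", "RHD*01N.01", "D-"),
    c("2020-33", "RHD*01W.1", "RHD*01W.1", "RHD*01W.1", "weak D type 1"),
    c("2020-34", "RHD*07.01", "RHD*07.01", "RHD*07.01", "DVII"),
    c("2021-31", "RHD*01N.01", "RHD*01N.01", "RHD*01N.01", "D-"),
    c("2021-32", "RHD*01EL.01", "RHD*01EL.01", "RHD*01EL.01", "Del"),
    c("2021-33", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2021-34", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2022-31", "RHD*19", "RHD*19", "RHD*19", "DHMi"),
    c("2022-32", "RHD*01W.1", "RHD*01W.1", "RHD*01W.1", "weak D type 1"),
    c("2022-33", "RHD*01N.01", "RHD*01N.01", "RHD*01N.01", "D-"),
    c("2022-34", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2023-31", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2023-32", "RHD*01N.01", "RHD*01N.01", "RHD*01N.01", "D-"),
    c("2023-33", "RHD*25", "RHD*01", "RHD*25/RHD*01", "DNB het."),
    c("2023-34", "RHD*01W.2", "RHD*01W.2", "RHD*01W.2", "weak D type 2"),
    c("2024-31", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2024-32", "RHD*01", "RHD*01", "RHD*01", "normal D antigen"),
    c("2024-33", "RHD*01W.3", "RHD*01W.3", "RHD*01W.3", "weak D type 3"),
    c("2024-34", "RHD*11", "RHD*11", "RHD*11", "weak partial type 11")
  )
  out <- as.data.frame(def, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "allele_a", "allele_b", "genotype",
                  "phenotype")
  out
}

#' Build the 24-sample EQA panel as diploid fixtures
#'
#' @param model an `rhd_gene_model`.
#' @param db an `rhd_allele_db`.
#' @return named list of 24 `rhd_sample` objects, with the panel definition
#'   attached as attribute `"truth"`.
#' @export
make_eqa_panel <- function(model, db) {
  def <- eqa_panel_definition()
  panel <- lapply(seq_len(nrow(def)), function(i) {
    make_sample(def$sample_id[i], def$allele_a[i], def$allele_b[i], model, db)
  })
  names(panel) <- def$sample_id
  attr(panel, "truth") <- def
  panel
}

#' Quality-value profile for trace simulation
#'
#' In `"clean"` mode every base call has QV >= 25, so the whole panel passes
#' the QV 20 acceptance filter automatically. `"degraded"` mode draws QVs
#' down to a floor of 5 and miscalls a fraction of the sub-threshold
#' positions, exercising the manual-review flagging path; miscalls never
#' occur at positions with QV >= 20, so the QV filter alone guarantees
#' correctness of accepted calls.
#'
#' @param mode `"clean"` or `"degraded"`.
#' @return list with `floor`, `ceiling`, `miscall_rate`.
#' @export
qv_profile <- function(mode = c("clean", "degraded")) {
  mode <- match.arg(mode)
  switch(mode,
         clean = list(floor = 25L, ceiling = 60L, miscall_rate = 0),
         degraded = list(floor = 5L, ceiling = 60L, miscall_rate = 0.3))
}

#' Simulate a single-direction Sanger trace for one exon amplicon
#'
#' The read covers the template between the exon's two primer binding sites
#' (primer sequence excluded) in the direction of the M13-tailed primer.
#' Positions where the two haplotypes carry different bases yield the
#' two-base IUPAC code; positions covered by a single haplotype (deletion in
#' trans) yield that haplotype's base. Per-position Phred QVs are drawn from
#' `profile`; in degraded mode, positions with QV < 20 may be miscalled.
#' Deterministic for a fixed seed.
#'
#' @param sample an `rhd_sample` whose haplotypes amplify this exon.
#' @param exon exon index (1..10).
#' @param model an `rhd_gene_model`.
#' @param profile a [qv_profile()].
#' @param seed integer seed.
#' @return object of class `rhd_trace`: list with `sample_id`, `exon`,
#'   `genomic_start` (0-based plus-strand start of the read window),
#'   `orientation`, `bases` (read-order character vector, IUPAC codes at
#'   mixed positions) and `qv` (integer vector).
#' @export
simulate_trace <- function(sample, exon, model, profile = qv_profile("clean"),
                           seed = 1L) {
  stopifnot(inherits(sample, "rhd_sample"), exon %in% 1:10)
  exa <- rhd_exon_assays()
  sites <- model$primer_sites
  w_start <- sites$end[sites$primer_id == exa$fwd_id[exon]]
  w_end <- sites$start[sites$primer_id == exa$rev_id[exon]]
  n <- w_end - w_start
  hap_windows <- list()
  for (hap in sample$haplotypes) {
    if (is.na(hap$rhd) || exon %in% hap$masked_exons) next
    hap_windows[[length(hap_windows) + 1L]] <-
      strsplit(substr(hap$rhd, w_start + 1L, w_end), "")[[1]]
  }
  if (length(hap_windows) == 0L) {
    stop("no haplotype of sample ", sample$sample_id, " amplifies exon ",
         exon, call. = FALSE)
  }
  bases <- hap_windows[[1]]
  if (length(hap_windows) == 2L) {
    other <- hap_windows[[2]]
    diff <- which(bases != other)
    if (length(diff)) {
      bases[diff] <- vapply(diff, function(i) iupac_code(bases[i], other[i]),
                            character(1))
    }
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  qv <- sample(profile$floor:profile$ceiling, n, replace = TRUE)
  if (profile$miscall_rate > 0) {
    low <- which(qv < 20L & bases %in% c("A", "C", "G", "T"))
    flip <- low[stats::runif(length(low)) < profile$miscall_rate]
    for (i in flip) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
    }
  }
  orientation <- exa$read_orientation[exon]
  if (orientation == "reverse") {
    bases <- rev(complement_iupac(bases))
    qv <- rev(qv)
  }
  trace <- list(sample_id = sample$sample_id, exon = exon,
                genomic_start = w_start, orientation = orientation,
                bases = bases, qv = qv)
  class(trace) <- "rhd_trace"
  trace
}

#' Simulate traces for all amplifiable exons of a sample
#'
#' @param sample an `rhd_sample`.
#' @param model an `rhd_gene_model`.
#' @param exons exon indices to sequence (default all ten).
#' @param profile a [qv_profile()].
#' @param seed master seed; each exon's trace uses `seed + exon`.
#' @return named list of `rhd_trace` objects (`"exon1"` .. `"exon10"`).
#' @export
simulate_sample_traces <- function(sample, model, exons = 1:10,
                                   profile = qv_profile("clean"), seed = 1L) {
  traces <- lapply(exons, function(k) {
    simulate_trace(sample, k, model, profile, seed = seed + k)
  })
  names(traces) <- paste0("exon", exons)
  traces
}

#' @export
print.rhd_trace <- function(x, ...) {
  cat("Trace ", x$sample_id, " exon ", x$exon, " (", x$orientation, "), ",
      length(x$bases), " bases, min QV ", min(x$qv), "\n", sep = "")
  invisible(x)
}
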