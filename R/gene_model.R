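#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   vcountPattern matchPattern
NULL

#' M13 forward (-21) universal sequencing primer
#'
#' Appended as a 5' tail to one primer of each exon amplification pair so that
#' every amplicon can be sequenced with a single universal primer.
#' @export
M13_TAIL <- "CAGGAAACAGCTATGAC"

#' Default RHD CDS exon lengths
#'
#' Lengths of the ten RHD coding exons (in coding bases); they sum to the
#' 1254-nt CDS of the RHD reference transcript.
#' @return integer vector of length 10.
#' @export
rhd_exon_lengths <- function() {
  c(148L, 187L, 151L, 148L, 167L, 138L, 134L, 80L, 74L, 27L)
}

#' Allele-specific PCR assay definitions (SSP stage)
#'
#' The four sequence-specific-priming assays for weak D types 1-3 and DVII,
#' each co-amplifying a beta-globin internal control. Lowercase primer
#' characters sit in introns, uppercase in exons; the discriminating base is
#' the 3'-terminal base of the allele-specific primer. `target_tm` and
#' `control_tm` are the empirically defined melt standards used for
#' melting-curve genotyping.
#'
#' @return data.frame, one row per assay.
#' @export
rhd_ssp_assays <- function() {
  data.frame(
    assay_name = c("RHD*01W.1", "RHD*01W.2", "RHD*01W.3", "RHD*07.01"),
    rs_id = c("rs121912763", "rs71652374", "rs144969459", "rs121912762"),
    snp = c("NM_016124.6:c.809T>G", "NM_016124.6:c.1154G>C",
            "NM_016124.6:c.8C>G", "NM_016124.6:c.329T>C"),
    fwd_id = c("WD1-809G-f", "WD2-1154C-f", "WD3-8G-f", "RHD-E2-201-f"),
    fwd_seq = c("acacgctatttctttgcagACTTATGG",
                "ctccaaatcttttaacattaaattatgcatttaaacagC",
                "acagagacggacacaggATGAGATG",
                "GCTTGGGCTTCCTCACCTCG"),
    fwd_conc = c(0.25, 0.5, 0.25, 0.25),
    rev_id = c("WD1-r", "WD2-r", "WD3-r", "RHD-329C-r"),
    rev_seq = c("GGTACTTGGCTCCCCCGAC",
                "gtgaaaaatcttacCTTCCAGAAAACTTGGTCATC",
                "CTTGATAGGATGCCACGAGCCC",
                "ccaccatcccaatacCTGAACG"),
    rev_conc = c(0.5, 0.5, 0.5, 0.15),
    discriminating_end = c("fwd", "fwd", "fwd", "rev"),
    target_tm = c(83.0, 74.4, 86.4, 85.8),
    control_fwd_id = c("G107F", "globin F", "G107F", "G107F"),
    control_fwd_seq = c("CTGGGCAGGTTGGTATCA", "CAACTTCATCCACGTTCACC",
                        "CTGGGCAGGTTGGTATCA", "CTGGGCAGGTTGGTATCA"),
    control_rev_id = c("G107R", "globin R", "G107R", "G107R"),
    control_rev_seq = c("GAGAGTCAGTGCCTATCAGAAAC", "GAAGAGCCAAGGACAGGTAC",
                        "GAGAGTCAGTGCCTATCAGAAAC", "GAGAGTCAGTGCCTATCAGAAAC"),
    control_tm = c(80.7, 86.0, 80.7, 80.7),
    stringsAsFactors = FALSE
  )
}

#' Exon amplification assay definitions (SBT stage)
#'
#' Primer pairs amplifying RHD exons 1-10 with flanking intron, one primer of
#' each pair carrying the M13 forward tail for downstream sequencing.
#' `tm` is the per-exon melt standard; `read_orientation` is the direction of
#' the single sequencing read (set by which primer carries the tail).
#'
#' @return data.frame, one row per exon.
#' @export
rhd_exon_assays <- function() {
  tail <- M13_TAIL
  data.frame(
    exon = 1:10,
    fwd_id = c("RHD_E1_2f_M13", "RHD-E2_936_F6", "Ds3s_M13", "RHD_E4_1f_M13",
               "RH_E5_1f_M13", "Ds6a_M13", "RHD_E7_1f_M13", "RHD_E8_3f",
               "RHD_E9_2s_M13", "RH_E10_1f_M13"),
    fwd_seq = c(paste0(tail, "GCTTCCGTGTTAACTCCATAGAG"),
                "ATGACAGTAACAGCACGCAC",
                paste0(tail, "GTCGTCCTGGCTCTCCCTCTCT"),
                paste0(tail, "TATCAGGGCTTGCCCC"),
                paste0(tail, "GACCTTTGGAGCAGGAGTG"),
                paste0(tail, "CTTCAGCCAAAGCAGAGGAGG"),
                paste0(tail, "CCCCCTTTGGTGGCC"),
                "GGAGGCTCTGAGAGGTTGAG",
                paste0(tail, "TCCAGGAATGACAGGGCT"),
                paste0(tail, "AGAGATCAAGCCAAAATCAGTAT")),
    rev_id = c("RHD_E1_2r", "RHD_i2+61R7_M13", "RH_E3_r1", "RHD_E4_2r",
               "RHD_E5_2r", "Ds6-s", "RHD_E7_2r", "RH_E8_2r_M13",
               "RH_E9_2r", "RHD_E10_1r"),
    rev_seq = c("GGGGGAATCTTTTTCCTT",
                paste0(tail, "TATCCCAGATCTTCTGGAACC"),
                "GAGATGAGGATCTTGCTATGATG",
                "TCAGACACCCAGGGGAAC",
                "TGTGACCACCCAGCATTCTA",
                "CAGGGTTGCCTTGTTCCCA",
                "CTTTGGTCTATACCTAGGTGGC",
                paste0(tail, "AATTATGTGATCCTCAGGGAAG"),
                "TTAAGTTCATGCACTCAAAATCTAT",
                "ATGGTGAGATTCTCCTCAAAG"),
    conc = c(0.5, 0.25, 0.25, 0.25, 0.15, 0.25, 0.25, 0.25, 0.15, 0.15),
    tm = c(88.4, 89.0, 86.5, 85.8, 88.7, 88.3, 87.1, 87.2, 78.4, 85.6),
    read_orientation = c("forward", "reverse", "forward", "forward",
                         "forward", "forward", "forward", "reverse",
                         "forward", "forward"),
    stringsAsFactors = FALSE
  )
}

#' Strip a leading M13 tail from a printed primer sequence
#' @param seq primer sequence as printed (tail included if present).
#' @return the template-binding core, uppercase.
#' @export
primer_core <- function(seq) {
  core <- ifelse(startsWith(toupper(seq), M13_TAIL),
                 substr(seq, nchar(M13_TAIL) + 1L, nchar(seq)), seq)
  toupper(core)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Reference bases at the allele-defining CDS positions of the packaged
# database; enforced on the synthetic reference after primer placement (the
# allele-specific primer blocks embed the *alternate* discriminating base).
rhd_reference_bases <- function() {
  c(`8` = "C", `329` = "T", `446` = "C", `809` = "T", `848` = "C",
    `885` = "G", `1063` = "G", `1154` = "G", `1227` = "G")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic RHD reference with registered primer sites
#'
#' Constructs a fully synthetic 10-exon RHD gene model: random intron and
#' flank sequence, exon sequence carrying the reference base at every
#' allele-defining CDS position, and the verbatim primer binding sites of the
#' SSP and exon-amplification assays embedded at registered locations
#' (lowercase primer characters land in introns, uppercase in exons). A
#' separate synthetic beta-globin control locus carries the two internal
#' control amplicons (107 bp and 268 bp). A post-build scan guarantees every
#' primer core (or its reverse complement) occurs exactly once; the random
#' background is regenerated on the rare accidental duplicate.
#'
#' @param seed integer seed; the model is deterministic for a fixed seed.
#' @param exon_lengths optional 10-vector of exon lengths summing to 1254.
#' @param intron_length length of each of the nine introns (default 300).
#' @param flank length of the 5' and 3' flanks (default 250).
#' @return object of class `rhd_gene_model`: list with `genomic` (character),
#'   `exon_intervals` (data.frame `exon`, `start`, `end`; 0-based half-open),
#'   `cds_length`, `cds_map` (genomic 0-based position of each CDS base),
#'   `primer_sites` (data.frame `primer_id`, `start`, `end`, `strand`),
#'   `control_sequence`, and `seed`.
#' @export
build_synthetic_reference <- function(seed = 20240806L, exon_lengths = NULL,
                                      intron_length = 300L, flank = 250L) {
  if (is.null(exon_lengths)) exon_lengths <- rhd_exon_lengths()
  stopifnot(length(exon_lengths) == 10L, sum(exon_lengths) == 1254L,
            intron_length >= 150L, flank >= 120L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  exon_start <- flank + cumsum(c(0L, exon_lengths[-10] + intron_length))
  exon_end <- exon_start + exon_lengths
  cds_start <- cumsum(c(1L, exon_lengths[-10]))
  cds_map <- unlist(lapply(1:10, function(k) {
    seq.int(exon_start[k], exon_end[k] - 1L)
  }))
  g_len <- exon_end[10] + flank
  g_of <- function(p) cds_map[p] # 0-based genomic of 1-based CDS

  ssp <- rhd_ssp_assays()
  exa <- rhd_exon_assays()
  gap_f <- 45L
  gap_r <- 25L

  # site table: what to write where (plus-strand sequence), built once
  sites <- list()
  add_site <- function(id, start0, seq_plus, strand) {
    sites[[length(sites) + 1L]] <<- data.frame(
      primer_id = id, start = start0, end = start0 + nchar(seq_plus),
      strand = strand, seq = toupper(seq_plus), stringsAsFactors = FALSE)
  }
  # exon amplification primers: fwd core ends gap_f before the exon, rev
  # site begins gap_r after it (both fully intronic / in flanks)
  for (k in 1:10) {
    fc <- primer_core(exa$fwd_seq[k])
    rc <- primer_core(exa$rev_seq[k])
    add_site(exa$fwd_id[k], exon_start[k] - gap_f - nchar(fc), fc, "+")
    add_site(exa$rev_id[k], exon_end[k] + gap_r, revcomp_chr(rc), "-")
  }
  # SSP sites (coordinates tied to the discriminating SNPs; the embedded
  # discriminating base is the alternate, overwritten below by the reference)
  add_site("WD1-809G-f", g_of(802L) - 19L, primer_core(ssp$fwd_seq[1]), "+")
  add_site("WD1-r", g_of(860L), revcomp_chr(primer_core(ssp$rev_seq[1])), "-")
  add_site("WD2-1154C-f", g_of(1154L) - 38L, primer_core(ssp$fwd_seq[2]), "+")
  add_site("WD2-r", g_of(1207L), revcomp_chr(primer_core(ssp$rev_seq[2])), "-")
  add_site("WD3-8G-f", g_of(1L) - 17L, primer_core(ssp$fwd_seq[3]), "+")
  add_site("WD3-r", g_of(60L), revcomp_chr(primer_core(ssp$rev_seq[3])), "-")
  add_site("RHD-E2-201-f", g_of(181L), primer_core(ssp$fwd_seq[4]), "+")
  add_site("RHD-329C-r", g_of(329L), revcomp_chr(primer_core(ssp$rev_seq[4])),
           "-")
  sites <- do.call(rbind, sites)
  if (any(sites$start < 0L | sites$end > g_len)) {
    stop("primer site outside the genomic interval; increase flank/intron",
         call. = FALSE)
  }

  ref_bases <- rhd_reference_bases()

  for (attempt in 0:24) {
    set.seed(seed + attempt)
    g <- strsplit(random_dna(g_len), "")[[1]]
    for (i in seq_len(nrow(sites))) {
      g[(sites$start[i] + 1L):sites$end[i]] <-
        strsplit(sites$seq[i], "")[[1]]
    }
    for (p in names(ref_bases)) {
      g[g_of(as.integer(p)) + 1L] <- ref_bases[[p]]
    }
    genomic <- paste(g, collapse = "")
    # control locus: G107 amplicon (107 bp) and globin amplicon (268 bp)
    ctrl <- strsplit(random_dna(700L), "")[[1]]
    place <- function(v, start0, s) {
      v[(start0 + 1L):(start0 + nchar(s))] <- strsplit(s, "")[[1]]
      v
    }
    ctrl <- place(ctrl, 50L, "CTGGGCAGGTTGGTATCA")
    ctrl <- place(ctrl, 50L + 107L - 23L,
                  revcomp_chr("GAGAGTCAGTGCCTATCAGAAAC"))
    ctrl <- place(ctrl, 330L, "CAACTTCATCCACGTTCACC")
    ctrl <- place(ctrl, 330L + 268L - 20L,
                  revcomp_chr("GAAGAGCCAAGGACAGGTAC"))
    control_sequence <- paste(ctrl, collapse = "")

    # Each registered binding site, as actually written (reference base at
    # the discriminating position), must be unique; the allele-specific
    # cores themselves (3' alternate base) must be absent from the
    # reference, so they can only prime variant haplotypes.
    site_seqs <- substring(genomic, sites$start + 1L, sites$end)
    site_counts <- vapply(unique(site_seqs), function(s) {
      count_occurrences(s, genomic) + count_occurrences(s, control_sequence)
    }, integer(1))
    disc_cores <- toupper(primer_core(
      c(ssp$fwd_seq[ssp$discriminating_end == "fwd"],
        ssp$rev_seq[ssp$discriminating_end == "rev"])))
    disc_counts <- vapply(disc_cores, function(s) {
      count_occurrences(s, genomic) + count_occurrences(s, control_sequence)
    }, integer(1))
    ctrl_counts <- vapply(unique(toupper(c(ssp$control_fwd_seq,
                                           ssp$control_rev_seq))),
                          function(s) {
                            count_occurrences(s, genomic) +
                              count_occurrences(s, control_sequence)
                          }, integer(1))
    if (all(site_counts == 1L) && all(disc_counts == 0L) &&
        all(ctrl_counts == 1L)) break
    if (attempt == 24L) {
      stop("could not build a collision-free reference", call. = FALSE)
    }
  }

  model <- list(
    genomic = genomic,
    exon_intervals = data.frame(exon = 1:10, start = exon_start,
                                end = exon_end),
    cds_length = 1254L,
    cds_map = cds_map,
    primer_sites = sites[, c("primer_id", "start", "end", "strand")],
    control_sequence = control_sequence,
    ref_id = "NM_016124.6",
    seed = seed
  )
  class(model) <- "rhd_gene_model"
  model
}

# occurrences of a core or its reverse complement in a sequence
count_occurrences <- function(core, sequence) {
  subj <- Biostrings::DNAString(sequence)
  n <- Biostrings::countPattern(Biostrings::DNAString(core), subj)
  rc <- revcomp_chr(core)
  if (rc != core) {
    n <- n + Biostrings::countPattern(Biostrings::DNAString(rc), subj)
  }
  as.integer(n)
}

#' CDS to genomic coordinate conversion
#'
#' @param model an `rhd_gene_model`.
#' @param cds_pos 1-based CDS position(s) in 1..cds_length.
#' @return 0-based genomic position(s).
#' @export
cds_to_genomic <- function(model, cds_pos) {
  stopifnot(inherits(model, "rhd_gene_model"))
  if (any(cds_pos < 1L | cds_pos > model$cds_length)) {
    stop("CDS position outside 1..", model$cds_length, call. = FALSE)
  }
  model$cds_map[cds_pos]
}

#' Genomic to CDS coordinate conversion
#'
#' @param model an `rhd_gene_model`.
#' @param genomic_pos 0-based genomic position(s).
#' @return 1-based CDS position(s); `NA` for non-coding (intron/flank)
#'   positions.
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  stopifnot(inherits(model, "rhd_gene_model"))
  match(genomic_pos, model$cds_map)
}

#' Exon index of a CDS position
#' @param model an `rhd_gene_model`.
#' @param cds_pos 1-based CDS position(s).
#' @return exon index (1..10).
#' @export
cds_to_exon <- function(model, cds_pos) {
  g <- cds_to_genomic(model, cds_pos)
  iv <- model$exon_intervals
  vapply(g, function(p) iv$exon[iv$start <= p & p < iv$end][1], integer(1))
}

#' Extract the CDS from a genomic haplotype sequence
#'
#' @param model an `rhd_gene_model`.
#' @param genomic haplotype genomic sequence (defaults to the reference).
#' @return CDS as a single character string of length `cds_length`.
#' @export
extract_cds <- function(model, genomic = model$genomic) {
  stopifnot(inherits(model, "rhd_gene_model"), nchar(genomic) >=
              max(model$cds_map) + 1L)
  chars <- strsplit(genomic, "")[[1]]
  paste(chars[model$cds_map + 1L], collapse = "")
}

#' Export a gene model as FASTA plus annotation table
#'
#' Writes `reference.fasta` (RHD genomic + control locus) and
#' `annotation.tsv` (exon intervals and primer sites) under `dir`.
#' @param model an `rhd_gene_model`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
export_gene_model <- function(model, dir) {
  stopifnot(inherits(model, "rhd_gene_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- Biostrings::DNAStringSet(c(RHD_synthetic = model$genomic,
                                   control_locus = model$control_sequence))
  fa_path <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(fa, fa_path)
  ann <- rbind(
    data.frame(feature = "exon",
               name = paste0("exon", model$exon_intervals$exon),
               start = model$exon_intervals$start,
               end = model$exon_intervals$end, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(feature = "primer_site", name = model$primer_sites$primer_id,
               start = model$primer_sites$start, end = model$primer_sites$end,
               strand = model$primer_sites$strand, stringsAsFactors = FALSE)
  )
  ann_path <- file.path(dir, "annotation.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa_path, ann_path))
}

#' @export
print.rhd_gene_model <- function(x, ...) {
  cat("Synthetic RHD gene model (seed ", x$seed, ")\n",
      "  genomic length: ", nchar(x$genomic), " nt; CDS: ", x$cds_length,
      " nt over 10 exons\n",
      "  primer sites registered: ", nrow(x$primer_sites), "\n", sep = "")
  invisible(x)
}
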