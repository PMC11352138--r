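#' @importFrom Biostrings writeXStringSet readDNAStringSet BStringSet
NULL

seed_header <- function(seed) sprintf("# seed: %d", seed)

read_seed_header <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# seed: (-?[0-9]+)$", first))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

#' Build a plate order for the SSP stage
#'
#' One reaction well per sample x assay, split over 96-well plates of 48
#' sample reactions each, with a no-template control in the configured well
#' of every plate. Columns are exactly the fields the instrument transport
#' needs: well position, sample ID, assay name, run profile name, and sample
#' role (plus a plate index).
#'
#' @param panel list of `rhd_sample`.
#' @param assays SSP assay table (default [rhd_ssp_assays()]).
#' @param run_profile_name run profile label.
#' @param ntc_well well reserved for the NTC on each plate (default
#'   `"H12"`).
#' @return data.frame plate order.
#' @export
build_plate_order <- function(panel, assays = rhd_ssp_assays(),
                              run_profile_name = "RHD_SSP_MCG_v1",
                              ntc_well = "H12") {
  wells <- setdiff(plate_wells(), ntc_well)
  ids <- vapply(panel, function(s) s$sample_id, character(1))
  grid <- expand.grid(sample_id = ids, assay_name = assays$assay_name,
                      stringsAsFactors = FALSE)
  per_plate <- 48L
  rows <- list()
  n_plates <- ceiling(nrow(grid) / per_plate)
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, nrow(grid))
    rows[[p]] <- rbind(
      data.frame(plate = p, well_position = wells[seq_along(idx)],
                 grid[idx, , drop = FALSE],
                 run_profile_name = run_profile_name,
                 sample_role = "sample", stringsAsFactors = FALSE),
      data.frame(plate = p, well_position = ntc_well, sample_id = "NTC",
                 assay_name = "NTC", run_profile_name = run_profile_name,
                 sample_role = "NTC", stringsAsFactors = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a plate order CSV
#'
#' @param path CSV path (a leading `# seed:` comment line is permitted).
#' @return the plate order data.frame.
#' @export
read_plate_order <- function(path) {
  po <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                        check.names = FALSE)
  needed <- c("well_position", "sample_id", "assay_name",
              "run_profile_name", "sample_role")
  miss <- setdiff(needed, names(po))
  if (length(miss)) {
    stop("plate order lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(po))) {
    if (any(!nzchar(trimws(unlist(po[i, needed]))))) {
      stop("malformed plate order at data line ", i, " of ", path,
           call. = FALSE)
    }
  }
  po
}

#' Write panel fixture files
#'
#' Exports a panel to disk as text formats: a multi-FASTA of haplotype
#' genomic sequences (absent deletion haplotypes are omitted and recorded in
#' the truth table), a truth table TSV, a plate order CSV, and simulated
#' sequencing traces as FASTQ (one record per sample x amplifiable exon;
#' IUPAC codes mark heterozygous positions). All files are deterministic for
#' a fixed seed, and the seed is recorded in every delimited file's header.
#'
#' @param panel list of `rhd_sample` with a `"truth"` attribute (see
#'   [make_eqa_panel()]).
#' @param model an `rhd_gene_model`.
#' @param dir output directory (created if needed).
#' @param seed master trace seed (same scheme as [run_panel()]).
#' @param profile a [qv_profile()].
#' @return invisibly, the named vector of paths written.
#' @export
write_panel_files <- function(panel, model, dir, seed = 20240806L,
                              profile = qv_profile("clean")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- attr(panel, "truth")
  if (is.null(truth)) {
    truth <- data.frame(
      sample_id = vapply(panel, function(s) s$sample_id, character(1)),
      allele_a = vapply(panel, function(s) s$truth[1], character(1)),
      allele_b = vapply(panel, function(s) s$truth[2], character(1)),
      genotype = NA_character_, phenotype = NA_character_,
      stringsAsFactors = FALSE)
  }

  haps <- list()
  for (s in panel) {
    for (h in 1:2) {
      hp <- s$haplotypes[[h]]
      if (!is.na(hp$rhd)) {
        haps[[paste0(s$sample_id, "|hap", h, "|", hp$allele)]] <- hp$rhd
      }
    }
  }
  fasta_path <- file.path(dir, "haplotypes.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(haps)), fasta_path)

  truth_path <- file.path(dir, "truth.tsv")
  con <- file(truth_path, "w")
  writeLines(seed_header(seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  plate_path <- file.path(dir, "plate_order.csv")
  con <- file(plate_path, "w")
  writeLines(seed_header(seed), con)
  utils::write.table(build_plate_order(panel), con, sep = ",",
                     quote = FALSE, row.names = FALSE)
  close(con)

  reads <- list()
  quals <- list()
  for (i in seq_along(panel)) {
    s <- panel[[i]]
    profile_df <- amplify_exons(s)
    exons <- profile_df$exon[profile_df$present]
    if (length(exons) == 0L) next
    tr <- simulate_sample_traces(s, model, exons = exons, profile = profile,
                                 seed = seed + 1000L * i)
    for (t in tr) {
      id <- paste(t$sample_id, t$exon, t$orientation, t$genomic_start,
                  sep = "|")
      reads[[id]] <- paste(t$bases, collapse = "")
      quals[[id]] <- paste(rawToChar(as.raw(pmin(t$qv, 93L) + 33L)),
                           collapse = "")
    }
  }
  fastq_path <- file.path(dir, "traces.fastq")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(reads)),
                              fastq_path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                unlist(quals)))
  invisible(c(haplotypes = fasta_path, truth = truth_path,
              plate_order = plate_path, traces = fastq_path))
}

#' Read panel fixture files back from disk
#'
#' Reconstructs `rhd_sample` objects from the haplotype FASTA and truth
#' table (absent haplotypes have no FASTA record) and parses the trace
#' FASTQ into `rhd_trace` objects.
#'
#' @param dir directory written by [write_panel_files()].
#' @param model an `rhd_gene_model` (supplies the control locus).
#' @return list with `panel`, `traces` (named by sample id), `truth`,
#'   `seed`.
#' @export
read_panel_files <- function(dir, model) {
  truth_path <- file.path(dir, "truth.tsv")
  seed <- read_seed_header(truth_path)
  truth <- utils::read.delim(truth_path, comment.char = "#",
                             colClasses = "character")
  fa <- Biostrings::readDNAStringSet(file.path(dir, "haplotypes.fasta"))
  fa_meta <- do.call(rbind, strsplit(names(fa), "|", fixed = TRUE))
  panel <- lapply(seq_len(nrow(truth)), function(i) {
    sid <- truth$sample_id[i]
    haps <- lapply(1:2, function(h) {
      j <- which(fa_meta[, 1] == sid & fa_meta[, 2] == paste0("hap", h))
      if (length(j) == 1L) {
        list(allele = fa_meta[j, 3], rhd = as.character(fa[[j]]),
             masked_exons = integer())
      } else {
        list(allele = truth[[paste0("allele_", letters[h])]][i],
             rhd = NA_character_, masked_exons = integer())
      }
    })
    s <- list(sample_id = sid, haplotypes = haps,
              truth = c(truth$allele_a[i], truth$allele_b[i]),
              control = model$control_sequence, role = "sample")
    class(s) <- "rhd_sample"
    s
  })
  names(panel) <- truth$sample_id
  attr(panel, "truth") <- truth

  fastq_path <- file.path(dir, "traces.fastq")
  traces <- list()
  if (file.exists(fastq_path)) {
    fq <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                       with.qualities = TRUE)
    qs <- S4Vectors::mcols(fq)$qualities
    meta <- do.call(rbind, strsplit(names(fq), "|", fixed = TRUE))
    for (i in seq_along(fq)) {
      if (nchar(as.character(fq[[i]])) == 0L) {
        stop("truncated FASTQ record '", names(fq)[i], "' in ", fastq_path,
             call. = FALSE)
      }
      t <- list(sample_id = meta[i, 1], exon = as.integer(meta[i, 2]),
                genomic_start = as.integer(meta[i, 4]),
                orientation = meta[i, 3],
                bases = strsplit(as.character(fq[[i]]), "")[[1]],
                qv = as.integer(charToRaw(as.character(qs[[i]]))) - 33L)
      class(t) <- "rhd_trace"
      traces[[meta[i, 1]]] <- c(traces[[meta[i, 1]]], list(t))
    }
  }
  list(panel = panel, traces = traces, truth = truth, seed = seed)
}

#' Type a panel from its fixture files
#'
#' File-driven entry point: reads the panel files written by
#' [write_panel_files()], runs the full two-stage pipeline using the stored
#' traces, and writes `report.csv`, `summary.json` and a per-sample
#' `log.tsv` under `out_dir`. Outputs are byte-identical across reruns of
#' the same inputs.
#'
#' @param dir panel fixture directory.
#' @param out_dir output directory (created if needed).
#' @param model an `rhd_gene_model`.
#' @param db an `rhd_allele_db`.
#' @param mode `"study"` or `"routine"`.
#' @return invisibly, the `rhd_run` object.
#' @export
type_panel_files <- function(dir, out_dir, model, db,
                             mode = c("study", "routine")) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  px <- read_panel_files(dir, model)
  run <- run_panel(px$panel, model, db, mode = mode, seed = px$seed,
                   traces = px$traces)

  report_path <- file.path(out_dir, "report.csv")
  con <- file(report_path, "w")
  writeLines(seed_header(px$seed), con)
  utils::write.table(run$reports, con, sep = ",", quote = TRUE,
                     row.names = FALSE)
  close(con)

  summary_path <- file.path(out_dir, "summary.json")
  s <- run$summary
  jsonlite::write_json(list(
    mode = s$mode, n_samples = s$n_samples,
    routes = as.list(s$routes), genotypes = as.list(s$genotypes),
    ssp_positives = as.list(s$ssp_positives),
    chromatograms = s$chromatograms, run_valid = s$run_valid,
    seed = px$seed), summary_path, auto_unbox = TRUE, pretty = TRUE)

  log_path <- file.path(out_dir, "log.tsv")
  log_df <- data.frame(sample_id = run$reports$sample_id,
                       stage = "final", route = run$reports$route,
                       evidence = ifelse(is.na(run$reports$hgvs_summary),
                                         run$reports$exon_profile,
                                         run$reports$hgvs_summary),
                       genotype = run$reports$genotype,
                       stringsAsFactors = FALSE)
  con <- file(log_path, "w")
  writeLines(seed_header(px$seed), con)
  utils::write.table(log_df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(run)
}

#' Export a melt curve as two-column delimited text
#' @param curve an `rhd_melt_curve`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_melt_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rhd_melt_curve"))
  utils::write.table(
    data.frame(temperature = curve$temperature, neg_dF_dT = curve$signal),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
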