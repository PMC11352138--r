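#' QV-filter a sequencing trace
#'
#' Partitions the read's positions into automatically validated calls and
#' review flags: pure base calls at or above the quality threshold are
#' accepted; pure calls below it are flagged `low_quality`; two-base IUPAC
#' calls are flagged `mixed_base` whatever their QV (mixed calls are never
#' silently dropped). The operation is idempotent: filtering an already
#' filtered read changes nothing.
#'
#' @param read an `rhd_trace` (or an already filtered read).
#' @param qv_threshold minimum accepted quality value, inclusive
#'   (default 20, i.e. error probability 0.01).
#' @return object of class `rhd_filtered_read`: the trace plus a `status`
#'   character vector (`"accepted"`, `"low_quality"`, `"mixed_base"`) and the
#'   threshold used.
#' @export
filter_read <- function(read, qv_threshold = 20L) {
  stopifnot(qv_threshold >= 0L,
            inherits(read, "rhd_trace") || inherits(read, "rhd_filtered_read"))
  pure <- read$bases %in% c("A", "C", "G", "T")
  status <- ifelse(!pure, "mixed_base",
                   ifelse(read$qv >= qv_threshold, "accepted", "low_quality"))
  out <- unclass(read)
  out$status <- status
  out$qv_threshold <- qv_threshold
  class(out) <- c("rhd_filtered_read", "rhd_trace")
  out
}

# read-order vectors -> plus-strand order
orient_plus <- function(read) {
  if (identical(read$orientation, "reverse")) {
    list(bases = rev(complement_iupac(read$bases)), qv = rev(read$qv),
         status = rev(read$status),
         read_pos = rev(seq_along(read$bases)))
  } else {
    list(bases = read$bases, qv = read$qv, status = read$status,
         read_pos = seq_along(read$bases))
  }
}

#' Call CDS variants from filtered per-exon reads
#'
#' Alignment is anchored placement: each read is positioned by its exon
#' amplicon's known coordinates on the gene model (reads are simulated
#' indel-free, so no general pairwise alignment is needed; a read whose
#' length does not match its amplicon window is an error). Accepted positions
#' that differ from the reference become homozygous-or-hemizygous calls;
#' mixed-base positions whose two bases are reference plus one alternate are
#' auto-resolved to heterozygous calls (a deterministic, conservative
#' automation of the manual chromatogram review step); any other flagged
#' position is left as a coverage gap for manual review.
#'
#' @param reads list of `rhd_filtered_read`/`rhd_trace` objects (traces are
#'   filtered at the default threshold).
#' @param model an `rhd_gene_model`.
#' @param qv_threshold threshold applied when a raw trace is supplied.
#' @return list of class `rhd_variant_calls`: `calls` (data.frame `cds_pos`,
#'   `ref`, `alt`, `zygosity`, `exon`, `read_pos`, `qv`), `uncovered`
#'   (CDS positions with no accepted or resolvable call among the sequenced
#'   exons, plus all positions of unsequenced exons), and `ref_id`.
#' @export
call_variants <- function(reads, model, qv_threshold = 20L) {
  stopifnot(inherits(model, "rhd_gene_model"))
  ref_chars <- strsplit(model$genomic, "")[[1]]
  exa <- rhd_exon_assays()
  sites <- model$primer_sites
  calls <- list()
  covered <- integer()
  sequenced_exons <- integer()
  for (read in reads) {
    if (!inherits(read, "rhd_filtered_read")) {
      read <- filter_read(read, qv_threshold)
    }
    k <- read$exon
    w_start <- sites$end[sites$primer_id == exa$fwd_id[k]]
    w_end <- sites$start[sites$primer_id == exa$rev_id[k]]
    if (length(read$bases) != w_end - w_start ||
        read$genomic_start != w_start) {
      stop("read for exon ", k, " cannot be placed on its amplicon window",
           call. = FALSE)
    }
    sequenced_exons <- c(sequenced_exons, k)
    p <- orient_plus(read)
    gpos <- seq.int(w_start, w_end - 1L)
    cds <- genomic_to_cds(model, gpos)
    in_cds <- which(!is.na(cds))
    for (i in in_cds) {
      cpos <- cds[i]
      refb <- ref_chars[gpos[i] + 1L]
      st <- p$status[i]
      if (st == "accepted") {
        covered <- c(covered, cpos)
        if (p$bases[i] != refb) {
          calls[[length(calls) + 1L]] <- data.frame(
            cds_pos = cpos, ref = refb, alt = p$bases[i],
            zygosity = "homozygous_or_hemizygous", exon = k,
            read_pos = p$read_pos[i], qv = p$qv[i],
            stringsAsFactors = FALSE)
        }
      } else if (st == "mixed_base") {
        both <- iupac_bases(p$bases[i])
        if (length(both) == 2L && refb %in% both) {
          covered <- c(covered, cpos)
          calls[[length(calls) + 1L]] <- data.frame(
            cds_pos = cpos, ref = refb, alt = setdiff(both, refb),
            zygosity = "heterozygous", exon = k,
            read_pos = p$read_pos[i], qv = p$qv[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(cds_pos = integer(), ref = character(), alt = character(),
               zygosity = character(), exon = integer(),
               read_pos = integer(), qv = integer(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$cds_pos), , drop = FALSE]
  rownames(calls) <- NULL
  out <- list(calls = calls,
              uncovered = setdiff(seq_len(model$cds_length), covered),
              ref_id = model$ref_id)
  class(out) <- "rhd_variant_calls"
  out
}

#' Summarize called variants as an HGVS CDS expression
#'
#' Zero calls over a fully covered CDS give the reference-identity form
#' `"<ref_id>:c.1_1254="`; a heterozygous substitution is written in the
#' two-allele bracket style `c.[1063G>A];[1063=]`; homozygous substitutions
#' are plain `c.885G>T`; multiple substitutions are semicolon-joined.
#' Incomplete CDS coverage adds an explicit `[incomplete]` qualifier.
#'
#' @param vc an `rhd_variant_calls` object (or a data.frame of calls).
#' @param ref_id reference identifier; taken from `vc` if available.
#' @param uncovered CDS positions without a validated call (taken from `vc`
#'   if available).
#' @param cds_length CDS length for the identity form.
#' @return a single character string.
#' @export
summarize_cds <- function(vc, ref_id = NULL, uncovered = NULL,
                          cds_length = 1254L) {
  if (inherits(vc, "rhd_variant_calls")) {
    calls <- vc$calls
    if (is.null(uncovered)) uncovered <- vc$uncovered
    if (is.null(ref_id)) ref_id <- vc$ref_id
  } else {
    calls <- vc
    if (is.null(uncovered)) uncovered <- integer()
  }
  if (is.null(ref_id)) ref_id <- "NM_016124.6"
  if (nrow(calls) == 0L) {
    body <- sprintf("c.1_%d=", cds_length)
  } else {
    parts <- vapply(seq_len(nrow(calls)), function(i) {
      v <- calls[i, ]
      if (v$zygosity == "heterozygous") {
        sprintf("c.[%d%s>%s];[%d=]", v$cds_pos, v$ref, v$alt, v$cds_pos)
      } else {
        sprintf("c.%d%s>%s", v$cds_pos, v$ref, v$alt)
      }
    }, character(1))
    body <- paste(parts, collapse = ";")
  }
  out <- paste0(ref_id, ":", body)
  if (length(uncovered) > 0L) {
    out <- paste0(out, " [incomplete: ", length(uncovered),
                  " position(s) unresolved]")
  }
  out
}

#' @export
print.rhd_variant_calls <- function(x, ...) {
  cat(summarize_cds(x), "\n")
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}
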