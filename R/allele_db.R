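#' Load an RHD allele database from a delimited table
#'
#' The database is a flat, editable table with one row per ISBT allele:
#' columns `allele_name`, `variants` (semicolon-separated HGVS c.
#' substitutions, empty for the reference allele and for structural alleles),
#' `structural_class` (`FULL_GENE`, `GENE_ABSENT`, `EXON_DROPOUT`),
#' `dropped_exons` (semicolon-separated exon indices, `EXON_DROPOUT` only),
#' `category`, `phenotype_label`, and optional `rs_ids`. The packaged default
#' covers the twelve alleles observed on the EQA panel; regional laboratories
#' are expected to extend it.
#'
#' @param path path to a tab-separated allele table. Defaults to the packaged
#'   database.
#' @param cds_length CDS length used to validate variant positions.
#' @return An object of class `rhd_allele_db`: a data.frame with list-columns
#'   `variants` (per-allele data.frame of `cds_pos`, `ref`, `alt`) and
#'   `dropped_exons` (integer vector).
#' @export
load_allele_db <- function(path = system.file("extdata", "rhd_alleles.tsv",
                                              package = "rhdtyper"),
                           cds_length = 1254L) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", fill = TRUE,
                           na.strings = NULL, check.names = FALSE)
  needed <- c("allele_name", "variants", "structural_class", "dropped_exons",
              "category", "phenotype_label")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("allele table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"rs_ids" %in% names(raw)) raw$rs_ids <- ""
  dup <- duplicated(raw$allele_name)
  if (any(dup)) {
    stop("duplicate allele name(s): ",
         paste(unique(raw$allele_name[dup]), collapse = ", "), call. = FALSE)
  }
  classes <- c("FULL_GENE", "GENE_ABSENT", "EXON_DROPOUT")
  variants <- vector("list", nrow(raw))
  dropped <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    cls <- raw$structural_class[i]
    if (!cls %in% classes) {
      stop("record ", i, " ('", raw$allele_name[i],
           "'): unknown structural_class '", cls, "'", call. = FALSE)
    }
    vstr <- trimws(raw$variants[i])
    if (nzchar(vstr)) {
      parts <- trimws(strsplit(vstr, ";", fixed = TRUE)[[1]])
      v <- tryCatch(hgvs_parse(parts, cds_length = cds_length),
                    error = function(e) {
                      stop("record ", i, " ('", raw$allele_name[i], "'): ",
                           conditionMessage(e), call. = FALSE)
                    })
    } else {
      v <- hgvs_parse(sprintf("NM_016124.6:c.1_%d=", cds_length))
    }
    if (cls == "GENE_ABSENT" && nrow(v) > 0L) {
      stop("record ", i, " ('", raw$allele_name[i],
           "'): GENE_ABSENT allele must have no defining variants",
           call. = FALSE)
    }
    dstr <- trimws(raw$dropped_exons[i])
    d <- if (nzchar(dstr)) {
      as.integer(strsplit(dstr, ";", fixed = TRUE)[[1]])
    } else {
      integer()
    }
    if (cls == "EXON_DROPOUT") {
      if (length(d) == 0L || any(diff(sort(d)) != 1L)) {
        stop("record ", i, " ('", raw$allele_name[i],
             "'): EXON_DROPOUT requires a contiguous non-empty exon set",
             call. = FALSE)
      }
    } else if (length(d) > 0L) {
      stop("record ", i, " ('", raw$allele_name[i],
           "'): dropped_exons only valid for EXON_DROPOUT", call. = FALSE)
    }
    variants[[i]] <- v
    dropped[[i]] <- sort(d)
  }
  db <- data.frame(allele_name = raw$allele_name,
                   structural_class = raw$structural_class,
                   category = raw$category,
                   phenotype_label = raw$phenotype_label,
                   rs_ids = raw$rs_ids,
                   stringsAsFactors = FALSE)
  db$variants <- variants
  db$dropped_exons <- dropped
  class(db) <- c("rhd_allele_db", class(db))
  db
}

db_allele <- function(db, name) {
  i <- match(name, db$allele_name)
  if (is.na(i)) stop("unknown allele '", name, "'", call. = FALSE)
  db[i, , drop = FALSE]
}

variant_key <- function(v) {
  if (nrow(v) == 0L) return(character())
  sort(sprintf("%d%s>%s", v$cds_pos, v$ref, v$alt))
}

#' Match observed variants against the allele database
#'
#' Implements the sequence-based-typing assignment rule: the observed
#' substitutions (with zygosity) are compared to the defining variant sets of
#' the database alleles. An empty observed set yields the reference allele
#' `RHD*01` (homozygous or hemizygous state cannot be distinguished by
#' sequencing alone, so the partner is reported `"unresolved"`). A set of
#' homozygous variants equal to an allele's defining set yields that allele
#' with an unresolved partner. A single heterozygous variant defining allele A
#' yields the pair (A, RHD*01), the in-trans reference haplotype being assumed
#' (single-direction Sanger reads cannot phase). Anything else -- including
#' multiple heterozygous variants -- is reported as a novel candidate carrying
#' the unmatched variants verbatim; unknown combinations never raise an error.
#'
#' @param observed data.frame with columns `cds_pos`, `ref`, `alt`,
#'   `zygosity` (values `"homozygous_or_hemizygous"` / `"heterozygous"`).
#'   Zero rows mean no deviation from the reference CDS.
#' @param db an `rhd_allele_db`.
#' @return list of class `rhd_allele_call` with `allele_pair` (character(2);
#'   second element may be `"unresolved"`), `note` (one of `exact_match`,
#'   `heterozygous_phase_assumed`, `novel_candidate`), and `unmatched`
#'   (data.frame of unexplained variants, zero rows unless novel).
#' @export
match_variants <- function(observed, db) {
  if (is.null(observed)) {
    observed <- data.frame(cds_pos = integer(), ref = character(),
                           alt = character(), zygosity = character(),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(observed))
  zyg_ok <- c("homozygous_or_hemizygous", "heterozygous")
  if (nrow(observed) > 0L) {
    stopifnot(all(c("cds_pos", "ref", "alt", "zygosity") %in% names(observed)))
    stopifnot(all(observed$zygosity %in% zyg_ok))
    observed <- observed[order(observed$cds_pos), , drop = FALSE]
  }
  none <- observed[0, , drop = FALSE]
  call <- function(pair, note, unmatched = none) {
    structure(list(allele_pair = pair, note = note, unmatched = unmatched),
              class = "rhd_allele_call")
  }
  seq_defined <- db[db$structural_class == "FULL_GENE", , drop = FALSE]
  keys <- lapply(seq_defined$variants, variant_key)

  if (nrow(observed) == 0L) {
    return(call(c("RHD*01", "unresolved"), "exact_match"))
  }
  obs_key <- variant_key(observed)
  hom <- observed$zygosity == "homozygous_or_hemizygous"
  if (all(hom)) {
    hit <- which(vapply(keys, function(k) identical(k, obs_key), logical(1)))
    if (length(hit) == 1L) {
      return(call(c(seq_defined$allele_name[hit], "unresolved"),
                  "exact_match"))
    }
    return(call(c("novel", "unresolved"), "novel_candidate",
                unmatched = observed))
  }
  if (nrow(observed) == 1L && !hom[1]) {
    hit <- which(vapply(keys, function(k) identical(k, obs_key), logical(1)))
    if (length(hit) == 1L) {
      return(call(c(seq_defined$allele_name[hit], "RHD*01"),
                  "heterozygous_phase_assumed"))
    }
    return(call(c("novel", "RHD*01"), "novel_candidate",
                unmatched = observed))
  }
  # mixtures of het/hom variants or multi-het sets: phase unknown
  call(c("novel", "unresolved"), "novel_candidate", unmatched = observed)
}

#' @export
print.rhd_allele_call <- function(x, ...) {
  cat("RHD allele call: ", x$allele_pair[1], " / ", x$allele_pair[2],
      "  [", x$note, "]\n", sep = "")
  if (nrow(x$unmatched)) {
    cat("unmatched variants:\n")
    print(x$unmatched)
  }
  invisible(x)
}
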