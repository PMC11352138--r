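#' Parse an HGVS coding-sequence substitution
#'
#' Parses strings of the form `"NM_016124.6:c.809T>G"` into a variant record.
#' Only single-nucleotide substitutions are supported; insertions, deletions,
#' duplications and other events raise an error, since the typing scheme calls
#' substitutions only. The reference-identity form `"<ref>:c.1_1254="` parses
#' to a zero-row variant table.
#'
#' @param s character vector of HGVS strings.
#' @param cds_length CDS length used to validate positions (default 1254).
#' @return A data.frame with columns `cds_pos`, `ref`, `alt` (one row per
#'   substitution; zero rows for the reference-identity form) and the
#'   reference id in attribute `ref_id`.
#' @examples
#' hgvs_parse("NM_016124.6:c.8C>G")
#' @export
hgvs_parse <- function(s, cds_length = 1254L) {
  stopifnot(is.character(s), length(s) >= 1L)
  out <- lapply(s, hgvs_parse_one, cds_length = cds_length)
  ref_ids <- unique(vapply(out, attr, "", "ref_id"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ref_id") <- ref_ids
  res
}

hgvs_parse_one <- function(s, cds_length) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+):c\\.(.+)$", s))[[1]]
  if (length(m) != 3L) {
    stop("not an HGVS c. expression: '", s, "'", call. = FALSE)
  }
  ref_id <- m[2]
  body <- m[3]
  if (grepl("^[0-9]+_[0-9]+=$", body)) {
    res <- data.frame(cds_pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
    attr(res, "ref_id") <- ref_id
    return(res)
  }
  if (grepl("(del|dup|ins|inv|>.*>|\\[)", body)) {
    stop("unsupported HGVS syntax (only substitutions are handled): '",
         s, "'", call. = FALSE)
  }
  sm <- regmatches(body, regexec("^([0-9]+)([ACGT])>([ACGT])$", body))[[1]]
  if (length(sm) != 4L) {
    stop("unsupported HGVS syntax (only substitutions are handled): '",
         s, "'", call. = FALSE)
  }
  pos <- as.integer(sm[2])
  if (pos < 1L || pos > cds_length) {
    stop("CDS position ", pos, " outside 1..", cds_length, " in '", s, "'",
         call. = FALSE)
  }
  if (sm[3] == sm[4]) {
    stop("reference and alternate base identical in '", s, "'", call. = FALSE)
  }
  res <- data.frame(cds_pos = pos, ref = sm[3], alt = sm[4],
                    stringsAsFactors = FALSE)
  attr(res, "ref_id") <- ref_id
  res
}

#' Format variants as HGVS coding-sequence substitutions
#'
#' Inverse of [hgvs_parse()]: an empty variant table formats as the
#' reference-identity expression `"<ref_id>:c.1_1254="`.
#'
#' @param variants data.frame with columns `cds_pos`, `ref`, `alt` (may have
#'   zero rows).
#' @param ref_id reference sequence identifier (default `"NM_016124.6"`).
#' @param cds_length CDS length for the identity form.
#' @return character vector, one element per variant row, or the single
#'   identity string when `variants` has no rows.
#' @export
hgvs_format <- function(variants, ref_id = "NM_016124.6", cds_length = 1254L) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) {
    return(sprintf("%s:c.1_%d=", ref_id, cds_length))
  }
  stopifnot(all(c("cds_pos", "ref", "alt") %in% names(variants)))
  bad <- variants$cds_pos < 1L | variants$cds_pos > cds_length
  if (any(bad)) {
    stop("CDS position outside 1..", cds_length, ": ",
         paste(variants$cds_pos[bad], collapse = ", "), call. = FALSE)
  }
  sprintf("%s:c.%d%s>%s", ref_id, variants$cds_pos, variants$ref, variants$alt)
}

#' Phred quality to error probability
#'
#' The standard Phred relation p = 10^(-QV/10); a quality value of 20
#' corresponds to an error probability of 0.01.
#'
#' @param qv integer vector of Phred quality values (>= 0).
#' @return numeric vector of error probabilities.
#' @export
phred_error_prob <- function(qv) {
  stopifnot(all(qv >= 0))
  10^(-qv / 10)
}
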