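#' In-silico PCR: locate an amplicon on a template
#'
#' Models sequence-specific priming: a product forms only if both primers find
#' convergently oriented binding sites whose 3'-terminal base matches the
#' template exactly; up to `max_mismatch` mismatches are tolerated elsewhere
#' in a primer (default 0 -- fixture references embed primer sites verbatim).
#' M13 tails are excluded from template matching but appended to the product.
#' If several products are possible, the shortest one below `max_len` wins
#' (PCR kinetics favor short products), ties going to the leftmost.
#'
#' @param template template sequence (character). `NULL`, `NA` or empty
#'   (an absent haplotype) yields no product.
#' @param fwd_seq,rev_seq primer sequences as printed 5'->3' (case preserved,
#'   M13 tail included if present).
#' @param max_len maximum product length including tails (default 1500).
#' @param max_mismatch mismatch budget outside the 3'-terminal base.
#' @return `NULL` if no product, else a list with `start`/`end` (0-based
#'   half-open template coordinates of the primed region), `insert` (template
#'   sequence between and including the primer sites), `product` (insert with
#'   tails restored) and `length` (product length).
#' @export
find_amplicon <- function(template, fwd_seq, rev_seq, max_len = 1500L,
                          max_mismatch = 0L) {
  if (is.null(template) || length(template) == 0L || is.na(template) ||
      nchar(template) == 0L) {
    return(NULL)
  }
  template <- toupper(template)
  fwd_core <- primer_core(fwd_seq)
  rev_core <- primer_core(rev_seq)
  fwd_tail <- substr(fwd_seq, 1L, nchar(fwd_seq) - nchar(fwd_core))
  rev_tail <- substr(rev_seq, 1L, nchar(rev_seq) - nchar(rev_core))
  subj <- Biostrings::DNAString(template)

  fwd_starts <- primer_site_starts(fwd_core, subj, max_mismatch,
                                   three_prime = "last")
  rev_starts <- primer_site_starts(revcomp_chr(rev_core), subj, max_mismatch,
                                   three_prime = "first")
  if (length(fwd_starts) == 0L || length(rev_starts) == 0L) return(NULL)

  rev_ends <- rev_starts + nchar(rev_core)
  tails_len <- nchar(fwd_tail) + nchar(rev_tail)
  best <- NULL
  for (f in sort(fwd_starts)) {
    ok <- rev_ends[rev_starts >= f + nchar(fwd_core)]
    ok <- ok[ok - f + tails_len <= max_len]
    if (length(ok) == 0L) next
    r <- min(ok)
    if (is.null(best) || (r - f) < (best$end - best$start)) {
      best <- list(start = f, end = r)
    }
  }
  if (is.null(best)) return(NULL)
  insert <- substr(template, best$start + 1L, best$end)
  product <- paste0(toupper(fwd_tail), insert, revcomp_chr(toupper(rev_tail)))
  list(start = best$start, end = best$end, insert = insert,
       product = product, length = nchar(product))
}

# 0-based start positions where `pattern` matches `subj` with at most
# `max_mismatch` mismatches, none of them at the primer's 3'-terminal base
# ("last" base of the pattern for a forward primer, "first" for the
# reverse-complemented site of a reverse primer).
primer_site_starts <- function(pattern, subj, max_mismatch, three_prime) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                   max.mismatch = max_mismatch)
  if (length(hits) == 0L) return(integer())
  starts <- BiocGenerics::start(hits) - 1L
  if (max_mismatch > 0L) {
    mm <- Biostrings::mismatch(Biostrings::DNAString(pattern), hits)
    crit <- if (three_prime == "last") nchar(pattern) else 1L
    keep <- !vapply(mm, function(m) crit %in% m, logical(1))
    starts <- starts[keep]
  }
  starts
}

#' Synthesize a -dF/dT melting curve from assigned product Tms
#'
#' Each product contributes a Gaussian peak centered at its assigned melting
#' temperature over the protocol's 70-95 degC melting window; the curve is
#' the sum. Peak amplitude and width are documented display constants -- only
#' peak positions carry information.
#'
#' @param products data.frame with columns `tm` (degC) and `amplitude`
#'   (relative height); zero rows give a flat curve.
#' @param sigma peak standard deviation in degC (default 0.8).
#' @param grid_step temperature grid step in degC (default 0.1).
#' @param min_height minimum -dF/dT value for a called peak (default 0.1).
#' @return object of class `rhd_melt_curve`: list with `temperature`,
#'   `signal`, and `peaks` (data.frame `tm`, `height`).
#' @export
synthesize_melt_curve <- function(products, sigma = 0.8, grid_step = 0.1,
                                  min_height = 0.1) {
  temperature <- seq(70, 95, by = grid_step)
  signal <- numeric(length(temperature))
  if (!is.null(products) && nrow(products) > 0L) {
    stopifnot(all(c("tm", "amplitude") %in% names(products)))
    for (i in seq_len(nrow(products))) {
      signal <- signal + products$amplitude[i] *
        exp(-((temperature - products$tm[i])^2) / (2 * sigma^2))
    }
  }
  n <- length(signal)
  is_peak <- c(FALSE, signal[2:(n - 1)] > signal[1:(n - 2)] &
                 signal[2:(n - 1)] >= signal[3:n], FALSE) &
    signal > min_height
  curve <- list(temperature = temperature, signal = signal,
                peaks = data.frame(tm = temperature[is_peak],
                                   height = signal[is_peak]))
  class(curve) <- "rhd_melt_curve"
  curve
}

#' @export
print.rhd_melt_curve <- function(x, ...) {
  cat("Melt curve, ", length(x$temperature), " grid points; ",
      nrow(x$peaks), " peak(s)", sep = "")
  if (nrow(x$peaks)) cat(" at ", paste(round(x$peaks$tm, 1), collapse = ", "),
                         " degC", sep = "")
  cat("\n")
  invisible(x)
}

#' Validate a set of melt standards against a classification tolerance
#'
#' Two standards closer than twice the tolerance cannot be discriminated;
#' this is a configuration error caught before any classification runs.
#' @param standards named numeric vector of reference Tms (degC).
#' @param tolerance classification half-window in degC.
#' @return invisibly `TRUE`.
#' @export
validate_melt_standards <- function(standards, tolerance = 1.0) {
  stopifnot(is.numeric(standards), !is.null(names(standards)), tolerance > 0)
  s <- sort(standards)
  if (any(diff(s) < 2 * tolerance)) {
    stop("melt standards closer than 2 x tolerance: ",
         paste(names(s), round(s, 1), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify melt peaks against predefined genotyping standards
#'
#' Each observed peak is matched to the nearest standard within `tolerance`;
#' peaks matching no standard are labelled `"unclassified_peak"`.
#'
#' @param curve an `rhd_melt_curve` (or a numeric vector of peak Tms).
#' @param standards named numeric vector of reference Tms.
#' @param tolerance matching half-window in degC (default 1.0).
#' @return character vector of labels, one per observed peak (possibly
#'   empty).
#' @export
classify_melt <- function(curve, standards, tolerance = 1.0) {
  validate_melt_standards(standards, tolerance)
  tms <- if (inherits(curve, "rhd_melt_curve")) curve$peaks$tm else curve
  if (length(tms) == 0L) return(character())
  vapply(tms, function(t) {
    d <- abs(standards - t)
    i <- which.min(d)
    if (d[i] <= tolerance) names(standards)[i] else "unclassified_peak"
  }, character(1))
}

#' Run one allele-specific PCR assay on a sample
#'
#' Amplifies the allele-specific target on each haplotype and the beta-globin
#' internal control on the sample's control locus, synthesizes the joint melt
#' curve, and classifies it by melting-curve genotyping. The call is
#' `POSITIVE` iff a target peak is present, `NEGATIVE` iff only the control
#' peak is seen (ruling out a false negative), and `INVALID` iff no peak at
#' all appears in a reaction that should at least amplify the control.
#'
#' @param sample an `rhd_sample` (see [make_sample()]).
#' @param assay one row of [rhd_ssp_assays()].
#' @param tolerance melt classification tolerance in degC.
#' @param max_mismatch primer mismatch budget outside the 3' base.
#' @return object of class `rhd_ssp_result`: list with `assay_name`, `call`,
#'   `observed_tms`, `genotype_label`, and `curve`.
#' @export
run_ssp_assay <- function(sample, assay, tolerance = 1.0, max_mismatch = 0L) {
  stopifnot(inherits(sample, "rhd_sample"), nrow(assay) == 1L)
  n_target <- 0L
  for (hap in sample$haplotypes) {
    amp <- find_amplicon(hap$rhd, assay$fwd_seq, assay$rev_seq,
                         max_mismatch = max_mismatch)
    if (!is.null(amp)) n_target <- n_target + 1L
  }
  ctrl_amp <- find_amplicon(sample$control, assay$control_fwd_seq,
                            assay$control_rev_seq,
                            max_mismatch = max_mismatch)
  products <- data.frame(tm = numeric(), amplitude = numeric())
  if (n_target > 0L) {
    products <- rbind(products,
                      data.frame(tm = assay$target_tm, amplitude = 1.0))
  }
  if (!is.null(ctrl_amp)) {
    products <- rbind(products,
                      data.frame(tm = assay$control_tm, amplitude = 0.6))
  }
  curve <- synthesize_melt_curve(products)
  standards <- c(target = assay$target_tm, control = assay$control_tm)
  labels <- classify_melt(curve, standards, tolerance)
  has_target <- "target" %in% labels
  has_control <- "control" %in% labels
  call <- if (has_target) "POSITIVE" else if (has_control) "NEGATIVE" else
    "INVALID"
  genotype_label <- switch(call,
                           POSITIVE = assay$assay_name,
                           NEGATIVE = paste0("non-", assay$assay_name),
                           INVALID = "invalid")
  res <- list(assay_name = assay$assay_name, call = call,
              observed_tms = curve$peaks$tm, genotype_label = genotype_label,
              curve = curve)
  class(res) <- "rhd_ssp_result"
  res
}

#' @export
print.rhd_ssp_result <- function(x, ...) {
  cat(x$assay_name, ": ", x$call, " (", x$genotype_label, "); peaks at ",
      paste(round(x$observed_tms, 1), collapse = ", "), " degC\n", sep = "")
  invisible(x)
}

#' Exon 1-10 amplification screen
#'
#' Runs the ten exon amplification reactions on a sample; an exon is present
#' iff at least one haplotype yields a product and the synthesized melt peak
#' classifies to that exon's melt standard.
#'
#' @param sample an `rhd_sample`.
#' @param exon_assays assay table, defaulting to [rhd_exon_assays()].
#' @param tolerance melt classification tolerance in degC.
#' @param max_mismatch primer mismatch budget outside the 3' base.
#' @return object of class `rhd_exon_profile`: data.frame with columns
#'   `exon`, `present`, `observed_tm` (NA when absent).
#' @export
amplify_exons <- function(sample, exon_assays = rhd_exon_assays(),
                          tolerance = 1.0, max_mismatch = 0L) {
  stopifnot(inherits(sample, "rhd_sample"))
  present <- logical(nrow(exon_assays))
  observed_tm <- rep(NA_real_, nrow(exon_assays))
  for (k in seq_len(nrow(exon_assays))) {
    amplified <- FALSE
    for (hap in sample$haplotypes) {
      amp <- find_amplicon(hap$rhd, exon_assays$fwd_seq[k],
                           exon_assays$rev_seq[k],
                           max_mismatch = max_mismatch)
      if (!is.null(amp)) amplified <- TRUE
    }
    if (amplified) {
      curve <- synthesize_melt_curve(
        data.frame(tm = exon_assays$tm[k], amplitude = 1.0))
      lab <- classify_melt(curve, c(exon = exon_assays$tm[k]), tolerance)
      if ("exon" %in% lab) {
        present[k] <- TRUE
        observed_tm[k] <- curve$peaks$tm[match("exon", lab)]
      }
    }
  }
  profile <- data.frame(exon = exon_assays$exon, present = present,
                        observed_tm = observed_tm)
  class(profile) <- c("rhd_exon_profile", class(profile))
  profile
}

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotides.
nn_dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
           CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
           GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
           TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
nn_ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
           CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
           GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
           TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

#' Thermodynamic melting temperature estimate
#'
#' Nearest-neighbor estimate (unified duplex parameters with initiation
#' terms), with the entropic salt correction 0.368 (N-1) ln[Na+]. Melting
#' behavior depends on length and sequence but predominantly on GC content;
#' this estimate is exposed as a diagnostic only -- melting-curve genotyping
#' always classifies against the empirically configured standards.
#'
#' @param sequence amplicon sequence (A/C/G/T only).
#' @param na_molar monovalent cation concentration in mol/L (default 0.05).
#' @param conc_molar total strand concentration in mol/L (default 2.5e-7).
#' @return estimated Tm in degC.
#' @export
estimate_tm <- function(sequence, na_molar = 0.05, conc_molar = 2.5e-7) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2L) {
    stop("sequence must have at least two bases", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("sequence contains non-ACGT symbols", call. = FALSE)
  }
  steps <- paste0(chars[-length(chars)], chars[-1])
  dh <- sum(nn_dh[steps])
  ds <- sum(nn_ds[steps])
  for (b in chars[c(1L, length(chars))]) {
    if (b %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (length(chars) - 1L) * log(na_molar)
  1000 * dh / (ds + 1.987 * log(conc_molar / 4)) - 273.15
}
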