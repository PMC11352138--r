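# Independent brute-force in-silico PCR oracle: plain substring scans over
# every start position, no Biostrings. Default (zero-mismatch) configuration.
oracle_find_amplicon <- function(template, fwd_seq, rev_seq,
                                 max_len = 1500L) {
  if (is.null(template) || is.na(template) || nchar(template) == 0L) {
    return(NULL)
  }
  template <- toupper(template)
  strip_tail <- function(s) {
    if (startsWith(toupper(s), "CAGGAAACAGCTATGAC")) {
      substr(s, 18L, nchar(s))
    } else {
      s
    }
  }
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }
  fwd_core <- toupper(strip_tail(fwd_seq))
  rev_core <- toupper(strip_tail(rev_seq))
  tails <- (nchar(fwd_seq) - nchar(fwd_core)) +
    (nchar(rev_seq) - nchar(rev_core))
  rev_site <- rc(rev_core)
  n <- nchar(template)
  all_sites <- function(pat) {
    m <- nchar(pat)
    hits <- integer()
    for (i in seq_len(n - m + 1L)) {
      if (substr(template, i, i + m - 1L) == pat) hits <- c(hits, i - 1L)
    }
    hits
  }
  f_starts <- all_sites(fwd_core)
  r_starts <- all_sites(rev_site)
  if (!length(f_starts) || !length(r_starts)) return(NULL)
  best <- NULL
  for (f in sort(f_starts)) {
    ends <- r_starts[r_starts >= f + nchar(fwd_core)] + nchar(rev_core)
    ends <- ends[ends - f + tails <= max_len]
    if (!length(ends)) next
    r <- min(ends)
    if (is.null(best) || (r - f) < (best$end - best$start)) {
      best <- list(start = f, end = r)
    }
  }
  best
}

# random primer/template case generator for the oracle comparison
random_pcr_case <- function(template_len = 2000L) {
  bases <- c("A", "C", "G", "T")
  templ <- paste(sample(bases, template_len, replace = TRUE), collapse = "")
  fwd <- paste(sample(bases, sample(18:25, 1), replace = TRUE),
               collapse = "")
  rev <- paste(sample(bases, sample(18:25, 1), replace = TRUE),
               collapse = "")
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  plant <- function(t, pos0, s) {
    paste0(substr(t, 1, pos0), s, substr(t, pos0 + nchar(s) + 1, nchar(t)))
  }
  scenario <- sample(c("product", "extra_rev", "fwd_only", "none"), 1,
                     prob = c(0.5, 0.2, 0.15, 0.15))
  if (scenario %in% c("product", "extra_rev", "fwd_only")) {
    a <- sample(50:800, 1)
    templ <- plant(templ, a, fwd)
    if (scenario != "fwd_only") {
      b <- sample((a + nchar(fwd) + 50):1500, 1)
      templ <- plant(templ, b, rc(rev))
      if (scenario == "extra_rev") {
        b2 <- sample((b + nchar(rev) + 20):1900, 1)
        templ <- plant(templ, b2, rc(rev))
      }
    }
  }
  list(template = templ, fwd = fwd, rev = rev)
}
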