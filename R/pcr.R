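#' Find annealing sites of a degenerate primer on a template
#'
#' Scans every window of the template for an IUPAC-aware match to the primer
#' with at most `max_mismatch` mismatched positions (no indels).  Forward
#' primers are matched against the plus strand; reverse primers are matched
#' as their reverse complement against the plus strand and reported on the
#' minus strand.
#'
#' @param template A single sequence (string, named character of length 1,
#'   or [Biostrings::DNAStringSet] of length 1).
#' @param primer One-row data.frame with `name`, `sequence`, `orientation`
#'   (see [read_primer_config()], [get_primer()]).
#' @param max_mismatch Maximum mismatches tolerated (default 0; universal
#'   16S primers are expected to match their organelle targets perfectly).
#' @return A data.frame with columns `template_id`, `primer_name`, `strand`,
#'   `start`, `end` (0-based half-open plus-strand footprint) and
#'   `mismatches`.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0L) {
  template <- as_seq_chr(template, default_prefix = "template")
  if (length(template) != 1L)
    stop("find_primer_sites expects a single template", call. = FALSE)
  if (!is.data.frame(primer) || nrow(primer) != 1L)
    stop("primer must be a one-row data.frame (see get_primer())",
         call. = FALSE)
  s <- template[[1L]]
  check_iupac(s, sprintf("template '%s'", names(template)))
  probe <- if (primer$orientation == "forward") primer$sequence
           else reverse_complement(primer$sequence)
  strand <- if (primer$orientation == "forward") "+" else "-"
  n <- nchar(s)
  m <- nchar(probe)
  empty <- data.frame(template_id = character(0), primer_name = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (n < m) return(empty)
  cs <- strsplit(s, "", fixed = TRUE)[[1L]]
  ps <- strsplit(probe, "", fixed = TRUE)[[1L]]
  starts0 <- 0:(n - m)
  mm <- integer(length(starts0))
  for (j in seq_len(m))
    mm <- mm + !iupac_match_matrix[cbind(cs[starts0 + j], ps[[j]])]
  keep <- mm <= max_mismatch
  if (!any(keep)) return(empty)
  data.frame(template_id = names(template), primer_name = primer$name,
             strand = strand, start = starts0[keep],
             end = starts0[keep] + m, mismatches = mm[keep],
             stringsAsFactors = FALSE)
}

#' In-silico PCR: derive amplicons from a primer pair
#'
#' Pairs every forward-primer site with every downstream reverse-primer site
#' on a template and reports the products (primer footprints included, as
#' amplicon lengths are conventionally reported).  Products from multiple
#' site pairs are all returned and flagged when they nest or overlap.
#'
#' @param template A single template sequence.
#' @param fwd,rev One-row primer data.frames with orientation `forward` and
#'   `reverse` respectively.
#' @param max_product_len Longest product reported (default 5000).
#' @param max_mismatch Mismatch tolerance for primer annealing (default 0).
#' @return A data.frame with columns `template_id`, `fwd_name`, `rev_name`,
#'   `start`, `end` (0-based half-open product coordinates), `length`,
#'   `sequence` and `overlapping` (TRUE when another reported product
#'   shares coordinates).  No forward or no reverse site yields zero rows.
#' @export
simulate_amplicon <- function(template, fwd, rev, max_product_len = 5000L,
                              max_mismatch = 0L) {
  if (!is.data.frame(fwd) || fwd$orientation[[1L]] != "forward")
    stop("fwd must be a forward primer", call. = FALSE)
  if (!is.data.frame(rev) || rev$orientation[[1L]] != "reverse")
    stop("rev must be a reverse primer", call. = FALSE)
  template <- as_seq_chr(template, default_prefix = "template")
  fs <- find_primer_sites(template, fwd, max_mismatch)
  rs <- find_primer_sites(template, rev, max_mismatch)
  empty <- data.frame(template_id = character(0), fwd_name = character(0),
                      rev_name = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0), overlapping = logical(0),
                      stringsAsFactors = FALSE)
  if (!nrow(fs) || !nrow(rs)) return(empty)
  pairs <- expand.grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
  keep <- fs$end[pairs$f] <= rs$start[pairs$r] &
    (rs$end[pairs$r] - fs$start[pairs$f]) <= max_product_len
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  start <- fs$start[pairs$f]
  end <- rs$end[pairs$r]
  out <- data.frame(template_id = names(template),
                    fwd_name = fwd$name, rev_name = rev$name,
                    start = start, end = end, length = end - start,
                    sequence = substring(template[[1L]], start + 1L, end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  n <- nrow(out)
  out$overlapping <- vapply(seq_len(n), function(i)
    any(out$start[-i] < out$end[i] & out$end[-i] > out$start[i]),
    logical(1L))
  rownames(out) <- NULL
  out
}

#' Guides fully contained in an amplicon
#'
#' Returns the guides whose protospacer and PAM both lie entirely within
#' the amplicon's product coordinates, on either strand (the PCR product is
#' double-stranded).  Only guides designed for Cas9 sites inside the
#' sequenced amplicon can deplete it.
#'
#' @param guides Guide table from [enumerate_guides()].
#' @param amplicon One row of a [simulate_amplicon()] result; guides and
#'   amplicon must share template coordinates (`source_id` ==
#'   `template_id`).
#' @param pam_len PAM length (default 3).
#' @return The qualifying subset of `guides` (row order preserved).
#' @export
guides_in_amplicon <- function(guides, amplicon, pam_len = 3L) {
  if (!is.data.frame(amplicon) || nrow(amplicon) != 1L)
    stop("amplicon must be a single row", call. = FALSE)
  span_start <- ifelse(guides$strand == "+", guides$start,
                       guides$start - pam_len)
  span_end <- ifelse(guides$strand == "+", guides$end + pam_len, guides$end)
  keep <- guides$source_id == amplicon$template_id &
    span_start >= amplicon$start & span_end <= amplicon$end
  guides[keep, , drop = FALSE]
}
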