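# Shared single-strand protospacer/PAM window scanner.
#
# Returns 0-based start positions (on the scanned strand) of every
# `guide_len` window of unambiguous ACGT immediately followed 3' by a window
# matching `pam_pattern`.  Pattern positions other than 'N' additionally
# require an unambiguous template base (a degenerate template base cannot be
# confirmed as a PAM); 'N' positions accept anything.
scan_protospacers <- function(seq, guide_len, pam_pattern) {
  n <- nchar(seq)
  plen <- nchar(pam_pattern)
  total <- guide_len + plen
  if (n < total) return(integer(0))
  cs <- strsplit(seq, "", fixed = TRUE)[[1L]]
  unamb <- cs %in% DNA_BASES
  cum <- c(0L, cumsum(!unamb))
  starts0 <- 0:(n - total)                       # 0-based window starts
  ok <- (cum[starts0 + guide_len + 1L] - cum[starts0 + 1L]) == 0L
  pat <- strsplit(pam_pattern, "", fixed = TRUE)[[1L]]
  for (p in seq_len(plen)) {
    if (pat[[p]] == "N") next
    tb <- cs[starts0 + guide_len + p]
    ok <- ok & unamb[starts0 + guide_len + p] &
      iupac_match_matrix[cbind(tb, pat[[p]])]
    ok[is.na(ok)] <- FALSE
  }
  starts0[ok]
}

#' Enumerate Cas9-targetable guide sites on a host 16S rRNA gene
#'
#' Scans each input sequence (both strands by default) for every
#' `guide_len`-mer of unambiguous ACGT immediately followed 3' by a PAM
#' matching `pam_pattern` (IUPAC-aware).  All overlapping sites are
#' reported; windows containing any ambiguous base in the protospacer or at
#' a fixed (non-N) PAM position are skipped, since such guides are not
#' synthesizable as unambiguous oligos.
#'
#' @param seqs Host gene sequence(s): a [Biostrings::DNAStringSet], a named
#'   character vector, or a single string.
#' @param guide_len Protospacer length (default 20).
#' @param pam_pattern IUPAC PAM pattern 3' of the protospacer (default
#'   `"NGG"`, the Cas9 PAM).
#' @param both_strands Scan the reverse strand too (default TRUE; the PCR
#'   amplicon is double-stranded).
#' @param id_prefix Prefix for guide ids, recycled over input sequences.
#'   Defaults to `"<source_id>_gRNA"`.  Ids are `<prefix><p>` where `p` is
#'   the 1-based plus-strand coordinate of the protospacer base closest to
#'   the PAM; on the rare id collision a strand tag is appended.
#' @return A data.frame with columns `guide_id`, `source_id`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open protospacer coordinates on
#'   the plus strand), `protospacer` (written 5'->3', PAM-proximal base
#'   last) and `pam` (the 3 observed PAM bases), sorted by (source, strand,
#'   start).  Sequences shorter than `guide_len + nchar(pam_pattern)`
#'   contribute no rows.
#' @examples
#' enumerate_guides(paste0(strrep("A", 20), "AGG"))
#' @export
enumerate_guides <- function(seqs, guide_len = 20L, pam_pattern = "NGG",
                             both_strands = TRUE, id_prefix = NULL) {
  seqs <- as_seq_chr(seqs)
  if (!is.numeric(guide_len) || guide_len < 1L)
    stop("guide_len must be >= 1", call. = FALSE)
  guide_len <- as.integer(guide_len)
  pam_pattern <- normalize_iupac(pam_pattern)
  check_iupac(pam_pattern, "pam_pattern")
  stopifnot_scalar_flag(both_strands, "both_strands")
  plen <- nchar(pam_pattern)
  prefixes <- if (is.null(id_prefix)) paste0(names(seqs), "_gRNA")
              else rep_len(id_prefix, length(seqs))

  one <- function(k) {
    s <- seqs[[k]]
    check_iupac(s, sprintf("sequence '%s'", names(seqs)[[k]]))
    n <- nchar(s)
    rows <- list()
    fwd <- scan_protospacers(s, guide_len, pam_pattern)
    if (length(fwd)) {
      rows[["+"]] <- data.frame(
        source_id = names(seqs)[[k]], strand = "+",
        start = fwd, end = fwd + guide_len,
        protospacer = substring(s, fwd + 1L, fwd + guide_len),
        pam = substring(s, fwd + guide_len + 1L, fwd + guide_len + plen),
        stringsAsFactors = FALSE)
    }
    if (both_strands) {
      rc <- reverse_complement(s)
      rev0 <- scan_protospacers(rc, guide_len, pam_pattern)
      if (length(rev0)) {
        rows[["-"]] <- data.frame(
          source_id = names(seqs)[[k]], strand = "-",
          start = n - rev0 - guide_len, end = n - rev0,
          protospacer = substring(rc, rev0 + 1L, rev0 + guide_len),
          pam = substring(rc, rev0 + guide_len + 1L, rev0 + guide_len + plen),
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(guide_id = character(0), source_id = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), protospacer = character(0),
                        pam = character(0), stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    df <- df[order(df$strand, df$start), , drop = FALSE]
    # PAM-proximal protospacer base, 1-based plus-strand coordinate
    p <- ifelse(df$strand == "+", df$end, df$start + 1L)
    id <- paste0(prefixes[[k]], p)
    dup <- id %in% id[duplicated(id)]
    id[dup] <- paste0(id[dup], ifelse(df$strand[dup] == "+", "f", "r"))
    df$guide_id <- id
    df
  }
  out <- do.call(rbind, lapply(seq_along(seqs), one))
  rownames(out) <- NULL
  out[c("guide_id", "source_id", "strand", "start", "end",
        "protospacer", "pam")]
}
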