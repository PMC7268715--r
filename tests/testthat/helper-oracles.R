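# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1L))
}

# --- brute-force protospacer/PAM window scan (single strand) ---------------
# Independent of the package's vectorized scanner: explicit loop + regexpr.
brute_scan_strand <- function(seq, guide_len = 20L, pam = "NGG") {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  n <- nchar(seq)
  plen <- nchar(pam)
  pat <- strsplit(pam, "")[[1]]
  hits <- integer(0)
  if (n < guide_len + plen) return(hits)
  for (i in 0:(n - guide_len - plen)) {
    proto <- substr(seq, i + 1, i + guide_len)
    if (grepl("[^ACGT]", proto)) next
    ok <- TRUE
    for (p in seq_len(plen)) {
      tb <- substr(seq, i + guide_len + p, i + guide_len + p)
      if (pat[p] == "N") next
      if (!tb %in% c("A", "C", "G", "T") ||
          !tb %in% sets[[pat[p]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# both-strand guide count, fully independent of enumerate_guides
brute_guide_count <- function(seq, guide_len = 20L, pam = "NGG") {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  length(brute_scan_strand(seq, guide_len, pam)) +
    length(brute_scan_strand(rc, guide_len, pam))
}

# --- edit-distance oracles -------------------------------------------------
# Total edits of the anchored subproblem: drop the PAM-proximal (last)
# column, take plain Levenshtein distance of the remainder via utils::adist.
oracle_total_edits <- function(guide, cand) {
  L <- nchar(guide)
  as.integer(utils::adist(substr(guide, 1, L - 1), substr(cand, 1, L - 1)))
}

# Minimum seed edits over all co-optimal alignments, by exhaustive recursive
# enumeration of alignment paths (use only for short strings).  Mismatch /
# deletion are charged to the guide index they consume; insertion to the
# adjacent PAM-proximal guide index.  String index i (1-based, full string
# of length L) is in the seed iff i > L - seed_len.
oracle_seed_edits <- function(guide, cand, seed_len) {
  L <- nchar(guide)
  g <- strsplit(substr(guide, 1, L - 1), "")[[1]]
  c_ <- strsplit(substr(cand, 1, L - 1), "")[[1]]
  n <- length(g)
  in_seed_consume <- function(i1) i1 > L - seed_len        # guide index i1
  in_seed_insert <- function(i_next) {
    # gap before guide index i_next (1-based); i_next == n+1 -> anchor
    if (i_next > n) TRUE else i_next > L - seed_len
  }
  best_total <- oracle_total_edits(guide, cand)
  best_seed <- Inf
  rec <- function(i, j, tot, seed) {
    if (tot > best_total) return()
    if (i > n && j > n) {
      if (tot == best_total && seed < best_seed) best_seed <<- seed
      return()
    }
    if (i <= n && j <= n) {
      mm <- as.integer(g[i] != c_[j])
      rec(i + 1, j + 1, tot + mm,
          seed + if (mm && in_seed_consume(i)) 1 else 0)
    }
    if (i <= n)
      rec(i + 1, j, tot + 1, seed + if (in_seed_consume(i)) 1 else 0)
    if (j <= n)
      rec(i, j + 1, tot + 1, seed + if (in_seed_insert(i)) 1 else 0)
  }
  rec(1, 1, 0, 0)
  as.integer(best_seed)
}

# --- exhaustive off-target count (no prefilter, pure R) --------------------
# Counts reference sequences (or sites) carrying >= 1 qualifying site for
# each guide, via extract_candidate_sites + align + classify; used as the
# all-pairs oracle against count_offtargets.
oracle_count_offtargets <- function(guides_df, refs_chr, criteria,
                                    unit = "sequences") {
  sites <- extract_candidate_sites(refs_chr)
  sapply(seq_len(nrow(guides_df)), function(gi) {
    g <- guides_df$protospacer[gi]
    if (!nrow(sites)) return(c(ngg = 0L, nag = 0L))
    aln <- align_guide_candidate(g, sites$protospacer, criteria)
    call <- classify_offtarget(aln, sites$pam_class, criteria)$is_offtarget
    if (unit == "sites") {
      c(ngg = sum(call & sites$pam_class == "NGG"),
        nag = sum(call & sites$pam_class == "NAG"))
    } else {
      ngg_refs <- unique(sites$ref_id[call & sites$pam_class == "NGG"])
      nag_refs <- setdiff(unique(sites$ref_id[call &
                                                sites$pam_class == "NAG"]),
                          ngg_refs)
      c(ngg = length(ngg_refs), nag = length(nag_refs))
    }
  })
}

# random community profile helper
random_profile <- function(n, host = 1L) {
  f <- runif(n)
  f <- f / sum(f)
  community_profile(paste0("m", seq_len(n)), f,
                    seq_len(n) %in% host)
}
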