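#' Extract candidate protospacer sites from a 16S reference set
#'
#' Finds every 20-nt unambiguous window immediately 5' of an observed
#' `NGG` or `NAG` trinucleotide, on both strands by default.  These are the
#' reference sites a Cas9 guide could conceivably cleave; each is later
#' aligned against the guide and classified.  Candidate windows containing
#' non-ACGT characters are skipped (an ambiguous base cannot be confirmed as
#' a match).
#'
#' @param refs Reference sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param pam_classes Subset of `c("NGG", "NAG")`.
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @param guide_len Protospacer length (default 20).
#' @return A data.frame with columns `ref_id`, `strand`, `start`, `end`
#'   (0-based half-open plus-strand protospacer coordinates), `protospacer`
#'   (PAM-proximal base last) and `pam_class`.
#' @details The counting path ([count_offtargets()]) calls the per-reference
#'   scanner directly and never materialises the full site table, so memory
#'   stays constant in the number of references.
#' @export
extract_candidate_sites <- function(refs, pam_classes = c("NGG", "NAG"),
                                    both_strands = TRUE, guide_len = 20L) {
  refs <- as_seq_chr(refs, default_prefix = "ref")
  pam_classes <- match.arg(pam_classes, several.ok = TRUE)
  out <- lapply(seq_along(refs), function(k)
    sites_one_ref(refs[[k]], names(refs)[[k]], pam_classes, both_strands,
                  guide_len))
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ref_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      protospacer = character(0), pam_class = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# per-reference candidate-site scan (streaming unit of count_offtargets)
sites_one_ref <- function(s, id, pam_classes, both_strands, guide_len = 20L) {
  n <- nchar(s)
  rows <- list()
  for (pc in pam_classes) {
    pat <- if (pc == "NGG") "NGG" else "NAG"
    fwd <- scan_protospacers(s, guide_len, pat)
    if (length(fwd))
      rows[[paste0(pc, "+")]] <- data.frame(
        ref_id = id, strand = "+", start = fwd, end = fwd + guide_len,
        protospacer = substring(s, fwd + 1L, fwd + guide_len),
        pam_class = pc, stringsAsFactors = FALSE)
    if (both_strands) {
      rc <- reverse_complement(s)
      rev0 <- scan_protospacers(rc, guide_len, pat)
      if (length(rev0))
        rows[[paste0(pc, "-")]] <- data.frame(
          ref_id = id, strand = "-",
          start = n - rev0 - guide_len, end = n - rev0,
          protospacer = substring(rc, rev0 + 1L, rev0 + guide_len),
          pam_class = pc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df[order(df$pam_class, df$strand, df$start), , drop = FALSE]
}

#' Anchored edit statistics for a guide/candidate pair
#'
#' Core alignment primitive, exposed for arbitrary equal lengths (>= 2) so
#' its optimality properties can be checked directly.  Both strings are
#' written 5'->3' with the PAM-proximal base last.  The PAM-proximal column
#' is anchored (compared positionally, `anchored_match`); the remaining
#' (L-1)-vs-(L-1) problem is a unit-cost global alignment.  `total_edits`
#' is its minimum edit distance and `seed_edits` the minimum number of edits
#' assigned to seed positions over all co-optimal alignments (lexicographic
#' objective), where a mismatch/deletion is charged to the guide position it
#' consumes and an insertion to the adjacent PAM-proximal guide position.
#'
#' @param guide Guide string (ACGT).
#' @param candidates Character vector of candidate strings, same length as
#'   `guide`.
#' @param seed_len Seed length (positions from the PAM).
#' @return A data.frame with columns `total_edits`, `seed_edits`,
#'   `anchored_match`.
#' @export
anchored_edit_stats <- function(guide, candidates, seed_len = 12L) {
  if (!is.character(guide) || length(guide) != 1L)
    stop("guide must be a single string", call. = FALSE)
  L <- nchar(guide)
  if (L < 2L) stop("guide must have length >= 2", call. = FALSE)
  if (!is_acgt(guide) || !all(is_acgt(candidates)))
    stop("guide and candidates must be ACGT-only", call. = FALSE)
  if (any(nchar(candidates) != L))
    stop("candidates must have the same length as the guide", call. = FALSE)
  m <- cpp_anchored_align(guide, candidates, as.integer(seed_len))
  data.frame(total_edits = unname(m[, 1L]), seed_edits = unname(m[, 2L]),
             anchored_match = unname(m[, 3L] == 1L), row.names = NULL)
}

#' Align a guide against candidate protospacers
#'
#' 20-nt front end over [anchored_edit_stats()] for guide specificity
#' screening; see there for the alignment model.
#'
#' @param guide 20-nt ACGT guide (PAM-proximal base last).
#' @param candidates 20-nt ACGT candidate protospacer(s).
#' @param criteria An [offtarget_criteria()] object.
#' @return A data.frame with columns `total_edits`, `seed_edits`,
#'   `anchored_match`, one row per candidate.
#' @examples
#' g <- strrep("ACGT", 5)
#' align_guide_candidate(g, g, offtarget_criteria())
#' @export
align_guide_candidate <- function(guide, candidates,
                                  criteria = offtarget_criteria()) {
  if (nchar(guide) != 20L || any(nchar(candidates) != 20L))
    stop("guide and candidates must be 20-nt strings", call. = FALSE)
  anchored_edit_stats(guide, candidates, criteria$seed_len)
}

#' Classify aligned candidate sites as off-targets
#'
#' Applies the seed-region criteria to alignment statistics: with edit
#' ceiling `T` for the site's PAM class, a site is an off-target iff the
#' anchored base matched and `total_edits < T`, or `total_edits == T` with
#' every edit outside the seed region (`seed_edits == 0`).
#'
#' @param alignment Data frame from [align_guide_candidate()] (columns
#'   `total_edits`, `seed_edits`, `anchored_match`).
#' @param pam_class `"NGG"` or `"NAG"`, recycled over rows.
#' @param criteria An [offtarget_criteria()] object.
#' @return The input with columns `is_offtarget` (logical) and `rule_fired`
#'   (`below_threshold`, `at_threshold_outside_seed`, `anchored_fail`,
#'   `rejected`) appended.
#' @export
classify_offtarget <- function(alignment, pam_class,
                               criteria = offtarget_criteria()) {
  stopifnot(all(c("total_edits", "seed_edits", "anchored_match") %in%
                  names(alignment)))
  pam_class <- rep_len(pam_class, nrow(alignment))
  if (!all(pam_class %in% c("NGG", "NAG")))
    stop("pam_class must be 'NGG' or 'NAG'", call. = FALSE)
  ceiling <- ifelse(pam_class == "NGG", criteria$max_edits_ngg,
                    criteria$max_edits_nag)
  anch_ok <- alignment$anchored_match | !criteria$anchored_last_base
  below <- alignment$total_edits < ceiling
  at_out <- alignment$total_edits == ceiling & alignment$seed_edits == 0L
  alignment$is_offtarget <- anch_ok & (below | at_out)
  alignment$rule_fired <- ifelse(!anch_ok, "anchored_fail",
                          ifelse(below, "below_threshold",
                          ifelse(at_out, "at_threshold_outside_seed",
                                 "rejected")))
  alignment
}

#' Lossless k-mer prefilter over candidate sites
#'
#' Drops candidate sites that share no exact k-mer with the guide.  The word
#' length is capped at `ceil((L - e)/(e + 1))` (`e` = the larger PAM-class
#' edit ceiling), so by pigeonhole over the untouched alignment segments no
#' site that [classify_offtarget()] would call an off-target is ever
#' dropped: filtering is bitwise-neutral to the final counts.
#'
#' @param guide 20-nt ACGT guide.
#' @param sites Candidate site table from [extract_candidate_sites()].
#' @param criteria An [offtarget_criteria()] object.
#' @return The subset of `sites` passing the filter.
#' @export
prefilter_candidates <- function(guide, sites,
                                 criteria = offtarget_criteria()) {
  if (!nrow(sites)) return(sites)
  w <- lossless_word(nchar(guide), criteria)
  nk <- nchar(guide) - w + 1L
  gk <- unique(substring(guide, seq_len(nk), seq_len(nk) + w - 1L))
  keep <- vapply(sites$protospacer, function(s) {
    sk <- substring(s, seq_len(nchar(s) - w + 1L),
                    seq_len(nchar(s) - w + 1L) + w - 1L)
    any(sk %in% gk)
  }, logical(1L), USE.NAMES = FALSE)
  sites[keep, , drop = FALSE]
}

#' Count off-targets and rank guide specificity
#'
#' For each guide, scans the reference set for qualifying off-target sites
#' (see [classify_offtarget()]) and reports off-target counts split by PAM
#' class, a specificity rank (1 = most specific) and whether the guide
#' passes the ranking cutoff.  References are processed one at a time, so
#' memory use is constant in the number of references.
#'
#' @param guides Guide table from [enumerate_guides()] (or a data.frame with
#'   at least `guide_id` and `protospacer`; a bare character vector of
#'   20-mers is also accepted).
#' @param refs Reference sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param criteria An [offtarget_criteria()] object.
#' @param exclude_ref_ids Reference record ids to drop before counting
#'   (e.g. host-organelle homologs such as chloroplast records when scoring
#'   plastid guides).  References whose id equals a guide's `source_id` are
#'   additionally skipped for that guide.
#' @param unit `"sequences"` (default): a reference counts once per guide if
#'   it carries >= 1 qualifying site, attributed to NGG when any NGG site
#'   qualifies, otherwise NAG.  `"sites"`: qualifying sites are summed.
#' @param prefilter Apply the lossless k-mer prefilter (default TRUE);
#'   results are identical with and without it.
#' @param both_strands Scan both reference strands (default TRUE).
#' @param cutoff_fraction If non-NULL, overrides `criteria$rank_cutoff` with
#'   `floor(cutoff_fraction * n_references_after_exclusion)`.
#' @param audit Collect one row per off-target call (guide_id, ref_id,
#'   strand, coordinates, pam_class, total_edits, seed_edits), returned as
#'   attribute `"audit"`.
#' @return A data.frame (`guide_id`, `protospacer`, `n_offtargets_ngg`,
#'   `n_offtargets_nag`, `n_offtargets`, `rank`, `passes_cutoff`) sorted by
#'   ascending `n_offtargets` with a deterministic tie-break on `guide_id`.
#' @export
count_offtargets <- function(guides, refs,
                             criteria = offtarget_criteria(),
                             exclude_ref_ids = character(0),
                             unit = c("sequences", "sites"),
                             prefilter = TRUE, both_strands = TRUE,
                             cutoff_fraction = NULL, audit = FALSE) {
  unit <- match.arg(unit)
  if (is.character(guides))
    guides <- data.frame(guide_id = if (is.null(names(guides)))
                           paste0("g", seq_along(guides)) else names(guides),
                         source_id = NA_character_,
                         protospacer = unname(guides),
                         stringsAsFactors = FALSE)
  if (!nrow(guides))
    return(data.frame(guide_id = character(0), protospacer = character(0),
                      n_offtargets_ngg = integer(0),
                      n_offtargets_nag = integer(0),
                      n_offtargets = integer(0), rank = integer(0),
                      passes_cutoff = logical(0)))
  if (any(nchar(guides$protospacer) != 20L) ||
      !all(is_acgt(guides$protospacer)))
    stop("guide protospacers must be 20-nt ACGT strings", call. = FALSE)
  refs <- as_seq_chr(refs, default_prefix = "ref")
  refs <- refs[!(names(refs) %in% exclude_ref_ids)]
  src <- if ("source_id" %in% names(guides)) guides$source_id
         else rep(NA_character_, nrow(guides))
  w <- lossless_word(20L, criteria)

  ngg <- nag <- integer(nrow(guides))
  audit_rows <- list()
  for (k in seq_along(refs)) {
    sites <- sites_one_ref(refs[[k]], names(refs)[[k]], c("NGG", "NAG"),
                           both_strands)
    if (is.null(sites) || !nrow(sites)) next
    res <- cpp_count_hits(guides$protospacer, sites$protospacer,
                          as.integer(sites$pam_class == "NAG"),
                          criteria$seed_len, criteria$max_edits_ngg,
                          criteria$max_edits_nag, isTRUE(prefilter), w,
                          isTRUE(audit))
    cnt <- res$counts
    # skip self-hits: reference record equal to the guide's source gene
    self <- !is.na(src) & src == names(refs)[[k]]
    cnt[self, ] <- 0L
    if (unit == "sites") {
      ngg <- ngg + cnt[, 1L]
      nag <- nag + cnt[, 2L]
    } else {
      ngg <- ngg + as.integer(cnt[, 1L] > 0L)
      nag <- nag + as.integer(cnt[, 1L] == 0L & cnt[, 2L] > 0L)
    }
    if (isTRUE(audit) && length(res$hits$guide_idx)) {
      h <- res$hits
      keep <- !self[h$guide_idx]
      if (any(keep))
        audit_rows[[length(audit_rows) + 1L]] <- data.frame(
          guide_id = guides$guide_id[h$guide_idx[keep]],
          ref_id = names(refs)[[k]],
          strand = sites$strand[h$site_idx[keep]],
          start = sites$start[h$site_idx[keep]],
          end = sites$end[h$site_idx[keep]],
          pam_class = sites$pam_class[h$site_idx[keep]],
          total_edits = h$total_edits[keep],
          seed_edits = h$seed_edits[keep],
          stringsAsFactors = FALSE)
    }
  }

  cutoff <- if (is.null(cutoff_fraction)) criteria$rank_cutoff
            else as.integer(floor(cutoff_fraction * length(refs)))
  rep_df <- data.frame(guide_id = guides$guide_id,
                       protospacer = guides$protospacer,
                       n_offtargets_ngg = ngg, n_offtargets_nag = nag,
                       n_offtargets = ngg + nag, stringsAsFactors = FALSE)
  rep_df <- rep_df[order(rep_df$n_offtargets, rep_df$guide_id), ,
                   drop = FALSE]
  rep_df$rank <- seq_len(nrow(rep_df))
  rep_df$passes_cutoff <- rep_df$n_offtargets < cutoff
  rownames(rep_df) <- NULL
  if (isTRUE(audit))
    attr(rep_df, "audit") <- if (length(audit_rows))
      do.call(rbind, audit_rows)
    else data.frame(guide_id = character(0), ref_id = character(0),
                    strand = character(0), start = integer(0),
                    end = integer(0), pam_class = character(0),
                    total_edits = integer(0), seed_edits = integer(0))
  rep_df
}
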