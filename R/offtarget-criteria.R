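#' Off-target classification criteria
#'
#' Bundles the thresholds used to decide whether a reference protospacer is
#' a potential Cas9 off-target of a guide: the seed length (guide positions
#' counted from the PAM), the edit ceilings for NGG and NAG PAM classes, the
#' anchored last-base rule (no mismatch/gap at the PAM-adjacent guide base),
#' the specificity ranking cutoff and the identity floor the lossless k-mer
#' prefilter must respect.
#'
#' The defaults encode the relaxed Cas9 recognition rules used for guide
#' specificity screening against a 16S reference set: an NGG site qualifies
#' with fewer than 4 mismatch/deletion/insertion (M/D/I) edits, or exactly 4
#' all outside the 12-bp seed; an NAG site with fewer than 2, or exactly 2
#' outside the seed; and in all cases the PAM-adjacent guide base must match.
#'
#' @param seed_len Seed-region length, guide positions 1..seed_len from the
#'   PAM (default 12).
#' @param max_edits_ngg Edit ceiling for NGG sites (default 4).
#' @param max_edits_nag Edit ceiling for NAG sites (default 2; must not
#'   exceed `max_edits_ngg`).
#' @param anchored_last_base Require a positional match at the PAM-adjacent
#'   guide base (default TRUE).
#' @param rank_cutoff Guides with fewer off-targets than this pass the
#'   specificity cutoff (default 3300; see `cutoff_fraction` in
#'   [count_offtargets()] for the fractional form).
#' @param prefilter_identity Pairwise identity floor the candidate prefilter
#'   must never violate (default 0.6).
#' @param prefilter_word Exact-k-mer word length used by the prefilter
#'   (default 4; capped internally so the prefilter stays lossless).
#' @return An object of class `offtarget_criteria`.
#' @export
offtarget_criteria <- function(seed_len = 12L, max_edits_ngg = 4L,
                               max_edits_nag = 2L, anchored_last_base = TRUE,
                               rank_cutoff = 3300L,
                               prefilter_identity = 0.6,
                               prefilter_word = 4L) {
  seed_len <- as.integer(seed_len)
  max_edits_ngg <- as.integer(max_edits_ngg)
  max_edits_nag <- as.integer(max_edits_nag)
  if (seed_len <= 0L || seed_len >= 20L)
    stop("seed_len must be in (0, 20)", call. = FALSE)
  if (max_edits_nag > max_edits_ngg)
    stop("max_edits_nag must not exceed max_edits_ngg", call. = FALSE)
  if (prefilter_identity < 0 || prefilter_identity > 1)
    stop("prefilter_identity must be in [0, 1]", call. = FALSE)
  stopifnot_scalar_flag(anchored_last_base, "anchored_last_base")
  structure(list(seed_len = seed_len,
                 max_edits_ngg = max_edits_ngg,
                 max_edits_nag = max_edits_nag,
                 anchored_last_base = anchored_last_base,
                 rank_cutoff = as.integer(rank_cutoff),
                 prefilter_identity = prefilter_identity,
                 prefilter_word = as.integer(prefilter_word)),
            class = "offtarget_criteria")
}

#' @export
print.offtarget_criteria <- function(x, ...) {
  cat("Off-target criteria:\n",
      sprintf("  seed region      : %d bp next to the PAM\n", x$seed_len),
      sprintf("  NGG edit ceiling : <%d M/D/I, or =%d all outside seed\n",
              x$max_edits_ngg, x$max_edits_ngg),
      sprintf("  NAG edit ceiling : <%d M/D/I, or =%d all outside seed\n",
              x$max_edits_nag, x$max_edits_nag),
      sprintf("  anchored base    : %s\n",
              if (x$anchored_last_base)
                "PAM-adjacent guide base must match" else "not enforced"),
      sprintf("  rank cutoff      : %d off-targets\n", x$rank_cutoff),
      sep = "")
  invisible(x)
}

# Largest prefilter word length that is still lossless for this edit
# ceiling: <= e edits leave <= e+1 untouched guide segments totalling
# >= L - e bases, so some exact shared k-mer of length
# ceil((L - e) / (e + 1)) survives in any qualifying site.
lossless_word <- function(guide_len, criteria) {
  e <- max(criteria$max_edits_ngg, criteria$max_edits_nag)
  w_safe <- ceiling((guide_len - e) / (e + 1))
  max(1L, min(criteria$prefilter_word, as.integer(w_safe)))
}
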