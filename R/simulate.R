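#' Specify a planted off-target site for fixture generation
#'
#' Describes one near-match of a guide to embed in a synthetic reference
#' set: the guide, how many substitution edits to apply and at which guide
#' positions (1 = PAM-adjacent), the PAM class of the planted site, and the
#' off-target call the site is expected to receive.  If `expected_call` is
#' omitted it is derived from the classification criteria (an edit at
#' position 1 breaks the anchored rule; otherwise the site qualifies when
#' `n_edits` is under the PAM-class ceiling, or at the ceiling with every
#' edited position outside the seed).
#'
#' @param guide 20-nt ACGT guide string (PAM-proximal base last).
#' @param n_edits Number of substitution edits (0..20).
#' @param edit_positions Integer set of guide positions to edit, size
#'   `n_edits`; required when `n_edits > 0`.
#' @param pam_class `"NGG"` or `"NAG"`.
#' @param expected_call Expected off-target call; an edit at position 1
#'   combined with `expected_call = TRUE` is a specification error (the
#'   anchored rule makes it impossible).
#' @param criteria Criteria used to derive the default `expected_call`.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(guide, n_edits, edit_positions = integer(0),
                       pam_class = c("NGG", "NAG"), expected_call = NULL,
                       criteria = offtarget_criteria()) {
  pam_class <- match.arg(pam_class)
  guide <- toupper(guide)
  if (nchar(guide) != 20L || !is_acgt(guide))
    stop("guide must be a 20-nt ACGT string", call. = FALSE)
  edit_positions <- sort(unique(as.integer(edit_positions)))
  if (length(edit_positions) != n_edits)
    stop("edit_positions must contain exactly n_edits distinct positions",
         call. = FALSE)
  if (length(edit_positions) &&
      (min(edit_positions) < 1L || max(edit_positions) > 20L))
    stop("edit positions must lie in 1..20", call. = FALSE)
  derived <- {
    ceiling <- if (pam_class == "NGG") criteria$max_edits_ngg
               else criteria$max_edits_nag
    anch_ok <- !(1L %in% edit_positions) || !criteria$anchored_last_base
    anch_ok && (n_edits < ceiling ||
                  (n_edits == ceiling &&
                     all(edit_positions > criteria$seed_len)))
  }
  if (is.null(expected_call)) expected_call <- derived
  if (isTRUE(expected_call) && 1L %in% edit_positions &&
      criteria$anchored_last_base)
    stop(paste("an edit at position 1 cannot yield an off-target call:",
               "the anchored last-base rule forbids it"), call. = FALSE)
  structure(list(guide = guide, n_edits = as.integer(n_edits),
                 edit_positions = edit_positions, pam_class = pam_class,
                 expected_call = isTRUE(expected_call)),
            class = "plant_spec")
}

# Apply a plant_spec's substitutions: guide position q (1 = PAM-adjacent)
# is string index 21 - q.
apply_plant_edits <- function(spec) {
  cs <- strsplit(spec$guide, "", fixed = TRUE)[[1L]]
  for (q in spec$edit_positions) {
    i <- 21L - q
    cs[i] <- sample(setdiff(DNA_BASES, cs[i]), 1L)
  }
  paste(cs, collapse = "")
}

# Draw a planted site realizing EXACTLY the specified edits under the
# alignment model: random substitutions can occasionally admit a cheaper
# indel interpretation (or a co-optimal alignment with fewer seed edits),
# so base choices are redrawn until the anchored alignment statistics equal
# the naive per-position counts.  Deterministic under the caller's seed.
draw_planted_site <- function(spec, criteria) {
  pos <- spec$edit_positions
  want_total <- sum(pos >= 2L)              # position 1 is the anchor column
  want_seed <- sum(pos >= 2L & pos <= criteria$seed_len)
  want_anch <- !(1L %in% pos)
  for (try in 1:100) {
    site <- apply_plant_edits(spec)
    st <- anchored_edit_stats(spec$guide, site, criteria$seed_len)
    if (st$total_edits == want_total && st$seed_edits == want_seed &&
        st$anchored_match == want_anch)
      return(site)
  }
  stop(sprintf(
    "could not realize a planted site with exactly %d edits at positions %s",
    spec$n_edits, paste(pos, collapse = ",")), call. = FALSE)
}

#' Generate a synthetic 16S-like reference set with planted off-targets
#'
#' Builds `n_seqs` pseudorandom ACGT sequences and, for each [plant_spec()],
#' embeds in one designated sequence (plant i goes into sequence i) a
#' candidate site derived from the guide by applying exactly the specified
#' substitutions, immediately followed by a PAM of the specified class
#' (`NGG`/`NAG` with a random N).  Fully reproducible from `seed`.
#'
#' Substituted bases are redrawn (deterministically under `seed`) until the
#' planted site's anchored alignment statistics equal the per-position edit
#' counts, so a site specified with, say, 5 edits can never be reached by a
#' cheaper indel interpretation.
#'
#' @param n_seqs Number of reference sequences (>= number of plants).
#' @param seq_len Length of each sequence (>= 23).
#' @param plants List of [plant_spec()] objects.
#' @param seed Integer seed.
#' @param criteria Criteria whose seed length governs the planted-site
#'   statistics.
#' @return A list with `sequences` (a named [Biostrings::DNAStringSet],
#'   ids `ref1..refN`) and `plants`, a data.frame of embedding coordinates
#'   (`ref_id`, `strand`, `start`, `end` for the planted 20-mer, 0-based
#'   half-open; `pam_class`, `site`, `n_edits`, `expected_call`).
#' @export
generate_reference_db <- function(n_seqs, seq_len, plants = list(), seed,
                                  criteria = offtarget_criteria()) {
  if (seq_len < 23L) stop("seq_len must be >= 23", call. = FALSE)
  if (length(plants) > n_seqs)
    stop("more plants than sequences", call. = FALSE)
  if (!all(vapply(plants, inherits, logical(1L), "plant_spec")))
    stop("plants must be a list of plant_spec objects", call. = FALSE)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_seqs), function(i)
      paste(sample(DNA_BASES, seq_len, replace = TRUE), collapse = ""),
      character(1L))
    names(seqs) <- paste0("ref", seq_len(n_seqs))
    rows <- lapply(seq_along(plants), function(i) {
      sp <- plants[[i]]
      site <- draw_planted_site(sp, criteria)
      pam <- paste0(sample(DNA_BASES, 1L),
                    if (sp$pam_class == "NGG") "GG" else "AG")
      start0 <- sample.int(seq_len - 23L + 1L, 1L) - 1L
      s <- seqs[[i]]
      substr(s, start0 + 1L, start0 + 23L) <- paste0(site, pam)
      seqs[[i]] <<- s
      data.frame(ref_id = names(seqs)[[i]], strand = "+", start = start0,
                 end = start0 + 20L, pam_class = sp$pam_class, site = site,
                 n_edits = sp$n_edits, expected_call = sp$expected_call,
                 stringsAsFactors = FALSE)
    })
    dna <- Biostrings::DNAStringSet(unname(seqs))
    names(dna) <- names(seqs)
    list(sequences = dna,
         plants = if (length(rows)) do.call(rbind, rows)
                  else data.frame(ref_id = character(0), strand = character(0),
                                  start = integer(0), end = integer(0),
                                  pam_class = character(0),
                                  site = character(0), n_edits = integer(0),
                                  expected_call = logical(0)))
  })
}

#' Build and validate an amplicon community profile
#'
#' @param member_id Character vector of member names.
#' @param fraction Non-negative fractions summing to 1 (tolerance 1e-9).
#' @param is_host Logical vector marking host-derived members.
#' @return A data.frame of class `community_profile`.
#' @export
community_profile <- function(member_id, fraction, is_host) {
  if (length(member_id) < 1L) stop("at least one member", call. = FALSE)
  if (length(fraction) != length(member_id) ||
      length(is_host) != length(member_id))
    stop("member_id, fraction and is_host must have equal length",
         call. = FALSE)
  if (any(fraction < 0)) stop("fractions must be non-negative",
                              call. = FALSE)
  if (abs(sum(fraction) - 1) > 1e-9)
    stop("fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  if (anyDuplicated(member_id)) stop("duplicated member ids", call. = FALSE)
  structure(data.frame(member_id = member_id, fraction = fraction,
                       is_host = is_host, stringsAsFactors = FALSE),
            class = c("community_profile", "data.frame"))
}

#' Cas9 digestion of an amplicon community (expected-value model)
#'
#' Reweights member fractions after per-member cleavage: with cleavage
#' efficiency `e_i` (the fraction of member i's amplicons cut, so removed
#' from re-amplification), post-digestion fractions are
#' `f_i' = f_i (1 - e_i) / sum_j f_j (1 - e_j)`.  The model is
#' deterministic at the fraction level; sampling noise enters only through
#' [sample_counts()].  For a two-member community with host fraction `h`
#' and host efficiency `e`, the host fraction after digestion is exactly
#' `h (1 - e) / (1 - h e)`.
#'
#' @param profile A [community_profile()].
#' @param efficiency Named numeric vector in `[0, 1]`, member_id ->
#'   cleavage efficiency; members not named default to 0 (uncut).
#' @return A new `community_profile` with updated fractions.
#' @details If every molecule is cleaved (total survival 0) the community
#'   is completely depleted and an error is raised.
#' @examples
#' p <- community_profile(c("host", "bact"), c(0.999, 0.001),
#'                        c(TRUE, FALSE))
#' digest_community(p, c(host = 1))
#' @export
digest_community <- function(profile, efficiency = numeric(0)) {
  if (!inherits(profile, "community_profile"))
    stop("profile must be a community_profile", call. = FALSE)
  e <- rep(0, nrow(profile))
  if (length(efficiency)) {
    if (is.null(names(efficiency)))
      stop("efficiency must be named by member_id", call. = FALSE)
    if (any(efficiency < 0 | efficiency > 1))
      stop("cleavage efficiencies must lie in [0, 1]", call. = FALSE)
    unknown <- setdiff(names(efficiency), profile$member_id)
    if (length(unknown))
      stop(sprintf("efficiency names not in profile: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    i <- match(names(efficiency), profile$member_id)
    e[i] <- efficiency
  }
  surv <- profile$fraction * (1 - e)
  denom <- sum(surv)
  if (denom <= 0)
    stop("complete depletion: no amplicon survives digestion",
         call. = FALSE)
  community_profile(profile$member_id, surv / denom, profile$is_host)
}

#' Multinomial read sampling from a community profile
#'
#' Emulates a rarefied OTU count table: a single multinomial draw of
#' `depth` reads from the member fractions, reproducible from `seed`.
#'
#' @param profile A [community_profile()].
#' @param depth Number of reads (>= 1).
#' @param seed Integer seed.
#' @return Named integer vector of counts summing to `depth`.
#' @export
sample_counts <- function(profile, depth, seed) {
  if (!inherits(profile, "community_profile"))
    stop("profile must be a community_profile", call. = FALSE)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  with_seed(seed, {
    cnt <- as.integer(stats::rmultinom(1L, size = as.integer(depth),
                                       prob = profile$fraction))
    names(cnt) <- profile$member_id
    cnt
  })
}
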