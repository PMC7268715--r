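crit <- offtarget_criteria()

test_that("candidate site extraction matches constructed and brute-force scans", {
  expect_equal(
    extract_candidate_sites(paste0(strrep("C", 20), "TGG"),
                            both_strands = FALSE)$pam_class, "NGG")
  expect_equal(
    extract_candidate_sites(paste0(strrep("C", 20), "TAG"),
                            both_strands = FALSE)$pam_class, "NAG")
  withr::with_seed(201, refs <- random_dna(100, 300))
  names(refs) <- paste0("r", seq_along(refs))
  sites <- extract_candidate_sites(refs)
  brute <- sum(vapply(refs, function(s)
    brute_guide_count(s, 20L, "NGG") + brute_guide_count(s, 20L, "NAG"),
    integer(1)))
  expect_equal(nrow(sites), brute)
  expect_true(all(sites$end - sites$start == 20L))
})

test_that("anchored alignment reproduces constructed edit patterns", {
  g <- "ACGTACGTACGTACGTACGT"
  id <- align_guide_candidate(g, g, crit)
  expect_equal(unlist(id), c(total_edits = 0, seed_edits = 0,
                             anchored_match = 1))
  # single substitution at guide position 15 from the PAM (string index 6)
  c15 <- g; substr(c15, 6, 6) <- "T"
  a <- align_guide_candidate(g, c15, crit)
  expect_equal(a$total_edits, 1L)
  expect_equal(a$seed_edits, 0L)
  expect_true(a$anchored_match)
  # substitution inside the seed (position 5 from PAM, string index 16)
  c5 <- g; substr(c5, 16, 16) <- "C"
  a5 <- align_guide_candidate(g, c5, crit)
  expect_equal(a5$total_edits, 1L)
  expect_equal(a5$seed_edits, 1L)
  # substitution at the PAM-adjacent base breaks the anchor, adds no edit
  c1 <- g; substr(c1, 20, 20) <- "A"
  a1 <- align_guide_candidate(g, c1, crit)
  expect_false(a1$anchored_match)
  expect_equal(a1$total_edits, 0L)
})

test_that("total edits agree with the textbook DP oracle on random pairs", {
  withr::with_seed(202, {
    gs <- random_dna(40, 20)
    cs <- random_dna(25, 20)
  })
  for (g in gs) {
    got <- align_guide_candidate(g, cs, crit)$total_edits
    want <- vapply(cs, function(cc) oracle_total_edits(g, cc), integer(1))
    expect_equal(got, unname(want))
  }
})

test_that("seed edits are minimal over co-optimal alignments", {
  # exhaustive-enumeration oracle is exponential: use short strings
  withr::with_seed(203, {
    for (rep in 1:150) {
      L <- sample(4:9, 1)
      seed_len <- sample(seq_len(L - 1), 1)
      g <- random_dna(1, L)
      cc <- random_dna(1, L)
      got <- anchored_edit_stats(g, cc, seed_len)
      expect_equal(got$total_edits, oracle_total_edits(g, cc),
                   info = paste(g, cc))
      expect_equal(got$seed_edits, oracle_seed_edits(g, cc, seed_len),
                   info = paste(g, cc, seed_len))
      expect_lte(got$seed_edits, got$total_edits)
    }
  })
})

test_that("classification implements the NGG/NAG seed-region criteria", {
  mk <- function(total, seed, anch = TRUE)
    data.frame(total_edits = total, seed_edits = seed,
               anchored_match = anch)
  # the eight canonical cases
  expect_true(classify_offtarget(mk(3, 3), "NGG", crit)$is_offtarget)
  expect_true(classify_offtarget(mk(4, 0), "NGG", crit)$is_offtarget)
  expect_false(classify_offtarget(mk(4, 1), "NGG", crit)$is_offtarget)
  expect_true(classify_offtarget(mk(1, 1), "NAG", crit)$is_offtarget)
  expect_true(classify_offtarget(mk(2, 0), "NAG", crit)$is_offtarget)
  expect_false(classify_offtarget(mk(2, 1), "NAG", crit)$is_offtarget)
  expect_false(classify_offtarget(mk(0, 0, FALSE), "NGG", crit)$is_offtarget)
  expect_true(classify_offtarget(mk(0, 0), "NGG", crit)$is_offtarget)
  # rule labels
  expect_equal(classify_offtarget(mk(4, 0), "NGG", crit)$rule_fired,
               "at_threshold_outside_seed")
  expect_equal(classify_offtarget(mk(0, 0, FALSE), "NGG", crit)$rule_fired,
               "anchored_fail")
  expect_equal(classify_offtarget(mk(5, 0), "NGG", crit)$rule_fired,
               "rejected")
})

test_that("prefilter is lossless with respect to the final call", {
  withr::with_seed(204, {
    refs <- random_dna(80, 200)
    names(refs) <- paste0("r", seq_along(refs))
    g <- random_dna(1, 20)
  })
  sites <- extract_candidate_sites(refs)
  kept <- prefilter_candidates(g, sites, crit)
  expect_true(nrow(kept) <= nrow(sites))
  # a site identical to the guide passes
  self_site <- sites[1, ]; self_site$protospacer <- g
  expect_equal(nrow(prefilter_candidates(g, self_site, crit)), 1L)
  # no dropped site is an off-target
  dropped <- sites[!rownames(sites) %in% rownames(kept), ]
  if (nrow(dropped)) {
    aln <- align_guide_candidate(g, dropped$protospacer, crit)
    calls <- classify_offtarget(aln, dropped$pam_class, crit)
    expect_false(any(calls$is_offtarget))
  }
})

test_that("planted near-match sites always pass the prefilter", {
  withr::with_seed(205, {
    for (rep in 1:25) {
      g <- random_dna(1, 20)
      pos <- sample(2:20, 4)
      sp <- plant_spec(g, 4, pos, "NGG")
      db <- generate_reference_db(3, 120, list(sp), seed = rep)
      sites <- extract_candidate_sites(as.character(db$sequences))
      kept <- prefilter_candidates(g, sites, crit)
      expect_true(db$plants$site %in% kept$protospacer)
    }
  })
})

test_that("off-target counts recover planted sites and rank monotonically", {
  withr::with_seed(206, {
    g_hit <- random_dna(1, 20)
    g_miss <- random_dna(1, 20)
  })
  k <- 5L
  plants <- replicate(k, plant_spec(g_hit, 2, c(15, 18), "NGG"),
                      simplify = FALSE)
  db <- generate_reference_db(50, 150, plants, seed = 207)
  guides <- data.frame(guide_id = c("hit", "miss"),
                       source_id = NA_character_,
                       protospacer = c(g_hit, g_miss))
  rep_df <- count_offtargets(guides, db$sequences, crit)
  expect_equal(rep_df$n_offtargets[rep_df$guide_id == "hit"], k)
  expect_equal(rep_df$n_offtargets[rep_df$guide_id == "miss"], 0L)
  expect_lt(rep_df$rank[rep_df$guide_id == "miss"],
            rep_df$rank[rep_df$guide_id == "hit"])
  expect_equal(rep_df$n_offtargets,
               rep_df$n_offtargets_ngg + rep_df$n_offtargets_nag)
  # empty reference: all-zero reports
  rep0 <- count_offtargets(guides, character(0), crit)
  expect_true(all(rep0$n_offtargets == 0L))
  # empty guide list
  expect_equal(nrow(count_offtargets(guides[0, ], db$sequences, crit)), 0L)
})

test_that("prefiltered counting equals the exhaustive all-pairs oracle", {
  withr::with_seed(208, {
    for (rep in 1:3) {
      refs <- random_dna(60, 150)
      names(refs) <- paste0("r", seq_along(refs))
      guides <- data.frame(guide_id = paste0("g", 1:8),
                           source_id = NA_character_,
                           protospacer = random_dna(8, 20))
      # plant a couple of near-matches so counts are non-trivial
      substr(refs[1], 11, 33) <- paste0(guides$protospacer[1], "TGG")
      substr(refs[2], 51, 73) <- paste0(guides$protospacer[2], "CAG")
      want <- oracle_count_offtargets(guides, refs, crit)
      got <- count_offtargets(guides, refs, crit)
      got <- got[match(guides$guide_id, got$guide_id), ]
      expect_equal(got$n_offtargets_ngg, unname(want["ngg", ]))
      expect_equal(got$n_offtargets_nag, unname(want["nag", ]))
      # and without the prefilter: bitwise-identical
      got2 <- count_offtargets(guides, refs, crit, prefilter = FALSE)
      expect_identical(got, got2[match(guides$guide_id, got2$guide_id), ])
      # site-unit counting agrees with its oracle too
      want_s <- oracle_count_offtargets(guides, refs, crit, unit = "sites")
      got_s <- count_offtargets(guides, refs, crit, unit = "sites")
      got_s <- got_s[match(guides$guide_id, got_s$guide_id), ]
      expect_equal(got_s$n_offtargets_ngg, unname(want_s["ngg", ]))
      expect_equal(got_s$n_offtargets_nag, unname(want_s["nag", ]))
    }
  })
})

test_that("reports are invariant to reference strand orientation", {
  withr::with_seed(209, {
    refs <- random_dna(40, 150)
    names(refs) <- paste0("r", seq_along(refs))
    guides <- data.frame(guide_id = paste0("g", 1:5),
                         source_id = NA_character_,
                         protospacer = random_dna(5, 20))
  })
  substr(refs[3], 21, 43) <- paste0(guides$protospacer[1], "AGG")
  r1 <- count_offtargets(guides, refs, crit)
  rc <- reverse_complement(refs)
  names(rc) <- names(refs)
  r2 <- count_offtargets(guides, rc, crit)
  expect_identical(r1, r2)
})

test_that("counts are monotone in edit ceilings and seed length", {
  withr::with_seed(210, {
    refs <- random_dna(40, 150)
    names(refs) <- paste0("r", seq_along(refs))
    guides <- data.frame(guide_id = paste0("g", 1:5),
                         source_id = NA_character_,
                         protospacer = random_dna(5, 20))
  })
  substr(refs[1], 11, 33) <- paste0(guides$protospacer[1], "TGG")
  base <- count_offtargets(guides, refs, crit, unit = "sites")
  looser <- count_offtargets(guides, refs,
                             offtarget_criteria(max_edits_ngg = 5,
                                                max_edits_nag = 3),
                             unit = "sites")
  shorter_seed <- count_offtargets(guides, refs,
                                   offtarget_criteria(seed_len = 6),
                                   unit = "sites")
  ord <- function(x) x[match(guides$guide_id, x$guide_id), "n_offtargets"]
  expect_true(all(ord(looser) >= ord(base)))
  expect_true(all(ord(shorter_seed) >= ord(base)))
})

test_that("reference exclusion and self-hits are honoured", {
  withr::with_seed(211, g <- random_dna(1, 20))
  refs <- c(host = paste0(strrep("T", 30), g, "AGG", strrep("T", 30)),
            other = paste0(strrep("C", 30), g, "TGG", strrep("C", 30)))
  guides <- data.frame(guide_id = "g1", source_id = "host",
                       protospacer = g)
  r_all <- count_offtargets(guides, refs)
  expect_equal(r_all$n_offtargets, 1L)  # host record skipped as self
  r_ex <- count_offtargets(guides, refs, exclude_ref_ids = "other")
  expect_equal(r_ex$n_offtargets, 0L)
  # fractional cutoff: floor(frac * post-exclusion reference count)
  r_frac <- count_offtargets(guides, refs, cutoff_fraction = 0.5)
  expect_false(r_frac$passes_cutoff)  # cutoff = floor(0.5*2) = 1, 1 < 1 FALSE
})

test_that("audit trail records qualifying sites with their coordinates", {
  withr::with_seed(212, g <- random_dna(1, 20))
  refs <- c(a = paste0(strrep("T", 10), g, "AGG", strrep("T", 10)))
  guides <- data.frame(guide_id = "g1", source_id = NA_character_,
                       protospacer = g)
  rep_df <- count_offtargets(guides, refs, audit = TRUE)
  aud <- attr(rep_df, "audit")
  expect_equal(nrow(aud), 1L)
  expect_equal(aud$ref_id, "a")
  expect_equal(c(aud$start, aud$end), c(10L, 30L))
  expect_equal(aud$total_edits, 0L)
  expect_equal(aud$pam_class, "NGG")
})
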