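# Synthetic organelle/bacterial 16S template generator.
#
# These are NOT real gene sequences: they are seeded random backgrounds with
# universal-primer annealing sites planted at canonical 16S coordinates, so
# that the amplicon geometry of a plant-host system can be exercised without
# shipping reference accessions.  The planted geometry encodes the study
# conditions the simulator models: the 799F-1193R pair amplifies the
# mitochondrial but not the plastid gene, and the mitochondrial 799F-1193R
# product is 84 bp longer than the bacterial one.

# 1-based plus-strand footprint starts per template; reverse primers are
# planted as their reverse complement ending at the stated position.
synthetic_site_plan <- function() {
  list(
    mt16S_synthetic = list(
      len = 1560L,
      fwd = c("515F" = 515L, "799F" = 781L),
      rev_end = c("806R" = 834L, "1193R" = 1276L)),
    cp16S_synthetic = list(
      len = 1490L,
      fwd = c("27F" = 8L, "515F" = 515L, "1114F" = 1114L),
      rev_end = c("338R" = 357L, "806R" = 826L, "1392R" = 1392L)),
    bact16S_synthetic = list(
      len = 1450L,
      fwd = c("27F" = 8L, "515F" = 515L, "799F" = 781L, "1114F" = 1114L),
      rev_end = c("338R" = 357L, "806R" = 826L, "1193R" = 1192L,
                  "1392R" = 1392L)))
}

# Deterministically concretize a degenerate primer: each IUPAC code becomes
# one of its bases (seeded draw).
concretize <- function(s) {
  cs <- strsplit(s, "", fixed = TRUE)[[1L]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  paste(vapply(cs, function(b) {
    opts <- sets[[b]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L)), collapse = "")
}

#' Synthetic 16S rRNA gene templates with planted primer sites
#'
#' Generates three ~1.5-kb synthetic templates standing in for a host
#' mitochondrial 16S gene, a host plastid 16S gene and a bacterial 16S
#' gene.  Each is a seeded random ACGT background with concrete instances
#' of the universal primers planted at canonical coordinates.  The planted
#' geometry models the host-depletion design problem: 27F-338R and
#' 1114F-1392R amplify only the plastid template, 799F-1193R amplifies only
#' the mitochondrial template, 515F-806R amplifies both organelles, and the
#' mitochondrial 799F-1193R product is 84 bp longer than the bacterial one.
#' These are synthetic stand-ins, not the real organelle genes; guide
#' counts and amplicon contents computed from them characterise the
#' generator, not any genome.
#'
#' @param seed Integer seed (default 20).
#' @param primers Primer table (default: the bundled universal primer
#'   config).
#' @return A list with `templates` (named [Biostrings::DNAStringSet]:
#'   `mt16S_synthetic`, `cp16S_synthetic`, `bact16S_synthetic`), `primers`
#'   (the primer table used) and `plan` (the planted footprints).
#' @export
synthetic_16s_templates <- function(seed = 20L, primers = NULL) {
  if (is.null(primers))
    primers <- read_primer_config(
      system.file("extdata", "universal_primers.tsv", package = "cas16s"))
  plan <- synthetic_site_plan()
  with_seed(seed, {
    out <- lapply(plan, function(pl) {
      s <- paste(sample(DNA_BASES, pl$len, replace = TRUE), collapse = "")
      for (nm in names(pl$fwd)) {
        p <- concretize(get_primer(primers, nm)$sequence)
        start <- pl$fwd[[nm]]
        substr(s, start, start + nchar(p) - 1L) <- p
      }
      for (nm in names(pl$rev_end)) {
        p <- reverse_complement(concretize(get_primer(primers, nm)$sequence))
        end <- pl$rev_end[[nm]]
        substr(s, end - nchar(p) + 1L, end) <- p
      }
      s
    })
    dna <- Biostrings::DNAStringSet(unlist(out, use.names = FALSE))
    names(dna) <- names(plan)
    list(templates = dna, primers = primers, plan = plan)
  })
}
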