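#' Assemble and validate a run configuration
#'
#' @param host_fasta Path to the host organelle 16S gene FASTA.
#' @param reference_fasta Path to the prokaryotic 16S reference FASTA.
#' @param output_dir Output directory (created if absent).
#' @param primer_config Optional path to a primer config
#'   ([read_primer_config()]); required when `fwd_primer`/`rev_primer` are
#'   set.
#' @param fwd_primer,rev_primer Optional primer names for the amplicon
#'   stage; when omitted the PCR/compatibility stages are skipped.
#' @param criteria An [offtarget_criteria()] object.
#' @param exclusions Optional path to a text file of reference ids to
#'   exclude (one per line, e.g. chloroplast records when scoring plastid
#'   guides).
#' @param seed Integer seed recorded in the manifest.
#' @param unit Off-target counting unit (see [count_offtargets()]).
#' @param cutoff_fraction Optional fractional ranking cutoff.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(host_fasta, reference_fasta, output_dir,
                       primer_config = NULL, fwd_primer = NULL,
                       rev_primer = NULL, criteria = offtarget_criteria(),
                       exclusions = NULL, seed = 1L,
                       unit = c("sequences", "sites"),
                       cutoff_fraction = NULL) {
  unit <- match.arg(unit)
  for (p in c(host_fasta = host_fasta, reference_fasta = reference_fasta,
              primer_config = primer_config, exclusions = exclusions)) {
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input path does not exist: %s", p), call. = FALSE)
  }
  if ((!is.null(fwd_primer) || !is.null(rev_primer)) &&
      is.null(primer_config))
    stop("fwd_primer/rev_primer require a primer_config", call. = FALSE)
  if (!inherits(criteria, "offtarget_criteria"))
    stop("criteria must be an offtarget_criteria object", call. = FALSE)
  structure(list(host_fasta = host_fasta,
                 reference_fasta = reference_fasta,
                 primer_config = primer_config, fwd_primer = fwd_primer,
                 rev_primer = rev_primer, criteria = criteria,
                 exclusions = exclusions, output_dir = output_dir,
                 seed = as.integer(seed), unit = unit,
                 cutoff_fraction = cutoff_fraction),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Plain-text structured configuration with the fields of [run_config()];
#' `criteria` may be a mapping of [offtarget_criteria()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  crit <- if (is.null(y$criteria)) offtarget_criteria()
          else do.call(offtarget_criteria, y$criteria)
  run_config(host_fasta = y$host_fasta,
             reference_fasta = y$reference_fasta,
             output_dir = y$output_dir,
             primer_config = y$primer_config,
             fwd_primer = y$fwd_primer, rev_primer = y$rev_primer,
             criteria = crit, exclusions = y$exclusions,
             seed = if (is.null(y$seed)) 1L else y$seed,
             unit = if (is.null(y$unit)) "sequences" else y$unit,
             cutoff_fraction = y$cutoff_fraction)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the end-to-end guide design workflow
#'
#' Wires the stages together: enumerate host guides, derive amplicons for
#' the chosen primer pair, intersect guides with amplicons, scan the
#' reference set for off-targets and rank guide specificity.  Writes
#' `guides.tsv`, `amplicons.tsv`, `compatible_guides.tsv`,
#' `specificity.tsv` and a `manifest.json` (package version, configuration
#' echo, input checksums, seed) to the output directory.  The manifest
#' carries no timestamp, so identical configurations produce byte-identical
#' outputs.
#'
#' @param config A `run_config` object (or path to a YAML config).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a named list of the output file paths.
#' @details A failure in any stage raises an error naming the stage.
#' @export
run_design_workflow <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    stop("config must be a run_config object or a YAML path", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  host <- stage("load-host", read_fasta(config$host_fasta))
  guides <- stage("design", enumerate_guides(host))
  out$guides <- write_tsv(guides, file.path(config$output_dir, "guides.tsv"))

  compatible <- guides
  if (!is.null(config$fwd_primer) && !is.null(config$rev_primer)) {
    primers <- stage("load-primers", read_primer_config(config$primer_config))
    amps <- stage("pcr", do.call(rbind, lapply(seq_along(host), function(k)
      simulate_amplicon(host[k], get_primer(primers, config$fwd_primer),
                        get_primer(primers, config$rev_primer)))))
    out$amplicons <- write_tsv(
      amps[setdiff(names(amps), "sequence")],
      file.path(config$output_dir, "amplicons.tsv"))
    compatible <- stage("compatible-guides", {
      keep <- do.call(rbind, lapply(seq_len(nrow(amps)), function(i)
        guides_in_amplicon(guides, amps[i, , drop = FALSE])))
      if (is.null(keep)) guides[0, , drop = FALSE]
      else unique(keep)
    })
    out$compatible_guides <- write_tsv(
      compatible, file.path(config$output_dir, "compatible_guides.tsv"))
  }

  refs <- stage("load-reference", read_fasta(config$reference_fasta))
  excl <- if (!is.null(config$exclusions))
    stage("load-exclusions", readLines(config$exclusions, warn = FALSE))
  else character(0)
  report <- stage("scan", count_offtargets(
    guides, refs, criteria = config$criteria, exclude_ref_ids = excl,
    unit = config$unit, cutoff_fraction = config$cutoff_fraction))
  out$specificity <- write_tsv(
    report, file.path(config$output_dir, "specificity.tsv"))

  manifest <- list(
    tool = "cas16s",
    version = as.character(utils::packageVersion("cas16s")),
    seed = config$seed,
    unit = config$unit,
    criteria = unclass(config$criteria),
    inputs = lapply(
      Filter(Negate(is.null),
             list(host_fasta = config$host_fasta,
                  reference_fasta = config$reference_fasta,
                  primer_config = config$primer_config,
                  exclusions = config$exclusions)),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    fwd_primer = config$fwd_primer, rev_primer = config$rev_primer,
    cutoff_fraction = config$cutoff_fraction,
    n_guides = nrow(guides), n_references = length(refs))
  out$manifest <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  say("done")
  invisible(out)
}
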