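#' IUPAC nucleotide alphabet
#'
#' The sixteen IUPAC nucleotide codes handled by the package (after
#' normalization: upper case, no U).
#' @format Character vector.
#' @export
IUPAC_ALPHABET <- names(Biostrings::IUPAC_CODE_MAP)

# 16x16 logical lookup: do the concrete-base sets of two IUPAC codes
# intersect?  Built once at load.
iupac_match_matrix <- local({
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  codes <- names(sets)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes)
    m[a, b] <- length(intersect(sets[[a]], sets[[b]])) > 0L
  m
})

normalize_iupac <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

check_iupac <- function(x, what = "sequence") {
  bad <- regmatches(x, regexpr(sprintf("[^%s]", paste(IUPAC_ALPHABET,
                                                      collapse = "")), x))
  if (length(bad) && any(nzchar(bad)))
    stop(sprintf("illegal character '%s' in %s", bad[nzchar(bad)][1L], what),
         call. = FALSE)
  invisible(x)
}

#' Read a FASTA file of nucleotide sequences
#'
#' Reads a (wrapped or unwrapped, multi-record) FASTA file and normalizes the
#' residues: upper case, `U` converted to `T`, and alignment gap characters
#' (`-`, `.`) stripped with a warning, so that aligned reference
#' distributions can be used directly as unaligned sequence sets.  The record
#' id is the first whitespace-delimited token of the header; the remainder is
#' kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with a
#'   `description` metadata column.  An empty file yields an empty set.
#' @details Malformed input (header-less file, empty record, characters
#'   outside the IUPAC nucleotide alphabet) raises an error naming the
#'   offending record and line.
#' @seealso [write_fasta()]
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some 16S gene", "acgu"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("path must be a single file path", call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) diagnose_fasta(path))
  if (length(raw) == 0L) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = character(0))
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  res <- toupper(as.character(raw))
  n_gap <- sum(nchar(res) - nchar(gsub("[-.]", "", res)))
  if (n_gap > 0L) {
    warning(sprintf(
      "stripped %d alignment gap character(s) ('-', '.') on load", n_gap),
      call. = FALSE)
    res <- gsub("[-.]", "", res)
  }
  res <- normalize_iupac(res)
  for (i in seq_along(res)) {
    if (!nzchar(res[[i]]))
      stop(sprintf("empty record '%s' in %s", ids[[i]], path), call. = FALSE)
    bad <- regmatches(res[[i]],
                      regexpr(sprintf("[^%s]",
                                      paste(IUPAC_ALPHABET, collapse = "")),
                              res[[i]]))
    if (length(bad) && nzchar(bad))
      stop(sprintf(
        "illegal character '%s' in record '%s' (%s, line %d)",
        bad, ids[[i]], path, find_bad_line(path, bad)), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(unname(res))
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

# Best-effort line-level diagnosis used when the fast parser rejects a file.
diagnose_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(Biostrings::BStringSet())
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA: line %d of %s is not a '>' header",
                 nonblank[1L], path), call. = FALSE)
  stop(sprintf("malformed FASTA file: %s", path), call. = FALSE)
}

find_bad_line <- function(path, ch) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(grepl(ch, lines, fixed = TRUE) & !startsWith(lines, ">"))
  if (length(hit)) hit[1L] else NA_integer_
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: ids and descriptions are re-joined into
#' headers, so `read_fasta(write_fasta(x))` round-trips id, description and
#' residues for normalized input.
#'
#' @param x A [Biostrings::DNAStringSet] (as returned by [read_fasta()]) or a
#'   named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    seqs <- as_seq_chr(x)
    desc <- rep("", length(seqs))
    dna <- Biostrings::DNAStringSet(unname(seqs))
    names(dna) <- names(seqs)
  } else {
    dna <- x
    mc <- S4Vectors::mcols(x)
    desc <- if (!is.null(mc) && "description" %in% colnames(mc))
      mc$description else rep("", length(x))
  }
  hdr <- ifelse(nzchar(desc), paste(names(dna), desc), names(dna))
  out <- dna
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Vectorized reverse complement that maps degenerate codes correctly
#' (R to Y, K to M, S to S, W to W, B to V, D to H, N to N).  An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Character vector of the same lengths.
#' @examples
#' reverse_complement(c("ACGT", "RAA"))
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) stop("x must be a character vector", call. = FALSE)
  x <- normalize_iupac(x)
  for (s in x) check_iupac(s)
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' IUPAC-aware base matching
#'
#' Two IUPAC codes match iff their concrete-base sets intersect: exact bases
#' match themselves, `R` (G/A) matches `A`, `N` matches everything.  Used for
#' degenerate primer annealing and PAM-pattern matching.
#'
#' @param template_base,primer_base Character vectors of single IUPAC codes
#'   (recycled to a common length).
#' @return Logical vector.
#' @examples
#' iupac_match(c("A", "C", "G"), c("R", "R", "N"))
#' @export
iupac_match <- function(template_base, primer_base) {
  a <- normalize_iupac(template_base)
  b <- normalize_iupac(primer_base)
  if (any(nchar(a) != 1L) || any(nchar(b) != 1L))
    stop("iupac_match compares single characters", call. = FALSE)
  if (any(!a %in% IUPAC_ALPHABET))
    stop(sprintf("illegal character '%s'", a[!a %in% IUPAC_ALPHABET][1L]),
         call. = FALSE)
  if (any(!b %in% IUPAC_ALPHABET))
    stop(sprintf("illegal character '%s'", b[!b %in% IUPAC_ALPHABET][1L]),
         call. = FALSE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  iupac_match_matrix[cbind(a, b)]
}

#' Read a primer configuration file
#'
#' Primers are supplied in a plain-text tab-separated file with a header line
#' and columns `name`, `sequence`, `orientation` (`forward` or `reverse`).
#' Sequences may use IUPAC degeneracy codes and are normalized on load.
#' No primer sequences are built into the package; an example configuration
#' with the canonical universal 16S primers ships in
#' `system.file("extdata", "universal_primers.tsv", package = "cas16s")`.
#'
#' @param path Path to the primer configuration file.
#' @return A data.frame with columns `name`, `sequence`, `orientation`.
#' @export
read_primer_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(df)))
    stop(sprintf("primer config must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df <- df[need]
  df$sequence <- normalize_iupac(df$sequence)
  for (i in seq_len(nrow(df))) {
    check_iupac(df$sequence[[i]], what = sprintf("primer '%s'", df$name[[i]]))
    if (nchar(df$sequence[[i]]) < 10L)
      stop(sprintf("primer '%s' is shorter than 10 nt", df$name[[i]]),
           call. = FALSE)
  }
  if (!all(df$orientation %in% c("forward", "reverse")))
    stop("primer orientation must be 'forward' or 'reverse'", call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicated primer names in config", call. = FALSE)
  df
}

#' Look up one primer from a primer table
#'
#' @param primers Data frame from [read_primer_config()].
#' @param name Primer name.
#' @return A one-row data.frame.
#' @export
get_primer <- function(primers, name) {
  i <- match(name, primers$name)
  if (is.na(i)) stop(sprintf("primer '%s' not found in config", name),
                     call. = FALSE)
  primers[i, , drop = FALSE]
}
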