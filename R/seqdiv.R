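# Pairwise divergence arithmetic on pre-aligned nucleotide sequences,
# reporting in the "N bp (P.PP%)" style conventional for ITS / 28S D2-D3
# comparisons in cyst-nematode taxonomy. No alignment is computed here;
# inputs must already be aligned (equal length).

SEQ_ALPHABET <- c("A", "C", "G", "T", "U", "N", "-",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

seq_chars <- function(seq, id = "sequence") {
  if (length(seq) != 1L || !is.character(seq)) stop(id, " must be one string")
  ch <- strsplit(toupper(seq), "")[[1]]
  if (length(ch) == 0L) stop("empty alignment (", id, ")")
  bad <- setdiff(unique(ch), SEQ_ALPHABET)
  if (length(bad)) stop(id, " contains invalid symbols: ",
                        paste(bad, collapse = ", "))
  ch
}

#' Pairwise divergence of two aligned sequences
#'
#' Counts differing positions and computes percent identity. Under
#' `"pairwise-delete"` (the default, conventional for "bp difference"
#' reports) any column containing a gap in either sequence is excluded
#' from the comparison. Under `"count-as-diff"` a gap opposite a residue
#' counts as a difference (gap-gap columns are still excluded). N and
#' IUPAC ambiguity codes are compared as exact symbols.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @param gap_policy `"pairwise-delete"` or `"count-as-diff"`.
#' @return An object of class `seq_divergence`: `diffs`, `compared`,
#'   `identity` (percent).
#' @export
#' @examples
#' pairwise_divergence("ACGT", "ACGA")  # 1 diff, identity 75
pairwise_divergence <- function(seq_a, seq_b,
                                gap_policy = c("pairwise-delete",
                                               "count-as-diff")) {
  gap_policy <- match.arg(gap_policy)
  a <- seq_chars(seq_a, "seq_a"); b <- seq_chars(seq_b, "seq_b")
  if (length(a) != length(b))
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)))
  gap_a <- a == "-"; gap_b <- b == "-"
  keep <- if (gap_policy == "pairwise-delete") !(gap_a | gap_b)
          else !(gap_a & gap_b)
  compared <- sum(keep)
  if (compared == 0L) stop("no comparable columns after gap handling")
  diffs <- sum(a[keep] != b[keep])
  structure(list(diffs = diffs, compared = compared,
                 identity = 100 * (compared - diffs) / compared,
                 gap_policy = gap_policy),
            class = "seq_divergence")
}

#' Format a divergence in publication style
#'
#' @param diffs Number of differing positions.
#' @param identity Percent identity.
#' @return A string such as `"8 bp (98.93%)"`.
#' @export
format_divergence <- function(diffs, identity) {
  sprintf("%d bp (%.2f%%)", diffs, identity)
}

#' @export
print.seq_divergence <- function(x, ...) {
  cat(format_divergence(x$diffs, x$identity),
      sprintf("over %d compared positions [%s]\n", x$compared, x$gap_policy))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around `Biostrings::readDNAStringSet()`; requires the
#' Biostrings package. Alternatively pass a named character vector of
#' sequences directly to [divergence_table()].
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_alignment <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA files requires the Biostrings package; ",
         "alternatively pass a named character vector of sequences")
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Divergence of every sequence from a reference
#'
#' @param seqs Named character vector of aligned sequences (equal
#'   lengths) or a path to an aligned FASTA file.
#' @param ref Id of the reference sequence.
#' @param gap_policy Passed to [pairwise_divergence()].
#' @return Data frame with one row per non-reference sequence: id, diffs,
#'   compared, identity, and a formatted `label` ("8 bp (98.93%)" style).
#' @export
divergence_table <- function(seqs, ref,
                             gap_policy = c("pairwise-delete",
                                            "count-as-diff")) {
  gap_policy <- match.arg(gap_policy)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_alignment(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  if (!ref %in% names(seqs)) stop("reference id not found: ", ref)
  others <- setdiff(names(seqs), ref)
  rows <- lapply(others, function(id) {
    d <- pairwise_divergence(seqs[[ref]], seqs[[id]], gap_policy)
    data.frame(id = id, diffs = d$diffs, compared = d$compared,
               identity = d$identity,
               label = format_divergence(d$diffs, d$identity),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
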