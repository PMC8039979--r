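# Seeded generators: synthetic specimens drawn inside a taxon's published
# ranges, and toy alignments with known pairwise differences. These make
# the identification and divergence machinery testable with ground truth
# and no external data.

#' Simulate specimen observations for a taxon
#'
#' Numeric characters are sampled inside the taxon's published interval;
#' categorical characters are copied from the profile. Policies:
#' `"uniform-strict-interior"` draws uniformly on the interval shrunk by
#' 0.1% of its width at each end (guaranteeing strict interiority up to
#' point values), `"truncated-normal"` draws from a normal with mean at
#' the midpoint and sd = width/6 (about 99.7% of the untruncated mass
#' in-range), rejected until inside.
#'
#' @param taxon Taxon name.
#' @param n Number of specimens (>= 1).
#' @param matrix A `cactodera_matrix`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param policy Sampling policy for numeric characters.
#' @param characters Optional character subset; default all characters
#'   recorded (non-unknown) for the taxon.
#' @return List of `specimen_observation` objects.
#' @export
#' @examples
#' m <- load_matrix("cactodera_v1")
#' obs <- simulate_specimens("C. tianzhuensis", 3, m, seed = 1)
simulate_specimens <- function(taxon, n, matrix, seed,
                               policy = c("uniform-strict-interior",
                                          "truncated-normal"),
                               characters = NULL) {
  policy <- match.arg(policy)
  stopifnot(n >= 1)
  taxon <- resolve_taxon(matrix, taxon)
  profile <- matrix$taxa[[taxon]]
  known <- names(profile$values)[!vapply(profile$values, is_unknown,
                                         logical(1))]
  if (length(known) == 0L) stop("taxon ", taxon,
                                " has no recorded characters to simulate")
  if (is.null(characters)) characters <- known
  missing <- setdiff(characters, known)
  if (length(missing)) stop("characters unrecorded for ", taxon, ": ",
                            paste(missing, collapse = ", "))
  set.seed(as.integer(seed))

  draw <- function(v) {
    if (v$lo == v$hi) return(v$lo)
    w <- v$hi - v$lo
    if (policy == "uniform-strict-interior")
      return(stats::runif(1, v$lo + 1e-3 * w, v$hi - 1e-3 * w))
    repeat {
      x <- stats::rnorm(1, mean = (v$lo + v$hi) / 2, sd = w / 6)
      if (x > v$lo && x < v$hi) return(x)
    }
  }
  lapply(seq_len(n), function(i) {
    vals <- lapply(characters, function(id) {
      v <- profile$values[[id]]
      if (v$kind == "category") cat_value(v$category) else num_value(draw(v))
    })
    names(vals) <- characters
    specimen_observation(sprintf("%s-sim-%d", gsub("[^A-Za-z]+", "_", taxon), i),
                         vals)
  })
}

#' Simulate an aligned sequence set with known differences
#'
#' Builds a random reference sequence and derivatives differing from it at
#' exactly the requested number of positions, emitting the ground-truth
#' difference table alongside the FASTA text.
#'
#' @param length Alignment length.
#' @param n_seqs Number of sequences (>= 2).
#' @param diffs Differences from sequence 1 for each other sequence;
#'   scalar (recycled) or vector of length `n_seqs - 1`. Must satisfy
#'   `0 <= diffs <= length`.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `fasta`
#'   (FASTA text) and `truth` (data frame id, diffs_from_ref).
#' @export
#' @examples
#' sim <- simulate_alignment(100, 2, 5, seed = 1)
#' pairwise_divergence(sim$sequences[[1]], sim$sequences[[2]])$diffs  # 5
simulate_alignment <- function(length, n_seqs, diffs, seed) {
  stopifnot(length >= 1, n_seqs >= 2)
  diffs <- as.integer(diffs)
  if (base::length(diffs) == 1L) diffs <- rep(diffs, n_seqs - 1L)
  if (base::length(diffs) != n_seqs - 1L)
    stop("diffs must be scalar or of length n_seqs - 1")
  if (any(diffs < 0L) || any(diffs > length))
    stop("infeasible diff spec: need 0 <= diffs <= alignment length")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length, replace = TRUE)
  seqs <- vector("list", n_seqs)
  seqs[[1]] <- ref
  for (k in seq_len(n_seqs - 1L)) {
    s <- ref
    if (diffs[k] > 0L) {
      pos <- sample.int(length, diffs[k])
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    seqs[[k + 1L]] <- s
  }
  ids <- paste0("seq", seq_len(n_seqs))
  sequences <- stats::setNames(vapply(seqs, paste, character(1), collapse = ""),
                               ids)
  fasta <- paste0(">", ids, "\n", sequences, collapse = "\n")
  list(sequences = sequences,
       fasta = paste0(fasta, "\n"),
       truth = data.frame(id = ids[-1], diffs_from_ref = diffs,
                          stringsAsFactors = FALSE))
}
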