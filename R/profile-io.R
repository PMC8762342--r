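#' @keywords internal
"_PACKAGE"

#' Amino-acid column order of a PSI-BLAST profile
#'
#' The fixed 20-letter column ordering used by PSI-BLAST ASCII PSSM output.
#' Every encoder in the package indexes profile columns against this order.
#'
#' @format Character vector of length 20.
#' @export
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

#' Construct a protein sequence record
#'
#' @param id Record identifier.
#' @param residues Residue string over the 20-letter amino-acid alphabet.
#' @param permissive If `TRUE`, the non-standard residues X, B, Z and U are
#'   accepted and mapped to `"X"`; otherwise any character outside the
#'   20-letter alphabet is an error.
#' @return An object of class `protein_sequence` with fields `id` and
#'   `residues`.
#' @export
protein_sequence <- function(id, residues, permissive = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L)
    stop("protein sequence '", id, "' is empty")
  if (permissive)
    residues <- chartr("BZU", "XXX", residues)
  allowed <- c(PSSM_ALPHABET, if (permissive) "X")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L)
    stop("illegal residue '", chars[bad[1L]], "' in record '", id,
         "' at position ", bad[1L])
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param permissive Passed to [protein_sequence()]: accept X/B/Z/U (mapped
#'   to X) instead of rejecting them.
#' @return List of `protein_sequence` objects in file order.
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  # byte-level reader: keeps illegal characters so validation can report
  # the exact record and position instead of silently dropping them
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  mapply(function(i, s) protein_sequence(i, s, permissive = permissive),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Construct a PSSM profile object
#'
#' @param id Profile identifier.
#' @param scores Numeric L x 20 matrix of per-position substitution scores,
#'   columns in [PSSM_ALPHABET] order.
#' @param normalized Whether the scores have already been squashed into
#'   (0, 1) by [normalize_pssm()].
#' @return Object of class `pssm_profile`.
#' @export
pssm_profile <- function(id, scores, normalized = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("a PSSM profile must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L) stop("PSSM profile '", id, "' has no rows")
  if (!all(is.finite(scores))) stop("non-finite score in profile '", id, "'")
  if (normalized && (any(scores <= 0) || any(scores >= 1)))
    stop("normalized profile entries must lie strictly in (0, 1)")
  storage.mode(scores) <- "double"
  colnames(scores) <- PSSM_ALPHABET
  rownames(scores) <- NULL
  structure(list(id = id, scores = scores, normalized = normalized),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> id=", x$id, " L=", nrow(x$scores),
      if (x$normalized) " (normalized)" else " (raw)", "\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the profile produced by PSI-BLAST's ASCII PSSM output option
#' (the `-out_ascii_pssm` / legacy `-Q` file). Each body row carries the
#' position, the query residue, 20 log-odds substitution scores, 20
#' weighted-percentage columns and two trailing information columns; only
#' the first 20 score columns are retained.
#'
#' A typical invocation producing such a file is three PSI-BLAST iterations
#' against NCBI NR, e.g.
#' `psiblast -query seq.fasta -db nr -num_iterations 3 -out_ascii_pssm seq.pssm`
#' (not executed by this package; profiles are consumed pre-computed).
#'
#' @param path Path to the ASCII PSSM file.
#' @param id Profile identifier; defaults to the file name without extension.
#' @return A raw (unnormalized) `pssm_profile`.
#' @export
parse_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    # body rows start with a position index followed by a residue letter
    if (!grepl("^\\s*\\d+\\s+[A-Za-z]\\s", line)) next
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L)
      stop("PSSM row at line ", ln, " of ", basename(path),
           " has ", length(vals), " parseable score fields (need >= 20)")
    rows[[length(rows) + 1L]] <- vals[1:20]
  }
  if (length(rows) == 0L)
    stop("no PSSM rows found in ", path)
  pssm_profile(id, do.call(rbind, rows), normalized = FALSE)
}

#' Write a PSSM profile to a simple TSV file
#'
#' Serializes the score matrix as tab-separated rows with a one-line header
#' (`id`, `L`, `normalized`). [read_pssm_tsv()] inverts this exactly.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @export
write_pssm_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#id", profile$id, nrow(profile$scores),
                   as.integer(profile$normalized), sep = "\t"), con)
  utils::write.table(profile$scores, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a PSSM profile from the TSV serialization
#'
#' @param path Path written by [write_pssm_tsv()].
#' @return A `pssm_profile`.
#' @export
read_pssm_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (header[1] != "#id") stop("not a vtpred PSSM TSV: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(m) <- NULL
  pssm_profile(header[2], m, normalized = as.logical(as.integer(header[4])))
}

#' Squash a raw PSSM into (0, 1) with the logistic function
#'
#' Applies `1 / (1 + exp(-x))` elementwise. Feature encoders that multiply
#' profile entries or divide by their sums (notably the transition
#' probability composition) require strictly positive entries; all encoders
#' in this package consume logistic-normalized profiles.
#'
#' @param profile A raw `pssm_profile`.
#' @return The normalized `pssm_profile`. Normalizing twice is an error.
#' @export
normalize_pssm <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (profile$normalized)
    stop("profile '", profile$id, "' is already normalized")
  pssm_profile(profile$id, 1 / (1 + exp(-profile$scores)), normalized = TRUE)
}

#' Specification for a synthetic labeled PSSM dataset
#'
#' Describes the simulated conditions: counts per class, sequence-length
#' range, the mean-score offset applied to a designated column subset in
#' positives (`class_shift`), and the probability that consecutive rows of
#' a positive profile share their argmax column (`transition_bias`).
#'
#' @param n_positive,n_negative Profile counts per class (each >= 1).
#' @param length_range Integer `c(min, max)` sequence lengths; min >= 10
#'   because the segmented encoders need non-empty lag windows.
#' @param class_shift Mean raw-score offset added to columns 1-5 of
#'   positive profiles before discretization.
#' @param transition_bias Probability in `[0, 1]` that row i of a positive
#'   profile is forced to share its argmax column with row i-1.
#' @param seed Integer RNG seed.
#' @return Object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_positive, n_negative,
                                   length_range = c(50L, 120L),
                                   class_shift = 2, transition_bias = 0.5,
                                   seed = 1L) {
  stopifnot(n_positive >= 1L, n_negative >= 1L,
            length(length_range) == 2L,
            length_range[1] <= length_range[2],
            transition_bias >= 0, transition_bias <= 1)
  if (length_range[1] < 10L)
    stop("minimum sequence length must be >= 10 (feature encoders require L >= 10)")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 length_range = as.integer(length_range),
                 class_shift = class_shift,
                 transition_bias = transition_bias,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Simulate labeled PSSM profiles with class-dependent structure
#'
#' Raw integer scores are drawn from a discretized normal (mean 0, sd 3,
#' clipped to \[-10, 13\]) to mimic the magnitude range of BLOSUM-scaled
#' log-odds. Positives receive `class_shift` on columns 1-5 (a composition
#' signal) and, with probability `transition_bias` per row, have the
#' previous row's argmax column forced to be their own argmax (a
#' row-transition signal picked up by transition/autocovariance encoders).
#'
#' @param spec A [synthetic_dataset_spec()].
#' @return List with `profiles` (list of raw `pssm_profile`s, positives
#'   first) and `labels` (integer vector, 1 = vesicular/positive), aligned.
#' @export
simulate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  set.seed(spec$seed)
  n <- spec$n_positive + spec$n_negative
  labels <- c(rep(1L, spec$n_positive), rep(0L, spec$n_negative))
  shift_cols <- 1:5
  profiles <- vector("list", n)
  lens <- seq(spec$length_range[1], spec$length_range[2])
  for (p in seq_len(n)) {
    # guard the scalar-x behaviour of sample() for degenerate ranges
    L <- if (length(lens) == 1L) lens else sample(lens, 1L)
    m <- matrix(stats::rnorm(L * 20, mean = 0, sd = 3), nrow = L)
    if (labels[p] == 1L)
      m[, shift_cols] <- m[, shift_cols] + spec$class_shift
    m <- pmin(pmax(round(m), -10), 13)
    if (labels[p] == 1L && spec$transition_bias > 0) {
      for (i in 2:L) {
        if (stats::runif(1) < spec$transition_bias) {
          cc <- which.max(m[i - 1L, ])
          m[i, cc] <- min(max(m[i, ]) + 1, 13)
        }
      }
    }
    profiles[[p]] <- pssm_profile(sprintf("%s%04d",
                                          if (labels[p] == 1L) "pos" else "neg",
                                          p),
                                  m, normalized = FALSE)
  }
  list(profiles = profiles, labels = labels)
}
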