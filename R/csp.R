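# Segment boundaries: 2 segments split at L1 = floor(L/2); 3 segments at
# L1 = floor(L/3) and 2*L1, the remainder absorbed by the last segment.
.segments <- function(L, n_segments) {
  if (n_segments == 2L) {
    L1 <- L %/% 2L
    list(c(1L, L1), c(L1 + 1L, L))
  } else if (n_segments == 3L) {
    L1 <- L %/% 3L
    list(c(1L, L1), c(L1 + 1L, 2L * L1), c(2L * L1 + 1L, L))
  } else stop("n_segments must be 2 or 3")
}

#' Segmented pseudo-PSSM features
#'
#' The profile is split into 2 (or 3) contiguous segments. For each segment
#' and column j, the lag-0 value is the per-column segment mean and the
#' lag-lambda value (lambda = 1..4 for 2 segments, 1..2 for 3) is the mean
#' squared difference between entries lambda rows apart within the segment:
#' `1/(n - lambda) * sum_i (P_ij - P_(i+lambda)j)^2`. This mixes
#' composition with local sequence-order information.
#'
#' @param profile A normalized `pssm_profile` with L >= 10 rows.
#' @param n_segments 2 (lambda 0..4; 200 values) or 3 (lambda 0..2; 180
#'   values).
#' @return Named numeric vector, ordered segment-outer, lambda-middle,
#'   column-inner.
#' @export
pse_pssm_segments <- function(profile, n_segments = 2L) {
  .check_normalized(profile)
  P <- profile$scores
  L <- nrow(P)
  if (L < 10L) stop("segmented PsePSSM requires L >= 10 (got L = ", L, ")")
  lambdas <- if (n_segments == 2L) 0:4 else 0:2
  segs <- .segments(L, n_segments)
  out <- numeric(0)
  for (s in seq_along(segs)) {
    a <- segs[[s]][1]; b <- segs[[s]][2]
    for (lam in lambdas) {
      if (lam == 0L) {
        v <- colMeans(P[a:b, , drop = FALSE])
      } else {
        d <- P[a:(b - lam), , drop = FALSE] - P[(a + lam):b, , drop = FALSE]
        v <- colSums(d * d) / (b - a + 1L - lam)
      }
      names(v) <- sprintf("PSE%d_S%d_L%d_%s", n_segments, s, lam,
                          PSSM_ALPHABET)
      out <- c(out, v)
    }
  }
  out
}

#' Segmented autocovariance transformation features
#'
#' Per segment and column, the autocovariance of profile scores at lag lg
#' around the segment mean m:
#' `1/(n - lg) * sum_i (P_ij - m)(P_(i+lg)j - m)`, with lg = 1..4 on 2
#' segments and lg = 1..2 on 3 segments, measuring correlation between
#' positions lg residues apart.
#'
#' @param profile A normalized `pssm_profile` with L >= 10 rows.
#' @param n_segments 2 (160 values) or 3 (120 values); the combined
#'   encoder uses both for 280.
#' @return Named numeric vector, ordered segment-outer, lag-middle,
#'   column-inner.
#' @export
act_segments <- function(profile, n_segments = 2L) {
  .check_normalized(profile)
  P <- profile$scores
  L <- nrow(P)
  if (L < 10L) stop("segmented ACT requires L >= 10 (got L = ", L, ")")
  lags <- if (n_segments == 2L) 1:4 else 1:2
  segs <- .segments(L, n_segments)
  out <- numeric(0)
  for (s in seq_along(segs)) {
    a <- segs[[s]][1]; b <- segs[[s]][2]
    m <- colMeans(P[a:b, , drop = FALSE])
    for (lg in lags) {
      d1 <- sweep(P[a:(b - lg), , drop = FALSE], 2L, m)
      d2 <- sweep(P[(a + lg):b, , drop = FALSE], 2L, m)
      v <- colSums(d1 * d2) / (b - a + 1L - lg)
      names(v) <- sprintf("ACT%d_S%d_G%d_%s", n_segments, s, lg,
                          PSSM_ALPHABET)
      out <- c(out, v)
    }
  }
  out
}

#' Consensus sequence of a PSSM
#'
#' The per-row argmax column index, `X(i) = argmax_j P_ij`; ties broken by
#' the lowest column index. Invariant under any monotone transform of the
#' scores, so raw and normalized profiles give the same consensus.
#'
#' @param profile A `pssm_profile` (raw or normalized).
#' @return Integer vector of length L with values in 1..20, of class
#'   `consensus_sequence`.
#' @export
consensus_sequence <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  idx <- apply(profile$scores, 1L, which.max)
  structure(as.integer(idx), class = "consensus_sequence")
}

#' Consensus-sequence composition features (CSAAC + CSCM, 40 values)
#'
#' CSAAC_j is the fraction of consensus positions equal to residue j;
#' CSCM_j is the composition moment, the sum of the 1-based positions
#' where the consensus equals j divided by `L * (L - 1)`, weighting
#' residues by where they occur along the sequence.
#'
#' @param profile A `pssm_profile` with L >= 2 rows.
#' @return Named numeric vector of length 40 (`CSAAC_*` then `CSCM_*`).
#' @export
cs_features <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  L <- nrow(profile$scores)
  if (L < 2L) stop("consensus composition moment requires L >= 2")
  cons <- unclass(consensus_sequence(profile))
  csaac <- tabulate(cons, nbins = 20L) / L
  cscm <- vapply(1:20, function(j) sum(which(cons == j)), numeric(1)) /
    (L * (L - 1))
  out <- c(csaac, cscm)
  names(out) <- c(paste0("CSAAC_", PSSM_ALPHABET),
                  paste0("CSCM_", PSSM_ALPHABET))
  out
}

#' CSP-SegPseP-SegACP encoding (700 features)
#'
#' Fuses the two- and three-segment pseudo-PSSM blocks (200 + 180), the
#' two- and three-segment autocovariance blocks (160 + 120) and the
#' consensus-sequence composition block (40) of one normalized profile.
#'
#' @param profile A normalized `pssm_profile` with L >= 10 rows.
#' @return Named numeric vector of length 700.
#' @export
csp_segpsep_segacp <- function(profile) {
  c(pse_pssm_segments(profile, 2L),
    pse_pssm_segments(profile, 3L),
    act_segments(profile, 2L),
    act_segments(profile, 3L),
    cs_features(profile))
}
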