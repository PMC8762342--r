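.check_normalized <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (!profile$normalized)
    stop("profile '", profile$id,
         "' is not normalized; call normalize_pssm() first")
  invisible(profile)
}

#' Amino-acid composition of a PSSM
#'
#' Per-column mean of the normalized profile:
#' `x_j = (1/L) * sum_i P_ij`, the average propensity of positions to
#' mutate into amino-acid type j over evolution.
#'
#' @param profile A normalized `pssm_profile`.
#' @return Named numeric vector of length 20 (`AAC_A` ... `AAC_Y`).
#' @export
aac <- function(profile) {
  .check_normalized(profile)
  out <- colMeans(profile$scores)
  names(out) <- paste0("AAC_", PSSM_ALPHABET)
  out
}

#' Transition probability composition of a PSSM
#'
#' From the transition products of consecutive positions,
#' `N_ij = sum_{k=1..L-1} P_ki * P_(k+1)j`, each source row i is
#' normalized by its total `sum_j N_ij`, yielding a 20 x 20 transition
#' probability matrix flattened row-major (source residue i outer, target
#' j inner). Rows with a zero denominator (impossible for
#' logistic-normalized profiles, kept defensive) emit zeros.
#'
#' @param profile A normalized `pssm_profile` with L >= 2 rows.
#' @return Named numeric vector of length 400 (`TPC_A_A`, `TPC_A_R`, ...).
#' @export
tpc <- function(profile) {
  .check_normalized(profile)
  P <- profile$scores
  L <- nrow(P)
  if (L < 2L) stop("TPC requires a profile with L >= 2 rows")
  N <- crossprod(P[-L, , drop = FALSE], P[-1L, , drop = FALSE])
  denom <- rowSums(N)
  X <- N
  nz <- denom > 0
  X[nz, ] <- N[nz, , drop = FALSE] / denom[nz]
  X[!nz, ] <- 0
  out <- as.vector(t(X))
  names(out) <- paste0("TPC_",
                       rep(PSSM_ALPHABET, each = 20L), "_",
                       rep(PSSM_ALPHABET, times = 20L))
  out
}

#' AATP encoding (AAC + TPC, 420 features)
#'
#' Concatenates the 20 amino-acid composition values and the 400
#' transition probability composition values of a normalized profile.
#'
#' @param profile A normalized `pssm_profile` with L >= 2 rows.
#' @return Named numeric vector of length 420.
#' @export
aatp <- function(profile) {
  c(aac(profile), tpc(profile))
}
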