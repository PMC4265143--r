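## Machine verification of the two headline properties of the
## counterexample families at small leaf counts.
##
## The published statements hold for every n >= 3; exhaustive machine
## checking is truncated at user-chosen bounds (the subset count grows as
## 2^n and the networks as ~2^n vertices), and every report records the
## bounds actually checked.

.verifyPair <- function(a, b, family, n, requireBinary = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  checks <- list(
    valid = length(validateNetwork(a, strict = TRUE)) == 0L &&
            length(validateNetwork(b, strict = TRUE)) == 0L,
    recoverable = isRecoverable(a) && isRecoverable(b),
    notEquivalent = !verdict(areEquivalent(a, b))
  )
  if (requireBinary)
    checks$binary <- isBinaryNetwork(a) && isBinaryNetwork(b)
  nw <- areNetworkEquivalent(a, b)
  checks$networkEquivalent <- verdict(nw)
  list(family = family, n = n,
       checks = checks,
       pass = all(unlist(checks)),
       failingSubset = if (!verdict(nw)) certificate(nw) else NULL,
       subsetsChecked = as.integer(2^length(taxa(a)) - 2),
       elapsed = round(proc.time()[["elapsed"]] - t0, 3L))
}

#' Verify the counterexample pairs at a range of leaf counts
#'
#' For each \code{n} in \code{nMin..nMax}, builds the requested pair and
#' checks the claimed properties: both members valid and recoverable
#' (and binary, for the binary family), NOT equivalent, yet
#' network-equivalent across all \code{2^n - 2} proper leaf subsets.
#' \code{verifyNonbinaryPair} checks \code{buildN(1, n)} vs
#' \code{buildN(2, n)}; \code{verifyBinaryPair} checks \code{buildH(1,
#' n)} vs \code{buildH(2, n)}.
#'
#' Since cost grows doubly exponentially in \code{n}, the drivers refuse
#' \code{nMax > 7} (nonbinary) and \code{nMax > 5} (binary) unless
#' \code{force = TRUE}.
#'
#' @param nMin,nMax Inclusive range of leaf counts, \code{3 <= nMin <=
#'   nMax}.
#' @param force Override the resource guard.
#' @return A report list with one entry per \code{n} (family, checks,
#'   pass flag, subsets checked, elapsed seconds) plus an overall
#'   \code{pass}.
#' @export
verifyNonbinaryPair <- function(nMin = 3L, nMax = 5L, force = FALSE) {
  stopifnot(nMin >= 3L, nMin <= nMax)
  if (nMax > 7L && !force)
    stop("nMax > 7 for the nonbinary family needs force = TRUE",
         call. = FALSE)
  entries <- lapply(nMin:nMax, function(n)
    .verifyPair(buildN(1L, n), buildN(2L, n), "nonbinary", n))
  list(family = "nonbinary", entries = entries,
       pass = all(vapply(entries, `[[`, logical(1L), "pass")))
}

#' @rdname verifyNonbinaryPair
#' @export
verifyBinaryPair <- function(nMin = 3L, nMax = 4L, force = FALSE) {
  stopifnot(nMin >= 3L, nMin <= nMax)
  if (nMax > 5L && !force)
    stop("nMax > 5 for the binary family needs force = TRUE", call. = FALSE)
  entries <- lapply(nMin:nMax, function(n)
    .verifyPair(buildH(1L, n), buildH(2L, n), "binary", n,
                requireBinary = TRUE))
  list(family = "binary", entries = entries,
       pass = all(vapply(entries, `[[`, logical(1L), "pass")))
}
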