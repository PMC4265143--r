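## Binary-sequence calculus.
##
## Sequences over {0,1} are represented as plain character strings of '0'
## and '1' ("011"), with the empty string as the empty sequence.  All
## indexing is 1-based, matching the usual convention for the i-th letter
## of a word read from the left.  These sequences name the vertices of the
## counterexample network families, so everything here is deterministic
## and pools are returned in lexicographic order.

.assertBits <- function(w) {
  if (!is.character(w) || length(w) != 1L || is.na(w))
    stop("a bit sequence must be a single character string", call. = FALSE)
  if (nchar(w) > 0L && grepl("[^01]", w))
    stop("a bit sequence may contain only '0' and '1': ", w, call. = FALSE)
  invisible(w)
}

#' Length of a bit sequence
#'
#' @param w A bit sequence given as a string of \code{"0"}/\code{"1"}
#'   characters; \code{""} is the empty sequence.
#' @return Integer length.
#' @export
bitLength <- function(w) {
  .assertBits(w)
  nchar(w)
}

#' Weight of a bit sequence
#'
#' The weight of a sequence is the number of 1s it contains, i.e. the sum
#' of its letters.
#'
#' @inheritParams bitLength
#' @return Nonnegative integer.
#' @examples
#' bitWeight("011")  # 2
#' @export
bitWeight <- function(w) {
  .assertBits(w)
  if (nchar(w) == 0L) return(0L)
  sum(strsplit(w, "", fixed = TRUE)[[1L]] == "1")
}

#' Support of a bit sequence
#'
#' The support is the set of 1-based positions holding a 1.  It is
#' undefined for the empty sequence.
#'
#' @inheritParams bitLength
#' @return Increasing integer vector of positions; \code{integer(0)} for an
#'   all-zero sequence.
#' @examples
#' bitSupport("011")  # c(2, 3)
#' @export
bitSupport <- function(w) {
  .assertBits(w)
  if (nchar(w) == 0L)
    stop("support is undefined for the empty sequence", call. = FALSE)
  which(strsplit(w, "", fixed = TRUE)[[1L]] == "1")
}

#' All-zero, all-one, and unit sequences
#'
#' \code{zeroSeq(n)} and \code{oneSeq(n)} are the length-\code{n} constant
#' sequences; \code{unitSeq(k, n)} has a single 1 in position \code{k}.
#'
#' @param n Sequence length, a nonnegative integer.
#' @param k Position of the single 1, with \code{1 <= k <= n}.
#' @return A bit sequence string.
#' @export
zeroSeq <- function(n) strrep("0", n)

#' @rdname zeroSeq
#' @export
oneSeq <- function(n) strrep("1", n)

#' @rdname zeroSeq
#' @export
unitSeq <- function(k, n) {
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  paste0(strrep("0", k - 1L), "1", strrep("0", n - k))
}

#' Letter access
#'
#' @inheritParams bitLength
#' @param i 1-based position.
#' @return 0 or 1 as an integer.
#' @export
bitAt <- function(w, i) {
  .assertBits(w)
  if (i < 1L || i > nchar(w)) stop("index out of range", call. = FALSE)
  as.integer(substr(w, i, i))
}

#' All length-n bit sequences
#'
#' @param n Length, \code{n >= 0}.
#' @return Character vector of all \code{2^n} sequences in lexicographic
#'   order (\code{""} for \code{n = 0}).
#' @export
allBitSequences <- function(n) {
  if (n < 0L) stop("n must be nonnegative", call. = FALSE)
  if (n == 0L) return("")
  grid <- expand.grid(rep(list(c("0", "1")), n), stringsAsFactors = FALSE)
  sort(do.call(paste0, grid))
}

#' All bit sequences of length at most n
#'
#' The vertex set of the prefix trie on length-\code{n} sequences.
#'
#' @param n Maximum length, \code{n >= 0}.
#' @return Character vector, lexicographic within each length, shorter
#'   lengths first.
#' @export
allBitSequencesUpTo <- function(n) {
  unlist(lapply(0:n, allBitSequences), use.names = FALSE)
}

#' Odd- and even-weight parity classes
#'
#' Splits the length-\code{n} sequences into the odd-weight class and the
#' even-weight class, with the convention that the all-zero sequence
#' belongs to neither.  The odd class has \code{2^(n-1)} members and the
#' even class \code{2^(n-1) - 1}.
#'
#' @param n Length, \code{n >= 1}.
#' @return A list with components \code{odd} and \code{even}, each a
#'   lexicographically sorted character vector.
#' @examples
#' parityClasses(3)
#' @export
parityClasses <- function(n) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  all <- allBitSequences(n)
  wt <- vapply(all, bitWeight, integer(1L))
  list(odd = unname(all[wt %% 2L == 1L]),
       even = unname(all[wt %% 2L == 0L & wt > 0L]))
}

#' Prefix test
#'
#' @param wShort,wLong Bit sequences.
#' @return \code{TRUE} iff \code{wShort} is a prefix of \code{wLong} (every
#'   sequence has itself and the empty sequence among its prefixes).
#' @export
isPrefix <- function(wShort, wLong) {
  .assertBits(wShort); .assertBits(wLong)
  nchar(wShort) <= nchar(wLong) &&
    substr(wLong, 1L, nchar(wShort)) == wShort
}

#' Maximal precursor within a pool
#'
#' A precursor of \code{w} in a pool \code{B} is a proper prefix of
#' \code{w} that is itself a member of \code{B}.  The maximal precursor is
#' the precursor of which every other precursor is in turn a precursor —
#' equivalently, the longest proper prefix of \code{w} present in the pool.
#' It is unique when it exists.
#'
#' @param w A bit sequence; must be a member of \code{pool}.
#' @param pool Character vector of distinct bit sequences.
#' @return The maximal precursor string, or \code{NULL} if \code{w} has no
#'   precursor in the pool.
#' @export
maximalPrecursor <- function(w, pool) {
  .assertBits(w)
  if (!(w %in% pool)) stop("w must be a member of the pool", call. = FALSE)
  prec <- setdiff(pool[vapply(pool, isPrefix, logical(1L), wLong = w)], w)
  if (length(prec) == 0L) return(NULL)
  prec[which.max(nchar(prec))]
}

#' Flip one letter
#'
#' Replaces letter \code{k} of \code{w} by its complement, leaving all
#' other letters unchanged.  Applying the same flip twice restores
#' \code{w}; on length-\code{n} sequences a flip always swaps weight
#' parity.
#'
#' @param k 1-based position, \code{1 <= k <=} length of \code{w}.
#' @inheritParams bitLength
#' @return The flipped sequence.
#' @examples
#' flipBit(1, "011")  # "111"
#' @export
flipBit <- function(k, w) {
  .assertBits(w)
  if (k < 1L || k > nchar(w)) stop("k out of range", call. = FALSE)
  substr(w, k, k) <- if (substr(w, k, k) == "1") "0" else "1"
  w
}
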