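#' Stranded allele counts at variant positions
#'
#' `StrandCounts` holds, for one or more genomic positions, the 2x2 table of
#' read counts cross-classifying allele (major vs minor, pooled across
#' strands) and strand (forward vs reverse):
#'
#' \tabular{lcc}{
#'              \tab major \tab minor \cr
#'     forward  \tab a     \tab b     \cr
#'     reverse  \tab c     \tab d
#' }
#'
#' The major allele is the one with the larger pooled count, so `a + c >=
#' b + d` is enforced by the validity method, along with non-negativity and a
#' total depth of at least one read per position.
#'
#' @param a,b,c,d Non-negative integer vectors of equal length: forward-major,
#'   forward-minor, reverse-major and reverse-minor read counts.
#' @param x A `StrandCounts` object (for the accessors).
#' @param ... Unused.
#'
#' @return `StrandCounts()` returns a `StrandCounts` object. `strandCounts()`
#'   extracts one from a container. `fwdDepth()`, `revDepth()` and
#'   `totalDepth()` return integer vectors of per-position strand and total
#'   depths.
#'
#' @examples
#' sc <- StrandCounts(a = 11, b = 2, c = 20, d = 0)
#' sbScore(sc)
#' fwdDepth(sc)
#'
#' @aliases StrandCounts-class
#' @export
StrandCounts <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    .asCount(x, what)
  }
  new("StrandCounts", a = rec(a, "a"), b = rec(b, "b"),
      c = rec(c, "c"), d = rec(d, "d"))
}

setClass("StrandCounts",
         slots = c(a = "integer", b = "integer", c = "integer", d = "integer"))

.asCount <- function(x, what) {
  if (!is.numeric(x))
    stop("'", what, "' must be numeric")
  if (any(!is.finite(x)))
    stop("'", what, "' contains non-finite values")
  if (any(abs(x - round(x)) > 1e-8))
    stop("'", what, "' must contain whole numbers")
  as.integer(round(x))
}

setValidity("StrandCounts", function(object) {
  n <- length(object@a)
  if (length(object@b) != n || length(object@c) != n ||
      length(object@d) != n)
    return("count slots must have equal length")
  if (anyNA(object@a) || anyNA(object@b) || anyNA(object@c) ||
      anyNA(object@d))
    return("counts must not contain NA")
  if (any(object@a < 0L | object@b < 0L | object@c < 0L | object@d < 0L))
    return("counts must be non-negative")
  tot <- object@a + object@b + object@c + object@d
  if (any(tot < 1L))
    return("total depth a+b+c+d must be >= 1 at every position")
  if (any(object@a + object@c < object@b + object@d))
    return(paste0("major/minor orientation violated: a+c must be >= b+d ",
                  "(the major allele is the one with the larger pooled ",
                  "count)"))
  TRUE
})

#' @rdname StrandCounts
#' @export
setMethod("strandCounts", "StrandCounts", function(x, ...) x)

setMethod("length", "StrandCounts", function(x) length(x@a))

setMethod("[", "StrandCounts", function(x, i, j, ..., drop = TRUE) {
  initialize(x, a = x@a[i], b = x@b[i], c = x@c[i], d = x@d[i])
})

setMethod("show", "StrandCounts", function(object) {
  cat("StrandCounts with", length(object), "position(s)\n")
  df <- as.data.frame(object)
  print(utils::head(df, 6L))
  if (length(object) > 6L)
    cat("...", length(object) - 6L, "more\n")
})

#' @exportS3Method base::as.data.frame
as.data.frame.StrandCounts <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(a = x@a, b = x@b, c = x@c, d = x@d, row.names = row.names)
}

setMethod("as.data.frame", "StrandCounts", as.data.frame.StrandCounts)

#' @rdname StrandCounts
#' @export
fwdDepth <- function(x) x@a + x@b

#' @rdname StrandCounts
#' @export
revDepth <- function(x) x@c + x@d

#' @rdname StrandCounts
#' @export
totalDepth <- function(x) x@a + x@b + x@c + x@d

#' Reduce raw per-allele observations to a biallelic 2x2 table
#'
#' At some positions reads support more than two alleles; third (and further)
#' alleles are almost always sequencing or alignment errors and are discarded
#' before scoring. The two alleles with the highest pooled (forward + reverse)
#' counts are kept; the higher-total allele becomes the major allele (counts
#' `a`, `c`), the other the minor (`b`, `d`). Ties are broken in favour of the
#' reference allele (when supplied), then by alphabetical nucleotide order.
#'
#' @param allele Character vector of observed allele symbols (one entry per
#'   distinct allele at the site).
#' @param forward,reverse Non-negative integer vectors of per-allele read
#'   counts on the forward and reverse strand.
#' @param ref Optional reference allele used to break ties in the
#'   major/minor ranking.
#'
#' @return A list with elements `counts` (a length-one [StrandCounts]),
#'   `major` and `minor` (allele symbols; `minor` is `NA` at a monoallelic
#'   site where `b = d = 0`), and `discarded` (alleles dropped by the
#'   reduction).
#'
#' @examples
#' ## a third allele with a single stray read is discarded
#' reduceToBiallelic(c("C", "T", "G"), forward = c(10, 4, 1),
#'                   reverse = c(10, 3, 0))
#'
#' @export
reduceToBiallelic <- function(allele, forward, reverse, ref = NULL) {
  if (length(allele) == 0L)
    stop("no allele observations: site is uncovered")
  if (length(forward) != length(allele) || length(reverse) != length(allele))
    stop("'allele', 'forward' and 'reverse' must have equal length")
  if (anyDuplicated(allele))
    stop("duplicate allele symbols in observation list")
  forward <- .asCount(forward, "forward")
  reverse <- .asCount(reverse, "reverse")
  total <- forward + reverse
  if (sum(total) < 1L)
    stop("site is uncovered: all allele counts are zero")
  isRef <- if (is.null(ref)) rep(FALSE, length(allele)) else allele == ref
  ord <- order(-total, !isRef, allele)
  major <- ord[1L]
  if (length(ord) >= 2L && total[ord[2L]] > 0L) {
    minor <- ord[2L]
    counts <- StrandCounts(forward[major], forward[minor],
                           reverse[major], reverse[minor])
    minorAllele <- allele[minor]
    discarded <- allele[ord[-(1:2)]]
  } else {
    counts <- StrandCounts(forward[major], 0L, reverse[major], 0L)
    minorAllele <- NA_character_
    discarded <- allele[ord[-1L]]
  }
  list(counts = counts, major = allele[major], minor = minorAllele,
       discarded = discarded)
}
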