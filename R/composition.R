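## Segment composition: how hull volume is distributed around the skeleton,
## and whether a fossil's segment proportion sits inside the extant range.

#' Per-segment fractions of total hull volume
#'
#' Divides each segment hull volume by the with-feet total. Fractions are
#' dimensionless, sum to one, and are invariant to uniform rescaling of all
#' volumes, which makes them comparable across body sizes.
#'
#' @param table a [hull_volume_table()].
#' @return named numeric vector of fractions in (0, 1), one per segment,
#'   with a `specimen` attribute.
#' @export
segment_fractions <- function(table) {
  stopifnot(inherits(table, "hull_volume_table"))
  f <- table$volumes / table$total_with_feet
  structure(f, specimen = table$specimen)
}

#' One-sample t-test of segment fractions against a reference value
#'
#' Compares the extant sample of segment fractions to a single fossil's
#' fraction: `t = (mean(sample) - reference) / (sd(sample)/sqrt(n))` with
#' n - 1 degrees of freedom. The tail is an explicit argument and is never
#' chosen automatically: whether the fossil is expected below or above the
#' extant mean is the analyst's hypothesis. Computed with [stats::t.test()].
#'
#' @param sample numeric vector of extant fractions, length >= 2.
#' @param reference the fossil fraction to test against.
#' @param tail `"two_sided"`, `"less"` (sample mean below reference) or
#'   `"greater"`.
#' @return list with `t`, `df`, `p`, `tail`, `mean`, `reference`.
#' @export
one_sample_t <- function(sample, reference, tail = c("two_sided", "less", "greater")) {
  tail <- match.arg(tail)
  if (length(sample) < 2L) {
    chm_error("insufficient_data", "need at least 2 observations for a t-test")
  }
  if (!is.finite(reference)) {
    chm_error("nonpositive_value", "reference must be finite")
  }
  if (stats::sd(sample) == 0) {
    chm_error("zero_variance", "sample has zero variance; t statistic undefined")
  }
  alt <- c(two_sided = "two.sided", less = "less", greater = "greater")[[tail]]
  ht <- stats::t.test(sample, mu = reference, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, tail = tail, mean = mean(sample), reference = reference)
}

#' Compare fossil segment fractions against an extant sample
#'
#' Runs [one_sample_t()] per segment shared between an extant fraction
#' matrix and one fossil's fractions.
#'
#' @param extant matrix or data.frame of extant fractions, one row per
#'   specimen, columns named by segment.
#' @param fossil named numeric vector of the fossil's fractions.
#' @param tail passed to [one_sample_t()].
#' @return data.frame with columns `segment`, `t`, `df`, `p`, `tail`.
#' @export
compare_fractions <- function(extant, fossil, tail = "two_sided") {
  extant <- as.matrix(extant)
  segs <- intersect(colnames(extant), names(fossil))
  if (length(segs) == 0L) {
    chm_error("schema", "no shared segment names between extant table and fossil")
  }
  rows <- lapply(segs, function(s) {
    r <- one_sample_t(extant[, s], fossil[[s]], tail = tail)
    data.frame(segment = s, t = r$t, df = r$df, p = r$p, tail = r$tail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
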