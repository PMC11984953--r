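#' Two-context individual-level sample at a single biallelic locus
#'
#' Container for the generative setting of the decision framework: a single
#' biallelic, autosomal variant measured in `n + m` individuals, the first `n`
#' in context `"A"` and the remaining `m` in context `"B"`. Within each
#' context the trait is modelled as a linear function of reference-allele
#' count with context-specific intercept, slope and residual variance.
#'
#' @param genotypes Integer vector of reference-allele counts, each 0, 1 or 2.
#' @param traits Numeric vector of continuous trait values, same length.
#' @param context Character (or factor) vector of context labels, `"A"` or
#'   `"B"`, same length. Both contexts must be represented.
#'
#' @return An object of class `"stratified_sample"`: a list with elements
#'   `genotypes`, `traits`, `context` (character), `n` (count in A) and `m`
#'   (count in B).
#'
#' @examples
#' s <- stratified_sample(c(0, 1, 2, 0, 1, 2),
#'                        c(0.1, 0.9, 2.2, 0.3, 1.4, 2.9),
#'                        c("A", "A", "A", "B", "B", "B"))
#' s$n
#' @export
stratified_sample <- function(genotypes, traits, context) {
  if (length(genotypes) != length(traits) ||
      length(genotypes) != length(context)) {
    gxe_stop("genotypes, traits and context must have equal length")
  }
  context <- as.character(context)
  if (anyNA(genotypes) || anyNA(traits) || anyNA(context)) {
    gxe_stop("missing values are not allowed in a stratified sample")
  }
  if (!all(genotypes %in% c(0, 1, 2))) {
    gxe_stop("genotypes must be reference-allele counts in {0, 1, 2}")
  }
  if (!all(context %in% c("A", "B"))) {
    gxe_stop("context labels must be \"A\" or \"B\"")
  }
  if (!is.numeric(traits) || any(!is.finite(traits))) {
    gxe_stop("traits must be finite numeric values")
  }
  n <- sum(context == "A")
  m <- sum(context == "B")
  if (n == 0L || m == 0L) {
    gxe_stop("both contexts must be represented", "gxe_empty_context")
  }
  structure(
    list(genotypes = as.integer(genotypes), traits = as.numeric(traits),
         context = context, n = n, m = m),
    class = "stratified_sample"
  )
}

#' @export
print.stratified_sample <- function(x, ...) {
  cat(sprintf("stratified_sample: %d individuals (A: %d, B: %d)\n",
              x$n + x$m, x$n, x$m))
  fa <- mean(x$genotypes[x$context == "A"]) / 2
  fb <- mean(x$genotypes[x$context == "B"]) / 2
  cat(sprintf("  effect-allele frequency: A %.3f, B %.3f\n", fa, fb))
  invisible(x)
}

#' Center traits within each context
#'
#' Subtracts the context-specific trait mean, leaving genotypes untouched.
#' Mean-centering is inconsequential for slope estimation but is assumed by
#' the identity expressing the pooled (additive) estimator as a weighted
#' combination of the stratified estimators, so it is applied before any
#' pooled/stratified comparison.
#'
#' @param sample A [stratified_sample()].
#' @return A `stratified_sample` whose traits have mean zero within each
#'   context (to numerical precision).
#' @examples
#' s <- stratified_sample(c(0, 1, 0, 1), c(1, 3, 5, 5), c("A", "A", "B", "B"))
#' tapply(center_within_context(s)$traits, s$context, mean)
#' @export
center_within_context <- function(sample) {
  assert_sample(sample)
  a <- sample$context == "A"
  sample$traits[a] <- sample$traits[a] - mean(sample$traits[a])
  sample$traits[!a] <- sample$traits[!a] - mean(sample$traits[!a])
  sample
}

assert_sample <- function(sample) {
  if (!inherits(sample, "stratified_sample")) {
    gxe_stop("expected a stratified_sample object")
  }
  invisible(sample)
}

#' Read an individual-level two-context table
#'
#' Reads a tab-separated file with columns `context` (A/B), `genotype`
#' (0/1/2) and `trait` (numeric) into a [stratified_sample()].
#'
#' @param path Path to a TSV file with a header row.
#' @return A `stratified_sample`.
#' @export
read_individual_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("context", "genotype", "trait")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    gxe_stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
             "gxe_bad_table")
  }
  stratified_sample(df$genotype, df$trait, df$context)
}
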