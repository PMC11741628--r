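# Genotype labels are dash-joined allele sets, e.g. "DQA1*01:02-DQB1*06:02".
# Carriage is dominant (genotype present / absent); a multi-allele label is
# satisfied in cis or in trans unless a phased (cis-only) predicate is
# requested, in which case all alleles must sit on one haplotype string.

parse_genotype_label <- function(label) {
  alleles <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(alleles) < 1 || any(!grepl("\\*", alleles)))
    stop("malformed genotype label: ", label)
  alleles
}

canonical_label <- function(alleles) paste(sort(unique(alleles)), collapse = "-")

allele_locus <- function(alleles) sub("\\*.*$", "", alleles)

#' Genotype carriage in a cohort
#'
#' Returns the logical carriage vector for a genotype label over a cohort
#' table. Labels are one to three dash-joined alleles; carriage requires
#' all of them. Class II multi-allele labels are evaluated in cis or in
#' trans (`phase = "either"`, the default) or restricted to a single
#' phased haplotype (`phase = "cis"`).
#'
#' @param cohort Cohort data.frame (see [read_cohort()]).
#' @param label Genotype label, e.g. `"DQA1*01:02-DQB1*06:02"`.
#' @param phase `"either"` or `"cis"`.
#' @return Logical vector, one element per individual.
#' @export
genotype_carriage <- function(cohort, label, phase = c("either", "cis")) {
  phase <- match.arg(phase)
  alleles <- parse_genotype_label(label)
  if (phase == "cis" && length(alleles) > 1) {
    h1 <- strsplit(cohort$hap1, "~", fixed = TRUE)
    h2 <- strsplit(cohort$hap2, "~", fixed = TRUE)
    inhap <- function(h) vapply(h, function(a) all(alleles %in% a), FALSE)
    return(inhap(h1) | inhap(h2))
  }
  cols <- as.matrix(cohort[, c(CLASS1_COLS, CLASS2_COLS)])
  out <- rep(TRUE, nrow(cohort))
  for (a in alleles) out <- out & (rowSums(cols == a, na.rm = TRUE) > 0)
  out
}

# n x m logical matrix of carriage for several labels
carriage_matrix <- function(cohort, labels, phase = "either") {
  m <- vapply(labels, function(l) genotype_carriage(cohort, l, phase),
              logical(nrow(cohort)))
  if (nrow(cohort) == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- labels
  m
}
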