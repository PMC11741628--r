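# Stratified transmission analysis for affected-child trios.

# Per-trio transmission contributions for one genotype: for each
# heterozygous (informative) parent, did the genotype-bearing haplotype go
# to the affected child?
.transmission_contrib <- function(trios, genotype) {
  alleles <- parse_genotype_label(genotype)
  hap_carries <- function(h) vapply(strsplit(h, "~", fixed = TRUE),
                                    function(x) all(alleles %in% x), FALSE)
  one_parent <- function(h1, h2, transmitted) {
    c1 <- hap_carries(h1); c2 <- hap_carries(h2)
    informative <- xor(c1, c2)
    carrier_hap <- ifelse(c1, 1L, 2L)
    transm <- informative & (transmitted == carrier_hap)
    nontransm <- informative & (transmitted != carrier_hap)
    list(t = as.integer(transm), nt = as.integer(nontransm),
         informative = informative)
  }
  fa <- one_parent(trios$father_hap1, trios$father_hap2, trios$father_transmitted)
  mo <- one_parent(trios$mother_hap1, trios$mother_hap2, trios$mother_transmitted)
  list(t = fa$t + mo$t, nt = fa$nt + mo$nt,
       n_informative = sum(fa$informative) + sum(mo$informative),
       n_uninformative = sum(!fa$informative) + sum(!mo$informative))
}

# child iKIR scores for stratification
.child_scores <- function(trios, weights = ikir_weights(),
                          include_kir3dl2 = FALSE) {
  ch <- trios_child_frame(trios)
  score_cohort(ch, weights = weights,
               include_kir3dl2 = include_kir3dl2)$ikir_score
}

#' Transmission / non-transmission counts per iKIR stratum
#'
#' Counts, separately for trios whose affected child has a high or low
#' iKIR score, how often the genotype-bearing parental haplotype was
#' transmitted (T) versus not transmitted (NT). Only heterozygous parents
#' (exactly one haplotype carrying the genotype) are informative;
#' uninformative parents are excluded and counted.
#'
#' @param trios `ikir_trios` data.frame.
#' @param genotype Genotype label, evaluated on single haplotypes (cis).
#' @param threshold iKIR score threshold; stratum assignment uses only the
#'   affected child's score (ties to `"low"`).
#' @param weights,include_kir3dl2 Score settings for the children.
#' @return Data.frame with one row per stratum: `stratum, T, NT,
#'   n_informative`; attribute `n_uninformative`.
#' @export
transmission_counts <- function(trios, genotype, threshold = 1.75,
                                weights = ikir_weights(),
                                include_kir3dl2 = FALSE) {
  contrib <- .transmission_contrib(trios, genotype)
  stratum <- stratify(.child_scores(trios, weights, include_kir3dl2), threshold)
  agg <- function(s) c(T = sum(contrib$t[stratum == s]),
                       NT = sum(contrib$nt[stratum == s]))
  hi <- agg("high"); lo <- agg("low")
  out <- data.frame(stratum = c("high", "low"),
                    T = c(hi["T"], lo["T"]), NT = c(hi["NT"], lo["NT"]),
                    n_informative = c(hi["T"] + hi["NT"], lo["T"] + lo["NT"]),
                    row.names = NULL)
  attr(out, "n_uninformative") <- contrib$n_uninformative
  out
}

#' Cross-strata transmission difference statistic
#'
#' The difference between the (log) transmission odds in the two strata:
#' `D = log(T/NT)_high - log(T/NT)_low` (default), or the raw-ratio
#' difference `(T/NT)_high - (T/NT)_low`. Under iKIR modification of a
#' protective genotype, under-transmission is weaker in the high stratum,
#' so D > 0. When any cell is zero, 0.5 is added to all four cells and the
#' correction is recorded in attribute `continuity`.
#'
#' @param counts Output of [transmission_counts()].
#' @param form `"log"` (default) or `"raw"`.
#' @return The scalar statistic D.
#' @export
strata_difference_stat <- function(counts, form = c("log", "raw")) {
  form <- match.arg(form)
  hi <- counts[counts$stratum == "high", ]; lo <- counts[counts$stratum == "low", ]
  cells <- c(hi$T, hi$NT, lo$T, lo$NT)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  D <- if (form == "log") log(cells[1] / cells[2]) - log(cells[3] / cells[4])
       else cells[1] / cells[2] - cells[3] / cells[4]
  structure(D, continuity = corrected)
}

#' Permutation test of the stratified transmission difference
#'
#' Builds the null distribution of the (genotype-set aggregated) statistic
#' by permuting the affected children's iKIR scores across trios; parental
#' data never move, so under the null the stratum split is exchangeable.
#' Aggregation over several genotypes is the carriage-frequency-weighted
#' mean of the per-genotype statistic (weights: carriage among the
#' affected children), mirroring the case-control multi-genotype test; a
#' single genotype reduces to its own D. Add-one empirical p-value.
#'
#' @param trios `ikir_trios` data.frame.
#' @param genotypes Character vector of genotype labels.
#' @param threshold iKIR score threshold for the children.
#' @param n_perm Number of permutations.
#' @param direction `"greater"` (protective set: D > 0 expected) or
#'   `"two-sided"`.
#' @param form Statistic form, see [strata_difference_stat()].
#' @param seed Integer seed.
#' @param weights,include_kir3dl2 Score settings for the children.
#' @return An `ikir_perm` object (see [permutation_test()]).
#' @export
tdt_permutation_test <- function(trios, genotypes, threshold = 1.75,
                                 n_perm = 1e4,
                                 direction = c("greater", "two-sided"),
                                 form = "log", seed = 1L,
                                 weights = ikir_weights(),
                                 include_kir3dl2 = FALSE) {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  scores <- .child_scores(trios, weights, include_kir3dl2)
  stratum_high <- scores > threshold
  if (length(unique(stratum_high)) < 2)
    stop("need non-empty high and low strata")
  contribs <- lapply(genotypes, function(g) .transmission_contrib(trios, g))
  child <- trios_child_frame(trios)
  w <- colMeans(carriage_matrix(child, genotypes))
  if (any(w <= 0))
    stop("genotype(s) not carried by any child: ",
         paste(genotypes[w <= 0], collapse = ", "))
  stat_for <- function(high) {
    d <- vapply(contribs, function(ct) {
      hi_t <- sum(ct$t[high]); hi_nt <- sum(ct$nt[high])
      lo_t <- sum(ct$t[!high]); lo_nt <- sum(ct$nt[!high])
      cells <- c(hi_t, hi_nt, lo_t, lo_nt)
      if (any(cells == 0)) cells <- cells + 0.5
      if (form == "log") log(cells[1] / cells[2]) - log(cells[3] / cells[4])
      else cells[1] / cells[2] - cells[3] / cells[4]
    }, 0)
    sum(w * d) / sum(w)
  }
  obs <- stat_for(stratum_high)
  set.seed(seed)
  n <- nrow(trios)
  perm_stats <- vapply(seq_len(n_perm), function(b)
    stat_for(stratum_high[sample.int(n)]), 0)
  .perm_result(obs, perm_stats, direction, seed, n_perm, per_genotype = NULL)
}
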