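#' Load an iKIR-pair weight table
#'
#' Each functional iKIR-ligand gene pair contributes a weight to the iKIR
#' score, reflecting the strength of the receptor-ligand interaction. The
#' packaged default table (id `"ikirmod-default-1"`) was chosen so that the
#' commonly used stratification thresholds 1.5-2.5 fall inside the
#' attainable score range (0 to 3.25 with KIR3DL2 excluded); it is not a
#' claim about measured affinities and can be replaced by any TSV with
#' columns `kir`, `ligand`, `weight`. The table id is recorded in score
#' output so results are traceable to the weights used.
#'
#' @param path Optional path to a custom weight TSV.
#' @param id Identifier recorded with the table (defaults to the file name
#'   for custom tables).
#' @return A data.frame with columns `kir`, `ligand`, `weight` and
#'   attributes `id` and `threshold_default` (1.75).
#' @export
ikir_weights <- function(path = NULL, id = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ikir_weights_default.tsv", package = "ikirmod")
    if (is.null(id)) id <- "ikirmod-default-1"
  } else if (is.null(id)) id <- basename(path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kir", "ligand", "weight") %in% names(tab)))
  if (!all(is.finite(tab$weight)) || all(tab$weight <= 0))
    stop("weights must be finite with at least one positive entry")
  if (any(tab$weight < 0)) stop("weights must be >= 0")
  attr(tab, "id") <- id
  attr(tab, "threshold_default") <- 1.75
  tab
}

#' Identify functional iKIR-ligand gene pairs
#'
#' An iKIR gene is "functional" when the individual also carries the gene
#' encoding its HLA class I ligand: KIR2DL1 pairs with C2, KIR2DL2 and
#' KIR2DL3 each pair with C1, KIR3DL1 with Bw4 (the strongest motif present
#' is recorded), and, optionally, KIR3DL2 with A3/A11.
#'
#' @param kir_genes Character vector of carried KIR genes (subset of
#'   `KIR2DL1, KIR2DL2, KIR2DL3, KIR3DL1, KIR3DL2`).
#' @param ligands An `ikir_ligands` profile from [assign_ligands()].
#' @param include_kir3dl2 Should the KIR3DL2-A3/A11 pair count? Default
#'   `FALSE`.
#' @return A data.frame with columns `kir` and `ligand`, one row per
#'   functional pair (zero rows when none).
#' @export
functional_pairs <- function(kir_genes, ligands, include_kir3dl2 = FALSE) {
  stopifnot(inherits(ligands, "ikir_ligands"))
  bad <- setdiff(kir_genes, IKIR_GENES)
  if (length(bad)) stop("unknown KIR gene(s): ", paste(bad, collapse = ", "))
  kir <- character(0); lig <- character(0)
  add <- function(k, l) { kir <<- c(kir, k); lig <<- c(lig, l) }
  if ("KIR2DL1" %in% kir_genes && ligands$c2) add("KIR2DL1", "C2")
  if ("KIR2DL2" %in% kir_genes && ligands$c1) add("KIR2DL2", "C1")
  if ("KIR2DL3" %in% kir_genes && ligands$c1) add("KIR2DL3", "C1")
  if ("KIR3DL1" %in% kir_genes && ligands$bw4 != "absent") add("KIR3DL1", ligands$bw4)
  if (include_kir3dl2 && "KIR3DL2" %in% kir_genes && ligands$a3a11) add("KIR3DL2", "A3A11")
  data.frame(kir = kir, ligand = lig, stringsAsFactors = FALSE)
}

#' Compute the iKIR score from functional pairs
#'
#' The score is the sum of per-pair weights over the individual's
#' functional iKIR-ligand pairs; with all weights equal to 1 it reduces to
#' the functional iKIR count.
#'
#' @param pairs Data.frame from [functional_pairs()].
#' @param weights Weight table from [ikir_weights()].
#' @return A single non-negative number with attribute `weights_id`.
#' @export
ikir_score <- function(pairs, weights = ikir_weights()) {
  if (nrow(pairs) == 0) {
    return(structure(0, weights_id = attr(weights, "id")))
  }
  key <- paste(pairs$kir, pairs$ligand)
  wkey <- paste(weights$kir, weights$ligand)
  idx <- match(key, wkey)
  if (anyNA(idx))
    stop("no weight defined for pair(s): ", paste(key[is.na(idx)], collapse = ", "))
  structure(sum(weights$weight[idx]), weights_id = attr(weights, "id"))
}

#' Stratify iKIR scores into high and low groups
#'
#' Individuals with score less than or equal to the threshold are labelled
#' `"low"`, all others `"high"`; ties go to `"low"`.
#'
#' @param scores Numeric vector of iKIR scores.
#' @param threshold Stratification threshold (1.75 gives a balanced split
#'   under typical European gene frequencies; 1.5, 2.0 and 2.5 are common
#'   sensitivity choices).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
stratify <- function(scores, threshold = 1.75) {
  stopifnot(is.numeric(scores), length(threshold) == 1, is.finite(threshold))
  ifelse(scores <= threshold, "low", "high")
}

# Vectorised score from a logical KIR carriage matrix (columns IKIR_GENES)
# and a character matrix of class I alleles; shared by score_cohort and the
# generators.
.score_parts <- function(kirmat, class1, weights, table, include_kir3dl2) {
  grp <- matrix(table$group[match(class1, table$allele)], nrow = nrow(class1))
  has <- function(g) rowSums(grp == g, na.rm = TRUE) > 0
  bw4i <- has("Bw4-80I"); bw4t <- has("Bw4-80T")
  c1 <- has("C1"); c2 <- has("C2"); a3 <- has("A3A11")
  w <- function(k, l) {
    i <- which(weights$kir == k & weights$ligand == l)
    if (length(i)) weights$weight[i[1]] else 0
  }
  bw4w <- ifelse(bw4i, w("KIR3DL1", "Bw4-80I"), ifelse(bw4t, w("KIR3DL1", "Bw4-80T"), 0))
  score <- kirmat[, "KIR2DL1"] * c2 * w("KIR2DL1", "C2") +
    kirmat[, "KIR2DL2"] * c1 * w("KIR2DL2", "C1") +
    kirmat[, "KIR2DL3"] * c1 * w("KIR2DL3", "C1") +
    kirmat[, "KIR3DL1"] * bw4w
  if (include_kir3dl2)
    score <- score + kirmat[, "KIR3DL2"] * a3 * w("KIR3DL2", "A3A11")
  as.numeric(score)
}

# Maximum attainable score under a weight table: each KIR gene can
# contribute at most its best ligand weight (KIR2DL2 and KIR2DL3 count
# separately).
max_attainable_score <- function(weights = ikir_weights(), include_kir3dl2 = FALSE) {
  genes <- setdiff(unique(weights$kir), if (!include_kir3dl2) "KIR3DL2" else character(0))
  sum(vapply(genes, function(g) max(weights$weight[weights$kir == g]), 0))
}

#' Score every individual in a cohort
#'
#' Computes the ligand profile, functional pairs and iKIR score for each
#' row of a cohort table (see [read_cohort()] for the format) and returns
#' the cohort with `ikir_score` and `ikir_stratum` columns appended.
#'
#' @param cohort A cohort data.frame.
#' @param weights Weight table, see [ikir_weights()].
#' @param table Ligand lookup, see [ligand_table()].
#' @param threshold Stratification threshold.
#' @param include_kir3dl2 Include the KIR3DL2-A3/A11 pair in the score?
#' @return The cohort with columns `ikir_score`, `ikir_stratum` and
#'   attribute `weights_id`.
#' @export
score_cohort <- function(cohort, weights = ikir_weights(), table = ligand_table(),
                         threshold = 1.75, include_kir3dl2 = FALSE) {
  class1 <- as.matrix(cohort[, c("A1", "A2", "B1", "B2", "C1", "C2")])
  kirmat <- vapply(IKIR_GENES, function(g)
    grepl(g, cohort$kir_genes, fixed = TRUE), logical(nrow(cohort)))
  if (nrow(cohort) == 1) kirmat <- matrix(kirmat, nrow = 1, dimnames = list(NULL, IKIR_GENES))
  cohort$ikir_score <- .score_parts(kirmat, class1, weights, table, include_kir3dl2)
  cohort$ikir_stratum <- stratify(cohort$ikir_score, threshold)
  attr(cohort, "weights_id") <- attr(weights, "id")
  cohort
}
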