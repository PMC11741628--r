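#' Load the packaged allele-to-ligand lookup table
#'
#' HLA class I alleles are mapped to the broad KIR ligand groups: `Bw4-80I`
#' and `Bw4-80T` (HLA-B, plus the HLA-A Bw4 alleles), `C1`/`C2` (the HLA-C
#' position-80 dimorphism) and `A3A11` (HLA-A3/A11, the KIR3DL2 ligand
#' group). The table is an editable two-column TSV (`allele`, `group`)
#' shipped with the package; pass your own to any function that accepts a
#' `ligand_table` to override it.
#'
#' @param path Optional path to a custom TSV with columns `allele`, `group`.
#' @return A data.frame with columns `allele` and `group`.
#' @export
ligand_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kir_ligand_table.tsv", package = "ikirmod")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("allele", "group") %in% names(tab)))
  ok <- tab$group %in% c("Bw4-80I", "Bw4-80T", "C1", "C2", "A3A11")
  if (!all(ok)) stop("unknown ligand group(s): ", paste(unique(tab$group[!ok]), collapse = ", "))
  tab
}

#' Assign KIR ligand groups from HLA class I alleles
#'
#' Derives the individual's ligand profile from the allele labels alone:
#' Bw4 status (absent / `Bw4-80I` / `Bw4-80T`, with 80I taken as the
#' stronger motif when both are present), C1 and C2 carriage (which may both
#' be `TRUE` in HLA-C heterozygotes) and A3/A11 carriage.
#'
#' @param alleles Character vector of HLA-A/B/C allele labels
#'   (e.g. `"B*57:01"`). Order and duplicates are irrelevant.
#' @param table Allele-to-ligand lookup, see [ligand_table()].
#' @param unknown Policy for alleles at A/B/C loci that are absent from the
#'   lookup: `"no-ligand"` (default; the allele contributes no ligand) or
#'   `"error"`.
#' @return A list of class `ikir_ligands` with elements `bw4`
#'   (`"absent"`, `"Bw4-80I"` or `"Bw4-80T"`), `c1`, `c2`, `a3a11` (logical).
#' @examples
#' assign_ligands(c("B*57:01", "C*07:01", "C*04:01"))
#' @export
assign_ligands <- function(alleles, table = ligand_table(),
                           unknown = c("no-ligand", "error")) {
  unknown <- match.arg(unknown)
  alleles <- alleles[!is.na(alleles) & nzchar(alleles)]
  groups <- table$group[match(alleles, table$allele)]
  if (unknown == "error" && anyNA(groups)) {
    miss <- unique(alleles[is.na(groups)])
    stop("allele(s) not in ligand table: ", paste(miss, collapse = ", "))
  }
  groups <- groups[!is.na(groups)]
  bw4 <- if ("Bw4-80I" %in% groups) "Bw4-80I" else
    if ("Bw4-80T" %in% groups) "Bw4-80T" else "absent"
  structure(list(bw4 = bw4,
                 c1 = "C1" %in% groups,
                 c2 = "C2" %in% groups,
                 a3a11 = "A3A11" %in% groups),
            class = "ikir_ligands")
}

#' @export
print.ikir_ligands <- function(x, ...) {
  cat("KIR ligand profile: Bw4 =", x$bw4,
      "| C1 =", x$c1, "| C2 =", x$c2, "| A3/A11 =", x$a3a11, "\n")
  invisible(x)
}
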