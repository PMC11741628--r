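# Delimited-text I/O for cohort tables and PED-like trio files.

#' Write / read a cohort genotype table
#'
#' UTF-8 tab-delimited with the fixed column set `id, status (1 = case,
#' 0 = control), sex (F/M), kir_genes (semicolon-separated), A1, A2, B1,
#' B2, C1, C2, DRB1_1, DRB1_2, DQA1_1, DQA1_2, DQB1_1, DQB1_2, hap1, hap2`
#' (the last two optional phased class II haplotype strings, `~`-joined).
#' `read_cohort` validates the table and reports the offending line number
#' on malformed rows; the pair `write_cohort` / `read_cohort` round-trips
#' exactly.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(setdiff(COHORT_COLS, c("hap1", "hap2")), names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"hap1" %in% names(cohort)) cohort$hap1 <- ""
  if (!"hap2" %in% names(cohort)) cohort$hap2 <- ""
  utils::write.table(cohort[, COHORT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, COHORT_COLS))
    stop("line 1: unexpected header; expected columns ",
         paste(COHORT_COLS, collapse = ", "))
  n <- length(lines) - 1L
  if (n == 0) {
    out <- as.data.frame(matrix(character(0), 0, length(COHORT_COLS)),
                         stringsAsFactors = FALSE)
    names(out) <- COHORT_COLS
    out$status <- integer(0)
    return(out)
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty hap2 field is dropped by strsplit; restore it
  fields[nf == length(COHORT_COLS) - 1L] <-
    lapply(fields[nf == length(COHORT_COLS) - 1L], function(f) c(f, ""))
  nf <- lengths(fields)
  bad <- which(nf != length(COHORT_COLS))
  if (length(bad))
    stop("line ", bad[1] + 1L, ": expected ", length(COHORT_COLS),
         " fields, found ", nf[bad[1]])
  m <- do.call(rbind, fields)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- COHORT_COLS
  badst <- which(!out$status %in% c("0", "1"))
  if (length(badst))
    stop("line ", badst[1] + 1L, ": status must be 0 or 1, found '",
         out$status[badst[1]], "'")
  out$status <- as.integer(out$status)
  badsex <- which(!out$sex %in% c("F", "M"))
  if (length(badsex))
    stop("line ", badsex[1] + 1L, ": sex must be F or M")
  # more than 2 alleles at a locus shows up as a separator inside a cell
  for (col in c(CLASS1_COLS, CLASS2_COLS)) {
    badal <- which(grepl("[;,/ ]", out[[col]]))
    if (length(badal))
      stop("line ", badal[1] + 1L, ": more than one allele in column ", col,
           " (at most 2 alleles per locus)")
  }
  dup <- which(duplicated(out$id))
  if (length(dup)) stop("line ", dup[1] + 1L, ": duplicate id '", out$id[dup[1]], "'")
  out
}

#' Write / read trios in a PED-like table
#'
#' One row per person (`family_id, person_id, father_id, mother_id,
#' sex (F/M), affected (1/0)`) followed by the genotype columns of the
#' cohort format. Children carry their paternal haplotype in `hap1` and
#' maternal haplotype in `hap2`; on reading, each parent's transmitted
#' haplotype is recovered by matching (homozygous parents are assigned
#' index 1 — they are uninformative for transmission either way).
#'
#' @param trios `ikir_trios` data.frame from [generate_trios()].
#' @param path File path.
#' @return `read_trios` returns an `ikir_trios` data.frame; `write_trios`
#'   returns `path` invisibly.
#' @export
write_trios <- function(trios, path) {
  stopifnot(inherits(trios, "ikir_trios"))
  blank1 <- function(n) rep("", n)
  n <- nrow(trios)
  person <- function(pid, fid, mid, sex, aff, kir, A1, A2, B1, B2, C1, C2,
                     hap1, hap2) {
    sp <- function(s, i) vapply(strsplit(s, "~", fixed = TRUE),
                                function(x) if (length(x) >= i) x[i] else "", "")
    data.frame(family_id = trios$family_id, person_id = pid, father_id = fid,
               mother_id = mid, sex = sex, affected = aff, kir_genes = kir,
               A1 = A1, A2 = A2, B1 = B1, B2 = B2, C1 = C1, C2 = C2,
               DRB1_1 = sp(hap1, 1), DRB1_2 = sp(hap2, 1),
               DQA1_1 = sp(hap1, 2), DQA1_2 = sp(hap2, 2),
               DQB1_1 = sp(hap1, 3), DQB1_2 = sp(hap2, 3),
               hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
  }
  fid <- paste0(trios$family_id, "_F"); mid <- paste0(trios$family_id, "_M")
  cid <- paste0(trios$family_id, "_C")
  out <- rbind(
    person(fid, blank1(n), blank1(n), "M", 0L, blank1(n),
           blank1(n), blank1(n), blank1(n), blank1(n), blank1(n), blank1(n),
           trios$father_hap1, trios$father_hap2),
    person(mid, blank1(n), blank1(n), "F", 0L, blank1(n),
           blank1(n), blank1(n), blank1(n), blank1(n), blank1(n), blank1(n),
           trios$mother_hap1, trios$mother_hap2),
    person(cid, fid, mid, trios$child_sex, 1L, trios$child_kir_genes,
           trios$child_A1, trios$child_A2, trios$child_B1, trios$child_B2,
           trios$child_C1, trios$child_C2, trios$child_hap1, trios$child_hap2))
  out <- out[order(out$family_id, out$person_id), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trios
#' @export
read_trios <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  ped$affected <- as.integer(ped$affected)
  kids <- ped[ped$affected == 1L & nzchar(ped$father_id), ]
  if (nrow(kids) == 0) stop("no affected children with named parents in ", path)
  match_parent <- function(pid) ped[match(pid, ped$person_id), ]
  fa <- match_parent(kids$father_id); mo <- match_parent(kids$mother_id)
  if (anyNA(fa$person_id) || anyNA(mo$person_id))
    stop("parent id(s) missing from file: ", path)
  which_hap <- function(parent_h1, parent_h2, child_h)
    ifelse(child_h == parent_h1, 1L, ifelse(child_h == parent_h2, 2L, NA_integer_))
  ft <- which_hap(fa$hap1, fa$hap2, kids$hap1)
  mt <- which_hap(mo$hap1, mo$hap2, kids$hap2)
  if (anyNA(ft) || anyNA(mt))
    stop("child haplotype not found in parental haplotypes (family ",
         kids$family_id[which(is.na(ft) | is.na(mt))[1]], ")")
  out <- data.frame(
    family_id = kids$family_id,
    father_hap1 = fa$hap1, father_hap2 = fa$hap2, father_transmitted = ft,
    mother_hap1 = mo$hap1, mother_hap2 = mo$hap2, mother_transmitted = mt,
    child_sex = kids$sex, child_kir_genes = kids$kir_genes,
    child_A1 = kids$A1, child_A2 = kids$A2, child_B1 = kids$B1,
    child_B2 = kids$B2, child_C1 = kids$C1, child_C2 = kids$C2,
    child_hap1 = kids$hap1, child_hap2 = kids$hap2,
    stringsAsFactors = FALSE)
  class(out) <- c("ikir_trios", "data.frame")
  out
}
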