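# Shared fixtures, built in code.

DQ6 <- "DQA1*01:02-DQB1*06:02"
PROT_SET <- c(DQ6, "DQB1*03:01", "DQA1*02:01", "DQA1*01:02")

# null configuration: no genotype, interaction or sex effects
null_config <- function(n_cases = 500, n_controls = 500, seed = 1L, ...) {
  cohort_config(n_cases = n_cases, n_controls = n_controls,
                effect_lnors = c("DQA1*01:02-DQB1*06:02" = 0),
                interaction_beta = 0, sex_lnor = 0, seed = seed, ...)
}

# a tiny deterministic cohort data.frame built by hand
toy_cohort <- function() {
  data.frame(
    id = paste0("T", 1:8),
    status = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    sex = rep(c("F", "M"), 4),
    kir_genes = c("KIR2DL1;KIR2DL3;KIR3DL1", "KIR2DL1", "KIR2DL2;KIR2DL3",
                  "KIR2DL1;KIR2DL2;KIR2DL3;KIR3DL1;KIR3DL2", "KIR3DL1",
                  "KIR2DL1;KIR2DL3", "KIR2DL3;KIR3DL1", ""),
    A1 = c("A*01:01", "A*24:02", "A*03:01", "A*02:01",
           "A*11:01", "A*24:02", "A*01:01", "A*02:01"),
    A2 = c("A*02:01", "A*02:01", "A*03:01", "A*32:01",
           "A*01:01", "A*23:01", "A*68:01", "A*29:02"),
    B1 = c("B*57:01", "B*07:02", "B*08:01", "B*44:02",
           "B*07:02", "B*08:01", "B*51:01", "B*35:01"),
    B2 = c("B*08:01", "B*15:01", "B*27:05", "B*40:01",
           "B*18:01", "B*44:03", "B*07:02", "B*55:01"),
    C1 = c("C*07:01", "C*07:02", "C*04:01", "C*05:01",
           "C*01:02", "C*06:02", "C*07:01", "C*03:04"),
    C2 = c("C*06:02", "C*07:01", "C*07:02", "C*04:01",
           "C*07:02", "C*07:01", "C*12:03", "C*04:01"),
    DRB1_1 = c("DRB1*15:01", "DRB1*03:01", "DRB1*04:01", "DRB1*07:01",
               "DRB1*15:01", "DRB1*11:01", "DRB1*01:01", "DRB1*13:01"),
    DRB1_2 = c("DRB1*03:01", "DRB1*07:01", "DRB1*04:01", "DRB1*01:01",
               "DRB1*15:01", "DRB1*03:01", "DRB1*08:01", "DRB1*11:01"),
    DQA1_1 = c("DQA1*01:02", "DQA1*05:01", "DQA1*03:01", "DQA1*02:01",
               "DQA1*01:02", "DQA1*05:05", "DQA1*01:01", "DQA1*01:03"),
    DQA1_2 = c("DQA1*05:01", "DQA1*02:01", "DQA1*03:01", "DQA1*01:01",
               "DQA1*01:02", "DQA1*05:01", "DQA1*04:01", "DQA1*05:05"),
    DQB1_1 = c("DQB1*06:02", "DQB1*02:01", "DQB1*03:02", "DQB1*02:02",
               "DQB1*06:02", "DQB1*03:01", "DQB1*05:01", "DQB1*06:03"),
    DQB1_2 = c("DQB1*02:01", "DQB1*02:02", "DQB1*03:02", "DQB1*05:01",
               "DQB1*06:02", "DQB1*02:01", "DQB1*04:02", "DQB1*03:01"),
    hap1 = c("DRB1*15:01~DQA1*01:02~DQB1*06:02", "DRB1*03:01~DQA1*05:01~DQB1*02:01",
             "DRB1*04:01~DQA1*03:01~DQB1*03:02", "DRB1*07:01~DQA1*02:01~DQB1*02:02",
             "DRB1*15:01~DQA1*01:02~DQB1*06:02", "DRB1*11:01~DQA1*05:05~DQB1*03:01",
             "DRB1*01:01~DQA1*01:01~DQB1*05:01", "DRB1*13:01~DQA1*01:03~DQB1*06:03"),
    hap2 = c("DRB1*03:01~DQA1*05:01~DQB1*02:01", "DRB1*07:01~DQA1*02:01~DQB1*02:02",
             "DRB1*04:01~DQA1*03:01~DQB1*03:02", "DRB1*01:01~DQA1*01:01~DQB1*05:01",
             "DRB1*15:01~DQA1*01:02~DQB1*06:02", "DRB1*03:01~DQA1*05:01~DQB1*02:01",
             "DRB1*08:01~DQA1*04:01~DQB1*04:02", "DRB1*11:01~DQA1*05:05~DQB1*03:01"),
    stringsAsFactors = FALSE)
}

# four hand-built trios for manual transmission counting.
# haplotypes: P = DQ6-bearing, N1/N2 = non-bearing
hand_trios <- function() {
  P <- "DRB1*15:01~DQA1*01:02~DQB1*06:02"
  N1 <- "DRB1*03:01~DQA1*05:01~DQB1*02:01"
  N2 <- "DRB1*07:01~DQA1*02:01~DQB1*02:02"
  kir_hi <- "KIR2DL1;KIR2DL2;KIR2DL3;KIR3DL1"  # score 3.25 with full ligands
  kir_lo <- ""                                  # score 0
  tr <- data.frame(
    family_id = c("F1", "F2", "F3", "F4"),
    # F1: father P/N1 transmits P; mother N1/N2 transmits N1 (informative father T)
    # F2: father P/N1 transmits N1 (father NT); mother P/P uninformative
    # F3: both parents N1/N2: uninformative for DQ6
    # F4: father P/N2 transmits P; mother P/N1 transmits N1 (T and NT)
    father_hap1 = c(P, P, N1, P), father_hap2 = c(N1, N1, N2, N2),
    father_transmitted = c(1L, 2L, 1L, 1L),
    mother_hap1 = c(N1, P, N1, P), mother_hap2 = c(N2, P, N2, N1),
    mother_transmitted = c(1L, 1L, 2L, 2L),
    child_sex = c("F", "M", "F", "M"),
    child_kir_genes = c(kir_hi, kir_lo, kir_hi, kir_lo),
    child_A1 = "A*01:01", child_A2 = "A*24:02",
    child_B1 = "B*57:01", child_B2 = "B*07:02",
    child_C1 = "C*07:01", child_C2 = "C*04:01",
    stringsAsFactors = FALSE)
  tr$child_hap1 <- with(tr, ifelse(father_transmitted == 1, father_hap1, father_hap2))
  tr$child_hap2 <- with(tr, ifelse(mother_transmitted == 1, mother_hap1, mother_hap2))
  class(tr) <- c("ikir_trios", "data.frame")
  tr
}
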