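# Shared column sets and gene lists (file sorts first so these exist when
# later files evaluate top-level code).

IKIR_GENES <- c("KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR3DL1", "KIR3DL2")

CLASS1_COLS <- c("A1", "A2", "B1", "B2", "C1", "C2")
CLASS2_COLS <- c("DRB1_1", "DRB1_2", "DQA1_1", "DQA1_2", "DQB1_1", "DQB1_2")

COHORT_COLS <- c("id", "status", "sex", "kir_genes", CLASS1_COLS, CLASS2_COLS,
                 "hap1", "hap2")
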