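# Shipped signature gene lists.
#
# "CD8 T cells": the published marker list kept verbatim, including its two
# printed duplicates (DNAJB1, ZFP36L2) which gene_signature() collapses, and
# its legacy identifiers (C4orf15, C19orf6, SFRS7, MYST3, AES, C12orf47...),
# which are deliberately not updated: scoring is exact identifier matching
# against the user's matrix and silent symbol modernization would change
# scores unreproducibly.
#
# "CAF": the 8 MCP-counter fibroblast population markers.
#
# The remaining 23 immune-cell lists are synthetic reconstructions from
# standard marker-gene knowledge (the original curated lists are not shipped
# here); users wanting the exact published lists should load them from GMT.

.builtin_signature_genes <- list(
  "B cells" = c("CD19", "MS4A1", "CD79A", "CD79B", "BLK", "CR2", "TNFRSF13B",
                "IGHM", "BLNK", "FCRL2", "PAX5", "TCL1A"),
  "T cells" = c("CD2", "CD3D", "CD3E", "CD3G", "CD6", "TRAT1", "ITM2A",
                "SH2D1A", "LCK", "TRBC1", "CD28"),
  "CD8 T cells" = c("DNAJB1", "DNAJB1", "ZFP36L2", "ZFP36L2", "VAMP2",
                    "PPP1R2", "TBCC", "LEPROTL1", "CAMLG", "KLF9", "GADD45A",
                    "CD8A", "ZNF91", "PF4", "THUMPD1", "TSC22D3", "SLC16A7",
                    "GZMM", "ZEB1", "RBM3", "APBA2", "C4orf15", "SF1",
                    "FLT3LG", "C19orf6", "ZNF609", "SFRS7", "PRF1", "TMC6",
                    "MYST3", "AES", "ZNF22", "ABT1", "CDKN2AIP", "ARHGAP8",
                    "LIME1", "PRR5", "C12orf47"),
  "T helper cells" = c("CD4", "ICOS", "CD28", "ANP32E", "BATF", "NUP107",
                       "FRYL", "GOLGA8A", "SEC24C", "UBE2L3"),
  "Tcm" = c("CCR7", "SELL", "IL7R", "TCF7", "LEF1", "CD27", "BCL2", "MAL",
            "NELL2", "FOXP1"),
  "Tem" = c("GZMK", "KLRG1", "CCL5", "EOMES", "CXCR4", "FAS", "IL2RB",
            "PRDM1", "TRA", "DDX17"),
  "TFH" = c("CXCL13", "CXCR5", "BCL6", "PDCD1", "ICOS", "IL21", "MAF",
            "SH2D1A", "TOX2", "CD200"),
  "Tgd" = c("TRGV9", "TRDV2", "TRGC1", "TRGC2", "TRDC", "CD160", "NR4A2",
            "FEZ1", "TARP"),
  "Th1" = c("IFNG", "TBX21", "STAT4", "IL12RB2", "CXCR3", "CCR5", "IL2",
            "LTA", "HAVCR2", "CSF2"),
  "Th2" = c("GATA3", "IL4", "IL5", "IL13", "CCR4", "STAT6", "PTGDR2",
            "IL17RB", "PMCH", "LAIR2"),
  "Th17" = c("IL17A", "IL17F", "RORC", "RORA", "CCR6", "IL21", "IL22",
             "IL23R", "STAT3"),
  "Treg" = c("FOXP3", "IL2RA", "CTLA4", "IKZF2", "TNFRSF18", "CCR8", "TIGIT",
             "FANK1", "LRRC32"),
  "Cytotoxic cells" = c("GZMA", "GZMB", "GZMH", "PRF1", "KLRB1", "KLRD1",
                        "KLRK1", "NKG7", "CTSW", "GNLY", "APOL3"),
  "NK cells" = c("NCR1", "KIR2DL1", "KIR2DL3", "KIR3DL1", "XCL1", "XCL2",
                 "NCR3", "KLRF1", "SPON2", "PSMD4"),
  "NK CD56dim cells" = c("KIR2DS1", "KIR2DS2", "KIR2DS5", "KIR3DS1", "S1PR5",
                         "FGFBP2", "GTF3C1", "IL21R", "TTC38"),
  "NK CD56bright cells" = c("NCAM1", "XCL1", "KLRC1", "GZMK", "SELL",
                            "DUSP4", "FOXJ1", "MADD", "MPPED1", "PLA2G6"),
  "DC" = c("CD1C", "CD1E", "CLEC10A", "FCER1A", "ITGAX", "HLA-DQA1",
           "HLA-DPB1", "CCL13", "CCL17", "NPR1"),
  "aDC" = c("LAMP3", "CCL22", "CD83", "CCR7", "FSCN1", "IDO1", "EBI3",
            "OAS3"),
  "iDC" = c("CD1A", "CD1B", "CD207", "MMP12", "F13A1", "SYT17", "PPARG",
            "CH25H", "GPAT3"),
  "pDC" = c("CLEC4C", "IL3RA", "LILRA4", "IRF7", "PLD4", "SERPINF1", "TCF4",
            "GZMB", "MAP1A"),
  "Eosinophils" = c("SIGLEC8", "CCR3", "IL5RA", "PRG2", "EPX", "CLC",
                    "RNASE2", "RNASE3", "EMR1", "HES1"),
  "Macrophages" = c("CD68", "CD163", "MSR1", "MRC1", "CSF1R", "MARCO",
                    "VSIG4", "C1QA", "C1QB", "APOE", "CHIT1"),
  "Mast cells" = c("TPSAB1", "TPSB2", "CPA3", "MS4A2", "KIT", "CMA1", "HDC",
                   "GATA2", "SLC18A2"),
  "Neutrophils" = c("FCGR3B", "CSF3R", "CXCR2", "CXCR1", "FPR1", "S100A12",
                    "CEACAM3", "SIGLEC5", "TNFRSF10C", "KCNJ15"),
  "CAF" = c("COL1A1", "COL3A1", "COL6A1", "COL6A2", "DCN", "GREM1", "PAMR1",
            "TAGLN")
)
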