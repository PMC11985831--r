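#' The bundled 40-gene pyroptosis panel
#'
#' Inflammasome sensors (AIM2, NLRP1, NLRP3, NLRC4, NAIP, NLRP9, ZBP1),
#' caspases, gasdermins, ESCRT-III / CHMP membrane-repair genes, granzymes,
#' interferon regulatory factors and associated regulators used throughout
#' the pipeline as the default gene universe for subtype discovery and
#' rank-pair classification.
#'
#' @return Character vector of 40 HGNC gene symbols in panel order.
#' @export
pyroptosis_panel <- function() {
  c("AIM2", "APIP", "BAK1", "BAX", "CASP1", "CASP3", "CASP4", "CASP5",
    "CASP6", "CASP8", "CHMP2A", "CHMP2B", "CHMP3", "CHMP4A", "CHMP4B",
    "CHMP4C", "CHMP7", "DHX9", "ELANE", "GSDMA", "GSDMB", "GSDMC",
    "GSDMD", "GSDME", "GZMA", "GZMB", "IL18", "IL1A", "IL1B", "IRF1",
    "IRF2", "NAIP", "NLRC4", "NLRP1", "NLRP3", "NLRP9", "PYCARD",
    "SCAF11", "TP53", "ZBP1")
}

#' Default differential signature between the two pyroptosis patterns
#'
#' The 19-gene signature separating the ELANE-high (C1) and ELANE-low (C2)
#' patterns: 16 genes up-regulated in C2 and 3 in C1. Used as the implanted
#' truth by the synthetic cohort generator.
#'
#' @return Named list with character vectors `up_c2` (16 genes) and
#'   `up_c1` (3 genes).
#' @export
subtype_signature <- function() {
  list(
    up_c2 = c("AIM2", "CASP1", "GSDMA", "GZMA", "GZMB", "NLRC4", "NLRP1",
              "ZBP1", "CASP5", "CHMP2B", "CHMP3", "CHMP4A", "CHMP4C",
              "CHMP7", "IRF1", "IRF2"),
    up_c1 = c("GSDMC", "ELANE", "TP53")
  )
}
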