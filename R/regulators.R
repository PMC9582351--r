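#' The 24-gene DNA methylation regulator panel
#'
#' The curated panel of DNA methylation regulators used as the feature space
#' for pattern discovery: 3 writers (the DNA methyltransferases that deposit
#' 5-methylcytosine), 3 erasers (the TET dioxygenases that remove it), and
#' 18 readers (methyl-CpG binding and associated proteins).
#'
#' @return A data.frame with columns `symbol` and `category`
#'   (`writer`/`eraser`/`reader`), 24 rows.
#' @export
#' @examples
#' table(regulator_set()$category)
regulator_set <- function() {
  writers <- c("DNMT1", "DNMT3A", "DNMT3B")
  erasers <- c("TET1", "TET2", "TET3")
  readers <- c("MBD1", "MBD2", "MBD3", "MBD4", "ZBTB33", "ZBTB38", "ZBTB4",
               "ZBTB24", "UHRF1", "UHRF2", "MECP2", "UNG", "TDG", "NTHL1",
               "SMUG1", "NSUN2", "MGMT", "DMAP1")
  data.frame(
    symbol = c(writers, erasers, readers),
    category = rep(c("writer", "eraser", "reader"),
                   times = c(length(writers), length(erasers), length(readers))),
    stringsAsFactors = FALSE
  )
}

#' Names of the 28 tumor microenvironment cell-type signatures
#'
#' The standard panel of 28 immune cell types scored by ssGSEA to
#' characterize tumor microenvironment infiltration. Only the names are
#' fixed here; member genes come from a user GMT or, for testing, from the
#' synthetic generator's planted signature blocks.
#'
#' @return Character vector of 28 cell-type names.
#' @export
tme_cell_types <- function() {
  c("Activated B cell", "Activated CD4 T cell", "Activated CD8 T cell",
    "Central memory CD4 T cell", "Central memory CD8 T cell",
    "Effector memory CD4 T cell", "Effector memory CD8 T cell",
    "Gamma delta T cell", "Immature B cell", "Memory B cell",
    "Regulatory T cell", "T follicular helper cell", "Type 1 T helper cell",
    "Type 17 T helper cell", "Type 2 T helper cell",
    "Activated dendritic cell", "CD56bright natural killer cell",
    "CD56dim natural killer cell", "Eosinophil", "Immature dendritic cell",
    "Macrophage", "Mast cell", "MDSC", "Monocyte", "Natural killer cell",
    "Natural killer T cell", "Neutrophil", "Plasmacytoid dendritic cell")
}

# Adaptive/cytotoxic cell types expected to track the immune-inflamed
# pattern; innate types track the immune-excluded pattern.
.adaptive_cell_types <- function() {
  c("Activated B cell", "Activated CD4 T cell", "Activated CD8 T cell",
    "Central memory CD4 T cell", "Central memory CD8 T cell",
    "Effector memory CD4 T cell", "Effector memory CD8 T cell",
    "T follicular helper cell", "Type 1 T helper cell",
    "Natural killer T cell", "Activated dendritic cell")
}

.innate_cell_types <- function() {
  c("Eosinophil", "Mast cell", "Plasmacytoid dendritic cell", "Monocyte",
    "Macrophage", "Neutrophil", "MDSC", "Immature dendritic cell")
}

#' Names of the 18 immune/stromal process signatures
#'
#' The classical panel of tumor biology process signatures (CD8 T effector,
#' DNA damage repair, antigen-processing machinery, immune checkpoint,
#' TGF-beta response, EMT, cell cycle, DNA repair pathways, ...) used for
#' single-sample pathway scoring of strata.
#'
#' @return Character vector of 18 signature names.
#' @export
process_signature_names <- function() {
  c("CD8 T effector", "DNA damage repair", "Antigen processing machinery",
    "Immune checkpoint", "Cell cycle regulators", "Fanconi anemia",
    "Pan-F-TBRS", "EMT1", "EMT2", "EMT3", "WNT targets", "FGFR3 related",
    "Cell cycle", "Mismatch repair", "Homologous recombination",
    "Nucleotide excision repair", "DNA replication", "Base excision repair")
}
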