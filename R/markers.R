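#' Built-in marker panels
#'
#' The marker gene panels used to annotate cell clusters, as mouse gene
#' symbols (case-sensitive; human panels use upper-case symbols).
#' Panels:
#' \describe{
#'   \item{epithelial}{Krt7, Krt8, Krt18, Krt19, Epcam, Egfr, Cdh1 — the
#'     classical epithelial tumor-cell markers.}
#'   \item{hematopoietic}{Ptprc (Cd45), Csf3r (Cd114), Cd14, Fcgr3 (Cd16),
#'     Itga2b (Cd41), Itgb3 (Cd61).}
#'   \item{endothelial}{Cdh5 (Cd144), Vwf, Thbd (Cd141), Pecam1 (Cd31),
#'     Mcam (Cd146), Sele (E-selectin), Cd34.}
#'   \item{platelet}{Itga2b, Itgb3 plus the platelet-specific transcripts
#'     Pf4 and Ppbp; used to flag platelet-adhered CTCs.}
#'   \item{proliferation}{Mki67.}
#'   \item{stem}{Aldh1a1, Aldh1a2, Prom1 (Cd133), Cd44, Met, Epcam.}
#'   \item{mesenchymal}{Cdh11, Vim, S100a4, Itga5, Sdc1.}
#'   \item{emt_epithelial}{Cdh1, Muc1 — the epithelial genes lost during
#'     epithelial-to-mesenchymal transition.}
#'   \item{ecm_mouse}{Dcn, Sparc, Ccdc80, Col1a2, Col3a1, Timp2 — the
#'     stromal extracellular-matrix genes screened in mouse CTCs.}
#'   \item{ctc_enriched}{Klf4, Igfbp5, Dcn — the highly CTC-enriched
#'     transcript trio.}
#'   \item{ecm_human_core}{SPARC, MGP, SPON2 — core-matrisome ECM
#'     glycoproteins screened in human CTCs. The full human candidate list
#'     is user-supplied; only these three are built in.}
#'   \item{housekeeping}{Gapdh, Actb — the RNA-quality screen genes.}
#' }
#'
#' @return a \linkS4class{GeneSetList}.
#' @examples
#' markerPanels()[["endothelial"]]
#' @export
markerPanels <- function() {
  GeneSetList(list(
    epithelial   = c("Krt7", "Krt8", "Krt18", "Krt19", "Epcam", "Egfr", "Cdh1"),
    hematopoietic = c("Ptprc", "Csf3r", "Cd14", "Fcgr3", "Itga2b", "Itgb3"),
    endothelial  = c("Cdh5", "Vwf", "Thbd", "Pecam1", "Mcam", "Sele", "Cd34"),
    platelet     = c("Itga2b", "Itgb3", "Pf4", "Ppbp"),
    proliferation = "Mki67",
    stem         = c("Aldh1a1", "Aldh1a2", "Prom1", "Cd44", "Met", "Epcam"),
    mesenchymal  = c("Cdh11", "Vim", "S100a4", "Itga5", "Sdc1"),
    emt_epithelial = c("Cdh1", "Muc1"),
    ecm_mouse    = c("Dcn", "Sparc", "Ccdc80", "Col1a2", "Col3a1", "Timp2"),
    ctc_enriched = c("Klf4", "Igfbp5", "Dcn"),
    ecm_human_core = c("SPARC", "MGP", "SPON2"),
    housekeeping = c("Gapdh", "Actb")
  ), provenance = "built-in marker panel")
}

#' Annotated platelet transcripts
#'
#' The gene set used for digital removal of platelet-derived transcripts
#' from platelet-adhered CTC profiles. In the synthetic cohort this is the
#' platelet marker panel plus the simulated platelet transcript module
#' (\code{plt_*} gene ids); with real data, supply an annotation-derived
#' list instead.
#'
#' @param nModule number of simulated \code{plt_*} module transcripts to
#'   include (matches the generator default).
#' @return character vector of gene ids.
#' @export
plateletTranscripts <- function(nModule = 21L) {
  c("Itga2b", "Itgb3", "Pf4", "Ppbp",
    if (nModule > 0L) sprintf("plt_%02d", seq_len(nModule)))
}
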